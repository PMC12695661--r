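# Synthetic-data generator. Produces miniature genomes with known ground
# truth: gene models on both strands, negative-binomial replicate counts
# with planted per-gene fold changes spanning the class taxonomy, library
# size factors, strand-specific fragments, CTCF/RAD21 peaks with summits,
# heights and oriented motif instances, and Pol II / ATAC signal with
# planted confounders. Every stage derives its own seed from the config
# seed, so identical configs give identical output.

#' Default regulation-class spectrum for the simulator
#'
#' Mass is concentrated in unchanged genes with a down-biased tail of
#' regulated genes (most regulated genes in the weak/intermediate down
#' classes), emulating the asymmetric, modest-effect regulation seen after
#' acute depletion of an architectural factor. Fold-change ranges are
#' linear and >= 1; direction is encoded by the class label.
#'
#' @return Named list: each element has `fraction` and `fc_range`.
#' @export
default_class_spectrum <- function() {
  list(
    NC = list(fraction = 0.90, fc_range = c(1, 1)),
    SD = list(fraction = 0.035, fc_range = c(1.32, 1.48)),
    ID = list(fraction = 0.025, fc_range = c(1.55, 1.95)),
    HD = list(fraction = 0.012, fc_range = c(2.1, 4)),
    SU = list(fraction = 0.014, fc_range = c(1.32, 1.48)),
    IU = list(fraction = 0.009, fc_range = c(1.55, 1.95)),
    HU = list(fraction = 0.005, fc_range = c(2.1, 4))
  )
}

#' Simulation configuration
#'
#' All knobs of the synthetic-data generator with defaults describing a
#' small but realistic perturbation experiment: a few hundred genes on two
#' chromosomes, negative-binomial counts with moderate biological
#' dispersion, 2 initial + 12 additional replicate pairs, 30-min labeling
#' (30 kb counting cap), CTCF peaks upstream-biased at ~-79 bp from the
#' TSS, and small planted antisense / Pol II / ATAC effects.
#'
#' @param n_genes,n_chromosomes,chrom_length genome-in-miniature geometry.
#' @param class_spectrum see [default_class_spectrum()]; fractions must sum
#'   to 1 and fold-change ranges must be >= 1.
#' @param global_asymmetry_fc linear factor multiplying every gene's
#'   treatment mean: a global composition/library confounder that the
#'   asymmetry correction must remove.
#' @param nb_mean_range range of expected control counts per gene
#'   (log-uniform draw).
#' @param nb_dispersion shared negative-binomial dispersion (> 0; the NB
#'   size parameter is `1/nb_dispersion`; values below 1e-8 fall back to
#'   Poisson).
#' @param size_factor_range per-sample multiplicative library factors
#'   (uniform draw).
#' @param n_replicates_initial,n_replicates_extra control/treatment pairs in
#'   the initial experiment and in the additional reproducibility series.
#' @param labeling_minutes treatment duration selecting the counting cap;
#'   one of 30, 60, 120, 240 (240 uses the full gene span).
#' @param peak_placement list: `fraction` of genes with a CTCF peak,
#'   summit `offset_mean`/`offset_sd`/`offset_max` (bp, gene-strand
#'   relative, negative = upstream), `height_range` (log-uniform),
#'   `orientation_probs` over forward/reverse/both/none, `rad21_fraction`
#'   of CTCF peaks with a paired RAD21 peak and `rad21_ratio_range`.
#' @param uastrx list: `fraction` of genes with planted upstream antisense
#'   upregulation, their `fc_range`, and the antisense `mean_range`
#'   (non-flagged genes get mean `background_mean`, below the antisense
#'   low-count filter).
#' @param polii list: `confounder` (global treatment library scale the
#'   anchored normalization must remove), `promoter_mean`, `body_mean`,
#'   and `uastrx_promoter_fc` (promoter-only Pol II gain at uasTrx genes).
#' @param atac list: `n_extra_peaks` without CTCF, `loss_fraction` /
#'   `gain_fraction` of all peaks with planted >= 2-fold changes,
#'   `loss_fc_range`, `mean_range`.
#' @param fragment_length fragment length in bp for BED emission.
#' @param gene_length_range,min_upstream_gap gene placement geometry (bp).
#' @param seed integer master seed; stage seeds are derived from it.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 300,
                              n_chromosomes = 2,
                              chrom_length = 1e7,
                              class_spectrum = default_class_spectrum(),
                              global_asymmetry_fc = 1,
                              nb_mean_range = c(50, 2000),
                              nb_dispersion = 0.02,
                              size_factor_range = c(0.7, 1.4),
                              n_replicates_initial = 2,
                              n_replicates_extra = 12,
                              labeling_minutes = 30,
                              peak_placement = list(),
                              uastrx = list(),
                              polii = list(),
                              atac = list(),
                              fragment_length = 100,
                              gene_length_range = c(2000, 80000),
                              min_upstream_gap = 5000,
                              seed = 1) {
  peak_placement <- modifyList(list(
    fraction = 0.4, offset_mean = -79, offset_sd = 120, offset_max = 400,
    height_range = c(5, 100),
    orientation_probs = c(forward = 0.5, reverse = 0.2, both = 0.1,
                          none = 0.2),
    rad21_fraction = 0.8, rad21_ratio_range = c(0.2, 1.5)
  ), peak_placement)
  uastrx <- modifyList(list(fraction = 0.05, fc_range = c(2.5, 6),
                            mean_range = c(15, 80), background_mean = 3),
                       uastrx)
  polii <- modifyList(list(confounder = 2, promoter_mean = 500,
                           body_mean = 1000, uastrx_promoter_fc = 2),
                      polii)
  atac <- modifyList(list(n_extra_peaks = 200, loss_fraction = 0.064,
                          gain_fraction = 0.0003,
                          loss_fc_range = c(2.2, 6),
                          mean_range = c(100, 1000)), atac)

  fr <- vapply(class_spectrum, function(x) x$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("class_spectrum fractions must sum to 1 (got ", sum(fr), ")")
  }
  for (cl in names(class_spectrum)) {
    if (any(class_spectrum[[cl]]$fc_range < 1)) {
      stop("fc_range for class ", cl, " must be >= 1 (direction is ",
           "encoded by the label)")
    }
  }
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (!labeling_minutes %in% c(30, 60, 120, 240)) {
    stop("labeling_minutes must be one of 30, 60, 120, 240")
  }
  if (n_genes < 0 || n_chromosomes < 1) stop("invalid genome geometry")

  cfg <- list(
    n_genes = as.integer(n_genes), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = chrom_length, class_spectrum = class_spectrum,
    global_asymmetry_fc = global_asymmetry_fc,
    nb_mean_range = nb_mean_range, nb_dispersion = nb_dispersion,
    size_factor_range = size_factor_range,
    n_replicates_initial = as.integer(n_replicates_initial),
    n_replicates_extra = as.integer(n_replicates_extra),
    labeling_minutes = labeling_minutes,
    peak_placement = peak_placement, uastrx = uastrx,
    polii = polii, atac = atac,
    fragment_length = as.integer(fragment_length),
    gene_length_range = gene_length_range,
    min_upstream_gap = min_upstream_gap,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  cfg
}

.runif_log <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))

.random_dna <- function(n) {
  rawToChar(sample(charToRaw("ACGT"), n, replace = TRUE))
}

#' Simulate gene models, CTCF/RAD21 peaks and a genome with planted motifs
#'
#' Places non-overlapping genes on both strands with at least
#' `min_upstream_gap` clearance, draws gene lengths straddling the counting
#' caps, assigns CTCF peaks (summit offset, height, motif orientation) to a
#' fraction of genes, optionally pairs RAD21 peaks, and plants the PWM
#' consensus at each configured summit in the random genome sequence so the
#' orientation scanner can recover the planted orientation.
#'
#' @param config a [simulation_config()].
#' @param sequence logical; generate the genome sequence (set `FALSE` for
#'   count-level simulations that never touch sequence).
#' @param pwm motif probability matrix whose consensus is planted;
#'   default [ctcf_pwm()].
#' @return List with `genes` ([gene_models]), `genome` (`DNAStringSet` or
#'   `NULL`), `ctcf_peaks`, `rad21_peaks` (peak tables with `peak_id`,
#'   `chrom`, `start`, `end`, `summit`, `height`) and `peak_truth`
#'   (per-gene `ctcf_bound`, `summit_offset`, `orientation`, `height`).
#' @export
simulate_gene_models <- function(config, sequence = TRUE, pwm = ctcf_pwm()) {
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))

  if (config$n_genes == 0L) {
    genome <- if (sequence) {
      DNAStringSet(setNames(
        vapply(chroms, function(x) .random_dna(config$chrom_length),
               character(1)), chroms))
    } else NULL
    return(list(genes = gene_models(character(), character(), character(),
                                    integer(), integer()),
                genome = genome,
                ctcf_peaks = .empty_peaks(), rad21_peaks = .empty_peaks(),
                peak_truth = data.frame()))
  }

  chrom_of <- rep_len(chroms, config$n_genes)
  lens <- round(runif(config$n_genes, config$gene_length_range[1],
                      config$gene_length_range[2]))
  strands <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  gap <- config$min_upstream_gap
  starts <- integer(config$n_genes)
  ends <- integer(config$n_genes)
  cursor <- setNames(rep(gap, length(chroms)), chroms)
  for (i in seq_len(config$n_genes)) {
    ch <- chrom_of[i]
    s <- cursor[ch] + round(runif(1, gap, 1.5 * gap))
    e <- s + lens[i] - 1L
    if (e + gap > config$chrom_length) {
      stop("chrom_length too small to place ", config$n_genes,
           " genes with the configured clearance")
    }
    starts[i] <- s; ends[i] <- e
    cursor[ch] <- e
  }
  genes <- gene_models(sprintf("gene%04d", seq_len(config$n_genes)),
                       chrom_of, strands, starts, ends,
                       transcript_id = sprintf("tx%04d",
                                               seq_len(config$n_genes)),
                       biotype = "protein_coding")

  pp <- config$peak_placement
  bound <- runif(config$n_genes) < pp$fraction
  offset <- round(rnorm(config$n_genes, pp$offset_mean, pp$offset_sd))
  offset <- pmax(-pp$offset_max, pmin(pp$offset_max, offset))
  height <- .runif_log(config$n_genes, pp$height_range)
  orientation <- sample(names(pp$orientation_probs), config$n_genes,
                        replace = TRUE, prob = pp$orientation_probs)
  orientation[!bound] <- NA_character_
  offset[!bound] <- NA_integer_
  height[!bound] <- NA_real_

  # gene-strand-relative offset -> absolute genomic summit
  summit <- ifelse(genes$strand == "+", genes$tss + offset,
                   genes$tss - offset)
  idx <- which(bound)
  ctcf <- data.frame(
    peak_id = sprintf("ctcf%04d", seq_along(idx)),
    chrom = genes$chrom[idx],
    start = summit[idx] - 150L, end = summit[idx] + 150L,
    summit = summit[idx], height = height[idx],
    gene_id = genes$gene_id[idx],
    stringsAsFactors = FALSE
  )

  has_rad <- runif(length(idx)) < pp$rad21_fraction
  jitter <- round(runif(length(idx), -20, 20))
  ratio <- runif(length(idx), pp$rad21_ratio_range[1],
                 pp$rad21_ratio_range[2])
  rad <- ctcf[has_rad, , drop = FALSE]
  if (nrow(rad)) {
    rad$peak_id <- sprintf("rad21%04d", seq_len(nrow(rad)))
    rad$summit <- rad$summit + jitter[has_rad]
    rad$start <- rad$summit - 150L
    rad$end <- rad$summit + 150L
    rad$height <- ctcf$height[has_rad] * ratio[has_rad]
  }

  genome <- NULL
  if (sequence) {
    genome <- DNAStringSet(setNames(
      vapply(chroms, function(x) .random_dna(config$chrom_length),
             character(1)), chroms))
    cons <- DNAString(pwm_consensus(pwm))
    w <- length(cons)
    plant <- function(chrom, pos, revcomp) {
      seq_ <- if (revcomp) reverseComplement(cons) else cons
      subseq(genome[[chrom]], pos, pos + w - 1L) <<- seq_
    }
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (is.na(orientation[i]) || orientation[i] == "none") next
      ch <- genes$chrom[i]
      # "forward" = motif on the gene's strand of transcription
      fwd_on_minus <- genes$strand[i] == "-"
      center <- summit[i]
      at <- function(p) as.integer(p - floor(w / 2))
      if (orientation[i] == "forward") {
        plant(ch, at(center), fwd_on_minus)
      } else if (orientation[i] == "reverse") {
        plant(ch, at(center), !fwd_on_minus)
      } else { # both: two non-overlapping instances inside summit +/- 100
        plant(ch, at(center - 30L), fwd_on_minus)
        plant(ch, at(center + 30L), !fwd_on_minus)
      }
    }
  }

  list(genes = genes, genome = genome,
       ctcf_peaks = ctcf[, setdiff(names(ctcf), "gene_id")],
       rad21_peaks = if (nrow(rad)) rad[, setdiff(names(rad), "gene_id")]
                     else .empty_peaks(),
       peak_truth = data.frame(gene_id = genes$gene_id, ctcf_bound = bound,
                               summit_offset = offset,
                               orientation = orientation, height = height,
                               stringsAsFactors = FALSE))
}

.empty_peaks <- function() {
  data.frame(peak_id = character(), chrom = character(), start = integer(),
             end = integer(), summit = integer(), height = numeric(),
             stringsAsFactors = FALSE)
}

.rcounts <- function(n, mu, dispersion) {
  if (dispersion < 1e-8) rpois(n, mu) else
    rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate replicate counts with planted fold changes
#'
#' Control counts are negative binomial with gene means drawn log-uniformly
#' from `nb_mean_range` scaled by per-sample size factors; treatment counts
#' additionally carry the gene's planted linear fold change and the global
#' asymmetry confounder. Samples comprise `n_replicates_initial` paired
#' control/treatment replicates (the initial experiment) plus
#' `n_replicates_extra` additional pairs for reproducibility analysis.
#' Antisense counts are generated alongside: a configured fraction of genes
#' gets upstream antisense signal with a planted upregulation, the rest sit
#' below the antisense low-count filter.
#'
#' Ground-truth class labels are computed by [assign_class()] on the planted
#' fold changes, keeping the class thresholds in a single place.
#'
#' @param config a [simulation_config()].
#' @param genes a [gene_models] table from [simulate_gene_models()].
#' @return List with `counts`, `antisense_counts` (integer matrices),
#'   `sample_sheet` (`sample`, `condition`, `replicate`, `pair`, `set`),
#'   `truth` (`gene_id`, `true_fc`, `true_class`, `uastrx`, `uastrx_fc`,
#'   `control_mean`), and `size_factors_true`.
#' @export
simulate_counts <- function(config, genes) {
  set.seed(config$seed + 1L)
  n <- nrow(genes)
  spec <- config$class_spectrum
  labels <- sample(names(spec), n, replace = TRUE,
                   prob = vapply(spec, function(x) x$fraction, numeric(1)))
  down <- labels %in% c("SD", "ID", "HD", "HD1", "HD2")
  mag <- vapply(seq_len(n), function(i) {
    r <- spec[[labels[i]]]$fc_range
    runif(1, r[1], r[2])
  }, numeric(1))
  true_fc <- ifelse(down, 1 / mag, mag)

  ni <- config$n_replicates_initial
  ne <- config$n_replicates_extra
  samples <- data.frame(
    sample = c(paste0("ctrl_", seq_len(ni)), paste0("trt_", seq_len(ni)),
               if (ne > 0) c(paste0("ctrl_e", seq_len(ne)),
                             paste0("trt_e", seq_len(ne)))),
    condition = c(rep("control", ni), rep("treatment", ni),
                  if (ne > 0) c(rep("control", ne), rep("treatment", ne))),
    replicate = c(seq_len(ni), seq_len(ni),
                  if (ne > 0) c(seq_len(ne), seq_len(ne))),
    pair = c(rep(NA_character_, 2 * ni),
             if (ne > 0) rep(paste0("pair_", seq_len(ne)), 2)),
    set = c(rep("initial", 2 * ni), if (ne > 0) rep("extra", 2 * ne)),
    stringsAsFactors = FALSE
  )
  ns <- nrow(samples)
  sf <- runif(ns, config$size_factor_range[1], config$size_factor_range[2])
  names(sf) <- samples$sample

  mu0 <- .runif_log(n, config$nb_mean_range)
  counts <- matrix(0L, n, ns, dimnames = list(genes$gene_id, samples$sample))
  asym <- config$global_asymmetry_fc
  for (j in seq_len(ns)) {
    mu <- mu0 * sf[j]
    if (samples$condition[j] == "treatment") mu <- mu * true_fc * asym
    counts[, j] <- .rcounts(n, mu, config$nb_dispersion)
  }

  ua <- config$uastrx
  uastrx <- runif(n) < ua$fraction
  ua_mu <- ifelse(uastrx, .runif_log(n, ua$mean_range), ua$background_mean)
  ua_fc <- ifelse(uastrx, runif(n, ua$fc_range[1], ua$fc_range[2]), 1)
  anti <- matrix(0L, n, ns, dimnames = dimnames(counts))
  for (j in seq_len(ns)) {
    mu <- ua_mu * sf[j]
    if (samples$condition[j] == "treatment") mu <- mu * ua_fc * asym
    anti[, j] <- .rcounts(n, mu, config$nb_dispersion)
  }

  storage.mode(counts) <- "integer"
  storage.mode(anti) <- "integer"
  truth <- data.frame(gene_id = genes$gene_id, true_fc = true_fc,
                      true_class = assign_class(true_fc, "standard"),
                      uastrx = uastrx, uastrx_fc = ua_fc,
                      control_mean = mu0, stringsAsFactors = FALSE)
  list(counts = counts, antisense_counts = anti, sample_sheet = samples,
       truth = truth, size_factors_true = sf)
}

#' Emit stranded fragment intervals reproducing a count matrix
#'
#' For each gene and sample, exactly the tabulated number of fragments is
#' placed uniformly inside the gene's counting window on the gene strand
#' (and antisense counts, if given, inside the upstream antisense window on
#' the opposite strand), so re-counting the emitted fragments reproduces
#' the matrix exactly. Fragments never cross exclusion regions (placement
#' is retried; configuration error if a window is saturated).
#'
#' @param counts integer matrix genes x samples (sense counts).
#' @param genes a [gene_models] table (rows aligned with `counts`).
#' @param labeling_minutes selects the counting window cap.
#' @param fragment_length fragment length in bp; must not exceed any window.
#' @param antisense_counts optional antisense count matrix.
#' @param exclude optional `GRanges` exclusion regions.
#' @param seed integer seed.
#' @return Named list of `GRanges`, one per sample.
#' @export
simulate_fragments <- function(counts, genes, labeling_minutes = 30,
                               fragment_length = 100,
                               antisense_counts = NULL, exclude = NULL,
                               seed = 1) {
  set.seed(seed + 2L)
  win <- compute_counting_window(genes, labeling_minutes,
                                 full_gene = labeling_minutes == 240)
  if (any(width(win) < fragment_length)) {
    stop("counting window shorter than fragment length for gene(s): ",
         paste(head(mcols(win)$gene_id[width(win) < fragment_length], 5),
               collapse = ", "))
  }
  anti_win <- if (!is.null(antisense_counts)) antisense_windows(genes)

  # uniform starts keeping the fragment fully inside the window; returns
  # plain coordinate vectors so each sample becomes a single GRanges
  place <- function(w, n_frag) {
    lo <- start(w); hi <- end(w) - fragment_length + 1L
    starts <- floor(runif(n_frag, lo, hi + 1))
    if (!is.null(exclude) && length(exclude)) {
      ex <- exclude[as.character(seqnames(exclude)) ==
                      as.character(seqnames(w))]
      if (length(ex)) {
        for (tries in 1:50) {
          bad <- vapply(starts, function(s) {
            any(s <= end(ex) & (s + fragment_length - 1L) >= start(ex))
          }, logical(1))
          if (!any(bad)) break
          if (tries == 50) stop("cannot place fragments outside exclusion ",
                                "regions; window saturated")
          starts[bad] <- floor(runif(sum(bad), lo, hi + 1))
        }
      }
    }
    data.frame(chrom = as.character(seqnames(w)), start = starts,
               strand = as.character(strand(w)))
  }

  out <- vector("list", ncol(counts))
  names(out) <- colnames(counts)
  for (j in seq_len(ncol(counts))) {
    pieces <- list()
    for (i in seq_len(nrow(counts))) {
      if (counts[i, j] > 0) {
        pieces[[length(pieces) + 1L]] <- place(win[i], counts[i, j])
      }
      if (!is.null(anti_win) && antisense_counts[i, j] > 0) {
        pieces[[length(pieces) + 1L]] <- place(anti_win[i],
                                               antisense_counts[i, j])
      }
    }
    if (length(pieces)) {
      df <- do.call(rbind, pieces)
      out[[j]] <- GRanges(df$chrom,
                          IRanges(df$start, width = fragment_length),
                          strand = df$strand)
    } else {
      out[[j]] <- GRanges()
    }
  }
  out
}

#' Simulate Pol II and ATAC signal with planted confounders
#'
#' Pol II promoter/body counts for two conditions carry a global treatment
#' library-scale confounder that the anchored normalization must remove;
#' genes downregulated in the transcription ground truth *and* CTCF-bound
#' lose Pol II in promoter and body proportionally to their fold change,
#' while uasTrx genes gain promoter-only Pol II. ATAC peaks comprise the
#' CTCF peaks plus unbound background peaks, with planted >= 2-fold losses
#' at a configured fraction of peaks (drawn preferentially from CTCF-bound
#' ones) and a tiny gain fraction.
#'
#' @param config a [simulation_config()].
#' @param genes,truth,ctcf_peaks outputs of [simulate_gene_models()] and
#'   [simulate_counts()].
#' @return List with `polii` (`promoter_counts`, `body_counts`,
#'   `truth`) and `atac` (`counts`, `sample_sheet`, `summits`, `truth`).
#' @export
simulate_signal_tracks <- function(config, genes, truth, ctcf_peaks) {
  set.seed(config$seed + 3L)
  n <- nrow(genes)
  po <- config$polii
  # CTCF-bound = a peak summit within the +/-400 bp promoter window
  bound <- rep(FALSE, n)
  if (nrow(ctcf_peaks)) {
    prom <- promoter_windows(genes, 400)
    pk <- GRanges(ctcf_peaks$chrom,
                  IRanges(ctcf_peaks$summit, ctcf_peaks$summit))
    bound <- overlapsAny(prom, pk, ignore.strand = TRUE)
  }

  down <- truth$true_fc < 1
  prom_fc <- ifelse(down & bound, truth$true_fc,
                    ifelse(truth$uastrx, po$uastrx_promoter_fc, 1))
  body_fc <- ifelse(down & bound, truth$true_fc, 1)

  mk <- function(base_mean, fc) {
    ctrl <- rpois(n, base_mean)
    trt <- rpois(n, base_mean * fc * po$confounder)
    m <- cbind(control = ctrl, treatment = trt)
    rownames(m) <- genes$gene_id
    m
  }
  polii <- list(
    promoter_counts = mk(po$promoter_mean, prom_fc),
    body_counts = mk(po$body_mean, body_fc),
    truth = data.frame(gene_id = genes$gene_id, polii_promoter_fc = prom_fc,
                       polii_body_fc = body_fc, stringsAsFactors = FALSE)
  )

  at <- config$atac
  n_ctcf <- nrow(ctcf_peaks)
  n_extra <- at$n_extra_peaks
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  extra_summit <- round(runif(n_extra, 1000, config$chrom_length - 1000))
  summits <- data.frame(
    peak_id = c(ctcf_peaks$peak_id,
                if (n_extra) sprintf("bg%04d", seq_len(n_extra))),
    chrom = c(ctcf_peaks$chrom,
              if (n_extra) sample(chroms, n_extra, replace = TRUE)),
    summit = c(ctcf_peaks$summit, extra_summit),
    ctcf = c(rep(TRUE, n_ctcf), rep(FALSE, n_extra)),
    stringsAsFactors = FALSE
  )
  np <- nrow(summits)
  n_loss <- round(at$loss_fraction * np)
  n_gain <- round(at$gain_fraction * np)
  pool <- c(which(summits$ctcf), which(!summits$ctcf))
  losers <- pool[seq_len(min(n_loss, np))]
  gainers <- setdiff(seq_len(np), losers)
  gainers <- if (n_gain > 0) sample(gainers, min(n_gain, length(gainers)))
             else integer(0)
  fc <- rep(1, np)
  fc[losers] <- 1 / .runif_log(length(losers), at$loss_fc_range)
  fc[gainers] <- .runif_log(length(gainers), at$loss_fc_range)

  mu <- .runif_log(np, at$mean_range)
  atac_counts <- cbind(
    ctrl_1 = rpois(np, mu), ctrl_2 = rpois(np, mu),
    trt_1 = rpois(np, mu * fc), trt_2 = rpois(np, mu * fc)
  )
  rownames(atac_counts) <- summits$peak_id

  list(
    polii = polii,
    atac = list(
      counts = atac_counts,
      sample_sheet = data.frame(
        sample = colnames(atac_counts),
        condition = c("control", "control", "treatment", "treatment"),
        stringsAsFactors = FALSE),
      summits = summits[, c("peak_id", "chrom", "summit", "ctcf")],
      truth = data.frame(peak_id = summits$peak_id, atac_fc = fc,
                         ctcf = summits$ctcf, stringsAsFactors = FALSE)
    )
  )
}

#' Simulate and write a complete dataset directory
#'
#' Thin orchestration over the simulator stages: writes genome FASTA, genes
#' GTF and TSV, counts and antisense counts TSV, sample sheet, CTCF/RAD21
#' narrowPeak files, Pol II and ATAC count TSVs, ground-truth TSV, the
#' config as JSON, optional per-sample fragment BEDs, and a manifest with
#' MD5 checksums of every file.
#'
#' @param config a [simulation_config()].
#' @param dir output directory.
#' @param force overwrite a non-empty directory.
#' @param fragments also emit per-sample fragment BED files (large; off by
#'   default).
#' @param sequence generate and write the genome FASTA.
#' @return Invisibly, the manifest `data.frame` (`file`, `md5`).
#' @export
simulate_dataset <- function(config, dir, force = FALSE, fragments = FALSE,
                             sequence = TRUE) {
  if (dir.exists(dir) && length(dir(dir)) && !force) {
    stop("output directory ", dir, " is not empty; use force = TRUE")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  gm <- simulate_gene_models(config, sequence = sequence)
  cc <- simulate_counts(config, gm$genes)
  sig <- simulate_signal_tracks(config, gm$genes, cc$truth, gm$ctcf_peaks)

  paths <- character(0)
  put <- function(p) { paths[[length(paths) + 1L]] <<- p; p }

  if (sequence && !is.null(gm$genome)) {
    writeXStringSet(gm$genome, put(file.path(dir, "genome.fa")))
  }
  write_genes_gtf(gm$genes, put(file.path(dir, "genes.gtf")))
  write_gene_models_tsv(gm$genes, put(file.path(dir, "genes.tsv")))
  write_counts_tsv(cc$counts, put(file.path(dir, "counts.tsv")))
  write_counts_tsv(cc$antisense_counts,
                   put(file.path(dir, "antisense_counts.tsv")))
  write.table(cc$sample_sheet, put(file.path(dir, "sample_sheet.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(gm$ctcf_peaks)) {
    write_narrowpeak(gm$ctcf_peaks,
                     put(file.path(dir, "ctcf_peaks.narrowPeak")))
  }
  if (nrow(gm$rad21_peaks)) {
    write_narrowpeak(gm$rad21_peaks,
                     put(file.path(dir, "rad21_peaks.narrowPeak")))
  }
  write_counts_tsv(sig$polii$promoter_counts,
                   put(file.path(dir, "polii_promoter_counts.tsv")))
  write_counts_tsv(sig$polii$body_counts,
                   put(file.path(dir, "polii_body_counts.tsv")))
  write_counts_tsv(sig$atac$counts, put(file.path(dir, "atac_counts.tsv")))
  write.table(sig$atac$summits, put(file.path(dir, "atac_summits.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- merge(cc$truth, gm$peak_truth, by = "gene_id", sort = FALSE)
  truth <- merge(truth, sig$polii$truth, by = "gene_id", sort = FALSE)
  write.table(truth, put(file.path(dir, "ground_truth.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sig$atac$truth, put(file.path(dir, "atac_truth.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  if (fragments) {
    frag_dir <- file.path(dir, "fragments")
    dir.create(frag_dir, showWarnings = FALSE)
    frags <- simulate_fragments(cc$counts, gm$genes,
                                labeling_minutes = config$labeling_minutes,
                                fragment_length = config$fragment_length,
                                antisense_counts = cc$antisense_counts,
                                seed = config$seed)
    for (s in names(frags)) {
      write_fragments_bed(frags[[s]],
                          put(file.path(frag_dir, paste0(s, ".bed"))))
    }
  }

  cfg <- config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, put(file.path(dir, "config.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- data.frame(
    file = basename(unlist(paths)),
    md5 = unname(tools::md5sum(unlist(paths))),
    stringsAsFactors = FALSE
  )
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
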