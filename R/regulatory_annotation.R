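#' Promoter-centric CTCF/RAD21 peak geometry
#'
#' Assigns peaks to genes by summit-to-TSS distance in gene-strand
#' coordinates (negative = upstream of the TSS). Per gene, the nearest
#' summit is reported together with its peak height and, when RAD21 peaks
#' are supplied, the RAD21/CTCF signal ratio of summit-paired peaks
#' (summits within `pairing_distance` bp). Window-membership flags use all
#' peaks, not only the nearest, so the nesting in_200bp => in_400bp =>
#' in_2kb always holds.
#'
#' @param peaks CTCF peaks: `data.frame` with columns `chrom`, `summit`
#'   (absolute 1-based position) and `height` (signal value). An error
#'   names any record lacking a summit.
#' @param genes a [gene_models] table.
#' @param rad21_peaks optional RAD21 peaks in the same format.
#' @param pairing_distance maximum summit-to-summit distance in bp for
#'   pairing a RAD21 peak with the nearest CTCF peak.
#' @return `data.frame` with one row per gene: `gene_id`,
#'   `nearest_distance` (signed bp, `NA` if no peak on the chromosome),
#'   `peak_height`, `in_2kb`, `in_400bp`, `in_200bp`, `rad21_ctcf_ratio`.
#' @export
annotate_promoter_peaks <- function(peaks, genes, rad21_peaks = NULL,
                                    pairing_distance = 100) {
  pk <- as.data.frame(peaks, stringsAsFactors = FALSE)
  if (!all(c("chrom", "summit") %in% names(pk))) {
    stop("peaks must have 'chrom' and 'summit' columns")
  }
  if (anyNA(pk$summit)) {
    stop("peak record(s) without summit at row(s): ",
         paste(head(which(is.na(pk$summit)), 5), collapse = ", "))
  }
  if (!"height" %in% names(pk)) pk$height <- NA_real_

  rad <- if (is.null(rad21_peaks)) NULL else
    as.data.frame(rad21_peaks, stringsAsFactors = FALSE)

  n <- nrow(genes)
  out <- data.frame(gene_id = genes$gene_id,
                    nearest_distance = NA_real_, peak_height = NA_real_,
                    in_2kb = FALSE, in_400bp = FALSE, in_200bp = FALSE,
                    rad21_ctcf_ratio = NA_real_)
  for (i in seq_len(n)) {
    sel <- pk$chrom == genes$chrom[i]
    if (!any(sel)) next
    summit <- pk$summit[sel]
    height <- pk$height[sel]
    dist <- if (genes$strand[i] == "+") summit - genes$tss[i] else
      genes$tss[i] - summit
    ord <- order(abs(dist), dist)
    out$nearest_distance[i] <- dist[ord[1L]]
    out$peak_height[i] <- height[ord[1L]]
    out$in_2kb[i] <- any(abs(dist) <= 2000)
    out$in_400bp[i] <- any(abs(dist) <= 400)
    out$in_200bp[i] <- any(abs(dist) <= 200)
    if (!is.null(rad) && nrow(rad)) {
      rsel <- rad$chrom == genes$chrom[i]
      if (any(rsel)) {
        near_summit <- summit[ord[1L]]
        dd <- abs(rad$summit[rsel] - near_summit)
        if (min(dd) <= pairing_distance) {
          out$rad21_ctcf_ratio[i] <-
            rad$height[rsel][which.min(dd)] / height[ord[1L]]
        }
      }
    }
  }
  out
}

#' Motif orientation relative to gene transcription
#'
#' Scans both strands of the sequence within `flank` bp of each peak summit
#' with a position weight matrix. Orientation is reported relative to the
#' direction of transcription of the associated gene: a hit whose genomic
#' strand equals the gene strand is `forward`, the opposite is `reverse`;
#' hits on both strands give `both`, no hit gives `none`. Windows running
#' off a contig are truncated with a warning.
#'
#' @param summits `data.frame` with columns `chrom` and `summit`.
#' @param genome a named `DNAStringSet` (or path to a FASTA file).
#' @param pwm 4 x w probability or log-odds matrix with rows A, C, G, T (as
#'   used by [Biostrings::matchPWM()]).
#' @param gene_strand character vector, `"+"`/`"-"`, one per summit: the
#'   strand of the gene each peak is being interpreted against.
#' @param flank half-window around the summit to scan.
#' @param min_score score threshold passed to `matchPWM` (default 80% of
#'   the maximal score).
#' @return `data.frame` with columns `orientation` (forward/reverse/both/
#'   none), `n_forward`, `n_reverse` (hit counts in gene-relative
#'   orientation).
#' @export
classify_motif_orientation <- function(summits, genome, pwm, gene_strand,
                                       flank = 100, min_score = "80%") {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  sm <- as.data.frame(summits, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "summit") %in% names(sm)),
            length(gene_strand) == nrow(sm))
  pwm <- as.matrix(pwm)
  orientation <- character(nrow(sm))
  n_fwd <- integer(nrow(sm))
  n_rev <- integer(nrow(sm))
  truncated <- FALSE
  for (i in seq_len(nrow(sm))) {
    chrom <- sm$chrom[i]
    if (!chrom %in% names(genome)) {
      stop("chromosome '", chrom, "' absent from genome")
    }
    L <- length(genome[[chrom]])
    lo <- sm$summit[i] - flank
    hi <- sm$summit[i] + flank
    if (lo < 1 || hi > L) {
      truncated <- TRUE
      lo <- max(1, lo); hi <- min(L, hi)
    }
    s <- subseq(genome[[chrom]], lo, hi)
    plus_hits <- length(matchPWM(pwm, s, min.score = min_score))
    minus_hits <- length(matchPWM(pwm, reverseComplement(s),
                                  min.score = min_score))
    if (gene_strand[i] == "+") {
      n_fwd[i] <- plus_hits; n_rev[i] <- minus_hits
    } else {
      n_fwd[i] <- minus_hits; n_rev[i] <- plus_hits
    }
    orientation[i] <- if (n_fwd[i] > 0 && n_rev[i] > 0) "both"
      else if (n_fwd[i] > 0) "forward"
      else if (n_rev[i] > 0) "reverse"
      else "none"
  }
  if (truncated) warning("scan window(s) truncated at contig bounds")
  data.frame(orientation = orientation, n_forward = n_fwd, n_reverse = n_rev)
}

#' Per-class summit-distance distributions
#'
#' For each regulation class, the signed summit-to-TSS distances (gene-
#' strand coordinates) of bound promoters restricted to within `window` bp,
#' and their median. Classes with no bound gene are omitted and listed in
#' the `"omitted"` attribute.
#'
#' @param distances named numeric vector of signed summit distances (named
#'   by gene id; `NA` = no peak).
#' @param classes named character vector of class labels per gene.
#' @param window restrict to |distance| <= `window`.
#' @return `data.frame` with columns `class`, `n`, `median_distance`, plus
#'   a `"distances"` attribute holding the per-class vectors.
#' @export
summarize_binding_positions <- function(distances, classes, window = 400) {
  shared <- intersect(names(distances), names(classes))
  d <- distances[shared]
  cl <- classes[shared]
  keep <- !is.na(d) & abs(d) <= window & !is.na(cl)
  split_d <- split(d[keep], cl[keep])
  all_classes <- unique(cl[!is.na(cl)])
  omitted <- setdiff(all_classes, names(split_d))
  out <- data.frame(
    class = names(split_d),
    n = vapply(split_d, length, integer(1)),
    median_distance = vapply(split_d, median, numeric(1)),
    row.names = NULL
  )
  attr(out, "distances") <- split_d
  attr(out, "omitted") <- omitted
  out
}

#' Pol II ChIP quantification anchored to unchanged genes
#'
#' ChIP libraries lack an internal scale, so treatment counts are rescaled
#' by an anchoring factor chosen such that the gene-body signal of genes
#' whose transcription does not change (the NC set) shows zero median log2
#' fold change. The factor is `2^median(log2(body_trt/body_ctrl))` over the
#' NC set, which makes that median exactly zero for any set size (a plain
#' median of ratios only guarantees this for odd n).
#'
#' @param promoter_counts,body_counts numeric matrices genes x 2 with
#'   columns `control`, `treatment` (promoter: TSS +/- 400 bp; body:
#'   TSS + 500 bp to TES). Rownames are gene ids.
#' @param nc_gene_set character vector of unchanged gene ids (non-empty).
#' @return `data.frame` with `gene_id`, `promoter_log2fc`, `body_log2fc`
#'   (after anchoring; `NA` where a count is zero), `body_short` flag for
#'   genes with missing/empty body counts; attribute `anchoring_factor`.
#' @export
polii_normalize_quantify <- function(promoter_counts, body_counts,
                                     nc_gene_set) {
  promoter_counts <- as.matrix(promoter_counts)
  body_counts <- as.matrix(body_counts)
  stopifnot(all(c("control", "treatment") %in% colnames(promoter_counts)),
            all(c("control", "treatment") %in% colnames(body_counts)))
  if (!length(nc_gene_set)) stop("nc_gene_set is empty")
  nc <- intersect(nc_gene_set, rownames(body_counts))
  ratios <- log2(body_counts[nc, "treatment"] / body_counts[nc, "control"])
  ratios <- ratios[is.finite(ratios)]
  if (!length(ratios)) stop("anchoring factor undefined: no NC gene with ",
                            "positive body counts in both conditions")
  factor <- 2^median(ratios)
  if (!is.finite(factor) || factor <= 0) stop("anchoring factor must be positive")

  lfc <- function(m) {
    l <- log2((m[, "treatment"] / factor) / m[, "control"])
    l[!is.finite(l)] <- NA_real_
    l
  }
  out <- data.frame(
    gene_id = rownames(promoter_counts),
    promoter_log2fc = lfc(promoter_counts),
    body_log2fc = lfc(body_counts),
    body_short = is.na(body_counts[, "control"]) |
      is.na(body_counts[, "treatment"]),
    row.names = NULL
  )
  attr(out, "anchoring_factor") <- factor
  out
}

#' Rank-based quartile stratification
#'
#' Splits values into four rank-based groups Q1 (lowest) to Q4 (highest)
#' with sizes differing by at most one; ties are broken by `ids` so the
#' assignment is deterministic.
#'
#' @param height numeric vector (e.g. CTCF peak heights).
#' @param ids tie-break keys; defaults to the element index.
#' @return Factor with levels `Q1`..`Q4` in the original element order.
#' @export
quartile_stratify <- function(height, ids = seq_along(height)) {
  stopifnot(length(height) == length(ids))
  n <- length(height)
  q <- integer(n)
  ord <- order(height, ids)
  q[ord] <- ceiling(4 * seq_len(n) / n)
  factor(paste0("Q", q), levels = paste0("Q", 1:4))
}

#' ATAC differential accessibility with CTCF-height quartiles
#'
#' Per-peak log2 fold change of mean normalized accessibility after
#' median-of-ratios scaling across peaks, with summary fractions of peaks
#' losing or gaining at least `fc_threshold`-fold. Peaks are split into
#' promoter (summit within 200 bp of any TSS) and distal strata, and
#' CTCF-overlapping peaks are assigned height quartiles Q1-Q4 within each
#' stratum; peaks without CTCF form a `no_ctcf` reference stratum.
#'
#' @param counts integer matrix peaks x samples; rownames are peak ids.
#' @param sample_sheet `data.frame` with `sample`, `condition`.
#' @param peak_summits `data.frame` with `peak_id`, `chrom`, `summit`.
#' @param ctcf_peaks `data.frame` with `chrom`, `start`, `end`, `height`
#'   (1-based inclusive intervals), or `NULL`.
#' @param tss `data.frame` with `chrom`, `tss`.
#' @param fc_threshold fold-change threshold for the loss/gain fractions.
#' @param promoter_bp summit-to-TSS distance defining promoter peaks.
#' @return List with `results` (`peak_id`, `log2fc`, `promoter`,
#'   `ctcf_height`, `stratum`, `quartile`), `fraction_loss`,
#'   `fraction_gain`, and `n_excluded` (peaks with zero counts in both
#'   conditions, excluded).
#' @export
atac_differential <- function(counts, sample_sheet, peak_summits,
                              ctcf_peaks = NULL, tss = NULL,
                              fc_threshold = 2, promoter_bp = 200) {
  counts <- as.matrix(counts)
  ctrl <- sample_sheet$sample[sample_sheet$condition == "control"]
  trt <- sample_sheet$sample[sample_sheet$condition == "treatment"]
  mc <- rowMeans(counts[, ctrl, drop = FALSE])
  mt <- rowMeans(counts[, trt, drop = FALSE])
  keep <- mc > 0 | mt > 0
  n_excluded <- sum(!keep)
  counts <- counts[keep, , drop = FALSE]

  sf <- estimate_size_factors(counts)
  norm <- sweep(counts, 2, sf[colnames(counts)], "/")
  l2fc <- log2(rowMeans(norm[, trt, drop = FALSE]) /
                 rowMeans(norm[, ctrl, drop = FALSE]))

  sm <- as.data.frame(peak_summits, stringsAsFactors = FALSE)
  sm <- sm[match(rownames(counts), sm$peak_id), , drop = FALSE]

  promoter <- rep(FALSE, nrow(sm))
  if (!is.null(tss) && nrow(as.data.frame(tss))) {
    td <- as.data.frame(tss, stringsAsFactors = FALSE)
    for (ch in unique(sm$chrom)) {
      tpos <- sort(td$tss[td$chrom == ch])
      i <- which(sm$chrom == ch)
      if (!length(tpos) || !length(i)) next
      lo <- findInterval(sm$summit[i] - promoter_bp - 0.5, tpos)
      hi <- findInterval(sm$summit[i] + promoter_bp + 0.5, tpos)
      promoter[i] <- (hi - lo) > 0
    }
  }

  ctcf_height <- rep(NA_real_, nrow(sm))
  if (!is.null(ctcf_peaks) && nrow(as.data.frame(ctcf_peaks))) {
    cp <- as.data.frame(ctcf_peaks, stringsAsFactors = FALSE)
    pk_gr <- GRanges(sm$chrom, IRanges(sm$summit, sm$summit))
    ct_gr <- GRanges(cp$chrom, IRanges(cp$start, cp$end))
    hits <- findOverlaps(pk_gr, ct_gr, ignore.strand = TRUE)
    if (length(hits)) {
      h <- tapply(cp$height[subjectHits(hits)], queryHits(hits), max)
      ctcf_height[as.integer(names(h))] <- as.numeric(h)
    }
  }

  stratum <- ifelse(promoter, "promoter", "distal")
  quartile <- factor(rep(NA_character_, nrow(sm)), levels = paste0("Q", 1:4))
  for (s in unique(stratum)) {
    i <- which(stratum == s & !is.na(ctcf_height))
    if (length(i)) {
      quartile[i] <- quartile_stratify(ctcf_height[i], rownames(counts)[i])
    }
  }
  stratum[is.na(ctcf_height)] <- paste0(stratum[is.na(ctcf_height)],
                                        "_no_ctcf")

  list(
    results = data.frame(peak_id = rownames(counts), log2fc = l2fc,
                         promoter = promoter, ctcf_height = ctcf_height,
                         stratum = stratum, quartile = quartile,
                         row.names = NULL),
    fraction_loss = mean(l2fc <= -log2(fc_threshold), na.rm = TRUE),
    fraction_gain = mean(l2fc >= log2(fc_threshold), na.rm = TRUE),
    n_excluded = n_excluded
  )
}
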