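#' Gene-set overlap enrichment (Fisher's exact test)
#'
#' Builds the 2x2 membership table of two gene sets within a universe and
#' computes the sample odds ratio OR = (a*d)/(b*c) and a two-sided Fisher
#' exact p value by direct hypergeometric tail summation (the sum of the
#' probabilities of all tables, at fixed margins, no more probable than the
#' observed one). Overlap fractions are reported per direction, plus the
#' fold enrichment of the conditional frequencies P(B|A) / P(B|not A).
#'
#' @param set_a,set_b character vectors of gene ids; must be subsets of
#'   `universe`.
#' @param universe character vector, typically the expressed genes common to
#'   the two contrasts.
#' @return List of class `contingency_result`: `table` (a, b, c, d), `or`
#'   (`Inf`/0 with `or_degenerate = TRUE` when a zero cell makes it so),
#'   `p`, `fraction_a_in_b` (|A&B|/|A|), `fraction_b_in_a` (|A&B|/|B|),
#'   `fold_enrichment`, and the set sizes.
#' @export
overlap_enrichment <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe is empty")
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("set_a and set_b must be subsets of the universe")
  }
  a <- length(intersect(set_a, set_b))
  b <- length(set_a) - a
  c_ <- length(set_b) - a
  d <- length(universe) - a - b - c_

  or <- (a * d) / (b * c_)
  degenerate <- b == 0 || c_ == 0 || a == 0 || d == 0
  p <- fisher_p_twosided(a, b, c_, d)

  structure(list(
    table = c(a = a, b = b, c = c_, d = d),
    or = or, or_degenerate = degenerate, p = p,
    fraction_a_in_b = if (length(set_a)) a / length(set_a) else NA_real_,
    fraction_b_in_a = if (length(set_b)) a / length(set_b) else NA_real_,
    fold_enrichment = if (length(set_a) && (c_ + d) > 0 && c_ > 0)
      (a / length(set_a)) / (c_ / (c_ + d)) else NA_real_,
    n_a = length(set_a), n_b = length(set_b), n_universe = length(universe)
  ), class = "contingency_result")
}

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Direct hypergeometric computation at fixed margins; the p value is the
#' sum over the support of all table probabilities not exceeding the
#' observed probability (with a relative tolerance guarding float ties,
#' the convention used by standard software).
#'
#' @param a,b,c,d non-negative integer cells (a = overlap).
#' @return p value in (0, 1].
#' @export
fisher_p_twosided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b
  n2 <- c + d
  k <- a + c
  support <- max(0L, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  pobs <- dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

#' Ratio of two class-conditional frequencies
#'
#' @param frac_1,frac_2 proportions (or percentages, consistently).
#' @return List with `ratio` (full precision), `presented`
#'   (integer-rounded), and `degenerate` flag when `frac_2` is zero
#'   (ratio `Inf`).
#' @export
fold_enrichment <- function(frac_1, frac_2) {
  if (frac_2 == 0) {
    return(list(ratio = if (frac_1 > 0) Inf else NaN,
                presented = NA_integer_, degenerate = TRUE))
  }
  r <- frac_1 / frac_2
  list(ratio = r, presented = as.integer(round(r)), degenerate = FALSE)
}

#' Per-class Mann-Whitney U tests against a reference class
#'
#' Each class's value distribution is compared with the reference class by a
#' two-sided Mann-Whitney U test (exact for small tie-free samples, midrank
#' normal approximation with continuity correction otherwise, the standard
#' `wilcox.test` behavior), then Benjamini-Hochberg corrected across the
#' family in one call. When both groups are a single identical constant the
#' test is degenerate and p = 1 is reported with a flag.
#'
#' @param values_by_class named list of numeric vectors, one per class.
#' @param reference_label name of the reference class (e.g. `"NC"`).
#' @return `data.frame` with columns `class`, `n`, `statistic` (U of the
#'   class vs reference), `p`, `p_adj`, `degenerate`.
#' @export
class_distribution_test <- function(values_by_class, reference_label) {
  if (!reference_label %in% names(values_by_class)) {
    stop("reference class '", reference_label, "' not present")
  }
  ref <- values_by_class[[reference_label]]
  if (!length(ref)) stop("reference class is empty")
  others <- setdiff(names(values_by_class), reference_label)
  rows <- lapply(others, function(cl) {
    x <- values_by_class[[cl]]
    if (!length(x)) stop("class '", cl, "' is empty")
    if (length(unique(c(x, ref))) == 1L) {
      return(data.frame(class = cl, n = length(x),
                        statistic = length(x) * length(ref) / 2,
                        p = 1, degenerate = TRUE))
    }
    wt <- suppressWarnings(wilcox.test(x, ref, alternative = "two.sided"))
    data.frame(class = cl, n = length(x),
               statistic = unname(wt$statistic), p = wt$p.value,
               degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out[, c("class", "n", "statistic", "p", "p_adj", "degenerate")]
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' @param values_a,values_b numeric vectors (each non-empty).
#' @return List with `D` (sup of the ECDF difference) and `p` (two-sided).
#' @export
ks_two_sample <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) stop("empty sample")
  kt <- suppressWarnings(ks.test(values_a, values_b,
                                 alternative = "two.sided"))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Feature proximity enrichment versus random gene controls
#'
#' Counts, per gene, features whose summit lies within `window_bp` of the
#' TSS, and compares the mean count over `gene_set` with the means of
#' `n_controls` random gene sets of equal size drawn from `all_genes`.
#' The empirical p value is the fraction of control means at or above the
#' observed mean.
#'
#' @param feature_summits `data.frame` with columns `chrom` and `summit`
#'   (1-based positions), e.g. enhancer peak summits.
#' @param tss `data.frame` with columns `gene_id`, `chrom`, `tss` covering
#'   every gene in `all_genes`.
#' @param gene_set character vector of gene ids of interest.
#' @param all_genes character vector the controls are drawn from (e.g. all
#'   expressed genes).
#' @param window_bp half-window around the TSS.
#' @param n_controls number of random control sets (a warning is emitted
#'   below 100, where the empirical p resolution is poor).
#' @param seed integer seed for the control draws.
#' @return List with `observed_mean`, `control_means`, `p`, and the
#'   per-gene `counts` for the observed set.
#' @export
proximity_enrichment <- function(feature_summits, tss, gene_set, all_genes,
                                 window_bp = 50000, n_controls = 1000,
                                 seed = 1) {
  if (n_controls < 100) {
    warning("fewer than 100 control sets: empirical p resolution is coarse")
  }
  stopifnot(all(gene_set %in% all_genes),
            all(all_genes %in% tss$gene_id))
  tss <- tss[match(all_genes, tss$gene_id), , drop = FALSE]
  counts <- integer(length(all_genes))
  for (ch in unique(tss$chrom)) {
    s <- sort(feature_summits$summit[feature_summits$chrom == ch])
    i <- which(tss$chrom == ch)
    if (!length(s) || !length(i)) next
    lo <- findInterval(tss$tss[i] - window_bp - 0.5, s)
    hi <- findInterval(tss$tss[i] + window_bp + 0.5, s)
    counts[i] <- hi - lo
  }
  names(counts) <- all_genes
  observed <- mean(counts[gene_set])
  set.seed(seed)
  control_means <- vapply(seq_len(n_controls), function(i) {
    mean(counts[sample(all_genes, length(gene_set))])
  }, numeric(1))
  list(observed_mean = observed, control_means = control_means,
       p = mean(control_means >= observed), counts = counts[gene_set])
}
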