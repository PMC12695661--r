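#' Median-of-ratios size factors
#'
#' Per-sample scaling factors estimated against a geometric-mean
#' pseudo-reference: for genes with positive counts in every sample,
#' \eqn{g_i = (\prod_j c_{ij})^{1/m}} and \eqn{s_j = median_i(c_{ij}/g_i)}.
#' Normalized counts are \eqn{c_{ij}/s_j}. A single-sample matrix returns
#' \eqn{s = 1}.
#'
#' @param counts integer matrix genes x samples.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1L) {
    return(setNames(1, colnames(counts)))
  }
  logc <- log(counts)
  loggeo <- rowMeans(logc)
  use <- is.finite(loggeo)
  if (!any(use)) {
    stop("no gene has positive counts in every sample; size factors are ",
         "undefined (consider adding a pseudo-count upstream)")
  }
  sf <- apply(logc[use, , drop = FALSE], 2, function(lc) {
    exp(median(lc - loggeo[use]))
  })
  setNames(as.numeric(sf), colnames(counts))
}

#' Asymmetry-corrected log2 fold changes
#'
#' Raw fold change per gene is the ratio of mean normalized treatment to
#' mean normalized control counts, on log2 scale. Perturbations that
#' predominantly act in one direction bias median-of-ratios scaling toward
#' the opposite direction; to correct, the median raw log2 fold change over
#' the expressed gene set (the asymmetry median `m`) is subtracted from
#' every gene, re-centering the unchanged bulk of the transcriptome at zero.
#'
#' @param counts integer matrix genes x samples.
#' @param sample_sheet `data.frame` with columns `sample` and `condition`.
#' @param expressed character vector of expressed `gene_id`s (or logical per
#'   row) defining the set over which the asymmetry median is taken.
#' @param size_factors optional precomputed size factors; estimated from
#'   `counts` when `NULL`.
#' @return `data.frame` of class `differential_result` with columns
#'   `gene_id`, `raw_log2fc`, `adjusted_log2fc`, `status` (`"ok"`,
#'   `"zero_control"`, `"zero_treatment"`, `"zero_both"`); attributes
#'   `size_factors` and `asymmetry_median`. Genes with a zero condition mean
#'   get `NA` fold changes rather than infinities.
#' @export
compute_adjusted_log2fc <- function(counts, sample_sheet, expressed,
                                    size_factors = NULL) {
  counts <- as.matrix(counts)
  ctrl <- sample_sheet$sample[sample_sheet$condition == "control"]
  trt <- sample_sheet$sample[sample_sheet$condition == "treatment"]
  if (!length(ctrl) || !length(trt)) {
    stop("contrast needs at least one control and one treatment sample")
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  norm <- sweep(counts, 2, size_factors[colnames(counts)], "/")
  mc <- rowMeans(norm[, ctrl, drop = FALSE])
  mt <- rowMeans(norm[, trt, drop = FALSE])
  raw <- log2(mt / mc)
  status <- rep("ok", nrow(counts))
  status[mc == 0 & mt > 0] <- "zero_control"
  status[mt == 0 & mc > 0] <- "zero_treatment"
  status[mc == 0 & mt == 0] <- "zero_both"
  raw[status != "ok"] <- NA_real_

  if (is.logical(expressed)) expressed <- rownames(counts)[expressed]
  if (!length(expressed)) stop("expressed gene set is empty")
  idx <- rownames(counts) %in% expressed
  m <- median(raw[idx], na.rm = TRUE)
  if (!is.finite(m)) stop("asymmetry median undefined on the expressed set")

  out <- data.frame(gene_id = rownames(counts), raw_log2fc = raw,
                    adjusted_log2fc = raw - m, status = status,
                    row.names = NULL)
  attr(out, "size_factors") <- size_factors
  attr(out, "asymmetry_median") <- m
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Per-replicate-pair adjusted log2 fold changes
#'
#' For each matched control/treatment replicate pair, the per-gene log2
#' ratio of normalized counts, re-centered by subtracting that pair's median
#' over the expressed gene set. Used by the reproducibility filter.
#'
#' @param counts integer matrix genes x samples.
#' @param sample_sheet `data.frame` with columns `sample`, `condition` and
#'   `pair`; every pair must contain exactly one control and one treatment
#'   sample.
#' @param expressed expressed gene ids (or logical per row).
#' @param size_factors optional precomputed size factors.
#' @return Numeric matrix genes x pairs of adjusted log2 fold changes;
#'   ratios with a zero count on either side are `NA`.
#' @export
per_replicate_log2fc <- function(counts, sample_sheet, expressed,
                                 size_factors = NULL) {
  counts <- as.matrix(counts)
  ss <- sample_sheet[!is.na(sample_sheet$pair), , drop = FALSE]
  if (!nrow(ss)) stop("sample sheet defines no replicate pairs")
  split_pairs <- split(ss, ss$pair)
  orphans <- names(split_pairs)[vapply(split_pairs, function(p) {
    sum(p$condition == "control") != 1L || sum(p$condition == "treatment") != 1L
  }, logical(1))]
  if (length(orphans)) {
    stop("unpaired replicate(s): pair(s) without exactly one control and ",
         "one treatment sample: ", paste(orphans, collapse = ", "))
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  norm <- sweep(counts, 2, size_factors[colnames(counts)], "/")
  if (is.logical(expressed)) expressed <- rownames(counts)[expressed]
  idx <- rownames(counts) %in% expressed

  pair_ids <- names(split_pairs)
  out <- matrix(NA_real_, nrow(counts), length(pair_ids),
                dimnames = list(rownames(counts), pair_ids))
  for (p in pair_ids) {
    pp <- split_pairs[[p]]
    cs <- pp$sample[pp$condition == "control"]
    ts <- pp$sample[pp$condition == "treatment"]
    l <- log2(norm[, ts] / norm[, cs])
    l[!is.finite(l)] <- NA_real_
    out[, p] <- l - median(l[idx], na.rm = TRUE)
  }
  out
}

#' Pearson correlation of fold-change vectors
#'
#' Aligns the two vectors on their shared (named) gene set, drops pairs with
#' non-finite entries, and returns the Pearson coefficient with the number
#' of genes used.
#'
#' @param fc_a,fc_b numeric vectors, named by gene id when alignment is
#'   needed.
#' @param method correlation flavor; only `"pearson"` is supported.
#' @return list with elements `estimate` and `n`.
#' @export
correlate <- function(fc_a, fc_b, method = "pearson") {
  method <- match.arg(method, "pearson")
  if (!is.null(names(fc_a)) && !is.null(names(fc_b))) {
    shared <- intersect(names(fc_a), names(fc_b))
    fc_a <- fc_a[shared]
    fc_b <- fc_b[shared]
  } else if (length(fc_a) != length(fc_b)) {
    stop("unnamed vectors must have equal length")
  }
  ok <- is.finite(fc_a) & is.finite(fc_b)
  fc_a <- fc_a[ok]; fc_b <- fc_b[ok]
  if (length(fc_a) < 3L) stop("need at least 3 finite paired values")
  list(estimate = cor(fc_a, fc_b, method = "pearson"), n = length(fc_a))
}
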