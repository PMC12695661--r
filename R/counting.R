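#' Count stranded fragments in per-gene windows
#'
#' A fragment is counted for a window when it overlaps the window by at
#' least one bp, satisfies the strand rule, and does not overlap any
#' exclusion region (e.g. rRNA/tRNA). A fragment overlapping the windows of
#' two genes is counted once per window. Counting is order-invariant.
#'
#' Strand rules relative to the window strand: `"sense"` requires the
#' fragment strand to equal the window strand, `"antisense"` the opposite,
#' `"unstranded"` ignores strand.
#'
#' @param fragments a named list of `GRanges` (one element per sample) or a
#'   `GRangesList`; strand must be `+` or `-` for stranded modes.
#' @param windows `GRanges` of per-gene windows with a `gene_id` metadata
#'   column and strand set (see [compute_counting_window()]).
#' @param exclude optional `GRanges` of exclusion regions; any fragment
#'   overlapping one (strand-blind) is discarded before counting.
#' @param mode overlap strand rule; see Details.
#' @return Integer matrix genes x samples (rownames `gene_id`, colnames the
#'   sample names), with a `"report"` attribute tallying fragments dropped
#'   per sample (`excluded`: overlapping an exclusion region; `off_chrom`:
#'   on a chromosome absent from `windows`; `no_strand`: strand `*` in a
#'   stranded mode).
#' @export
count_fragments <- function(fragments, windows, exclude = NULL,
                            mode = c("sense", "antisense", "unstranded")) {
  mode <- match.arg(mode)
  if (inherits(fragments, "GRanges")) fragments <- list(sample = fragments)
  fragments <- as.list(fragments)
  if (is.null(names(fragments)) || any(names(fragments) == "")) {
    names(fragments) <- paste0("sample", seq_along(fragments))
  }
  gene_ids <- mcols(windows)$gene_id
  if (is.null(gene_ids)) stop("windows must carry a gene_id metadata column")
  win_strand <- as.character(strand(windows))
  win_chroms <- unique(as.character(seqnames(windows)))

  counts <- matrix(0L, nrow = length(windows), ncol = length(fragments),
                   dimnames = list(gene_ids, names(fragments)))
  report <- data.frame(sample = names(fragments), excluded = 0L,
                       off_chrom = 0L, no_strand = 0L)

  for (j in seq_along(fragments)) {
    frag <- fragments[[j]]
    fs <- as.character(strand(frag))
    if (mode != "unstranded") {
      bad <- fs == "*"
      report$no_strand[j] <- sum(bad)
      frag <- frag[!bad]
      fs <- fs[!bad]
    }
    off <- !(as.character(seqnames(frag)) %in% win_chroms)
    report$off_chrom[j] <- sum(off)
    if (!is.null(exclude) && length(exclude)) {
      excl <- overlapsAny(frag, exclude, ignore.strand = TRUE)
      report$excluded[j] <- sum(excl)
      frag <- frag[!excl]
      fs <- fs[!excl]
    }
    if (!length(frag)) next
    hits <- findOverlaps(frag, windows, ignore.strand = TRUE)
    if (mode != "unstranded") {
      fstr <- fs[queryHits(hits)]
      wstr <- win_strand[subjectHits(hits)]
      keep <- if (mode == "sense") fstr == wstr else fstr != wstr
      hits <- hits[keep]
    }
    counts[, j] <- tabulate(subjectHits(hits), nbins = length(windows))
  }
  storage.mode(counts) <- "integer"
  attr(counts, "report") <- report
  counts
}

#' Quantify upstream antisense transcription
#'
#' Counts fragments on the strand opposite each gene within the -1.7 kb to
#' -200 bp upstream window (see [antisense_windows()]). Requires a
#' strand-specific library; non-stranded data cannot resolve antisense
#' signal and is rejected.
#'
#' @param fragments as in [count_fragments()].
#' @param genes a [gene_models] table.
#' @param stranded logical flag asserting the library is strand-specific.
#' @param exclude optional exclusion regions.
#' @return Integer matrix genes x samples of antisense counts.
#' @export
quantify_antisense <- function(fragments, genes, stranded = TRUE, exclude = NULL) {
  if (!isTRUE(stranded)) {
    stop("antisense quantification requires strand-specific data: ",
         "a non-stranded library cannot distinguish upstream antisense ",
         "transcription from sense signal of neighboring genes")
  }
  win <- antisense_windows(genes)
  # window strand already encodes the expected (antisense) fragment strand
  count_fragments(fragments, win, exclude = exclude, mode = "sense")
}

#' Transcripts-per-million on counting windows
#'
#' \eqn{TPM_{ij} = 10^6 (c_{ij}/L_i) / \sum_k (c_{kj}/L_k)} with \eqn{L} the
#' counting-window length in kb. Columns sum to 1e6 exactly up to floating
#' point.
#'
#' @param counts integer matrix genes x samples.
#' @param lengths window length in bp per gene (same order as rows).
#' @return Numeric matrix of TPM values.
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts))
  if (any(lengths <= 0)) stop("window lengths must be positive")
  rate <- counts / (lengths / 1000)
  cs <- colSums(rate)
  if (any(cs == 0)) {
    stop("TPM undefined for all-zero sample(s): ",
         paste(colnames(counts)[cs == 0], collapse = ", "))
  }
  sweep(rate, 2, cs, "/") * 1e6
}

#' Low-count and expression filters
#'
#' A gene is `low_count_excluded` when its mean raw count is at or below
#' `low_count` in *both* the control and the treatment condition; it is
#' `expressed` when not excluded and the average of the control-mean and
#' treatment-mean TPM exceeds `tpm_expressed`.
#'
#' @param counts integer matrix genes x samples (raw, unscaled).
#' @param tpm TPM matrix with identical dimensions.
#' @param sample_sheet `data.frame` with columns `sample` and `condition`
#'   (`"control"` / `"treatment"`), covering every column of `counts`.
#' @param low_count mean-count threshold (inclusive) for exclusion.
#' @param tpm_expressed TPM threshold (exclusive) for the expressed flag.
#' @return `data.frame` with per-gene mean counts and TPM per condition and
#'   logical columns `low_count_excluded` and `expressed`.
#' @export
apply_expression_filters <- function(counts, tpm, sample_sheet,
                                     low_count = 20, tpm_expressed = 15) {
  counts <- as.matrix(counts)
  ctrl <- sample_sheet$sample[sample_sheet$condition == "control"]
  trt <- sample_sheet$sample[sample_sheet$condition == "treatment"]
  if (!length(ctrl) || !length(trt)) {
    stop("sample sheet must define both control and treatment samples")
  }
  if (!all(c(ctrl, trt) %in% colnames(counts))) {
    stop("sample sheet names samples absent from the count matrix")
  }
  mc_c <- rowMeans(counts[, ctrl, drop = FALSE])
  mc_t <- rowMeans(counts[, trt, drop = FALSE])
  mt_c <- rowMeans(tpm[, ctrl, drop = FALSE])
  mt_t <- rowMeans(tpm[, trt, drop = FALSE])
  low <- mc_c <= low_count & mc_t <= low_count
  data.frame(
    gene_id = rownames(counts),
    mean_count_control = mc_c, mean_count_treatment = mc_t,
    mean_tpm_control = mt_c, mean_tpm_treatment = mt_t,
    low_count_excluded = low,
    expressed = !low & (mt_c + mt_t) / 2 > tpm_expressed,
    row.names = NULL
  )
}
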