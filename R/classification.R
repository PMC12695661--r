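#' Regulation-class assignment from linear fold changes
#'
#' The `standard` scheme partitions the linear fold-change axis
#' (f = treatment/control) into: HU (f >= 2), IU (1.5 <= f < 2),
#' SU (1.3 <= f < 1.5), NC (1/1.2 < f < 1.2), SD (1/1.5 <= f < 1/1.3),
#' ID (1/2 <= f < 1/1.5), HD (f < 1/2); the deliberate slivers between NC
#' and the S classes fall into `Others`. Down-class bounds follow the
#' fold-down reading (e.g. SD is >1.3- and <=1.5-fold downregulation).
#'
#' The `a485` scheme is defined on fold-downs d = 1/f: ND (d <= 1.2),
#' ID (1.5 < d <= 2), HD1 (2 < d <= 4), HD2 (d > 4). Fold-downs in the
#' deliberate gap (1.2, 1.5] are returned as `NA` (unlabeled), with the gap
#' count reported in the `"gap_n"` attribute.
#'
#' @param fc numeric vector of linear fold changes (must be finite and
#'   positive; genes without a defined fold change should not be passed).
#' @param scheme `"standard"` or `"a485"`.
#' @return Character vector of class labels, same length as `fc`.
#' @export
assign_class <- function(fc, scheme = c("standard", "a485")) {
  scheme <- match.arg(scheme)
  if (any(!is.finite(fc)) || any(fc <= 0)) {
    stop("fold changes must be finite and positive; filter undefined genes first")
  }
  if (scheme == "standard") {
    lab <- rep("Others", length(fc))
    lab[fc >= 2] <- "HU"
    lab[fc >= 1.5 & fc < 2] <- "IU"
    lab[fc >= 1.3 & fc < 1.5] <- "SU"
    lab[fc > 1 / 1.2 & fc < 1.2] <- "NC"
    d <- 1 / fc
    lab[d > 1.3 & d <= 1.5] <- "SD"
    lab[d > 1.5 & d <= 2] <- "ID"
    lab[d > 2] <- "HD"
    lab
  } else {
    d <- 1 / fc
    lab <- rep(NA_character_, length(fc))
    lab[d <= 1.2] <- "ND"
    lab[d > 1.5 & d <= 2] <- "ID"
    lab[d > 2 & d <= 4] <- "HD1"
    lab[d > 4] <- "HD2"
    attr(lab, "gap_n") <- sum(is.na(lab))
    lab
  }
}

#' Two-time-point down-class averaging
#'
#' For contrasts measured at two depletion time points, a gene qualifies as
#' downregulated only when it is more than `gate`-fold down at *both* time
#' points; qualifying genes are labeled by the arithmetic mean of the two
#' fold-downs: HD (> 2), ID (1.5, 2], SD (1.3, 1.5]. Everything else,
#' including genes with a missing time point, is `"unclassified"`.
#'
#' @param fc_2h,fc_4h numeric vectors of linear fold changes
#'   (treatment/control) at the two time points; `NA` allowed.
#' @param gate fold-down gate that must hold at both time points.
#' @return Character vector of labels in `HD`, `ID`, `SD`, `unclassified`.
#' @export
average_npc_classes <- function(fc_2h, fc_4h, gate = 1.3) {
  stopifnot(length(fc_2h) == length(fc_4h))
  d2 <- 1 / fc_2h
  d4 <- 1 / fc_4h
  lab <- rep("unclassified", length(fc_2h))
  both <- !is.na(d2) & !is.na(d4) & d2 > gate & d4 > gate
  avg <- (d2 + d4) / 2
  lab[both & avg > 2] <- "HD"
  lab[both & avg > 1.5 & avg <= 2] <- "ID"
  lab[both & avg > 1.3 & avg <= 1.5] <- "SD"
  lab
}

#' Merge regulation classes smaller than a minimum size
#'
#' Classes on the up side (HU, IU, SU) and down side (HD, ID, SD) are
#' treated independently; any class with fewer than `min_n` genes merges
#' with its neighbor toward NC on the same side (the mildest class, if
#' small, merges outward instead). Merging iterates until every surviving
#' group reaches `min_n` or a side collapses to a single group. Merged
#' groups carry a joint name ordered extreme-to-mild, e.g. `"HU + IU"`.
#' NC and Others never merge.
#'
#' @param labels character vector of standard-scheme class labels.
#' @param min_n minimum class size.
#' @return Character vector of merged labels (same length/order as input),
#'   with a `"mapping"` attribute giving the label -> merged-label map.
#' @export
merge_small_classes <- function(labels, min_n = 10) {
  sides <- list(c("HU", "IU", "SU"), c("HD", "ID", "SD"))
  mapping <- setNames(unique(labels), unique(labels))
  for (side in sides) {
    groups <- lapply(side[side %in% labels], identity)
    repeat {
      if (length(groups) <= 1L) break
      n <- vapply(groups, function(g) sum(labels %in% g), integer(1))
      small <- which(n < min_n)
      if (!length(small)) break
      i <- small[1L]
      j <- if (i < length(groups)) i + 1L else i - 1L
      merged <- union(groups[[min(i, j)]], groups[[max(i, j)]])
      groups[[min(i, j)]] <- merged[order(match(merged, side))]
      groups[[max(i, j)]] <- NULL
    }
    for (g in groups) {
      mapping[g] <- paste(g, collapse = " + ")
    }
  }
  out <- unname(mapping[labels])
  attr(out, "mapping") <- mapping
  out
}

#' Replicate-reproducibility filter
#'
#' A gene passes when (1) its initial fold change is at least `fc_threshold`
#' in the stated direction and (2) the same-direction change of at least
#' `per_replicate_threshold`-fold holds in at least
#' `ceiling(min_fraction * n_replicates)` of the additional replicate
#' pairs. `NA` replicate values count as failures.
#'
#' @param initial_log2fc numeric vector of initial adjusted log2 fold
#'   changes.
#' @param replicate_log2fc matrix genes x replicate pairs of adjusted log2
#'   fold changes (see [per_replicate_log2fc()]); rows aligned with
#'   `initial_log2fc`.
#' @param direction `"down"` or `"up"`.
#' @param fc_threshold linear fold threshold on the initial measurement.
#' @param per_replicate_threshold linear fold threshold per replicate.
#' @param min_fraction minimum fraction of replicates that must agree.
#' @return Logical vector, one verdict per gene.
#' @export
reproducibility_filter <- function(initial_log2fc, replicate_log2fc,
                                   direction = c("down", "up"),
                                   fc_threshold = 1.3,
                                   per_replicate_threshold = 1.3,
                                   min_fraction = 0.5) {
  direction <- match.arg(direction)
  replicate_log2fc <- as.matrix(replicate_log2fc)
  n_rep <- ncol(replicate_log2fc)
  if (n_rep == 0L) stop("no replicate pairs supplied")
  stopifnot(length(initial_log2fc) == nrow(replicate_log2fc))
  sgn <- if (direction == "down") -1 else 1
  init_ok <- !is.na(initial_log2fc) &
    sgn * initial_log2fc >= log2(fc_threshold)
  hits <- rowSums(sgn * replicate_log2fc >= log2(per_replicate_threshold),
                  na.rm = TRUE)
  init_ok & hits >= ceiling(min_fraction * n_rep)
}

#' Fraction of a gene set with consistent replicate regulation
#'
#' @param replicate_log2fc matrix genes x replicate pairs (rownames are gene
#'   ids).
#' @param gene_set character vector of gene ids (non-empty, present in the
#'   matrix).
#' @param min_replicates minimum number of replicates in which the change
#'   must hold.
#' @param threshold linear fold threshold per replicate.
#' @param direction `"down"` or `"up"`.
#' @return Fraction in \[0, 1\].
#' @export
consistency_fraction <- function(replicate_log2fc, gene_set,
                                 min_replicates, threshold = 1.3,
                                 direction = c("down", "up")) {
  direction <- match.arg(direction)
  if (!length(gene_set)) stop("gene_set is empty")
  m <- as.matrix(replicate_log2fc)
  missing <- setdiff(gene_set, rownames(m))
  if (length(missing)) {
    stop("gene_set members absent from replicate matrix: ",
         paste(head(missing, 5), collapse = ", "))
  }
  sgn <- if (direction == "down") -1 else 1
  hits <- rowSums(sgn * m[gene_set, , drop = FALSE] >= log2(threshold),
                  na.rm = TRUE)
  mean(hits >= min_replicates)
}

#' Call upstream-antisense upregulation candidates
#'
#' Genes whose upstream antisense transcription increases more than
#' `threshold_fc`-fold, restricted to genes whose sense transcript is
#' expressed and whose antisense counts passed the low-count filter. The
#' result is a candidate list pending curation: genuinely independent
#' antisense initiation cannot be separated from overlapping-transcript
#' artifacts without inspection, which this package does not automate.
#'
#' @param antisense_log2fc named numeric vector of antisense adjusted log2
#'   fold changes (named by gene id).
#' @param sense_expressed character vector of gene ids with expressed sense
#'   transcripts.
#' @param antisense_included gene ids whose antisense counts passed the
#'   low-count filter; defaults to all names of `antisense_log2fc`.
#' @param threshold_fc linear fold-change threshold (exclusive).
#' @return Character vector of candidate gene ids, with attribute
#'   `"status"` set to `"candidates pending curation"`.
#' @export
call_uastrx_up <- function(antisense_log2fc, sense_expressed,
                           antisense_included = names(antisense_log2fc),
                           threshold_fc = 2) {
  ids <- names(antisense_log2fc)
  if (is.null(ids)) stop("antisense_log2fc must be named by gene id")
  keep <- !is.na(antisense_log2fc) &
    antisense_log2fc > log2(threshold_fc) &
    ids %in% sense_expressed &
    ids %in% antisense_included
  out <- ids[keep]
  attr(out, "status") <- "candidates pending curation"
  out
}

#' Group standard-scheme labels into direction summaries
#'
#' @param labels character vector of standard-scheme labels (`NA` for genes
#'   without a defined fold change).
#' @return Character vector in `down` (HD/ID/SD), `up` (HU/IU/SU), `NC`,
#'   `none` (Others and undefined).
#' @export
regulation_grouping <- function(labels) {
  out <- rep("none", length(labels))
  out[labels %in% c("HD", "ID", "SD")] <- "down"
  out[labels %in% c("HU", "IU", "SU")] <- "up"
  out[labels %in% "NC"] <- "NC"
  out
}
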