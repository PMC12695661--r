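#' Gene model table
#'
#' A `gene_models` object is a plain `data.frame` (one row per gene) holding
#' the representative transcript of each gene: genomic span, strand, TSS/TES
#' and biotype. All coordinates are 1-based inclusive (GRanges convention);
#' BED input/output converts at the I/O boundary.
#'
#' @param gene_id character vector of gene identifiers (unique).
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"` per gene.
#' @param start,end 1-based inclusive genomic span of the representative
#'   transcript.
#' @param transcript_id optional representative transcript identifiers.
#' @param biotype optional biotype labels (e.g. `"protein_coding"`).
#'
#' @return A `data.frame` of class `gene_models` with columns `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `tss`, `tes`, `transcript_length`,
#'   `transcript_id`, `biotype`. The TSS is `start` for plus-strand genes and
#'   `end` for minus-strand genes.
#' @export
gene_models <- function(gene_id, chrom, strand, start, end,
                        transcript_id = NA_character_,
                        biotype = NA_character_) {
  stopifnot(length(start) == length(gene_id),
            length(end) == length(gene_id))
  chrom <- rep_len(chrom, length(gene_id))
  strand <- rep_len(strand, length(gene_id))
  if (anyDuplicated(gene_id)) {
    stop("duplicated gene_id in gene model table: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  if (length(gene_id) > 0) {
    if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(end < start)) stop("end must be >= start")
  }
  df <- data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    start = as.integer(start),
    end = as.integer(end),
    stringsAsFactors = FALSE
  )
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  df$tes <- ifelse(df$strand == "+", df$end, df$start)
  df$transcript_length <- df$end - df$start + 1L
  df$transcript_id <- rep_len(as.character(transcript_id), nrow(df))
  df$biotype <- rep_len(as.character(biotype), nrow(df))
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Select one representative transcript per gene
#'
#' Two-step selection mirroring standard nascent-RNA reference building:
#' transcripts of the retained biotypes with steady-state expression
#' (TPM above `tpm_min`) and an active-promoter mark peak within
#' `peak_distance` of their TSS are deemed peak-supported; among these the
#' longest isoform per gene wins. Genes with no peak-supported isoform fall
#' back to their longest isoform overall. Length ties break by
#' lexicographically smallest `transcript_id` so the selection is
#' deterministic.
#'
#' @param transcripts `data.frame` with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `start`, `end` (1-based inclusive) and `biotype`.
#' @param tpm named numeric vector of steady-state TPM per `transcript_id`
#'   (missing transcripts are treated as TPM 0), or `NULL`.
#' @param peaks promoter-mark peak summits: a `data.frame` with columns
#'   `chrom` and `summit` (1-based position), or `NULL` for none.
#' @param biotypes biotypes to retain.
#' @param tpm_min expression threshold (exclusive) for peak-supported status.
#' @param peak_distance maximum |summit - TSS| in bp for a peak to support a
#'   transcript.
#'
#' @return A [gene_models] table with exactly one row per retained gene.
#'   Transcripts lacking a `gene_id` are dropped and reported in the
#'   `"rejected"` attribute.
#' @export
select_reference_transcripts <- function(transcripts, tpm = NULL, peaks = NULL,
                                         biotypes = c("protein_coding", "lincRNA"),
                                         tpm_min = 2, peak_distance = 1000) {
  need <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  missing_cols <- setdiff(need, names(transcripts))
  if (length(missing_cols)) {
    stop("transcripts is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  tx <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  bad <- is.na(tx$gene_id) | tx$gene_id == ""
  rejected <- tx$transcript_id[bad]
  tx <- tx[!bad, , drop = FALSE]
  if ("biotype" %in% names(tx)) {
    tx <- tx[tx$biotype %in% biotypes, , drop = FALSE]
  }
  if (nrow(tx) == 0L) {
    out <- gene_models(character(), character(), character(), integer(), integer())
    attr(out, "rejected") <- rejected
    return(out)
  }

  tx$tss <- ifelse(tx$strand == "+", tx$start, tx$end)
  tx$len <- tx$end - tx$start + 1L

  tx$tpm <- if (is.null(tpm)) 0 else {
    v <- tpm[tx$transcript_id]
    v[is.na(v)] <- 0
    as.numeric(v)
  }

  tx$peak_supported <- FALSE
  if (!is.null(peaks) && nrow(as.data.frame(peaks)) > 0) {
    pk <- as.data.frame(peaks, stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "summit") %in% names(pk)))
    for (ch in unique(tx$chrom)) {
      s <- pk$summit[pk$chrom == ch]
      if (!length(s)) next
      i <- which(tx$chrom == ch)
      # nearest summit per TSS; supported if within peak_distance
      nearest <- vapply(tx$tss[i], function(p) min(abs(s - p)), numeric(1))
      tx$peak_supported[i] <- nearest <= peak_distance
    }
  }
  tx$expressed <- tx$tpm > tpm_min & tx$peak_supported

  pick <- function(sub) {
    cand <- if (any(sub$expressed)) sub[sub$expressed, , drop = FALSE] else sub
    cand <- cand[order(-cand$len, cand$transcript_id), , drop = FALSE]
    cand[1L, , drop = FALSE]
  }
  chosen <- do.call(rbind, lapply(split(tx, tx$gene_id), pick))
  chosen <- chosen[order(chosen$chrom, chosen$start), , drop = FALSE]

  out <- gene_models(chosen$gene_id, chosen$chrom, chosen$strand,
                     chosen$start, chosen$end,
                     transcript_id = chosen$transcript_id,
                     biotype = if ("biotype" %in% names(chosen)) chosen$biotype else NA)
  attr(out, "rejected") <- rejected
  out
}

.window_caps <- c("30" = 30000L, "60" = 90000L, "120" = 240000L)

#' Elongation-aware counting windows
#'
#' The quantified gene-body window runs from the TSS toward the TES on the
#' gene strand and is truncated at a cap set by the treatment duration:
#' 30 kb for 30 min, 90 kb for 60 min and 240 kb for 120 min, reflecting how
#' far elongating Pol II carries labeled nascent RNA into the gene body.
#' Other durations require `full_gene = TRUE` (whole span) and error
#' otherwise, preventing silent miscounting.
#'
#' @param genes a [gene_models] table.
#' @param treatment_minutes treatment duration; one of 30, 60, 120, or any
#'   other value together with `full_gene = TRUE`.
#' @param full_gene logical; use the full gene span regardless of duration.
#' @return `GRanges` (1-based) with one window per gene, `gene_id` metadata
#'   column, strand set to the gene strand.
#' @export
compute_counting_window <- function(genes, treatment_minutes, full_gene = FALSE) {
  cap <- if (full_gene) NA_integer_ else {
    key <- as.character(treatment_minutes)
    if (!key %in% names(.window_caps)) {
      stop("treatment duration ", treatment_minutes,
           " min has no defined counting cap; pass full_gene = TRUE to use ",
           "the whole gene span")
    }
    .window_caps[[key]]
  }
  if (nrow(genes) == 0L) {
    return(GRanges())
  }
  span <- genes$transcript_length
  w <- if (is.na(cap)) span else pmin(span, cap)
  win_start <- ifelse(genes$strand == "+", genes$tss, genes$tss - w + 1L)
  win_end <- ifelse(genes$strand == "+", genes$tss + w - 1L, genes$tss)
  gr <- GRanges(genes$chrom, IRanges(win_start, win_end), strand = genes$strand)
  mcols(gr)$gene_id <- genes$gene_id
  names(gr) <- genes$gene_id
  gr
}

#' Promoter windows around the TSS
#'
#' @param genes a [gene_models] table.
#' @param half_width half-width in bp (e.g. 2000, 400 or 200 for the nested
#'   promoter definitions).
#' @return `GRanges` spanning TSS +/- `half_width` (clipped at position 1),
#'   strand set to the gene strand, with a `gene_id` column.
#' @export
promoter_windows <- function(genes, half_width = 2000) {
  if (nrow(genes) == 0L) return(GRanges())
  gr <- GRanges(genes$chrom,
                IRanges(pmax(1L, genes$tss - as.integer(half_width)),
                        genes$tss + as.integer(half_width)),
                strand = genes$strand)
  mcols(gr)$gene_id <- genes$gene_id
  names(gr) <- genes$gene_id
  gr
}

#' Upstream antisense windows
#'
#' Window for quantifying upstream antisense transcription (uasTrx): the
#' region -1.7 kb to -200 bp upstream of the TSS in gene-strand coordinates,
#' on the strand opposite the gene. The returned strand is the strand on
#' which antisense fragments are expected, so counting these windows in
#' `mode = "sense"` quantifies antisense transcription.
#'
#' @param genes a [gene_models] table.
#' @param upstream numeric length-2: (far, near) upstream offsets in bp;
#'   default `c(1700, 200)`.
#' @return `GRanges` with a `gene_id` column; width `upstream[1] - upstream[2]`.
#' @export
antisense_windows <- function(genes, upstream = c(1700, 200)) {
  stopifnot(length(upstream) == 2, upstream[1] > upstream[2])
  if (nrow(genes) == 0L) return(GRanges())
  far <- as.integer(upstream[1]); near <- as.integer(upstream[2])
  plus <- genes$strand == "+"
  # plus-strand gene: [tss - far, tss - near - 1] on "-";
  # minus-strand gene: [tss + near + 1, tss + far] on "+"
  w_start <- ifelse(plus, genes$tss - far, genes$tss + near + 1L)
  w_end <- ifelse(plus, genes$tss - near - 1L, genes$tss + far)
  gr <- GRanges(genes$chrom,
                IRanges(pmax(1L, w_start), w_end),
                strand = ifelse(plus, "-", "+"))
  mcols(gr)$gene_id <- genes$gene_id
  names(gr) <- genes$gene_id
  gr
}
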