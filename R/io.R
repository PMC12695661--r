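# File I/O. GTF and BED conversions are delegated to rtracklayer; count
# matrices, gene tables and narrowPeak go through plain TSV writers with
# fixed schemas. All on-disk BED is 0-based half-open, everything in memory
# is 1-based (GRanges convention).

#' Write / read a gene-by-sample count matrix as TSV
#'
#' @param counts integer matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), as.data.frame(counts),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @return `read_counts_tsv` returns the integer matrix.
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write / read a gene model table as TSV
#' @param genes a [gene_models] table.
#' @param path file path.
#' @export
write_gene_models_tsv <- function(genes, path) {
  write.table(as.data.frame(genes), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_models_tsv
#' @export
read_gene_models_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  gene_models(df$gene_id, df$chrom, df$strand, df$start, df$end,
              transcript_id = df$transcript_id, biotype = df$biotype)
}

#' Export gene models as GTF
#'
#' Writes one `gene` and one `transcript` feature per gene with
#' `gene_id`/`transcript_id` attributes (GENCODE-style dialect).
#'
#' @param genes a [gene_models] table.
#' @param path output `.gtf` path.
#' @export
write_genes_gtf <- function(genes, path) {
  if (nrow(genes) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  mk <- function(type) {
    gr <- GRanges(genes$chrom, IRanges(genes$start, genes$end),
                  strand = genes$strand)
    mcols(gr)$source <- "eureg"
    mcols(gr)$type <- type
    mcols(gr)$gene_id <- genes$gene_id
    mcols(gr)$transcript_id <- ifelse(is.na(genes$transcript_id),
                                      paste0(genes$gene_id, ".1"),
                                      genes$transcript_id)
    gr
  }
  gr <- c(mk("gene"), mk("transcript"))
  gr <- gr[order(as.character(seqnames(gr)), start(gr))]
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Import transcripts from a GTF file
#'
#' Reads `transcript` features and returns the transcript table expected by
#' [select_reference_transcripts()]. The biotype is taken from the
#' `transcript_type` attribute (GENCODE) falling back to `transcript_biotype`
#' or `gene_type`.
#'
#' @param path a `.gtf` file.
#' @return `data.frame` with `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `biotype`.
#' @export
read_gtf_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[mcols(gr)$type == "transcript"]
  bt <- mcols(gr)$transcript_type
  if (is.null(bt)) bt <- mcols(gr)$transcript_biotype
  if (is.null(bt)) bt <- mcols(gr)$gene_type
  if (is.null(bt)) bt <- rep(NA_character_, length(gr))
  data.frame(
    transcript_id = mcols(gr)$transcript_id,
    gene_id = mcols(gr)$gene_id,
    chrom = as.character(seqnames(gr)),
    strand = as.character(strand(gr)),
    start = start(gr), end = end(gr),
    biotype = bt,
    stringsAsFactors = FALSE
  )
}

#' Write / read fragments as BED6
#'
#' One file per sample; strand in column 6; 0-based half-open on disk.
#'
#' @param fragments `GRanges` of fragments.
#' @param path output `.bed` path.
#' @export
write_fragments_bed <- function(fragments, path) {
  if (length(fragments) && is.null(names(fragments))) {
    names(fragments) <- paste0("frag", seq_along(fragments))
  }
  mcols(fragments)$score <- 0L
  rtracklayer::export(fragments, path, format = "bed")
  invisible(path)
}

#' @rdname write_fragments_bed
#' @export
read_fragments_bed <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' Write / read ENCODE narrowPeak
#'
#' Columns: chrom, chromStart (0-based), chromEnd, name, score, strand,
#' signalValue (peak height), pValue, qValue, peak (summit offset from
#' chromStart). In-memory representation uses 1-based `start`, `end` and
#' absolute 1-based `summit`.
#'
#' @param peaks `data.frame` with `peak_id`, `chrom`, `start`, `end`,
#'   `summit`, `height`.
#' @param path output `.narrowPeak` path.
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- data.frame(
    chrom = peaks$chrom,
    chromStart = peaks$start - 1L,
    chromEnd = peaks$end,
    name = peaks$peak_id,
    score = 0L,
    strand = ".",
    signalValue = peaks$height,
    pValue = -1,
    qValue = -1,
    peak = peaks$summit - peaks$start
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_narrowpeak
#' @export
read_narrowpeak <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(df) != 10L) {
    stop("narrowPeak file '", path, "' must have 10 columns, found ",
         ncol(df))
  }
  names(df) <- c("chrom", "chromStart", "chromEnd", "name", "score",
                 "strand", "signalValue", "pValue", "qValue", "peak")
  if (any(df$peak < 0)) {
    stop("narrowPeak file '", path, "' has no summit (peak = -1) at line(s): ",
         paste(head(which(df$peak < 0), 5), collapse = ", "))
  }
  data.frame(
    peak_id = df$name, chrom = df$chrom,
    start = df$chromStart + 1L, end = df$chromEnd,
    summit = df$chromStart + df$peak + 1L,
    height = df$signalValue,
    stringsAsFactors = FALSE
  )
}

#' Read a JASPAR-format position frequency matrix
#'
#' Parses the JASPAR text format (`>ID NAME` header, then four rows
#' `A [ 1 2 ... ]`) and returns a column-normalized probability matrix with
#' rows A, C, G, T, suitable for [Biostrings::matchPWM()].
#'
#' @param path a JASPAR `.jaspar`/`.pfm` text file.
#' @return 4 x w numeric probability matrix.
#' @export
read_jaspar_pwm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- grep("^[ACGT]", lines, value = TRUE)
  if (length(rows) != 4L) stop("expected 4 base rows in JASPAR file")
  parse_row <- function(l) {
    nums <- regmatches(l, gregexpr("[0-9.]+", sub("^[ACGT]", "", l)))[[1]]
    as.numeric(nums)
  }
  base <- substr(rows, 1, 1)
  m <- do.call(rbind, lapply(rows, parse_row))
  rownames(m) <- base
  m <- m[c("A", "C", "G", "T"), , drop = FALSE]
  sweep(m, 2, colSums(m), "/")
}

#' Built-in synthetic CTCF-like position weight matrix
#'
#' A non-palindromic probability matrix built around a CTCF-like consensus.
#' It is a synthetic stand-in for a database CTCF matrix (which must be
#' supplied by the user as a JASPAR file for real analyses); its only
#' guarantees are a defined consensus and orientation asymmetry, which is
#' what the simulator and the orientation scanner exercise.
#'
#' @param consensus_prob probability of the consensus base at each position.
#' @return 4 x 16 probability matrix with rows A, C, G, T and a
#'   `"consensus"` attribute.
#' @export
ctcf_pwm <- function(consensus_prob = 0.85) {
  consensus <- "CCACCAGGGGGCGCTA"
  bases <- c("A", "C", "G", "T")
  w <- nchar(consensus)
  m <- matrix((1 - consensus_prob) / 3, nrow = 4, ncol = w,
              dimnames = list(bases, NULL))
  cons <- strsplit(consensus, "")[[1]]
  for (j in seq_len(w)) m[cons[j], j] <- consensus_prob
  attr(m, "consensus") <- consensus
  m
}

#' Consensus sequence of a probability matrix
#' @param pwm 4 x w matrix with rows A, C, G, T.
#' @return Character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
}
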