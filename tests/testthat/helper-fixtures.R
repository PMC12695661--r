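# Shared fixture builders and independent oracles. Oracles deliberately use
# a different computational route than the implementation they check.

# A tiny deterministic gene set on two strands
make_test_genes <- function() {
  gene_models(
    gene_id = c("gA", "gB", "gC", "gD"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    strand = c("+", "-", "+", "-"),
    start = c(10000L, 60000L, 20000L, 300000L),
    end = c(14999L, 100000L, 319999L, 400000L)
  )
}

# Brute-force per-fragment overlap counting (the oracle for count_fragments):
# scans every fragment against every window with plain interval arithmetic.
brute_force_count <- function(fragments, windows, exclude = NULL,
                              mode = "sense") {
  win_chrom <- as.character(GenomicRanges::seqnames(windows))
  win_start <- GenomicRanges::start(windows)
  win_end <- GenomicRanges::end(windows)
  win_strand <- as.character(GenomicRanges::strand(windows))
  ex <- if (!is.null(exclude)) data.frame(
    chrom = as.character(GenomicRanges::seqnames(exclude)),
    start = GenomicRanges::start(exclude),
    end = GenomicRanges::end(exclude)) else NULL
  out <- sapply(fragments, function(fr) {
    fc <- as.character(GenomicRanges::seqnames(fr))
    fs <- GenomicRanges::start(fr)
    fe <- GenomicRanges::end(fr)
    fstr <- as.character(GenomicRanges::strand(fr))
    counts <- integer(length(windows))
    for (k in seq_along(fr)) {
      if (!is.null(ex) &&
          any(ex$chrom == fc[k] & fs[k] <= ex$end & fe[k] >= ex$start)) next
      for (w in seq_along(windows)) {
        if (win_chrom[w] != fc[k]) next
        if (fs[k] > win_end[w] || fe[k] < win_start[w]) next
        ok <- switch(mode,
                     sense = fstr[k] == win_strand[w],
                     antisense = fstr[k] != win_strand[w],
                     unstranded = TRUE)
        if (ok) counts[w] <- counts[w] + 1L
      }
    }
    counts
  })
  rownames(out) <- GenomicRanges::mcols(windows)$gene_id
  out
}

# Exact two-sided Mann-Whitney p by complete enumeration of group splits
mwu_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- combn(n1 + n2, n1, u_of)
  lo <- min(u_obs, n1 * n2 - u_obs)
  mean(pmin(us, n1 * n2 - us) <= lo + 1e-9)
}

# KS statistic by explicit ECDF sweep over all breakpoints
ks_D_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}
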