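small_config <- function(...) {
  simulation_config(n_genes = 30, n_chromosomes = 2, chrom_length = 1.5e6,
                    gene_length_range = c(2000, 40000), seed = 101, ...)
}

test_that("config validation", {
  expect_error(simulation_config(class_spectrum = list(
    NC = list(fraction = 0.5, fc_range = c(1, 1)))), "sum to 1")
  expect_error(simulation_config(class_spectrum = list(
    NC = list(fraction = 0.5, fc_range = c(1, 1)),
    HD = list(fraction = 0.5, fc_range = c(0.5, 1)))), ">= 1")
  expect_error(simulation_config(labeling_minutes = 45), "labeling")
})

test_that("gene model generation: geometry, determinism, empty case", {
  cfg <- small_config()
  gm1 <- simulate_gene_models(cfg, sequence = FALSE)
  gm2 <- simulate_gene_models(cfg, sequence = FALSE)
  expect_identical(gm1, gm2)                       # determinism contract
  g <- gm1$genes
  expect_equal(nrow(g), 30L)
  expect_true(all(c("+", "-") %in% g$strand))
  # lengths straddle the 30 kb cap
  expect_true(any(g$transcript_length < 30000))
  expect_true(any(g$transcript_length > 30000))
  # non-overlapping with >= 5 kb clearance per chromosome
  for (ch in unique(g$chrom)) {
    gg <- g[g$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) {
      expect_true(all(gg$start[-1] - gg$end[-nrow(gg)] >= 5000))
    }
  }
  # empty case
  gm0 <- simulate_gene_models(simulation_config(n_genes = 0, seed = 1,
                                                chrom_length = 1e5),
                              sequence = TRUE)
  expect_equal(nrow(gm0$genes), 0L)
  expect_s4_class(gm0$genome, "DNAStringSet")
  # placement failure signals chrom_length too small
  expect_error(simulate_gene_models(
    simulation_config(n_genes = 50, chrom_length = 1e5, seed = 1),
    sequence = FALSE), "chrom_length")
})

test_that("planted motifs are recovered by the orientation scanner", {
  cfg <- small_config()
  gm <- simulate_gene_models(cfg)
  tr <- gm$peak_truth
  bound <- tr[tr$ctcf_bound & !is.na(tr$orientation), ]
  g <- gm$genes[match(bound$gene_id, gm$genes$gene_id), ]
  summit <- ifelse(g$strand == "+", g$tss + bound$summit_offset,
                   g$tss - bound$summit_offset)
  got <- classify_motif_orientation(
    data.frame(chrom = g$chrom, summit = summit),
    gm$genome, ctcf_pwm(), g$strand)
  expect_equal(got$orientation, bound$orientation)
})

test_that("counts carry the planted fold changes and size factors", {
  cfg <- simulation_config(
    n_genes = 200, chrom_length = 8e6, seed = 11,
    n_replicates_initial = 4, n_replicates_extra = 0,
    nb_mean_range = c(1000, 1000),
    class_spectrum = list(NC = list(fraction = 0.5, fc_range = c(1, 1)),
                          HD = list(fraction = 0.5, fc_range = c(4, 4))),
    size_factor_range = c(1, 1))
  gm <- simulate_gene_models(cfg, sequence = FALSE)
  cc <- simulate_counts(cfg, gm$genes)
  expect_identical(cc$counts, simulate_counts(cfg, gm$genes)$counts)

  sheet <- cc$sample_sheet
  ctrl <- sheet$sample[sheet$condition == "control"]
  trt <- sheet$sample[sheet$condition == "treatment"]
  hd <- cc$truth$gene_id[cc$truth$true_class == "HD"]
  # planted 4-fold down, control mean 1000, 4 replicates: summed-count
  # ratio within the NB sampling band. Per-gene relative sd of the ratio is
  # sqrt(v_c/S_c^2 + v_t/S_t^2) with v = n(mu + disp*mu^2), S = n*mu:
  # ~10.5% here, so the median sits in the tight band and every gene
  # within +/- 4 sd (4 sd, not 3, because ~100 genes are tested jointly:
  # a per-gene 3 sd band fails some gene with ~25% probability).
  ratio <- rowSums(cc$counts[hd, ctrl]) / rowSums(cc$counts[hd, trt])
  expect_gt(median(ratio), 3.2)
  expect_lt(median(ratio), 5.0)
  rel_sd <- sqrt((1000 + 0.02 * 1000^2) / (4 * 1000^2) +
                   (250 + 0.02 * 250^2) / (4 * 250^2))
  expect_true(all(ratio > 4 * (1 - 4 * rel_sd) & ratio < 4 * (1 + 4 * rel_sd)))
  # ground-truth labels equal classification of the true fold changes
  expect_equal(cc$truth$true_class, assign_class(cc$truth$true_fc))
})

test_that("null simulation: count ratios center at 1", {
  cfg <- simulation_config(
    n_genes = 300, chrom_length = 2e7, seed = 13,
    n_replicates_initial = 4, n_replicates_extra = 0,
    nb_mean_range = c(500, 500),
    class_spectrum = list(NC = list(fraction = 1, fc_range = c(1, 1))),
    size_factor_range = c(1, 1))
  gm <- simulate_gene_models(cfg, sequence = FALSE)
  cc <- simulate_counts(cfg, gm$genes)
  sheet <- cc$sample_sheet
  ratio <- rowMeans(cc$counts[, sheet$condition == "treatment"]) /
    rowMeans(cc$counts[, sheet$condition == "control"])
  expect_lt(abs(mean(ratio) - 1), 0.02)
})

test_that("fragments conserve counts and round-trip through counting", {
  cfg <- simulation_config(n_genes = 20, chrom_length = 1.2e6, seed = 17,
                           gene_length_range = c(2000, 40000),
                           n_replicates_initial = 1, n_replicates_extra = 0,
                           nb_mean_range = c(5, 40))
  gm <- simulate_gene_models(cfg, sequence = FALSE)
  cc <- simulate_counts(cfg, gm$genes)
  frags <- simulate_fragments(cc$counts, gm$genes, labeling_minutes = 30,
                              antisense_counts = cc$antisense_counts,
                              seed = cfg$seed)
  win <- compute_counting_window(gm$genes, 30)
  sense <- count_fragments(frags, win, mode = "sense")
  expect_equal(unclass(sense)[, ], unclass(cc$counts)[, colnames(sense)],
               ignore_attr = TRUE)
  anti <- quantify_antisense(frags, gm$genes)
  expect_equal(unclass(anti)[, ], unclass(cc$antisense_counts)[, ],
               ignore_attr = TRUE)
  # minus-strand genes emit minus-strand sense fragments
  minus <- gm$genes$gene_id[gm$genes$strand == "-"][1]
  wm <- win[mcols(win)$gene_id == minus]
  fr <- frags[[1]]
  inside <- fr[overlapsAny(fr, wm, ignore.strand = TRUE)]
  expect_true(all(as.character(strand(inside)) == "-"))
  # window shorter than fragment length is a config error
  expect_error(simulate_fragments(cc$counts, gm$genes,
                                  fragment_length = 50000), "shorter")
})

test_that("signal tracks: anchoring identity and planted ATAC fractions", {
  cfg <- simulation_config(n_genes = 150, chrom_length = 7e6, seed = 19,
                           atac = list(n_extra_peaks = 400))
  gm <- simulate_gene_models(cfg, sequence = FALSE)
  cc <- simulate_counts(cfg, gm$genes)
  sig <- simulate_signal_tracks(cfg, gm$genes, cc$truth, gm$ctcf_peaks)

  # anchored normalization removes the planted 2x confounder exactly
  nc <- cc$truth$gene_id[cc$truth$true_fc == 1 & !cc$truth$uastrx]
  pq <- polii_normalize_quantify(sig$polii$promoter_counts,
                                 sig$polii$body_counts, nc)
  expect_equal(median(pq$body_log2fc[match(nc, pq$gene_id)]), 0,
               tolerance = 1e-12)
  expect_lt(abs(attr(pq, "anchoring_factor") - cfg$polii$confounder), 0.2)

  # planted loss fraction recovered within binomial error
  at <- sig$atac
  res <- atac_differential(at$counts, at$sample_sheet, at$summits)
  planted <- mean(at$truth$atac_fc < 1)
  se <- sqrt(planted * (1 - planted) / nrow(at$truth))
  expect_lt(abs(res$fraction_loss - planted), 0.02 + 3 * se)
})

test_that("dataset writer emits a complete, reproducible directory", {
  cfg <- small_config()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- simulate_dataset(cfg, d1, force = TRUE)
  m2 <- simulate_dataset(cfg, d2, force = TRUE)
  expect_equal(m1$md5, m2$md5)                 # byte-identical outputs
  expect_true(all(c("genome.fa", "genes.gtf", "counts.tsv",
                    "sample_sheet.tsv", "ground_truth.tsv",
                    "ctcf_peaks.narrowPeak", "config.json") %in% m1$file))
  expect_error(simulate_dataset(cfg, d1), "force")

  # narrowPeak round trip preserves summit and height
  pk <- read_narrowpeak(file.path(d1, "ctcf_peaks.narrowPeak"))
  gm <- simulate_gene_models(cfg)
  expect_equal(pk$summit, gm$ctcf_peaks$summit)
  expect_equal(pk$height, gm$ctcf_peaks$height, tolerance = 1e-6)
  # counts round trip
  cc <- simulate_counts(cfg, gm$genes)
  expect_identical(read_counts_tsv(file.path(d1, "counts.tsv")), cc$counts)
  # GTF round trip preserves transcript coordinates, strand and ids
  tx <- read_gtf_transcripts(file.path(d1, "genes.gtf"))
  tx <- tx[match(gm$genes$transcript_id, tx$transcript_id), ]
  expect_equal(tx$gene_id, gm$genes$gene_id)
  expect_equal(tx$start, gm$genes$start)
  expect_equal(tx$end, gm$genes$end)
  expect_equal(tx$strand, gm$genes$strand)
})
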