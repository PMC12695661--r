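test_that("promoter peak geometry: signed distances and window flags", {
  genes <- gene_models(c("gp", "gm"), "chr1", c("+", "-"),
                       c(10000L, 30000L), c(20000L, 40000L))
  # gp TSS = 10000 (+), gm TSS = 40000 (-)
  peaks <- data.frame(chrom = "chr1",
                      summit = c(9850L, 39850L),
                      height = c(7, 9))
  ann <- annotate_promoter_peaks(peaks, genes)
  # summit at TSS-150 on a plus-strand gene: distance -150 (upstream)
  expect_equal(ann$nearest_distance[1], -150)
  expect_true(ann$in_200bp[1])
  # summit 150 bp left of a minus-strand TSS is downstream: +150
  expect_equal(ann$nearest_distance[2], 150)
  expect_equal(ann$peak_height[2], 9)

  # nearest rule with two peaks; both counted for the 2 kb flag
  peaks2 <- data.frame(chrom = "chr1", summit = c(9700L, 8500L),
                       height = c(1, 2))
  ann2 <- annotate_promoter_peaks(peaks2, genes[1, ])
  expect_equal(ann2$nearest_distance, -300)
  expect_true(ann2$in_2kb)
  expect_true(ann2$in_400bp)    # -300 is inside the 400 bp window
  expect_false(ann2$in_200bp)

  expect_error(annotate_promoter_peaks(
    data.frame(chrom = "chr1", summit = NA), genes), "summit")
})

test_that("window nesting in_200bp => in_400bp => in_2kb (property)", {
  set.seed(43)
  genes <- gene_models(paste0("g", 1:50), "chr1",
                       sample(c("+", "-"), 50, TRUE),
                       seq(10000L, by = 20000L, length.out = 50),
                       seq(15000L, by = 20000L, length.out = 50))
  peaks <- data.frame(chrom = "chr1",
                      summit = sample(5000:1100000, 300),
                      height = runif(300, 1, 50))
  ann <- annotate_promoter_peaks(peaks, genes)
  expect_true(all(!ann$in_200bp | ann$in_400bp))
  expect_true(all(!ann$in_400bp | ann$in_2kb))
})

test_that("RAD21/CTCF ratio from summit-paired peaks", {
  genes <- gene_models("g", "chr1", "+", 10000L, 20000L)
  ctcf <- data.frame(chrom = "chr1", summit = 9900L, height = 10)
  rad <- data.frame(chrom = "chr1", summit = 9930L, height = 4)
  ann <- annotate_promoter_peaks(ctcf, genes, rad21_peaks = rad)
  expect_equal(ann$rad21_ctcf_ratio, 0.4)
  # beyond the pairing distance: undefined, not zero
  rad_far <- data.frame(chrom = "chr1", summit = 9700L, height = 4)
  ann2 <- annotate_promoter_peaks(ctcf, genes, rad21_peaks = rad_far)
  expect_true(is.na(ann2$rad21_ctcf_ratio))
})

test_that("motif orientation is relative to the gene strand", {
  pwm <- ctcf_pwm()
  cons <- attr(pwm, "consensus")
  set.seed(47)
  bg <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  plant <- function(seq_str, at, motif) {
    paste0(substr(seq_str, 1, at - 1), motif,
           substr(seq_str, at + nchar(motif), nchar(seq_str)))
  }
  rc <- as.character(reverseComplement(DNAString(cons)))
  genome_fwd <- DNAStringSet(c(chr1 = plant(bg, 993, cons)))
  genome_rev <- DNAStringSet(c(chr1 = plant(bg, 993, rc)))
  genome_both <- DNAStringSet(c(chr1 = plant(plant(bg, 940, cons), 1040, rc)))
  s <- data.frame(chrom = "chr1", summit = 1000L)

  # consensus on + strand, gene on +: forward
  expect_equal(classify_motif_orientation(s, genome_fwd, pwm, "+")$orientation,
               "forward")
  # same sequence, gene on -: reverse (orientation is gene-relative)
  expect_equal(classify_motif_orientation(s, genome_fwd, pwm, "-")$orientation,
               "reverse")
  expect_equal(classify_motif_orientation(s, genome_rev, pwm, "+")$orientation,
               "reverse")
  expect_equal(classify_motif_orientation(s, genome_rev, pwm, "-")$orientation,
               "forward")
  expect_equal(classify_motif_orientation(s, genome_both, pwm, "+")$orientation,
               "both")
  # no planted motif: none
  expect_equal(classify_motif_orientation(
    s, DNAStringSet(c(chr1 = bg)), pwm, "+")$orientation, "none")
  # jointly flipping gene strand and motif strand leaves orientation fixed
  expect_equal(
    classify_motif_orientation(s, genome_fwd, pwm, "+")$orientation,
    classify_motif_orientation(s, genome_rev, pwm, "-")$orientation)
  # truncation at contig bounds warns
  expect_warning(classify_motif_orientation(
    data.frame(chrom = "chr1", summit = 30L),
    DNAStringSet(c(chr1 = bg)), pwm, "+"), "truncat")
})

test_that("binding position summaries per class", {
  d <- c(a = -79, b = -79, c = -79, d = 100, e = -100, f = 600, g = NA)
  cl <- c(a = "X", b = "X", c = "X", d = "Y", e = "Y", f = "Y", g = "Z")
  s <- summarize_binding_positions(d, cl, window = 400)
  expect_equal(s$median_distance[s$class == "X"], -79)
  expect_equal(s$median_distance[s$class == "Y"], 0)   # symmetric +/-100
  # f is outside the 400 bp window; g has no peak; Z omitted with note
  expect_equal(s$n[s$class == "Y"], 2L)
  expect_equal(attr(s, "omitted"), "Z")
})

test_that("anchored Pol II normalization", {
  set.seed(53)
  n <- 101
  ids <- paste0("g", 1:n)
  ctrl_body <- rpois(n, 1000)
  # global 2x library confounder, bodies truly unchanged
  prom <- cbind(control = rpois(n, 500), treatment = rpois(n, 500) * 2L)
  body <- cbind(control = ctrl_body, treatment = ctrl_body * 2L)
  rownames(prom) <- rownames(body) <- ids
  res <- polii_normalize_quantify(prom, body, nc_gene_set = ids)
  expect_equal(attr(res, "anchoring_factor"), 2.0)
  expect_equal(res$body_log2fc, rep(0, n))

  # noisy bodies: anchoring factor recovers the planted confounder and the
  # NC median is exactly zero, including at even set sizes
  for (n2 in c(100, 101)) {
    ids2 <- paste0("g", 1:n2)
    b2 <- cbind(control = rpois(n2, 2000),
                treatment = rpois(n2, 2000 * 1.7))
    p2 <- cbind(control = rpois(n2, 500), treatment = rpois(n2, 500 * 1.7))
    rownames(b2) <- rownames(p2) <- ids2
    r2 <- polii_normalize_quantify(p2, b2, ids2)
    expect_equal(median(r2$body_log2fc), 0, tolerance = 1e-12)
    expect_lt(abs(attr(r2, "anchoring_factor") - 1.7), 0.1)
  }

  # promoter-only gain stays visible after anchoring
  gain <- cbind(control = rpois(50, 400), treatment = rpois(50, 400 * 3))
  flatb <- cbind(control = rpois(50, 1000), treatment = rpois(50, 1000))
  rownames(gain) <- rownames(flatb) <- paste0("g", 1:50)
  r3 <- polii_normalize_quantify(gain, flatb, paste0("g", 1:50))
  expect_gt(median(r3$promoter_log2fc), 1)
  expect_equal(median(r3$body_log2fc), 0, tolerance = 1e-12)

  expect_error(polii_normalize_quantify(prom, body, character(0)), "empty")
})

test_that("quartile stratification", {
  q <- quartile_stratify(1:8)
  expect_equal(as.character(q), rep(paste0("Q", 1:4), each = 2))
  # sizes differ by at most one, all elements assigned
  set.seed(59)
  for (n in c(7, 10, 41)) {
    q <- quartile_stratify(runif(n))
    expect_false(anyNA(q))
    expect_lte(diff(range(table(q))), 1)
  }
  # deterministic under ties via the id tie-break
  h <- rep(1, 8)
  expect_equal(quartile_stratify(h, letters[1:8]),
               quartile_stratify(h, letters[1:8]))
})

test_that("ATAC differential accessibility and stratification", {
  set.seed(61)
  np <- 400
  ids <- sprintf("p%03d", 1:np)
  mu <- runif(np, 100, 1000)
  fc <- rep(1, np)
  losers <- 1:40                       # 10% planted >= 2-fold losses
  fc[losers] <- 1 / runif(40, 2.5, 5)
  counts <- cbind(c1 = rpois(np, mu), c2 = rpois(np, mu),
                  t1 = rpois(np, mu * fc), t2 = rpois(np, mu * fc))
  rownames(counts) <- ids
  sheet <- data.frame(sample = colnames(counts),
                      condition = c("control", "control",
                                    "treatment", "treatment"))
  summits <- data.frame(peak_id = ids, chrom = "chr1",
                        summit = seq(5000L, by = 5000L, length.out = np))
  tss <- data.frame(chrom = "chr1",
                    tss = summits$summit[seq(1, np, by = 4)] + 50L)
  ctcf <- data.frame(chrom = "chr1",
                     start = summits$summit[1:200] - 100L,
                     end = summits$summit[1:200] + 100L,
                     height = runif(200, 1, 40))
  res <- atac_differential(counts, sheet, summits, ctcf, tss)
  expect_lt(abs(res$fraction_loss - 0.1), 0.04)
  expect_lt(res$fraction_gain, 0.01)
  r <- res$results
  # promoter flag: every 4th peak has a TSS within 200 bp
  expect_true(all(r$promoter[match(ids[seq(1, np, 4)], r$peak_id)]))
  # quartiles partition CTCF-overlapping peaks within each stratum
  for (s in c("promoter", "distal")) {
    i <- r$stratum == s & !is.na(r$ctcf_height)
    if (any(i)) {
      expect_false(anyNA(r$quartile[i]))
      expect_lte(diff(range(table(r$quartile[i]))), 1)
    }
  }
  expect_true(all(is.na(r$quartile[is.na(r$ctcf_height)])))

  # all-unchanged null: both fractions zero
  counts0 <- cbind(c1 = rpois(np, mu), c2 = rpois(np, mu),
                   t1 = rpois(np, mu), t2 = rpois(np, mu))
  rownames(counts0) <- ids
  res0 <- atac_differential(counts0, sheet, summits, ctcf, tss)
  expect_equal(res0$fraction_loss, 0)
  expect_equal(res0$fraction_gain, 0)
})

test_that("quartile recovery from four planted height strata", {
  set.seed(67)
  n <- 2000
  stratum <- sample(rep(1:4, each = n / 4))
  height <- runif(n, (stratum - 1) * 10 + 0.5, stratum * 10 - 0.5)
  q <- as.integer(quartile_stratify(height))
  expect_gte(mean(q == stratum), 0.99)
})
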