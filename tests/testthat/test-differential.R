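test_that("size factors reproduce hand computation and equivariance", {
  # hand computation: geometric means (sqrt(200), sqrt(800), sqrt(1800));
  # all per-gene ratios for sample1 are 1/sqrt(2), for sample2 sqrt(2)
  m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  sf <- estimate_size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # scale equivariance: multiplying one sample by k multiplies its factor
  # relative to the others by exactly k (the pseudo-reference itself picks
  # up k^(1/m), so only size-factor ratios -- which is what normalization
  # divides by -- are equivariant)
  set.seed(5)
  m <- matrix(rpois(300, 100) + 1L, 50, 6)
  colnames(m) <- paste0("s", 1:6)
  sf1 <- estimate_size_factors(m)
  m2 <- m; m2[, 3] <- m2[, 3] * 4L
  sf2 <- estimate_size_factors(m2)
  expect_equal(unname((sf2[3] / sf2[1]) / (sf1[3] / sf1[1])), 4,
               tolerance = 1e-9)
  # doubling every count of one sample doubles its factor ratio exactly
  d <- cbind(s1 = c(10L, 20L, 30L), s2 = c(20L, 40L, 60L))
  sfd <- estimate_size_factors(d)
  expect_equal(unname(sfd[2] / sfd[1]), 2, tolerance = 1e-12)

  # degenerate cases
  expect_equal(unname(estimate_size_factors(matrix(5, 3, 1))), 1)
  expect_error(estimate_size_factors(cbind(c(0, 1), c(1, 0))),
               "positive counts")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(9)
  m <- matrix(rnbinom(600, mu = 200, size = 10), 100, 6)
  colnames(m) <- paste0("s", 1:6)
  ours <- estimate_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("asymmetry-corrected fold changes", {
  sheet <- data.frame(sample = c("c1", "t1"),
                      condition = c("control", "treatment"))
  # pure library effect: all genes doubled -> adjusted log2FC all zero
  m <- cbind(c1 = c(100L, 200L, 300L), t1 = c(200L, 400L, 600L))
  rownames(m) <- c("a", "b", "c")
  res <- compute_adjusted_log2fc(m, sheet, expressed = c("a", "b", "c"))
  expect_equal(res$adjusted_log2fc, rep(0, 3), tolerance = 1e-12)

  # symmetric case: median 0, adjusted == raw
  m <- cbind(c1 = c(200L, 200L, 200L), t1 = c(100L, 200L, 400L))
  rownames(m) <- c("a", "b", "c")
  res <- compute_adjusted_log2fc(m, sheet, expressed = c("a", "b", "c"),
                                 size_factors = c(c1 = 1, t1 = 1))
  expect_equal(attr(res, "asymmetry_median"), 0)
  expect_equal(res$adjusted_log2fc, res$raw_log2fc)

  # zero-count guards: no infinities escape
  m <- cbind(c1 = c(0L, 100L, 50L), t1 = c(10L, 0L, 50L))
  rownames(m) <- c("a", "b", "c")
  res <- compute_adjusted_log2fc(m, sheet, expressed = "c",
                                 size_factors = c(c1 = 1, t1 = 1))
  expect_equal(res$status, c("zero_control", "zero_treatment", "ok"))
  expect_true(all(is.na(res$raw_log2fc[1:2])))
})

test_that("median of adjusted log2FC over expressed genes is 0 (invariant)", {
  set.seed(21)
  sheet <- data.frame(sample = c("c1", "c2", "t1", "t2"),
                      condition = c("control", "control",
                                    "treatment", "treatment"))
  for (i in 1:5) {
    n <- 201
    m <- matrix(rnbinom(4 * n, mu = 300, size = 20) + 1L, n, 4,
                dimnames = list(paste0("g", 1:n), sheet$sample))
    expressed <- sample(rownames(m), 151)
    res <- compute_adjusted_log2fc(m, sheet, expressed)
    expect_lt(abs(median(res$adjusted_log2fc[res$gene_id %in% expressed],
                         na.rm = TRUE)), 1e-9)
  }
})

test_that("per-replicate fold changes: identity, planted FC, orphans", {
  n <- 120
  sheet <- data.frame(
    sample = c(paste0("c", 1:12), paste0("t", 1:12)),
    condition = rep(c("control", "treatment"), each = 12),
    pair = rep(paste0("p", 1:12), 2)
  )
  # identical control/treatment libraries: all adjusted per-replicate FC = 0
  base <- matrix(rpois(n * 12, 500) + 1L, n, 12)
  m <- cbind(base, base)
  dimnames(m) <- list(paste0("g", 1:n), sheet$sample)
  rep_fc <- per_replicate_log2fc(m, sheet, expressed = rownames(m))
  expect_equal(max(abs(rep_fc)), 0)

  # planted FC = 1/2 for one gene across 12 simulated pairs
  set.seed(13)
  mu <- rep(800, n)
  fc <- rep(1, n); fc[1] <- 0.5
  ctrl <- sapply(1:12, function(j) rnbinom(n, mu = mu, size = 50))
  trt <- sapply(1:12, function(j) rnbinom(n, mu = mu * fc, size = 50))
  m <- cbind(ctrl, trt)
  dimnames(m) <- list(paste0("g", 1:n), sheet$sample)
  rep_fc <- per_replicate_log2fc(m, sheet, expressed = rownames(m))
  med <- median(2^rep_fc[1, ])
  expect_gt(med, 0.4)
  expect_lt(med, 0.62)

  # unpaired replicate is an error naming the orphan
  bad <- sheet; bad$pair[1] <- "orphan"
  expect_error(per_replicate_log2fc(m, bad, rownames(m)), "orphan")

  # zero counts are guarded as NA, not -Inf
  m2 <- m; m2[2, "t1"] <- 0L
  rep_fc <- per_replicate_log2fc(m2, sheet, expressed = rownames(m))
  expect_true(is.na(rep_fc[2, "p1"]))
  expect_false(any(is.infinite(rep_fc)))
})

test_that("correlate: identity, antisymmetry, hand-computed fixture", {
  x <- c(g1 = 0.5, g2 = -1, g3 = 2, g4 = 0, g5 = 1)
  expect_equal(correlate(x, x)$estimate, 1)
  expect_equal(correlate(x, -x)$estimate, -1)
  # hand-computed covariance ratio on a fixed 5-point fixture
  y <- c(g1 = 1, g2 = 0, g3 = 3, g4 = -1, g5 = 2)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate(x, y)$estimate, r_hand, tolerance = 1e-12)
  # alignment on shared names, non-finite pairs dropped, n reported
  y2 <- c(g5 = 2, g3 = 3, g1 = 1, g2 = 0, g4 = -1, g9 = 100)
  expect_equal(correlate(x, y2)$estimate, r_hand, tolerance = 1e-12)
  expect_equal(correlate(x, y2)$n, 5L)
  expect_error(correlate(c(a = 1, b = 2), c(a = 1, b = 2)), "3")
})
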