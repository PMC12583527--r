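test_that("detection-p filter applies each rule and their combination", {
  n <- 10L
  detp <- rbind(
    good      = rep(0.001, n),                      # passes all rules
    mean_bad  = rep(0.06, n),                       # mean 0.06 > 0.05
    half_bad  = c(rep(0.2, 5), rep(0.001, 5)),      # > 0.05 in half the samples
    frac_bad  = c(rep(0.02, 3), rep(0.001, 7)),     # >= 0.01 in 30% > 20%
    edge_ok   = c(rep(0.02, 2), rep(0.001, 8)))     # >= 0.01 in exactly 20%
  res <- filterProbesByDetection(detp)
  expect_identical(res$kept, c("good", "edge_ok"))
  expect_equal(unname(res$removedBy["total_removed"]), 3)

  # order independence: each rule evaluated on the full matrix
  r1 <- rownames(detp)[rowMeans(detp) <= 0.05]
  r2 <- rownames(detp)[rowSums(detp > 0.05) < n / 2]
  r3 <- rownames(detp)[rowSums(detp >= 0.01) <= 0.2 * n]
  expect_setequal(res$kept, Reduce(intersect, list(r1, r2, r3)))

  expect_error(filterProbesByDetection(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(filterProbesByDetection(matrix(-0.1, 2, 2)), "\\[0, 1\\]")
})

test_that("logit transform matches hand arithmetic and clips boundaries", {
  expect_equal(logitTransform(0.5), 0)
  expect_equal(logitTransform(0.75), log(3))
  expect_equal(logitTransform(1.0, eps = 1e-6), log((1 - 1e-6) / 1e-6),
               tolerance = 1e-9)
  expect_equal(logitTransform(1.0, eps = 1e-6), 13.815509, tolerance = 1e-6)
  expect_error(logitTransform(-0.1), "\\[0, 1\\]")
  expect_error(logitTransform(1.2), "\\[0, 1\\]")
  # round trip on the open interval
  b <- matrix(runif(200, 0.01, 0.99), 20, 10)
  expect_equal(plogis(logitTransform(b)), b, tolerance = 1e-12)
})

test_that("biomarker transform yields A/M/D with the exact invariants", {
  # hand-computed example
  a <- transformBiomarkers(c(100, 200, 400, 800), c(1, 2, 3, 4), c(2, 4, 6, 8))$a
  expect_equal(a, c(-1.16190, -0.38730, 0.38730, 1.16190), tolerance = 1e-4)

  set.seed(21)
  t <- rlnorm(50, 3, 0.4)
  # t_raw == n_raw => D identically zero
  amd <- transformBiomarkers(rlnorm(50, 7, 0.5), t, t)
  expect_equal(amd$d, rep(0, 50), tolerance = 1e-12)
  # n_raw = c * t_raw: scale() is shift invariant on the log scale
  amd2 <- transformBiomarkers(rlnorm(50, 7, 0.5), t, 3.7 * t)
  expect_equal(amd2$d, rep(0, 50), tolerance = 1e-12)
  expect_equal(amd2$m, (log(t) - mean(log(t))) / sd(log(t)), tolerance = 1e-12)

  # corr(M, D) vanishes exactly for arbitrary positive inputs
  n <- rlnorm(50, 5.5, 0.4) * t^0.8
  amd3 <- transformBiomarkers(rlnorm(50, 7, 0.5), t, n)
  expect_lt(abs(cor(amd3$m, amd3$d)), 1e-10)
  expect_equal(mean(amd3$a), 0, tolerance = 1e-12)
  expect_equal(sd(amd3$a), 1, tolerance = 1e-12)
  expect_equal(mean(amd3$m), 0, tolerance = 1e-12)

  expect_error(transformBiomarkers(c(-1, 2, 3), c(1, 2, 3), c(1, 2, 3)),
               "positive")
  expect_error(transformBiomarkers(c(2, 2, 2), c(1, 2, 3), c(1, 2, 3)),
               "zero variance")
})

test_that("cell-type PCA has deterministic signs and errors on degenerate input", {
  toy <- rbind(c(0.9, 0.1), c(0.1, 0.9), c(0.5, 0.5))
  res <- cellTypePCA(toy, k = 1)
  expect_equal(abs(res$scores[, 1]), c(0.4, 0.4, 0) * sqrt(2), tolerance = 1e-10)
  expect_equal(unname(res$scores[3, 1]), 0, tolerance = 1e-12)
  # sign convention: largest-magnitude loading positive
  expect_gt(max(res$loadings[, 1]), 0)

  set.seed(9)
  props <- methylAMD:::rdirichlet(40, c(9, 6, 3, 4, 5, 30, 1.5))
  res7 <- cellTypePCA(props)           # k = 3 by default
  expect_equal(ncol(res7$scores), 3L)
  expect_true(res7$explainedFraction > 0 && res7$explainedFraction <= 1)

  same <- matrix(rep(c(0.2, 0.3, 0.5), each = 10), 10, 3)
  expect_error(cellTypePCA(same, k = 1), "non-degenerate")
})
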