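test_that("cohort generation is deterministic and respects invariants", {
  c1 <- tinyCohort(seed = 33L)
  c2 <- tinyCohort(seed = 33L)
  expect_identical(methylation(c1), methylation(c2))
  expect_identical(biomarkers(c1), biomarkers(c2))

  b <- methylation(c1)
  expect_true(all(b > 0 & b < 1))
  covTab <- covariates(c1)
  cellCols <- grep("^cell_", colnames(covTab))
  expect_equal(rowSums(covTab[, cellCols]), rep(1, nrow(covTab)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(covTab$apoe4 %in% 0:2))
})

test_that("within-cluster logit-scale correlation tracks the configured block level", {
  rho <- 0.45
  ch <- generateCohort(cohortConfig(nSamples = 400L, nClusters = 3L,
                                    probesPerCluster = 40L,
                                    blockCorrelation = rho, seed = 5L))
  mv <- logitTransform(methylation(ch))
  cl <- cohortTruth(ch)$cluster
  avg <- sapply(unique(cl), function(cc) {
    R <- cor(t(mv[cl == cc, ]))
    mean(R[upper.tri(R)])
  })
  expect_true(all(abs(avg - rho) < 0.05))
})

test_that("biomarker correlation and APOE4 frequencies match the configuration", {
  ch <- generateCohort(cohortConfig(nSamples = 5000L, nClusters = 1L,
                                    probesPerCluster = 5L, seed = 8L))
  bio <- biomarkers(ch)
  expect_lt(abs(cor(log(bio$t_raw), log(bio$n_raw)) - 0.981), 0.01)
  # raw-scale correlation of a lognormal pair stays close to the log-scale one
  expect_lt(abs(cor(bio$t_raw, bio$n_raw) - 0.981), 0.03)

  # AD stratum carrier fraction: 73.9% with a large AD-only cohort
  cfgAD <- cohortConfig(nSamples = 10000L, nClusters = 1L,
                        probesPerCluster = 5L,
                        dxProportions = c(CN = 0, MCI = 0, AD = 1), seed = 13L)
  chAD <- generateCohort(cfgAD)
  carrier <- mean(covariates(chAD)$apoe4 >= 1)
  expect_lt(abs(carrier - 0.739), 0.02)
})

test_that("invalid configurations are rejected", {
  expect_error(cohortConfig(dxProportions = c(0.5, 0.4, 0.2)), "simplex")
  cfg <- cohortConfig()
  cfg@corrAT <- 1.5
  expect_error(validObject(cfg), "corrAT")
  expect_error(cohortConfig(blockCorrelation = 1), "blockCorrelation")
})

test_that("covariate effect draws have the right support, mean and determinism", {
  e1 <- drawCovariateEffects(4L)
  e2 <- drawCovariateEffects(4L)
  expect_identical(e1, e2)
  expect_true(all(abs(c(e1$betaDx, e1$betaApoe4)) >= 0.1))
  expect_true(all(abs(c(e1$betaDx, e1$betaApoe4)) <= 0.5))

  set.seed(100)
  draws <- vapply(sample.int(1e6, 3400), function(s)
    abs(drawCovariateEffects(s)$betaDx), numeric(3))
  expect_lt(abs(mean(draws) - 0.3), 0.01)   # E|U(0.1, 0.5)| = 0.3
})

test_that("scenario construction matches its definition", {
  S <- diag(c(1, 1, 0.1))
  null <- makeScenario("null", m = 100L, sigmaStar = S, seed = 2L)
  expect_true(all(null@betaP == 0))

  mod <- makeScenario("moderate", m = 100L, sigmaStar = S, seed = 2L)
  expect_equal(sum(mod@betaP == 0.04), 5L)
  expect_equal(sum(mod@betaP != 0), 5L)
  expect_setequal(as.integer(rowSums(mod@betaP != 0)), c(2L, 2L, 1L))

  str <- makeScenario("strong", m = 100L, sigmaStar = S, seed = 3L)
  expect_true(all(str@betaP[str@betaP != 0] == 0.08))

  single <- makeScenario("single_phenotype", m = 60L, sigmaStar = S, seed = 4L)
  expect_equal(sum(rowSums(single@betaP != 0) > 0), 1L)
  expect_equal(sum(single@betaP != 0), 5L)
})

# reproduces the internal error draw for the null-scenario identity above
simulatePhenotypesNoise <- function(n, S, seed) {
  set.seed(seed)
  MASS::mvrnorm(n, mu = rep(0, 3), Sigma = S)
}

test_that("phenotype simulation obeys the generating equation", {
  n <- 40L; m <- 20L
  X <- stdDesign(n, m, seed = 6L)
  dx <- sample(0:2, n, TRUE)
  ap <- sample(0:2, n, TRUE)
  S <- diag(c(1, 0.9, 0.1))
  sc <- makeScenario("moderate", m = m, sigmaStar = S, seed = 9L, nSignals = 5L)

  s1 <- simulatePhenotypes(X, dx, ap, sc, seed = 10L)
  s2 <- simulatePhenotypes(X, dx, ap, sc, seed = 10L)
  expect_identical(s1$Y, s2$Y)

  # noise-free limit: zero covariate effects and vanishing sigma
  scz <- sc
  scz@betaDx <- rep(0, 3); scz@betaApoe4 <- rep(0, 3)
  scz@sigmaStar <- diag(1e-24, 3)
  s0 <- simulatePhenotypes(X, dx, ap, scz, seed = 11L)
  expect_equal(unname(s0$Y), unname(X %*% t(sc@betaP)), tolerance = 1e-9)

  # null scenario: Y independent of X
  scn <- makeScenario("null", m = m, sigmaStar = S, seed = 12L)
  sn <- simulatePhenotypes(X, dx, ap, scn, seed = 13L)
  expect_equal(unname(sn$Y),
               unname(outer(dx, scn@betaDx) + outer(ap, scn@betaApoe4) +
                        simulatePhenotypesNoise(n, S, 13L)),
               tolerance = 1e-12)

  expect_error(simulatePhenotypes(X[, 1:5], dx, ap, sc, seed = 1L), "columns")
})

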