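test_that("unpenalized limit reproduces multivariate OLS and the inverse MLE covariance", {
  set.seed(51)
  n <- 60L; m <- 4L; q <- 3L
  X <- stdDesign(n, m, seed = 52L)
  W <- cbind(1, rnorm(n))
  Y <- matrix(rnorm(n * q), n, q)
  fit <- fitPenalized(Y, X, W, lambda = 0, rho = 0, tol = 1e-10,
                      maxOuter = 500L)
  Z <- cbind(W, X)
  Bols <- qr.coef(qr(Z), Y)
  expect_lt(max(abs(rbind(fit@gammaW, t(probeEffects(fit))) - Bols)), 1e-6)
  S <- crossprod(Y - Z %*% Bols) / n
  expect_lt(max(abs(precisionMatrix(fit) - solve(S))), 1e-6)
})

test_that("q = 1, rho = 0 solution is the lasso fixed point checked against glmnet", {
  skip_if_not_installed("glmnet")
  set.seed(61)
  n <- 80L; m <- 10L
  X <- stdDesign(n, m, seed = 62L)
  y <- X[, 1] * 0.5 - X[, 4] * 0.3 + rnorm(n)
  lam <- 0.3
  fit <- fitPenalized(matrix(y, ncol = 1), X, lambda = lam, rho = 0,
                      tol = 1e-10, maxOuter = 2000L)
  # with scalar precision theta = n / RSS estimated jointly, the
  # coefficient step is a lasso at penalty lambda / (2 theta)
  theta <- precisionMatrix(fit)[1, 1]
  g <- glmnet::glmnet(X, y, lambda = lam / (2 * theta), standardize = FALSE,
                      intercept = TRUE, thresh = 1e-14)
  expect_lt(max(abs(as.numeric(g$beta) - as.numeric(probeEffects(fit)))), 1e-6)
  expect_lt(abs(as.numeric(g$a0) - fit@gammaW[1, 1]), 1e-6)
})

test_that("objective matches the independent proximal-gradient oracle on random instances", {
  for (i in 1:8) {
    set.seed(70 + i)
    n <- sample(30:60, 1); m <- sample(3:6, 1)
    prob <- toyProblem(n = n, m = m, seed = 70 + i)
    lam <- runif(1, 0.02, 0.3); rho <- runif(1, 0.01, 0.2)
    fit <- fitPenalized(prob$Y, prob$X, lambda = lam, rho = rho, tol = 1e-8,
                        maxOuter = 500L)
    orc <- fitPenalizedProx(prob$Y, prob$X, lambda = lam, rho = rho)
    expect_lt(abs(fit@objective - orc$objective), 1e-4)
    expect_identical(abs(probeEffects(fit)) > 1e-6, abs(orc$Gamma3) > 1e-6)
  }
})

test_that("objective path is monotone and Theta stays positive definite", {
  prob <- toyProblem(n = 60L, m = 6L, seed = 81L)
  fit <- fitPenalized(prob$Y, prob$X, lambda = 0.05, rho = 0.05)
  expect_true(all(diff(fit@objPath) <= 1e-8 * (1 + abs(fit@objPath[-1]))))
  ev <- eigen(precisionMatrix(fit), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("penalty grid: KKT at lambda_max, monotone path, configured lengths", {
  prob <- toyProblem(n = 60L, m = 6L, seed = 91L)
  g <- makeGrid(prob$Y, prob$X)
  expect_length(g$lambda, 20L)
  expect_length(g$rho, 10L)
  for (r in g$rho[c(1, 5, 10)]) {
    f <- fitPenalized(prob$Y, prob$X, lambda = g$lambda[1], rho = r)
    expect_true(all(probeEffects(f) == 0))
  }
  # nonzero count nondecreasing as lambda shrinks (warm-started path)
  init <- NULL
  counts <- integer(0)
  for (lam in g$lambda) {
    f <- fitPenalized(prob$Y, prob$X, lambda = lam, rho = g$rho[5],
                      init = init)
    init <- list(B = rbind(f@gammaW, t(probeEffects(f))), Theta = f@Theta)
    counts <- c(counts, sum(probeEffects(f) != 0))
  }
  expect_equal(counts[1], 0L)
  expect_gt(counts[length(counts)], 0L)
  expect_error(makeGrid(prob$Y, matrix(0, 60, 3)), "all zero")
})

test_that("BIC counts stored nonzeros only and charges log(n) per parameter", {
  prob <- toyProblem(n = 50L, m = 5L, seed = 101L)
  fit <- fitPenalized(prob$Y, prob$X, lambda = 0.08, rho = 0.05)
  n <- 50L
  S <- crossprod(fit@residuals) / n
  Th <- precisionMatrix(fit)
  df <- sum(probeEffects(fit) != 0) + sum(Th[upper.tri(Th)] != 0)
  manual <- n * (sum(S * Th) - determinant(Th, logarithm = TRUE)$modulus[1]) +
    log(n) * df
  expect_equal(computeBIC(fit, n), manual, ignore_attr = TRUE)

  # one extra explicit zero changes nothing; one extra nonzero adds log(n)
  fit2 <- fit
  expect_equal(computeBIC(fit2, n), computeBIC(fit, n), ignore_attr = TRUE)
  fit3 <- fit
  # flip a zero entry to a tiny nonzero without changing residuals
  idx <- which(fit3@Gamma3 == 0)[1]
  expect_false(is.na(idx))
  g3 <- fit3@Gamma3; g3[idx] <- 1e-12
  fit3@Gamma3 <- g3
  expect_equal(computeBIC(fit3, n) - computeBIC(fit, n), log(n),
               ignore_attr = TRUE)
})

test_that("hand-set tiny fit matches the BIC formula", {
  n <- 10L
  resid <- matrix(c(1, -1, 2, 0, 1, -2, 1, 0, -1, 1,
                    0.5, 0, -0.5, 1, -1, 0.5, 0, -0.5, 1, -1), n, 2)
  Th <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  G <- matrix(c(0.3, 0, 0, 0), 2, 2)
  fit <- new("PenalizedFit", gammaW = matrix(0, 1, 2), Gamma3 = G,
             Theta = Th, lambda = 0.1, rho = 0.1, objective = 0,
             objPath = 0, bic = NA_real_, cvError = NA_real_,
             nIter = 1L, converged = TRUE, residuals = resid)
  S <- crossprod(resid) / n
  expected <- n * (sum(S * Th) - log(det(Th))) + log(n) * (1 + 1)
  expect_equal(computeBIC(fit, n), expected, ignore_attr = TRUE)
})

test_that("cross-validation is deterministic and its surface is finite", {
  prob <- toyProblem(n = 60L, m = 5L, seed = 111L)
  f1 <- tuneFit(prob$Y, prob$X, criterion = "cv", nLambda = 4L, nRho = 3L,
                seed = 5L)
  f2 <- tuneFit(prob$Y, prob$X, criterion = "cv", nLambda = 4L, nRho = 3L,
                seed = 5L)
  expect_equal(attr(f1, "score"), attr(f2, "score"))
  expect_true(all(is.finite(attr(f1, "score"))))
  expect_identical(probeEffects(f1), probeEffects(f2))

  # degenerate single-point grid returns that point
  f3 <- tuneFit(prob$Y, prob$X, criterion = "bic", nLambda = 1L, nRho = 1L)
  g <- makeGrid(prob$Y, prob$X, nLambda = 1L, nRho = 1L)
  expect_equal(f3@lambda, g$lambda[1])
  expect_equal(f3@rho, g$rho[1])
})

test_that("probe selection merges duplicates and ranks by largest absolute effect", {
  mkFit <- function(G) {
    q <- nrow(G); m <- ncol(G)
    new("PenalizedFit", gammaW = matrix(0, 1, q), Gamma3 = G,
        Theta = diag(q), lambda = 0.1, rho = 0.1, objective = 0,
        objPath = 0, bic = NA_real_, cvError = NA_real_, nIter = 1L,
        converged = TRUE, residuals = matrix(0, 4, q))
  }
  G1 <- matrix(0, 3, 3, dimnames = list(c("A", "M", "D"),
                                        c("cg01", "cg02", "cg03")))
  G1["M", "cg01"] <- 0.02
  G1["M", "cg02"] <- 0.0746
  G2 <- matrix(0, 3, 2, dimnames = list(c("A", "M", "D"),
                                        c("cg01", "cg04")))
  G2["M", "cg01"] <- 0.03
  G2["D", "cg04"] <- -0.0705
  tab <- selectProbes(list(cl1 = mkFit(G1), cl2 = mkFit(G2)))
  expect_equal(tab$probe_id, c("cg02", "cg04", "cg01"))
  expect_equal(tab$effect_M[tab$probe_id == "cg01"], 0.03)  # merge keeps max |.|
  expect_equal(tab$clusters[tab$probe_id == "cg01"], "cl1,cl2")
  expect_equal(tab$max_abs_effect, sort(tab$max_abs_effect, decreasing = TRUE))

  empty <- selectProbes(list(cl1 = mkFit(matrix(0, 3, 2,
    dimnames = list(c("A", "M", "D"), c("x", "y"))))))
  expect_equal(nrow(empty), 0L)
})

test_that("phenotypes are not re-scaled inside the fit", {
  prob <- toyProblem(n = 50L, m = 4L, seed = 121L)
  Yshift <- prob$Y + 5                        # shifted, not rescaled by the fit
  f1 <- fitPenalized(prob$Y, prob$X, lambda = 0.1, rho = 0.05)
  f2 <- fitPenalized(Yshift, prob$X, lambda = 0.1, rho = 0.05)
  # intercept absorbs the shift; probe coefficients identical
  expect_equal(probeEffects(f2), probeEffects(f1), tolerance = 1e-6)
  expect_equal(f2@gammaW[1, ], f1@gammaW[1, ] + 5, tolerance = 1e-6)
  # scaling Y scales the solution: fits are NOT scale invariant
  f3 <- fitPenalized(2 * prob$Y, prob$X, lambda = 0.1, rho = 0.05)
  expect_false(isTRUE(all.equal(probeEffects(f3), probeEffects(f1))))
})
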