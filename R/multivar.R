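#' Fit the L1-penalized multivariate regression for one cluster
#'
#' Jointly estimates the coefficient matrix and the residual precision
#' matrix Theta by alternating optimization of
#' \deqn{(1/n)\,tr[(Y - W\Gamma_u - X\Gamma_3^\top)^\top (Y - W\Gamma_u -
#'   X\Gamma_3^\top)\,\Theta] - \log\det\Theta + \lambda\|\Gamma_3\|_1 +
#'   \rho\|\Theta\|_{1,off}}
#' over the unpenalized covariate coefficients \eqn{\Gamma_u}, the
#' penalized probe coefficients \eqn{\Gamma_3} and \eqn{\Theta \succ 0}.
#' The coefficient step is cyclic coordinate descent with closed-form
#' soft-threshold updates (compiled); the precision step is a graphical
#' lasso on the residual covariance with the off-diagonal penalty `rho`
#' (diagonal unpenalized), or the exact inverse MLE when `rho = 0`. The
#' objective is nonincreasing across outer iterations; the fit stops when
#' its relative change drops below `tol`.
#'
#' Phenotypes are used exactly as supplied — they are deliberately not
#' re-centered or re-scaled inside the fit.
#'
#' @param Y n x q phenotype matrix (q = 3 for A/M/D).
#' @param X n x m standardized probe residuals (columns mean 0, SD 1).
#' @param W n x c unpenalized design; default intercept only. Use
#'   [covariateBlock()] for the intercept/diagnosis/APOE4 block.
#' @param lambda,rho nonnegative penalties on the probe block and the
#'   off-diagonal precision entries.
#' @param tol relative objective tolerance for the outer loop.
#' @param maxOuter maximum outer iterations.
#' @param init optional warm start: list with `B` ((c+m) x q) and `Theta`.
#' @return a [PenalizedFit-class]; `bic` is filled in via [computeBIC()].
#' @export
fitPenalized <- function(Y, X, W = NULL, lambda, rho, tol = 1e-4,
                         maxOuter = 100L, init = NULL) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y); q <- ncol(Y); m <- ncol(X)
  if (nrow(X) != n) stop("Y and X row counts differ")
  if (n <= q) stop("need n > q")
  if (lambda < 0 || rho < 0) stop("penalties must be nonnegative")
  if (is.null(W)) W <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  W <- as.matrix(W)
  cW <- ncol(W)
  Z <- cbind(W, X)
  penal <- c(rep(0L, cW), rep(1L, m))

  if (is.null(init)) {
    B <- matrix(0, cW + m, q)
    B[seq_len(cW), ] <- qr.coef(qr(W), Y)
    R0 <- Y - W %*% B[seq_len(cW), , drop = FALSE]
    v <- pmax(colSums(R0^2) / n, 1e-8)
    Theta <- diag(1 / v, q)
  } else {
    B <- init$B
    Theta <- init$Theta
  }

  obj <- function(R, B, Theta) {
    S <- crossprod(R) / n
    sum(S * Theta) - determinant(Theta, logarithm = TRUE)$modulus[1] +
      lambda * sum(abs(B[penal == 1L, ])) +
      rho * (sum(abs(Theta)) - sum(abs(diag(Theta))))
  }

  objPath <- numeric(0)
  objPrev <- Inf
  converged <- FALSE
  it <- 0L
  R <- Y - Z %*% B
  for (it in seq_len(maxOuter)) {
    gs <- cppGammaStep(Z, Y, B, Theta, as.integer(penal), lambda,
                       tol * 1e-3, 1000L)
    B <- gs$B; R <- gs$R
    S <- crossprod(R) / n
    Theta <- thetaStep(S, rho, tol)
    objNew <- obj(R, B, Theta)
    objPath <- c(objPath, objNew)
    if (is.finite(objPrev) && abs(objPrev - objNew) < tol * (1 + abs(objNew))) {
      converged <- TRUE
      objPrev <- objNew
      break
    }
    objPrev <- objNew
  }
  if (!converged)
    warning("fitPenalized: no convergence in ", maxOuter,
            " outer iterations; returning best iterate")

  gammaW <- B[seq_len(cW), , drop = FALSE]
  rownames(gammaW) <- colnames(W)
  Gamma3 <- t(B[cW + seq_len(m), , drop = FALSE])     # q x m
  colnames(Gamma3) <- colnames(X)
  rownames(Gamma3) <- colnames(Y)
  new("PenalizedFit", gammaW = gammaW, Gamma3 = Gamma3, Theta = Theta,
      lambda = lambda, rho = rho, objective = objPrev, objPath = objPath,
      bic = NA_real_, cvError = NA_real_, nIter = it, converged = converged,
      residuals = R)
}

# precision step: graphical lasso with off-diagonal penalty, or exact
# inverse of the residual covariance MLE when rho = 0
thetaStep <- function(S, rho, tol) {
  q <- nrow(S)
  if (rho == 0) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12 * max(ev))
      stop("residual covariance is singular with rho = 0; ",
           "increase rho or the sample size")
    return(solve(S))
  }
  res <- cppGlasso(S, rho, min(tol, 1e-6) * max(diag(S)), 200L)
  Th <- res$Theta
  ev <- eigen(Th, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("precision step produced a non-PD matrix")
  Th
}

#' Penalty grids for tuning
#'
#' `lambdaMax` is the smallest coefficient penalty for which the probe
#' block is entirely zero at the covariates-only solution; from the KKT
#' conditions of the (1/n)-normalized objective it equals
#' `(2/n) max |X' R0 Theta0|` with `R0` the covariates-only OLS residuals
#' and `Theta0` the corresponding precision step at a given `rho`. The
#' maximum over the rho grid is used so the bound holds everywhere.
#' `rhoMax` is the largest absolute off-diagonal entry of the
#' covariates-only residual covariance (above it the glasso solution is
#' diagonal). Both grids are log-spaced over `[0.01 max, max]`.
#'
#' @param Y,X,W as in [fitPenalized()].
#' @param nLambda,nRho grid sizes (defaults 20 and 10).
#' @return list with `lambda` (decreasing) and `rho` (decreasing).
#' @export
makeGrid <- function(Y, X, W = NULL, nLambda = 20L, nRho = 10L) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (all(X == 0)) stop("X is all zero")
  n <- nrow(Y)
  if (is.null(W)) W <- matrix(1, n, 1)
  R0 <- qr.resid(qr(as.matrix(W)), Y)
  S0 <- crossprod(R0) / n
  rhoMax <- max(abs(S0[upper.tri(S0)]), 1e-8)
  rhoGrid <- exp(seq(log(rhoMax), log(0.01 * rhoMax), length.out = nRho))
  lamMax <- max(vapply(rhoGrid, function(r) {
    Th <- thetaStep(S0, r, 1e-6)
    (2 / n) * max(abs(crossprod(X, R0) %*% Th))
  }, numeric(1)))
  lambdaGrid <- exp(seq(log(lamMax), log(0.01 * lamMax), length.out = nLambda))
  list(lambda = lambdaGrid, rho = rhoGrid)
}

#' BIC of a penalized fit
#'
#' `BIC = n [tr(S_res Theta) - log det Theta] + log(n) df`, where
#' `S_res` is the residual covariance MLE of the fit and `df` counts the
#' nonzero probe coefficients plus the nonzero upper off-diagonal entries
#' of Theta.
#'
#' @param fit a [PenalizedFit-class].
#' @param n sample size used in the fit.
#' @return the BIC value.
#' @export
computeBIC <- function(fit, n) {
  S <- crossprod(fit@residuals) / n
  Th <- fit@Theta
  df <- sum(fit@Gamma3 != 0) + sum(Th[upper.tri(Th)] != 0)
  n * (sum(S * Th) - determinant(Th, logarithm = TRUE)$modulus[1]) +
    log(n) * df
}

#' Tune the penalized fit over a grid
#'
#' Fits the whole (rho, lambda) grid with warm starts along decreasing
#' lambda within each rho, scores each fit by BIC (default) or k-fold
#' cross-validated held-out Gaussian negative log-likelihood, and refits
#' at the winning pair. Fold assignment and hence the CV surface are
#' deterministic given `seed`.
#'
#' @param Y,X,W as in [fitPenalized()].
#' @param criterion `"bic"` or `"cv"`.
#' @param nLambda,nRho grid sizes passed to [makeGrid()].
#' @param k folds for CV.
#' @param seed fold-assignment seed (CV only).
#' @param tol,maxOuter passed to [fitPenalized()].
#' @return the winning [PenalizedFit-class] with `bic`/`cvError` set, plus
#'   attributes `grid` and `score` (the full surface, rho x lambda).
#' @export
tuneFit <- function(Y, X, W = NULL, criterion = c("bic", "cv"),
                    nLambda = 20L, nRho = 10L, k = 5L, seed = 1L,
                    tol = 1e-4, maxOuter = 100L) {
  criterion <- match.arg(criterion)
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  grid <- makeGrid(Y, X, W, nLambda = nLambda, nRho = nRho)
  score <- matrix(NA_real_, length(grid$rho), length(grid$lambda),
                  dimnames = list(NULL, NULL))
  bestFit <- NULL

  if (criterion == "cv") {
    if (n < 2 * k) stop("need n >= 2k for ", k, "-fold CV")
    set.seed(seed)
    fold <- sample(rep(seq_len(k), length.out = n))
    for (f in seq_len(k)) {
      te <- fold == f
      if (any(apply(Y[!te, , drop = FALSE], 2, sd) == 0))
        stop("a CV training fold has a zero-variance phenotype")
    }
    for (ri in seq_along(grid$rho)) {
      for (f in seq_len(k)) {
        te <- fold == f
        init <- NULL
        for (li in seq_along(grid$lambda)) {
          fit <- fitPenalized(Y[!te, , drop = FALSE], X[!te, , drop = FALSE],
                              if (is.null(W)) NULL else W[!te, , drop = FALSE],
                              lambda = grid$lambda[li], rho = grid$rho[ri],
                              tol = tol, maxOuter = maxOuter, init = init)
          init <- list(B = rbind(fit@gammaW, t(fit@Gamma3)), Theta = fit@Theta)
          Wte <- if (is.null(W)) matrix(1, sum(te), 1) else W[te, , drop = FALSE]
          Rte <- Y[te, , drop = FALSE] - Wte %*% fit@gammaW -
            X[te, , drop = FALSE] %*% t(fit@Gamma3)
          Ste <- crossprod(Rte) / sum(te)
          err <- sum(Ste * fit@Theta) -
            determinant(fit@Theta, logarithm = TRUE)$modulus[1]
          score[ri, li] <- if (f == 1L) err / k else score[ri, li] + err / k
        }
      }
    }
  } else {
    for (ri in seq_along(grid$rho)) {
      init <- NULL
      for (li in seq_along(grid$lambda)) {
        fit <- fitPenalized(Y, X, W, lambda = grid$lambda[li],
                            rho = grid$rho[ri], tol = tol,
                            maxOuter = maxOuter, init = init)
        init <- list(B = rbind(fit@gammaW, t(fit@Gamma3)), Theta = fit@Theta)
        score[ri, li] <- computeBIC(fit, n)
        if (score[ri, li] <= min(score, na.rm = TRUE)) bestFit <- fit
      }
    }
  }

  best <- which(score == min(score), arr.ind = TRUE)[1, ]
  if (criterion == "cv" || is.null(bestFit) ||
      bestFit@lambda != grid$lambda[best[2]] ||
      bestFit@rho != grid$rho[best[1]]) {
    # refit on the full data, warm-started along the lambda path at the
    # winning rho (a cold start at a dense solution is needlessly slow)
    init <- NULL
    for (li in seq_len(best[2])) {
      bestFit <- fitPenalized(Y, X, W, lambda = grid$lambda[li],
                              rho = grid$rho[best[1]], tol = tol,
                              maxOuter = maxOuter, init = init)
      init <- list(B = rbind(bestFit@gammaW, t(bestFit@Gamma3)),
                   Theta = bestFit@Theta)
    }
  }
  fit <- bestFit
  fit@bic <- computeBIC(fit, n)
  if (criterion == "cv") fit@cvError <- score[best[1], best[2]]
  attr(fit, "grid") <- grid
  attr(fit, "score") <- score
  fit
}

#' Merge cluster fits into a ranked probe-selection table
#'
#' Takes the union over clusters of probes with any nonzero penalized
#' coefficient. A probe appearing in several clusters is merged into one
#' row keeping, per phenotype, the entry of largest magnitude. Rows are
#' ordered by descending maximum absolute effect, ties broken by probe
#' id.
#'
#' @param fits named list of [PenalizedFit-class] objects (names are
#'   cluster ids); each needs probe ids as `colnames(probeEffects(fit))`.
#' @return data.frame with `probe_id`, one effect column per phenotype,
#'   `max_abs_effect`, and `clusters` (comma-separated sources).
#' @export
selectProbes <- function(fits) {
  rows <- list()
  for (cl in names(fits)) {
    G <- probeEffects(fits[[cl]])
    nz <- which(colSums(G != 0) > 0)
    if (!length(nz)) next
    ph <- rownames(G)
    if (is.null(ph)) ph <- paste0("Y", seq_len(nrow(G)))
    df <- data.frame(probe_id = colnames(G)[nz], cluster = cl,
                     stringsAsFactors = FALSE)
    for (r in seq_along(ph)) df[[paste0("effect_", ph[r])]] <- G[r, nz]
    rows[[length(rows) + 1L]] <- df
  }
  effCols <- NULL
  if (!length(rows))
    return(data.frame(probe_id = character(), max_abs_effect = numeric(),
                      clusters = character()))
  all <- do.call(rbind, rows)
  effCols <- grep("^effect_", colnames(all), value = TRUE)
  merged <- lapply(split(all, all$probe_id), function(d) {
    out <- d[1, c("probe_id", effCols), drop = FALSE]
    for (cc in effCols) out[[cc]] <- d[[cc]][which.max(abs(d[[cc]]))]
    out$clusters <- paste(sort(unique(d$cluster)), collapse = ",")
    out
  })
  tab <- do.call(rbind, merged)
  tab$max_abs_effect <- do.call(pmax, lapply(tab[effCols], abs))
  tab <- tab[order(-tab$max_abs_effect, tab$probe_id), ]
  rownames(tab) <- NULL
  tab[, c("probe_id", effCols, "max_abs_effect", "clusters")]
}
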