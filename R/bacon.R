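#' Bias and inflation correction of test statistics
#'
#' Fits a three-component normal mixture to z-scale statistics by
#' expectation-maximization: a central component carrying the bulk of the
#' mass (the empirical null, whose mean and SD need not be 0 and 1) and
#' two tail components for true associations. The central component's
#' mean is the estimated bias and its SD the estimated inflation;
#' statistics are corrected as `z_adj = (z - bias) / inflation` and
#' two-sided p-values recomputed from the standard normal.
#'
#' EM initialization: central mean = median(z), central SD =
#' 1.4826 * MAD(z), tail means at +/- 3 central SDs, weights
#' (0.9, 0.05, 0.05). Convergence at a log-likelihood change below `tol`;
#' component SDs are floored at a small multiple of sd(z) to prevent
#' degenerate collapse, and the tail means are constrained to stay at
#' least two central SDs below/above the central mean so the central
#' component keeps the null bulk even when no true signals are present. After fitting, components are relabeled so the
#' largest-weight component is central; `z_adj` is a strictly increasing
#' affine function of `z`.
#'
#' @param z finite z-scale statistics (>= 1000 recommended).
#' @param tol log-likelihood convergence tolerance.
#' @param maxIter maximum EM iterations.
#' @return list with `fit` (a [BaconFit-class]), `zAdj`, and `pAdj`.
#' @export
baconCorrect <- function(z, tol = 1e-8, maxIter = 1000L) {
  z <- as.numeric(z)
  if (!length(z) || any(!is.finite(z))) stop("z must be non-empty and finite")
  if (length(z) < 1000L)
    warning("fewer than 1000 statistics; mixture estimates may be unstable")
  m0 <- median(z)
  s0 <- mad(z)                     # includes the 1.4826 consistency constant
  if (s0 <= 0) s0 <- max(sd(z), 1e-6)
  mu <- c(m0, m0 - 3 * s0, m0 + 3 * s0)
  sg <- rep(s0, 3)
  w <- c(0.9, 0.05, 0.05)
  sdFloor <- max(1e-6, 1e-4 * sd(z))
  n <- length(z)
  ll <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxIter)) {
    dens <- vapply(1:3, function(k) w[k] * dnorm(z, mu[k], sg[k]),
                   numeric(n))
    rowTot <- rowSums(dens)
    rowTot[rowTot < .Machine$double.xmin] <- .Machine$double.xmin
    llNew <- sum(log(rowTot))
    resp <- dens / rowTot
    nk <- colSums(resp)
    w <- pmax(nk / n, 1e-12)
    w <- w / sum(w)
    for (k in 1:3) {
      if (nk[k] > 1e-10) {
        mu[k] <- sum(resp[, k] * z) / nk[k]
        sg[k] <- sqrt(sum(resp[, k] * (z - mu[k])^2) / nk[k])
      }
      sg[k] <- max(sg[k], sdFloor)
    }
    # identifiability: tail means stay at least 2 central SDs below/above
    # the central mean so the central component keeps the null bulk
    mu[2] <- min(mu[2], mu[1] - 2 * sg[1])
    mu[3] <- max(mu[3], mu[1] + 2 * sg[1])
    if (is.finite(ll) && abs(llNew - ll) < tol * (1 + abs(llNew))) {
      ll <- llNew
      converged <- TRUE
      break
    }
    ll <- llNew
  }
  if (!converged)
    stop("EM did not converge in ", maxIter, " iterations; last estimates: ",
         sprintf("bias=%.4f inflation=%.4f", mu[which.max(w)], sg[which.max(w)]))
  # relabel: central = largest weight first, then tails ordered by mean
  central <- which.max(w)
  tails <- setdiff(1:3, central)
  tails <- tails[order(mu[tails])]
  ord <- c(central, tails)
  fit <- new("BaconFit", bias = mu[central], inflation = sg[central],
             weights = w[ord], means = mu[ord], sds = sg[ord],
             logLik = ll, nIter = it, converged = converged)
  zAdj <- (z - fit@bias) / fit@inflation
  pAdj <- 2 * pnorm(abs(zAdj), lower.tail = FALSE)
  list(fit = fit, zAdj = zAdj, pAdj = pAdj)
}

#' @importFrom stats dnorm
NULL
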