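#' Reference proximal-gradient solver for the penalized multivariate model
#'
#' Solves the same objective as [fitPenalized()] by a fully independent
#' algorithm: the coefficient step uses FISTA (accelerated proximal
#' gradient with full-matrix gradient and an explicit Lipschitz constant)
#' and the precision step uses ADMM for the graphical lasso (closed-form
#' eigen-decomposition update plus off-diagonal soft-thresholding).
#' Intended for cross-checking the production coordinate-descent /
#' block-coordinate solver on small instances; it shares no code path
#' with it.
#'
#' @inheritParams fitPenalized
#' @param tolOuter relative objective tolerance of the outer alternation.
#' @return list with `B` ((c+m) x q), `Gamma3` (q x m), `Theta`,
#'   `objective`, and `nIter`.
#' @export
fitPenalizedProx <- function(Y, X, W = NULL, lambda, rho,
                             tolOuter = 1e-9, maxOuter = 500L) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y); q <- ncol(Y); m <- ncol(X)
  if (is.null(W)) W <- matrix(1, n, 1)
  W <- as.matrix(W)
  cW <- ncol(W)
  Z <- cbind(W, X)
  pen <- c(rep(FALSE, cW), rep(TRUE, m))

  objective <- function(B, Theta) {
    R <- Y - Z %*% B
    S <- crossprod(R) / n
    sum(S * Theta) - determinant(Theta, logarithm = TRUE)$modulus[1] +
      lambda * sum(abs(B[pen, ])) +
      rho * (sum(abs(Theta)) - sum(abs(diag(Theta))))
  }

  B <- matrix(0, cW + m, q)
  B[seq_len(cW), ] <- qr.coef(qr(W), Y)
  R0 <- Y - W %*% B[seq_len(cW), , drop = FALSE]
  Theta <- diag(1 / pmax(colSums(R0^2) / n, 1e-8), q)

  ZtZ <- crossprod(Z)
  eigZ <- max(eigen(ZtZ, symmetric = TRUE, only.values = TRUE)$values)
  objPrev <- objective(B, Theta)
  it <- 0L
  for (it in seq_len(maxOuter)) {
    L <- (2 / n) * eigZ *
      max(eigen(Theta, symmetric = TRUE, only.values = TRUE)$values)
    B <- fistaStep(Z, Y, B, Theta, pen, lambda, n, L)
    S <- crossprod(Y - Z %*% B) / n
    Theta <- if (rho == 0) solve(S) else admmGlasso(S, rho)
    objNew <- objective(B, Theta)
    if (abs(objPrev - objNew) < tolOuter * (1 + abs(objNew))) {
      objPrev <- objNew
      break
    }
    objPrev <- objNew
  }
  list(B = B, Gamma3 = t(B[cW + seq_len(m), , drop = FALSE]),
       Theta = Theta, objective = objPrev, nIter = it)
}

# FISTA on g(B) = (1/n) tr[(Y-ZB)'(Y-ZB) Theta] + lambda |B_pen|_1
fistaStep <- function(Z, Y, B, Theta, pen, lambda, n, L,
                      tol = 1e-12, maxIter = 20000L) {
  gval <- function(B) {
    R <- Y - Z %*% B
    sum((crossprod(R) / n) * Theta) + lambda * sum(abs(B[pen, ]))
  }
  Bk <- B; Byk <- B; tk <- 1
  fPrev <- gval(B)
  for (i in seq_len(maxIter)) {
    grad <- -(2 / n) * crossprod(Z, Y - Z %*% Byk) %*% Theta
    Bnew <- Byk - grad / L
    Bnew[pen, ] <- sign(Bnew[pen, ]) * pmax(abs(Bnew[pen, ]) - lambda / L, 0)
    tNew <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Byk <- Bnew + ((tk - 1) / tNew) * (Bnew - Bk)
    Bk <- Bnew; tk <- tNew
    if (i %% 25L == 0L) {
      fNew <- gval(Bk)
      if (abs(fPrev - fNew) < tol * (1 + abs(fNew))) break
      fPrev <- fNew
    }
  }
  Bk
}

# ADMM for min tr(S Theta) - logdet Theta + rho |Theta|_{1,off}
admmGlasso <- function(S, rho, tau = 1, tol = 1e-10, maxIter = 10000L) {
  q <- nrow(S)
  Theta <- diag(1 / pmax(diag(S), 1e-8))
  Zm <- Theta; U <- matrix(0, q, q)
  for (i in seq_len(maxIter)) {
    eg <- eigen(tau * (Zm - U) - S, symmetric = TRUE)
    d <- (eg$values + sqrt(eg$values^2 + 4 * tau)) / (2 * tau)
    Theta <- eg$vectors %*% (d * t(eg$vectors))
    Zold <- Zm
    A <- Theta + U
    Zm <- sign(A) * pmax(abs(A) - rho / tau, 0)
    diag(Zm) <- diag(A)                   # diagonal unpenalized
    U <- U + Theta - Zm
    if (max(abs(Theta - Zm)) < tol && max(abs(Zm - Zold)) < tol) break
  }
  # Zm carries the exact sparsity; symmetrize and ensure PD
  Th <- 0.5 * (Zm + t(Zm))
  ev <- eigen(Th, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) Th <- 0.5 * (Theta + t(Theta))
  Th
}
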