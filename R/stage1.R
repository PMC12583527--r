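#' Stage-1 residualization of logit methylation
#'
#' Regresses each probe's logit-methylation on the global covariates
#' (intercept, years of education, age, epigenetic age acceleration, sex,
#' and the first three cell-type principal components) by ordinary least
#' squares, and returns the per-probe residuals standardized to mean 0
#' and sample SD 1. These standardized residuals are the methylation
#' input of both the univariate scan and the penalized multivariate
#' model, so downstream coefficients read as effects per 1 SD of
#' residual methylation.
#'
#' @param mvalues probes x samples matrix of logit-transformed beta values.
#' @param covariates data.frame with columns `yoe`, `age`, `eaa`, `sex`,
#'   `pc1`, `pc2`, `pc3` (one row per sample, in column order of
#'   `mvalues`).
#' @param dropTol probes whose raw residual SD falls below this are
#'   dropped with a warning (their methylation is fully explained by the
#'   covariates).
#' @return list with `residuals` (samples x probes, standardized),
#'   `coefficients` (covariates x probes) and `dropped` (probe ids).
#' @export
residualize <- function(mvalues, covariates, dropTol = 1e-12) {
  need <- c("yoe", "age", "eaa", "sex", "pc1", "pc2", "pc3")
  miss <- setdiff(need, colnames(covariates))
  if (length(miss)) stop("covariates missing columns: ", paste(miss, collapse = ", "))
  if (ncol(mvalues) != nrow(covariates))
    stop("ncol(mvalues) must equal nrow(covariates)")
  if (anyNA(covariates[, need]) || anyNA(mvalues))
    stop("complete cases required: missing values present")
  D <- cbind(intercept = 1, as.matrix(covariates[, need]))
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[(qrD$rank + 1L):ncol(D)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  Yt <- t(mvalues)                       # samples x probes
  coefs <- qr.coef(qrD, Yt)
  res <- qr.resid(qrD, Yt)
  sds <- apply(res, 2, sd)
  drop <- sds < dropTol
  if (any(drop)) {
    warning(sum(drop), " probe(s) dropped: residual SD below ", dropTol)
    res <- res[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  res <- sweep(res, 2, sds, `/`)
  list(residuals = res,
       coefficients = coefs[, !drop, drop = FALSE],
       dropped = rownames(mvalues)[drop])
}
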