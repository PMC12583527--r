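#' Univariate EWAS scan of one phenotype against cluster residuals
#'
#' For each probe fits the second-stage univariate model: phenotype on an
#' intercept, diagnosis, APOE4 allele count, and the probe's standardized
#' stage-1 residual. Diagnosis enters as two indicator columns when given
#' as a factor (MCI and AD versus CN) or as a single numeric column when
#' numeric (the simulation coding). The probe slope, its t statistic
#' (mapped to the z scale through the t p-value) and the two-sided
#' p-value are reported per probe.
#'
#' Computation uses the Frisch-Waugh decomposition: phenotype and probe
#' residuals are orthogonalized against the covariate block once, giving
#' slopes and standard errors identical to the full per-probe OLS fit.
#'
#' @param Y phenotype vector (length n).
#' @param X n x m matrix of standardized probe residuals.
#' @param dx diagnosis factor (CN/MCI/AD) or numeric code.
#' @param apoe4 numeric allele counts.
#' @param phenotype label stored in the output.
#' @return data.frame with columns `probe_id`, `phenotype`, `beta`, `se`,
#'   `t`, `df`, `z`, `p`, plus `skipped` for zero-variance probes.
#' @export
ewasScan <- function(Y, X, dx, apoe4, phenotype = "Y") {
  n <- length(Y)
  if (nrow(X) != n) stop("nrow(X) must equal length(Y)")
  W <- covariateBlock(dx, apoe4, n)
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) stop("covariate block is rank deficient")
  yr <- qr.resid(qrW, Y)
  Xr <- qr.resid(qrW, X)
  sxx <- colSums(Xr^2)
  dfRes <- n - ncol(W) - 1L
  if (dfRes < 1L) stop("not enough residual degrees of freedom")
  skipped <- sxx < 1e-12 * n
  slope <- se <- tval <- rep(NA_real_, ncol(X))
  ok <- !skipped
  slope[ok] <- colSums(Xr[, ok, drop = FALSE] * yr) / sxx[ok]
  rss <- colSums((yr - sweep(Xr[, ok, drop = FALSE], 2, slope[ok], `*`))^2)
  se[ok] <- sqrt(rss / dfRes / sxx[ok])
  tval[ok] <- slope[ok] / se[ok]
  p <- 2 * pt(abs(tval), dfRes, lower.tail = FALSE)
  z <- sign(tval) * qnorm(pmax(p / 2, .Machine$double.xmin), lower.tail = FALSE)
  ids <- colnames(X)
  if (is.null(ids)) ids <- sprintf("probe%d", seq_len(ncol(X)))
  data.frame(probe_id = ids, phenotype = phenotype, beta = slope, se = se,
             t = tval, df = dfRes, z = z, p = p, skipped = skipped,
             row.names = NULL)
}

# intercept + diagnosis coding + APOE4 count
covariateBlock <- function(dx, apoe4, n) {
  if (length(dx) != n || length(apoe4) != n) stop("dx/apoe4 length mismatch")
  if (is.factor(dx) || is.character(dx)) {
    dx <- factor(dx, levels = c("CN", "MCI", "AD"))
    W <- cbind(intercept = 1, dxMCI = as.numeric(dx == "MCI"),
               dxAD = as.numeric(dx == "AD"), apoe4 = apoe4)
  } else {
    W <- cbind(intercept = 1, dx = as.numeric(dx), apoe4 = apoe4)
  }
  W
}

#' Genomic inflation factor
#'
#' `lambda_gc = median(z^2) / 0.4549364`, the median of the chi-squared
#' distribution with one degree of freedom.
#'
#' @param z vector of z-scale statistics.
#' @return the inflation factor.
#' @export
inflationFactor <- function(z) {
  if (!length(z)) stop("empty statistic vector")
  median(z^2) / qchisq(0.5, df = 1)
}

#' Significance calls at corrected thresholds
#'
#' Genome-wide significance at `3.6e-8 / nPhenotypes` and suggestive
#' significance at `1e-5 / nPhenotypes` (both thresholds divided by the
#' number of phenotypes tested).
#'
#' @param pAdj corrected p-values in (0, 1\].
#' @param nPhenotypes number of phenotypes tested jointly (default 3).
#' @return factor with levels `genome_wide`, `suggestive`, `none`.
#' @export
callSignificance <- function(pAdj, nPhenotypes = 3) {
  gw <- 3.6e-8 / nPhenotypes
  sugg <- 1e-5 / nPhenotypes
  out <- ifelse(pAdj < gw, "genome_wide",
                ifelse(pAdj < sugg, "suggestive", "none"))
  factor(out, levels = c("genome_wide", "suggestive", "none"))
}
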