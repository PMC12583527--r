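#' Entry-wise selection metrics
#'
#' Compares the support of an estimated 3 x m coefficient matrix against
#' the truth, entry by entry. An entry is positive when its magnitude
#' exceeds `zeroTol`. TPR and TNR are undefined (NA) when their
#' denominator is zero; the MCC is computed on counts and is NA when any
#' marginal vanishes.
#'
#' @param trueBeta,estBeta matrices of identical shape.
#' @param zeroTol magnitude threshold separating zero from nonzero.
#' @return list with `tp`, `fp`, `fn`, `tn`, `tpr`, `tnr`, `mcc`.
#' @export
confusionMetrics <- function(trueBeta, estBeta, zeroTol = 1e-8) {
  if (!all(dim(trueBeta) == dim(estBeta)))
    stop("trueBeta and estBeta must have identical shapes")
  tPos <- abs(trueBeta) > zeroTol
  ePos <- abs(estBeta) > zeroTol
  tp <- sum(tPos & ePos); fp <- sum(!tPos & ePos)
  fn <- sum(tPos & !ePos); tn <- sum(!tPos & !ePos)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else NA_real_
  list(tp = tp, fp = fp, fn = fn, tn = tn, tpr = tpr, tnr = tnr, mcc = mcc)
}

#' Univariate EWAS selector over a cluster
#'
#' Runs the univariate second-stage scan per phenotype and probe and
#' selects entries with p below `alpha`. The default threshold is the
#' within-cluster Bonferroni correction `0.05 / (3 m)`.
#'
#' @param Y n x 3 phenotype matrix.
#' @param X n x m standardized probe residuals.
#' @param dx,apoe4 covariates (see [ewasScan()]).
#' @param alpha selection threshold; `NULL` means `0.05 / (3 m)`.
#' @return 3 x m binary matrix of selected entries (rows = phenotypes).
#' @export
ewasSelector <- function(Y, X, dx, apoe4, alpha = NULL) {
  q <- ncol(Y); m <- ncol(X)
  if (is.null(alpha)) alpha <- 0.05 / (q * m)
  sel <- matrix(0L, q, m,
                dimnames = list(colnames(Y), colnames(X)))
  for (k in seq_len(q)) {
    scan <- ewasScan(Y[, k], X, dx, apoe4,
                     phenotype = colnames(Y)[k] %||% paste0("Y", k))
    sel[k, ] <- as.integer(!scan$skipped & !is.na(scan$p) & scan$p < alpha)
  }
  sel
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the probe-selection simulation study
#'
#' For each simulated dataset: a fresh synthetic cohort is generated, its
#' logit methylation is residualized on the stage-1 covariates, one
#' cluster of probes is taken as the predictor block, a scenario's true
#' coefficient matrix is drawn, phenotypes are simulated, and each method
#' (BIC-tuned multivariate fit, CV-tuned multivariate fit, univariate
#' Bonferroni EWAS selector) is scored entry-wise against the truth.
#' The residual covariance of the phenotype generator is the empirical
#' covariance of the cohort's transformed A/M/D. Deterministic given
#' `seed`.
#'
#' @param nDatasets simulated datasets per scenario.
#' @param scenarios scenario names (see [makeScenario()]).
#' @param methods subset of `c("mvBIC", "mvCV", "ewas")`.
#' @param seed master seed; per-dataset seeds are derived from it.
#' @param n,m cohort size and cluster size.
#' @param nLambda,nRho tuning-grid sizes for the multivariate fits.
#' @param k CV folds.
#' @param tol,maxOuter solver controls.
#' @return list with `perDataset` (one row per dataset x scenario x
#'   method) and `aggregate` (means and medians of defined metrics).
#' @export
runSimulationStudy <- function(nDatasets = 50L,
                               scenarios = c("null", "moderate", "strong"),
                               methods = c("mvBIC", "mvCV", "ewas"),
                               seed = 1L, n = 540L, m = 100L,
                               nLambda = 10L, nRho = 5L, k = 5L,
                               tol = 1e-4, maxOuter = 100L) {
  methods <- match.arg(methods, c("mvBIC", "mvCV", "ewas"), several.ok = TRUE)
  rows <- list()
  for (d in seq_len(nDatasets)) {
    seedD <- seed * 1000L + d
    cfg <- cohortConfig(nSamples = n, nClusters = 1L, probesPerCluster = m,
                        seed = seedD)
    cohort <- generateCohort(cfg)
    covTab <- covariates(cohort)
    bio <- biomarkers(cohort)
    mv <- logitTransform(methylation(cohort))
    X <- residualize(mv, covTab)$residuals
    dxNum <- as.numeric(factor(covTab$dx, levels = c("CN", "MCI", "AD"))) - 1
    apoe4 <- covTab$apoe4
    sigmaStar <- cov(cbind(bio$a, bio$m, bio$d))
    Wfit <- covariateBlock(dxNum, apoe4, n)

    for (sc in scenarios) {
      scen <- makeScenario(sc, m = ncol(X), sigmaStar = sigmaStar,
                           seed = seedD + 7L)
      sim <- simulatePhenotypes(X, dxNum, apoe4, scen, seed = seedD + 13L)
      Y <- sim$Y
      for (meth in methods) {
        est <- switch(meth,
          mvBIC = probeEffects(tuneFit(Y, X, Wfit, criterion = "bic",
                                       nLambda = nLambda, nRho = nRho,
                                       tol = tol, maxOuter = maxOuter)),
          mvCV = probeEffects(tuneFit(Y, X, Wfit, criterion = "cv",
                                      nLambda = nLambda, nRho = nRho, k = k,
                                      seed = seedD + 29L, tol = tol,
                                      maxOuter = maxOuter)),
          ewas = ewasSelector(Y, X, dxNum, apoe4))
        metr <- confusionMetrics(scen@betaP, est)
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = d, scenario = sc, method = meth,
          tp = metr$tp, fp = metr$fp, fn = metr$fn, tn = metr$tn,
          tpr = metr$tpr, tnr = metr$tnr, mcc = metr$mcc)
      }
    }
  }
  perDataset <- do.call(rbind, rows)
  aggregate <- aggregateMetrics(perDataset)
  list(perDataset = perDataset, aggregate = aggregate)
}

#' Aggregate per-dataset metrics
#'
#' Means and medians per scenario and method; undefined (NA) metrics are
#' excluded with their exclusion counts reported.
#'
#' @param perDataset the per-dataset table from [runSimulationStudy()].
#' @return data.frame with one row per scenario x method.
#' @export
aggregateMetrics <- function(perDataset) {
  parts <- split(perDataset,
                 list(perDataset$scenario, perDataset$method), drop = TRUE)
  out <- lapply(parts, function(d) data.frame(
    scenario = d$scenario[1], method = d$method[1], nDatasets = nrow(d),
    mean_tpr = mean(d$tpr, na.rm = TRUE), median_tpr = median(d$tpr, na.rm = TRUE),
    mean_tnr = mean(d$tnr, na.rm = TRUE), median_tnr = median(d$tnr, na.rm = TRUE),
    mean_mcc = mean(d$mcc, na.rm = TRUE), median_mcc = median(d$mcc, na.rm = TRUE),
    n_undefined_tpr = sum(is.na(d$tpr)), n_undefined_mcc = sum(is.na(d$mcc)),
    mean_fp = mean(d$fp)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
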