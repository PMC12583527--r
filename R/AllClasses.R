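#' @import methods
#' @importFrom stats median mad qnorm pnorm pt qchisq rnorm runif rgamma
#'   rbinom sd var cov cor prcomp plogis qlogis setNames quantile
NULL

#' Configuration for the synthetic cohort generator
#'
#' Holds every knob of the ADNI-like cohort generator: cohort size, the
#' block structure of the methylation matrix, the lognormal model for the
#' raw CSF biomarkers (amyloid-beta 42 \eqn{A^*}, phosphorylated tau
#' \eqn{T^*}, total tau \eqn{N^*}), APOE4 allele-count frequencies by
#' diagnosis, and diagnosis proportions.
#'
#' Defaults emulate the published cohort: 540 participants split
#' CN/MCI/AD as 174/278/88, APOE4 carrier fractions 24.7/41.0/73.9
#' percent by diagnosis, and corr(\eqn{T^*},\eqn{N^*}) = 0.981 on the
#' log scale.
#'
#' @slot nSamples number of participants.
#' @slot nClusters number of gene clusters (one gene per cluster).
#' @slot probesPerCluster CpG probes simulated per cluster.
#' @slot blockCorrelation within-cluster latent (logit-scale) correlation,
#'   in \[0, 1).
#' @slot biomarkerLogMeans,biomarkerLogSds length-3 mean/SD of
#'   (log A*, log T*, log N*).
#' @slot corrTN,corrAT log-scale correlations; corr(A*, N*) is taken as
#'   their product.
#' @slot apoe4FreqByDx 3x3 matrix, rows CN/MCI/AD, columns allele count
#'   0/1/2; each row sums to 1.
#' @slot dxProportions length-3 simplex over CN/MCI/AD.
#' @slot failFraction fraction of detection p-value entries simulated as
#'   failed (exercises QC only).
#' @slot seed integer seed; generation is deterministic given it.
#' @export
setClass("CohortConfig",
  representation(
    nSamples = "integer", nClusters = "integer", probesPerCluster = "integer",
    blockCorrelation = "numeric",
    biomarkerLogMeans = "numeric", biomarkerLogSds = "numeric",
    corrTN = "numeric", corrAT = "numeric",
    apoe4FreqByDx = "matrix", dxProportions = "numeric",
    failFraction = "numeric", seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msgs <- character()
  if (object@nSamples < 10L) msgs <- c(msgs, "nSamples must be >= 10")
  if (object@nClusters < 1L) msgs <- c(msgs, "nClusters must be >= 1")
  if (object@probesPerCluster < 2L) msgs <- c(msgs, "probesPerCluster must be >= 2")
  if (object@blockCorrelation < 0 || object@blockCorrelation >= 1)
    msgs <- c(msgs, "blockCorrelation must be in [0, 1)")
  if (length(object@biomarkerLogMeans) != 3L || length(object@biomarkerLogSds) != 3L)
    msgs <- c(msgs, "biomarkerLogMeans/Sds must have length 3")
  if (any(object@biomarkerLogSds <= 0)) msgs <- c(msgs, "biomarkerLogSds must be positive")
  if (object@corrTN <= 0 || object@corrTN >= 1) msgs <- c(msgs, "corrTN must be in (0, 1)")
  if (abs(object@corrAT) >= 1) msgs <- c(msgs, "corrAT must be in (-1, 1)")
  R <- biomarkerCorrMatrix(object@corrTN, object@corrAT)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10)
    msgs <- c(msgs, "implied biomarker correlation matrix is not positive definite")
  if (!all(dim(object@apoe4FreqByDx) == c(3L, 3L)))
    msgs <- c(msgs, "apoe4FreqByDx must be a 3x3 matrix (dx x allele count)")
  else if (any(abs(rowSums(object@apoe4FreqByDx) - 1) > 1e-8) ||
           any(object@apoe4FreqByDx < 0))
    msgs <- c(msgs, "apoe4FreqByDx rows must be simplexes")
  if (length(object@dxProportions) != 3L ||
      abs(sum(object@dxProportions) - 1) > 1e-8 || any(object@dxProportions < 0))
    msgs <- c(msgs, "dxProportions must be a length-3 simplex")
  if (object@failFraction < 0 || object@failFraction >= 1)
    msgs <- c(msgs, "failFraction must be in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

# correlation matrix of (log A*, log T*, log N*); corr(A,N) = corrAT * corrTN
biomarkerCorrMatrix <- function(corrTN, corrAT) {
  corrAN <- corrAT * corrTN
  matrix(c(1, corrAT, corrAN,
           corrAT, 1, corrTN,
           corrAN, corrTN, 1), 3L, 3L,
         dimnames = list(c("A", "T", "N"), c("A", "T", "N")))
}

#' A generated ADNI-like cohort
#'
#' Wraps a [SummarizedExperiment::RangedSummarizedExperiment] holding the
#' beta-value and detection p-value assays (probes x samples, with probe
#' positions as row ranges and all covariates plus raw and transformed
#' biomarkers as column data), together with the gene annotation used to
#' lay probes out and the generator truth (the configuration and cluster
#' membership).
#'
#' @slot se RangedSummarizedExperiment with assays `beta` and `detp`.
#' @slot genes [GenomicRanges::GRanges] of simulated genes.
#' @slot truth list with the generating `config` and per-probe `cluster`.
#' @export
setClass("SyntheticCohort",
  representation(se = "RangedSummarizedExperiment", genes = "GRanges",
                 truth = "list")
)

setValidity("SyntheticCohort", function(object) {
  msgs <- character()
  b <- SummarizedExperiment::assay(object@se, "beta")
  if (any(b <= 0) || any(b >= 1)) msgs <- c(msgs, "beta values must lie strictly in (0,1)")
  cd <- SummarizedExperiment::colData(object@se)
  cellCols <- grep("^cell_", colnames(cd), value = TRUE)
  if (length(cellCols) != 7L) msgs <- c(msgs, "expected 7 cell-type proportion columns")
  else if (any(abs(rowSums(as.matrix(cd[, cellCols])) - 1) > 1e-8))
    msgs <- c(msgs, "cell-type proportions must sum to 1 per sample")
  if (length(msgs)) msgs else TRUE
})

#' Simulation scenario for phenotype generation
#'
#' Describes the true generating model for the three phenotypes:
#' diagnosis and APOE4 effects (`betaDx`, `betaApoe4`), the sparse
#' 3 x m probe-effect matrix `betaP`, and the residual covariance
#' `sigmaStar` for the multivariate-normal error.
#'
#' Named scenarios: `"null"` (betaP all zero), `"moderate"` (5 entries at
#' 0.04, spread across the three phenotypes as 2/2/1), `"strong"` (same at
#' 0.08), and `"single_phenotype"` (5 entries at 0.04 on one phenotype).
#'
#' @slot name scenario label.
#' @slot betaDx,betaApoe4 length-3 covariate effects.
#' @slot betaP 3 x m matrix of probe effects.
#' @slot sigmaStar 3 x 3 positive-definite residual covariance.
#' @slot nSignals number of nonzero `betaP` entries.
#' @slot effectSize common magnitude of the nonzero entries.
#' @export
setClass("ScenarioSpec",
  representation(name = "character", betaDx = "numeric", betaApoe4 = "numeric",
                 betaP = "matrix", sigmaStar = "matrix",
                 nSignals = "integer", effectSize = "numeric")
)

setValidity("ScenarioSpec", function(object) {
  msgs <- character()
  if (!object@name %in% c("null", "moderate", "strong", "single_phenotype"))
    msgs <- c(msgs, "name must be one of null/moderate/strong/single_phenotype")
  if (length(object@betaDx) != 3L || length(object@betaApoe4) != 3L)
    msgs <- c(msgs, "betaDx and betaApoe4 must have length 3")
  if (nrow(object@betaP) != 3L) msgs <- c(msgs, "betaP must have 3 rows")
  nz <- sum(object@betaP != 0)
  if (object@name == "null" && nz != 0L) msgs <- c(msgs, "null scenario requires betaP == 0")
  if (object@name != "null" && nz != object@nSignals)
    msgs <- c(msgs, sprintf("expected %d nonzero betaP entries, found %d",
                            object@nSignals, nz))
  if (object@name == "moderate" && nz && !all(object@betaP[object@betaP != 0] == 0.04))
    msgs <- c(msgs, "moderate scenario requires nonzero entries equal to 0.04")
  if (object@name == "strong" && nz && !all(object@betaP[object@betaP != 0] == 0.08))
    msgs <- c(msgs, "strong scenario requires nonzero entries equal to 0.08")
  if (object@name == "single_phenotype" && nz &&
      sum(rowSums(object@betaP != 0) > 0) != 1L)
    msgs <- c(msgs, "single_phenotype scenario must place all signals on one phenotype")
  if (!all(dim(object@sigmaStar) == c(3L, 3L)) ||
      min(eigen(object@sigmaStar, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    msgs <- c(msgs, "sigmaStar must be 3x3 positive definite")
  if (length(msgs)) msgs else TRUE
})

#' Mixture-model fit to a set of test statistics
#'
#' Result of the bias/inflation correction: a three-component normal
#' mixture fitted by EM to z-scale statistics. The central (largest
#' weight) component is taken as the empirical null; its mean is the
#' `bias` and its SD the `inflation`.
#'
#' @slot bias estimated null mean.
#' @slot inflation estimated null SD (> 0).
#' @slot weights,means,sds length-3 mixture parameters; component 1 is
#'   the central one.
#' @slot logLik final observed-data log-likelihood.
#' @slot nIter EM iterations used.
#' @slot converged logical.
#' @export
setClass("BaconFit",
  representation(bias = "numeric", inflation = "numeric",
                 weights = "numeric", means = "numeric", sds = "numeric",
                 logLik = "numeric", nIter = "integer", converged = "logical")
)

setValidity("BaconFit", function(object) {
  msgs <- character()
  if (object@inflation <= 0) msgs <- c(msgs, "inflation must be positive")
  if (abs(sum(object@weights) - 1) > 1e-6) msgs <- c(msgs, "weights must sum to 1")
  if (which.max(object@weights) != 1L)
    msgs <- c(msgs, "central component (index 1) must carry the largest weight")
  if (length(msgs)) msgs else TRUE
})

#' Fit of the L1-penalized multivariate regression
#'
#' Joint estimate of the coefficient matrix and the residual precision
#' matrix for one gene cluster. The unpenalized covariate block
#' (intercept, diagnosis, APOE4) is in `gammaW` (c x q); the penalized
#' probe block is `Gamma3` (q x m, responses x probes). `Theta` is the
#' q x q precision matrix with L1 penalty on its off-diagonals.
#'
#' @slot gammaW unpenalized coefficients, covariates x responses.
#' @slot Gamma3 penalized probe coefficients, responses x probes.
#' @slot Theta residual precision matrix (symmetric positive definite).
#' @slot lambda,rho penalty levels used.
#' @slot objective final objective value.
#' @slot objPath objective after each outer iteration (nonincreasing).
#' @slot bic BIC of the fit (NA until computed).
#' @slot cvError held-out negative log-likelihood (NA unless tuned by CV).
#' @slot nIter outer iterations used.
#' @slot converged logical.
#' @slot residuals n x q residual matrix.
#' @export
setClass("PenalizedFit",
  representation(gammaW = "matrix", Gamma3 = "matrix", Theta = "matrix",
                 lambda = "numeric", rho = "numeric",
                 objective = "numeric", objPath = "numeric",
                 bic = "numeric", cvError = "numeric",
                 nIter = "integer", converged = "logical",
                 residuals = "matrix")
)

setValidity("PenalizedFit", function(object) {
  msgs <- character()
  Th <- object@Theta
  if (max(abs(Th - t(Th))) > 1e-8) msgs <- c(msgs, "Theta must be symmetric")
  else if (min(eigen(Th, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    msgs <- c(msgs, "Theta must be positive definite")
  if (!is.finite(object@objective)) msgs <- c(msgs, "objective must be finite")
  if (length(msgs)) msgs else TRUE
})
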