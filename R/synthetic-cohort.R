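#' Construct a cohort-generator configuration
#'
#' Defaults reproduce the structure of the study cohort: n = 540 with
#' diagnosis proportions 174/278/88 (CN/MCI/AD), APOE4 carrier fractions
#' 24.7/41.0/73.9 percent by diagnosis, lognormal CSF biomarkers with
#' corr(T*, N*) = 0.981 on the log scale, and block-correlated bimodal
#' methylation organised into gene clusters.
#'
#' @param nSamples,nClusters,probesPerCluster cohort dimensions.
#' @param blockCorrelation within-cluster logit-scale probe correlation.
#' @param biomarkerLogMeans,biomarkerLogSds lognormal parameters of
#'   (A*, T*, N*).
#' @param corrTN,corrAT log-scale correlations; corr(A*, N*) is their
#'   product.
#' @param apoe4FreqByDx 3x3 matrix (rows CN/MCI/AD, cols 0/1/2 alleles).
#' @param dxProportions length-3 simplex over CN/MCI/AD.
#' @param failFraction fraction of detection p-value entries failed.
#' @param seed integer seed.
#' @return a validated [CohortConfig-class] object.
#' @export
cohortConfig <- function(nSamples = 540L,
                         nClusters = 20L,
                         probesPerCluster = 100L,
                         blockCorrelation = 0.4,
                         biomarkerLogMeans = c(6.86, 3.18, 5.54),
                         biomarkerLogSds = c(0.60, 0.45, 0.40),
                         corrTN = 0.981,
                         corrAT = -0.5,
                         apoe4FreqByDx = rbind(
                           CN  = c(0.753, 0.185, 0.062),
                           MCI = c(0.590, 0.3075, 0.1025),
                           AD  = c(0.261, 0.554, 0.185)),
                         dxProportions = c(CN = 174, MCI = 278, AD = 88) / 540,
                         failFraction = 0.005,
                         seed = 1L) {
  new("CohortConfig",
      nSamples = as.integer(nSamples), nClusters = as.integer(nClusters),
      probesPerCluster = as.integer(probesPerCluster),
      blockCorrelation = blockCorrelation,
      biomarkerLogMeans = biomarkerLogMeans, biomarkerLogSds = biomarkerLogSds,
      corrTN = corrTN, corrAT = corrAT,
      apoe4FreqByDx = apoe4FreqByDx, dxProportions = dxProportions,
      failFraction = failFraction, seed = as.integer(seed))
}

# Dirichlet sampler via gamma normalisation
rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

# Blood cell types measured by reference-based deconvolution;
# neutrophil-dominated composition typical of whole blood.
.cellTypes <- c("CD4T", "CD8T", "NK", "Bcell", "Mono", "Neu", "Eos")
.cellAlphas <- c(CD4T = 9, CD8T = 6, NK = 3, Bcell = 4, Mono = 5, Neu = 30, Eos = 1.5)

#' Generate a synthetic ADNI-like cohort
#'
#' Methylation is generated as the inverse logit of block-correlated
#' latent Gaussians: each cluster shares a per-sample factor with loading
#' sqrt(blockCorrelation), per-probe baseline logit-means come from a
#' two-component (hypo/hyper-methylated) mixture so beta values are
#' bimodal, and per-probe scales vary. Raw biomarkers are lognormal with
#' the configured correlation structure; APOE4 allele counts are drawn
#' conditionally on diagnosis; cell-type proportions are Dirichlet over
#' the 7 blood cell types with their first three principal components
#' precomputed. Deterministic given `config@seed`.
#'
#' @param config a [CohortConfig-class].
#' @return a [SyntheticCohort-class].
#' @export
generateCohort <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nSamples
  nc <- config@nClusters
  ppc <- config@probesPerCluster
  p <- nc * ppc

  sampleIds <- sprintf("S%04d", seq_len(n))
  probeIds <- sprintf("cg%08d", seq_len(p))
  cluster <- rep(seq_len(nc), each = ppc)

  ## --- covariates -----------------------------------------------------
  dxLv <- c("CN", "MCI", "AD")
  dx <- factor(sample(dxLv, n, replace = TRUE, prob = config@dxProportions),
               levels = dxLv)
  apoe4 <- integer(n)
  for (g in dxLv) {
    idx <- which(dx == g)
    if (length(idx))
      apoe4[idx] <- sample(0:2, length(idx), replace = TRUE,
                           prob = config@apoe4FreqByDx[g, ])
  }
  age <- pmin(pmax(rnorm(n, 74.6, 7.5), 55), 95)
  yoe <- round(pmin(pmax(rnorm(n, 16.2, 2.6), 8), 20))
  sex <- rbinom(n, 1L, 0.46)
  eaa <- rnorm(n, 0, 3.5)
  cellProps <- rdirichlet(n, .cellAlphas)
  colnames(cellProps) <- .cellTypes
  pca <- cellTypePCA(cellProps, k = 3L)

  ## --- biomarkers ------------------------------------------------------
  R <- biomarkerCorrMatrix(config@corrTN, config@corrAT)
  Sg <- diag(config@biomarkerLogSds) %*% R %*% diag(config@biomarkerLogSds)
  logRaw <- MASS::mvrnorm(n, mu = config@biomarkerLogMeans, Sigma = Sg)
  aRaw <- exp(logRaw[, 1]); tRaw <- exp(logRaw[, 2]); nRaw <- exp(logRaw[, 3])
  amd <- transformBiomarkers(aRaw, tRaw, nRaw)

  ## --- methylation -----------------------------------------------------
  rho <- config@blockCorrelation
  hyper <- rbinom(p, 1L, 0.5)
  mu <- ifelse(hyper == 1L, rnorm(p, 2.8, 0.7), rnorm(p, -2.8, 0.7))
  tau <- runif(p, 0.3, 0.8)
  beta <- matrix(NA_real_, p, n, dimnames = list(probeIds, sampleIds))
  for (cc in seq_len(nc)) {
    rows <- which(cluster == cc)
    f <- rnorm(n)                        # shared cluster factor per sample
    e <- matrix(rnorm(length(rows) * n), length(rows), n)
    lat <- sqrt(rho) * matrix(f, length(rows), n, byrow = TRUE) +
      sqrt(1 - rho) * e
    beta[rows, ] <- plogis(mu[rows] + tau[rows] * lat)
  }
  # strict (0,1): logit-normal never reaches the boundary but guard the
  # representable range anyway
  beta <- pmin(pmax(beta, 1e-12), 1 - 1e-12)

  detp <- matrix(runif(p * n, 0, 0.01), p, n,
                 dimnames = list(probeIds, sampleIds))
  if (config@failFraction > 0) {
    nf <- round(config@failFraction * length(detp))
    if (nf > 0) {
      bad <- sample(length(detp), nf)
      detp[bad] <- runif(nf, 0.05, 0.5)
    }
  }

  ## --- genomic layout --------------------------------------------------
  geneStarts <- 5e5 + (seq_len(nc) - 1L) * 1e6
  geneLen <- round(runif(nc, 2e4, 5e4))
  genes <- GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(start = geneStarts + 1L,
                              end = geneStarts + geneLen),
    gene_id = sprintf("GENE%03d", seq_len(nc)))
  pos <- integer(p)
  for (cc in seq_len(nc)) {
    rows <- which(cluster == cc)
    lo <- geneStarts[cc] - 1e5
    hi <- geneStarts[cc] + geneLen[cc] + 1e5 - 1
    pos[rows] <- sort(sample(seq(lo, hi), length(rows)))
  }
  rr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos + 1L, width = 1L),
                               probe_id = probeIds, cluster = cluster)
  names(rr) <- probeIds

  cd <- S4Vectors::DataFrame(
    sample_id = sampleIds, yoe = as.numeric(yoe), age = age, eaa = eaa,
    sex = sex, dx = dx, apoe4 = apoe4,
    a_raw = aRaw, t_raw = tRaw, n_raw = nRaw,
    a = amd$a, m = amd$m, d = amd$d,
    pc1 = pca$scores[, 1], pc2 = pca$scores[, 2], pc3 = pca$scores[, 3],
    row.names = sampleIds)
  for (j in seq_along(.cellTypes))
    cd[[paste0("cell_", .cellTypes[j])]] <- cellProps[, j]

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = beta, detp = detp), rowRanges = rr, colData = cd)

  new("SyntheticCohort", se = se, genes = genes,
      truth = list(config = config, cluster = cluster))
}

#' Draw diagnosis and APOE4 effect vectors for a simulated dataset
#'
#' Each of the three phenotypes receives an effect with magnitude drawn
#' from Unif(0.1, 0.5) and sign positive or negative with probability 1/2
#' (i.e. Unif(0.1, 0.5) or Unif(-0.5, -0.1) with equal probability).
#'
#' @param seed integer seed; deterministic given it.
#' @return list with `betaDx` and `betaApoe4`, each length 3.
#' @export
drawCovariateEffects <- function(seed) {
  set.seed(seed)
  draw <- function() {
    mag <- runif(3, 0.1, 0.5)
    sgn <- ifelse(runif(3) < 0.5, -1, 1)
    mag * sgn
  }
  list(betaDx = draw(), betaApoe4 = draw())
}

# partition nSignals across 3 phenotypes as evenly as possible; for 5
# that is (2,2,1) with the short phenotype chosen uniformly
signalCountsPerPhenotype <- function(nSignals) {
  base <- nSignals %/% 3L
  extra <- nSignals %% 3L
  counts <- rep(base, 3L)
  if (extra > 0L) {
    bump <- sample(3L, extra)
    counts[bump] <- counts[bump] + 1L
  }
  counts
}

#' Build a simulation scenario
#'
#' Constructs the true probe-effect matrix for the named scenario:
#' `"null"` has no signals; `"moderate"`/`"strong"` place `nSignals`
#' entries of size 0.04/0.08 spread as evenly as possible across the three
#' phenotypes (5 signals become 2/2/1); `"single_phenotype"` places all
#' `nSignals` on one uniformly chosen phenotype at 0.04. Signal columns
#' are drawn uniformly without replacement within each phenotype.
#' Covariate effects are drawn via [drawCovariateEffects()].
#'
#' @param name scenario name.
#' @param m cluster size (columns of betaP).
#' @param sigmaStar 3x3 residual covariance, e.g. the empirical
#'   covariance of a cohort's transformed A/M/D.
#' @param seed integer seed.
#' @param nSignals number of nonzero entries (default 5).
#' @return a validated [ScenarioSpec-class].
#' @export
makeScenario <- function(name = c("null", "moderate", "strong", "single_phenotype"),
                         m, sigmaStar, seed, nSignals = 5L) {
  name <- match.arg(name)
  eff <- drawCovariateEffects(seed)
  set.seed(seed + 1L)
  effectSize <- switch(name, null = 0, moderate = 0.04, strong = 0.08,
                       single_phenotype = 0.04)
  betaP <- matrix(0, 3L, m)
  if (name %in% c("moderate", "strong")) {
    counts <- signalCountsPerPhenotype(nSignals)
    for (r in 1:3) if (counts[r] > 0)
      betaP[r, sample(m, counts[r])] <- effectSize
  } else if (name == "single_phenotype") {
    r <- sample(3L, 1L)
    betaP[r, sample(m, nSignals)] <- effectSize
  }
  new("ScenarioSpec", name = name, betaDx = eff$betaDx,
      betaApoe4 = eff$betaApoe4, betaP = betaP, sigmaStar = sigmaStar,
      nSignals = if (name == "null") 0L else as.integer(nSignals),
      effectSize = effectSize)
}

#' Simulate phenotypes from a scenario
#'
#' Generates `Y = DX * betaDx' + APOE4 * betaApoe4' + X * betaP' + E`
#' with rows of `E` i.i.d. MVN(0, sigmaStar). In simulation, diagnosis
#' enters as a single numeric code (CN/MCI/AD = 0/1/2), matching the
#' length-3 diagnosis effect vector.
#'
#' @param X n x m matrix of standardized methylation residuals for one
#'   cluster.
#' @param dx per-sample numeric diagnosis code (0/1/2) or factor.
#' @param apoe4 per-sample allele count.
#' @param scenario a [ScenarioSpec-class] with `ncol(betaP) == ncol(X)`.
#' @param seed integer seed for the residual draw.
#' @return list with `Y` (n x 3, columns A/M/D) and `truth` (the scenario).
#' @export
simulatePhenotypes <- function(X, dx, apoe4, scenario, seed) {
  validObject(scenario)
  if (ncol(scenario@betaP) != ncol(X))
    stop("scenario betaP has ", ncol(scenario@betaP),
         " columns but X has ", ncol(X))
  if (is.factor(dx)) dx <- as.numeric(dx) - 1
  if (length(dx) != nrow(X) || length(apoe4) != nrow(X))
    stop("dx/apoe4 length must match nrow(X)")
  set.seed(seed)
  n <- nrow(X)
  E <- MASS::mvrnorm(n, mu = rep(0, 3), Sigma = scenario@sigmaStar)
  Y <- outer(dx, scenario@betaDx) + outer(apoe4, scenario@betaApoe4) +
    X %*% t(scenario@betaP) + E
  colnames(Y) <- c("A", "M", "D")
  list(Y = Y, truth = scenario)
}
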