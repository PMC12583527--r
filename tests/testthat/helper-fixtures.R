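# shared fixtures: all generated in code, sized for fast tests

tinyCohort <- function(n = 80L, nClusters = 2L, ppc = 25L, seed = 11L) {
  generateCohort(cohortConfig(nSamples = n, nClusters = nClusters,
                              probesPerCluster = ppc, seed = seed))
}

# standardized design with columns mean 0, sample SD 1
stdDesign <- function(n, m, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m)
  X <- scale(X)
  X %*% diag(1 / apply(X, 2, sd), m)
}

# small penalized problem with a planted sparse signal
toyProblem <- function(n = 50L, m = 5L, q = 3L, seed = 7L, noiseSd = 0.5) {
  X <- stdDesign(n, m, seed)
  set.seed(seed + 1L)
  B <- matrix(0, m, q)
  B[1, 1] <- 0.5
  if (m >= 3 && q >= 2) B[3, 2] <- -0.4
  Y <- X %*% B + matrix(rnorm(n * q, sd = noiseSd), n, q)
  list(Y = Y, X = X, B = B)
}
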