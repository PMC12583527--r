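#' Filter probes by detection p-values
#'
#' A probe is removed if any of three rules fires: (i) its mean detection
#' p-value across samples exceeds `looseThreshold`; (ii) its detection
#' p-value exceeds `looseThreshold` in half or more of the samples;
#' (iii) its detection p-value is at or above `strictThreshold` in more
#' than `strictFraction` of the samples. Survivors are returned in input
#' order. The rules are order-independent (each is evaluated on the full
#' input matrix).
#'
#' @param detp probes x samples matrix of detection p-values in \[0, 1\].
#' @param looseThreshold,strictThreshold,strictFraction rule parameters.
#' @return list with `kept` (surviving probe ids, input order) and
#'   `removedBy` (named counts per rule, non-exclusive).
#' @export
filterProbesByDetection <- function(detp, looseThreshold = 0.05,
                                    strictThreshold = 0.01,
                                    strictFraction = 0.20) {
  if (!is.matrix(detp) || nrow(detp) == 0L || ncol(detp) == 0L)
    stop("detp must be a non-empty matrix")
  if (any(detp < 0) || any(detp > 1)) stop("detection p-values must lie in [0, 1]")
  n <- ncol(detp)
  ids <- rownames(detp)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(detp)))
  r1 <- rowMeans(detp) > looseThreshold
  r2 <- rowSums(detp > looseThreshold) >= n / 2
  r3 <- rowSums(detp >= strictThreshold) > strictFraction * n
  keep <- !(r1 | r2 | r3)
  list(kept = ids[keep],
       removedBy = c(mean_loose = sum(r1), half_loose = sum(r2),
                     frac_strict = sum(r3), total_removed = sum(!keep)))
}

#' Logit (M-value) transform of beta values
#'
#' Clips values into `[eps, 1 - eps]` and returns the natural-log
#' log-odds, elementwise and shape-preserving.
#'
#' @param beta matrix or vector of beta values in \[0, 1\].
#' @param eps boundary clip.
#' @return object of the same shape containing `log(b / (1 - b))`.
#' @export
logitTransform <- function(beta, eps = 1e-6) {
  if (any(beta < 0) || any(beta > 1)) stop("beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, eps), 1 - eps)
  out <- log(b / (1 - b))
  if (is.matrix(beta)) dimnames(out) <- dimnames(beta)
  out
}

# scale to mean 0, sample SD 1 (n - 1 denominator)
scaleVec <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("zero variance in input to scaling")
  (x - mean(x)) / s
}

#' Transform raw CSF biomarkers to A/M/D
#'
#' `A = scale(log A*)`, `M = (scale(log T*) + scale(log N*)) / 2`,
#' `D = scale(log N*) - scale(log T*)`, where `scale` centers and scales
#' to unit sample variance. M and D are uncorrelated in sample by
#' construction (both scaled logs have variance exactly 1).
#'
#' @param aRaw,tRaw,nRaw positive vectors of raw amyloid-beta 42,
#'   phosphorylated tau and total tau.
#' @return data.frame with columns `a`, `m`, `d`.
#' @export
transformBiomarkers <- function(aRaw, tRaw, nRaw) {
  if (length(aRaw) < 3L) stop("need at least 3 samples")
  if (any(aRaw <= 0) || any(tRaw <= 0) || any(nRaw <= 0))
    stop("raw biomarker values must be positive")
  sT <- scaleVec(log(tRaw))
  sN <- scaleVec(log(nRaw))
  data.frame(a = scaleVec(log(aRaw)), m = (sT + sN) / 2, d = sN - sT)
}

#' Principal components of cell-type proportions
#'
#' Centers the columns and returns the first `k` principal-component
#' scores with a deterministic sign convention (the largest-magnitude
#' loading of each component is positive), plus the cumulative fraction
#' of variance they explain.
#'
#' @param cellProps n x 7 matrix of proportions (rows sum to 1).
#' @param k number of components (default 3).
#' @return list with `scores` (n x k), `explainedFraction`, `loadings`.
#' @export
cellTypePCA <- function(cellProps, k = 3L) {
  cellProps <- as.matrix(cellProps)
  if (nrow(cellProps) <= k) stop("need more samples than components")
  if (any(abs(rowSums(cellProps) - 1) > 1e-6))
    stop("cell-type proportions must sum to 1 per sample")
  pc <- prcomp(cellProps, center = TRUE, scale. = FALSE)
  posVar <- sum(pc$sdev^2 > 1e-12 * pc$sdev[1]^2)
  if (k >= posVar + 1L || pc$sdev[1] < 1e-12)
    stop("k = ", k, " components requested but input has only ", posVar,
         " non-degenerate dimensions")
  flip <- apply(pc$rotation[, seq_len(k), drop = FALSE], 2, function(v)
    sign(v[which.max(abs(v))]))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, `*`)
  list(scores = scores,
       explainedFraction = sum(pc$sdev[seq_len(k)]^2) / sum(pc$sdev^2),
       loadings = loadings)
}
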