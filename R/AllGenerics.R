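#' @rdname SyntheticCohort-class
#' @param object,x a `SyntheticCohort` (or `PenalizedFit` where noted).
#' @export
setGeneric("methylation", function(x) standardGeneric("methylation"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("detectionP", function(x) standardGeneric("detectionP"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("biomarkers", function(x) standardGeneric("biomarkers"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("probePositions", function(x) standardGeneric("probePositions"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("geneAnnotation", function(x) standardGeneric("geneAnnotation"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname PenalizedFit-class
#' @export
setGeneric("probeEffects", function(x) standardGeneric("probeEffects"))

#' @rdname PenalizedFit-class
#' @export
setGeneric("precisionMatrix", function(x) standardGeneric("precisionMatrix"))

#' Beta-value matrix (probes x samples)
#' @rdname SyntheticCohort-class
#' @export
setMethod("methylation", "SyntheticCohort", function(x)
  SummarizedExperiment::assay(x@se, "beta"))

#' @rdname SyntheticCohort-class
#' @export
setMethod("detectionP", "SyntheticCohort", function(x)
  SummarizedExperiment::assay(x@se, "detp"))

#' Covariate table (one row per sample)
#' @rdname SyntheticCohort-class
#' @export
setMethod("covariates", "SyntheticCohort", function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x@se))
  keep <- c("sample_id", "yoe", "age", "eaa", "sex",
            grep("^cell_", colnames(cd), value = TRUE),
            "pc1", "pc2", "pc3", "dx", "apoe4")
  cd[, keep]
})

#' Raw and transformed biomarker table
#' @rdname SyntheticCohort-class
#' @export
setMethod("biomarkers", "SyntheticCohort", function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x@se))
  cd[, c("sample_id", "a_raw", "t_raw", "n_raw", "a", "m", "d")]
})

#' Probe positions as GRanges (single-base), with cluster membership
#' @rdname SyntheticCohort-class
#' @export
setMethod("probePositions", "SyntheticCohort", function(x)
  SummarizedExperiment::rowRanges(x@se))

#' @rdname SyntheticCohort-class
#' @export
setMethod("geneAnnotation", "SyntheticCohort", function(x) x@genes)

#' Generator truth: configuration and per-probe cluster assignment
#' @rdname SyntheticCohort-class
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)

setMethod("show", "SyntheticCohort", function(object) {
  se <- object@se
  cat("SyntheticCohort:", nrow(se), "probes x", ncol(se), "samples\n")
  cat("  clusters:", length(unique(object@truth$cluster)),
      " genes:", length(object@genes), "\n")
  dx <- table(SummarizedExperiment::colData(se)$dx)
  cat("  diagnosis:", paste(names(dx), dx, sep = "=", collapse = " "), "\n")
})

#' Penalized probe coefficients (responses x probes)
#' @rdname PenalizedFit-class
#' @export
setMethod("probeEffects", "PenalizedFit", function(x) x@Gamma3)

#' Estimated residual precision matrix
#' @rdname PenalizedFit-class
#' @export
setMethod("precisionMatrix", "PenalizedFit", function(x) x@Theta)

setMethod("show", "PenalizedFit", function(object) {
  cat("PenalizedFit: q =", nrow(object@Gamma3), ", m =", ncol(object@Gamma3), "\n")
  cat(sprintf("  lambda = %.5g, rho = %.5g, objective = %.6g\n",
              object@lambda, object@rho, object@objective))
  cat("  nonzero probe effects:", sum(object@Gamma3 != 0),
      "| outer iterations:", object@nIter,
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  if (is.finite(object@bic)) cat(sprintf("  BIC = %.4f\n", object@bic))
  if (is.finite(object@cvError)) cat(sprintf("  CV error = %.4f\n", object@cvError))
})

setMethod("show", "BaconFit", function(object) {
  cat(sprintf("BaconFit: bias = %.4f, inflation = %.4f (%s, %d EM iterations)\n",
              object@bias, object@inflation,
              if (object@converged) "converged" else "not converged", object@nIter))
  cat("  weights:", sprintf("%.3f", object@weights), "\n")
})

setMethod("show", "ScenarioSpec", function(object) {
  cat("ScenarioSpec:", object@name, "| m =", ncol(object@betaP),
      "| signals =", sum(object@betaP != 0),
      "| effect =", object@effectSize, "\n")
})
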