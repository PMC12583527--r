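#' Run the full analysis pipeline on files
#'
#' Executes the stages in order — detection-p QC, logit transform,
#' cell-type PCA, biomarker transform, stage-1 residualization, the
#' univariate EWAS with mixture correction, gene-cluster construction,
#' the tuned penalized multivariate fit per cluster, and the ranked
#' probe-selection table — reading plain-text inputs and writing every
#' stage's output plus a JSON run manifest, so stages can be re-run
#' individually from intermediate files.
#'
#' @param config named list or path to a YAML file with entries:
#'   `beta`, `detp`, `covariates`, `biomarkers`, `genes`, `probes` (input
#'   paths), `out` (output directory), and optionally `flank` (100000),
#'   `maxClusterSize` (300), `criterion` ("bic" or "cv"), `nLambda` (20),
#'   `nRho` (10), `seed` (1), `qcLoose` (0.05), `qcStrict` (0.01),
#'   `qcFraction` (0.2).
#' @return the manifest list, invisibly; all outputs are written under
#'   `config$out`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(flank = 100000L, maxClusterSize = 300L, criterion = "bic",
                   nLambda = 20L, nRho = 10L, seed = 1L,
                   qcLoose = 0.05, qcStrict = 0.01, qcFraction = 0.2)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  needed <- c("beta", "detp", "covariates", "biomarkers", "genes", "probes", "out")
  miss <- setdiff(needed, names(config))
  if (length(miss)) stop("pipeline config missing entries: ",
                         paste(miss, collapse = ", "))
  inputs <- config[c("beta", "detp", "covariates", "biomarkers",
                     "genes", "probes")]
  absent <- names(inputs)[!vapply(unlist(inputs), file.exists, logical(1))]
  if (length(absent))
    stop("missing input file(s) for: ", paste(absent, collapse = ", "))
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config, stages = list())

  ## QC ------------------------------------------------------------------
  beta <- readMatrixTSV(config$beta)
  detp <- readMatrixTSV(config$detp)
  qc <- filterProbesByDetection(detp, config$qcLoose, config$qcStrict,
                                config$qcFraction)
  beta <- beta[qc$kept, , drop = FALSE]
  jsonlite::write_json(as.list(qc$removedBy), file.path(out, "qc_report.json"),
                       auto_unbox = TRUE)
  manifest$stages$qc <- list(kept = length(qc$kept),
                             removed = unname(qc$removedBy["total_removed"]))

  ## transforms ----------------------------------------------------------
  covTab <- readTableCSV(config$covariates)
  bio <- readTableCSV(config$biomarkers)
  cellCols <- grep("^cell_", colnames(covTab), value = TRUE)
  if (length(cellCols) && !all(c("pc1", "pc2", "pc3") %in% colnames(covTab))) {
    pca <- cellTypePCA(as.matrix(covTab[, cellCols]), k = 3L)
    covTab$pc1 <- pca$scores[, 1]; covTab$pc2 <- pca$scores[, 2]
    covTab$pc3 <- pca$scores[, 3]
  }
  if (!all(c("a", "m", "d") %in% colnames(bio))) {
    amd <- transformBiomarkers(bio$a_raw, bio$t_raw, bio$n_raw)
    bio <- cbind(bio, amd)
  }
  writeTableCSV(bio, file.path(out, "biomarkers_amd.csv"))

  mv <- logitTransform(beta)
  st1 <- residualize(mv, covTab)
  X <- st1$residuals
  writeMatrixTSV(t(X), file.path(out, "residuals.tsv"))
  manifest$stages$stage1 <- list(probes = ncol(X), dropped = length(st1$dropped))

  ## EWAS ----------------------------------------------------------------
  Y <- as.matrix(bio[, c("a", "m", "d")])
  colnames(Y) <- c("A", "M", "D")
  dx <- covTab$dx
  apoe4 <- covTab$apoe4
  ewasTabs <- list()
  lambdaGC <- c()
  for (k in 1:3) {
    tab <- ewasScan(Y[, k], X, dx, apoe4, phenotype = colnames(Y)[k])
    zOK <- tab$z[!tab$skipped]
    lamBefore <- inflationFactor(zOK)
    bc <- tryCatch(suppressWarnings(baconCorrect(zOK)), error = function(e) NULL)
    if (!is.null(bc)) {
      tab$z_adj <- NA_real_; tab$p_adj <- NA_real_
      tab$z_adj[!tab$skipped] <- bc$zAdj
      tab$p_adj[!tab$skipped] <- bc$pAdj
      lamAfter <- inflationFactor(bc$zAdj)
    } else {
      tab$z_adj <- tab$z; tab$p_adj <- tab$p
      lamAfter <- lamBefore
    }
    tab$significance <- callSignificance(tab$p_adj)
    ewasTabs[[k]] <- tab
    lambdaGC <- rbind(lambdaGC,
                      data.frame(phenotype = colnames(Y)[k],
                                 lambda_before = lamBefore,
                                 lambda_after = lamAfter))
  }
  ewasAll <- do.call(rbind, ewasTabs)
  writeTableCSV(ewasAll, file.path(out, "ewas.csv"))
  jsonlite::write_json(lambdaGC, file.path(out, "ewas_inflation.json"),
                       digits = NA)
  manifest$stages$ewas <- list(
    tests = nrow(ewasAll),
    genome_wide = sum(ewasAll$significance == "genome_wide", na.rm = TRUE),
    suggestive = sum(ewasAll$significance == "suggestive", na.rm = TRUE))

  ## clusters ------------------------------------------------------------
  genesBed <- readBed(config$genes)
  probesBed <- readBed(config$probes)
  genes <- data.frame(gene_id = genesBed$name, chrom = genesBed$chrom,
                      start = genesBed$start, end = genesBed$end)
  probes <- data.frame(probe_id = probesBed$name, chrom = probesBed$chrom,
                       pos = probesBed$start)
  probes <- probes[probes$probe_id %in% colnames(X), , drop = FALSE]
  clusters <- buildGeneClusters(genes, probes, flank = config$flank,
                                maxSize = config$maxClusterSize)
  data.table::fwrite(clusters, file.path(out, "clusters.tsv"), sep = "\t")
  manifest$stages$clusters <- list(
    nClusters = length(unique(clusters$cluster_id)),
    coverage = clusterSummary(clusters, colnames(X))$coverage)

  ## multivariate fits ---------------------------------------------------
  Wfit <- covariateBlock(dx, apoe4, nrow(X))
  fits <- list()
  fitRecords <- list()
  for (cl in unique(clusters$cluster_id)) {
    ids <- clusters$probe_id[clusters$cluster_id == cl]
    Xc <- X[, intersect(ids, colnames(X)), drop = FALSE]
    if (ncol(Xc) < 1L) next
    fit <- tuneFit(Y, Xc, Wfit, criterion = config$criterion,
                   nLambda = config$nLambda, nRho = config$nRho,
                   seed = config$seed)
    fits[[cl]] <- fit
    fitRecords[[cl]] <- list(lambda = fit@lambda, rho = fit@rho,
                             bic = fit@bic, nonzero = sum(fit@Gamma3 != 0))
  }
  jsonlite::write_json(fitRecords, file.path(out, "cluster_fits.json"),
                       auto_unbox = TRUE, digits = NA)

  selection <- selectProbes(fits)
  data.table::fwrite(selection, file.path(out, "selection.tsv"), sep = "\t")
  manifest$stages$multivar <- list(clusters_fit = length(fits),
                                   probes_selected = nrow(selection))

  manifest$seed <- config$seed
  manifest$packageVersion <-
    as.character(utils::packageVersion("methylAMD"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
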