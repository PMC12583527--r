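#' @importFrom data.table fread fwrite
#' @importFrom jsonlite write_json read_json
NULL

# numeric fields are serialized with full precision (>= 15 significant
# digits) so every stage output round-trips exactly through files

#' Write a probes-x-samples matrix as TSV (first column probe_id)
#' @param m matrix with probe rownames and sample colnames.
#' @param path output file.
#' @export
writeMatrixTSV <- function(m, path) {
  dt <- data.table::data.table(probe_id = rownames(m))
  for (j in seq_len(ncol(m))) dt[[colnames(m)[j]]] <- fullPrec(m[, j])
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
}

# 17 significant digits: doubles round-trip exactly through text
fullPrec <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

#' Read a probes-x-samples TSV written by [writeMatrixTSV()]
#' @param path input file.
#' @return numeric matrix with probe rownames.
#' @export
readMatrixTSV <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' Write a data.frame as CSV at full numeric precision
#' @param df data.frame.
#' @param path output file.
#' @export
writeTableCSV <- function(df, path) {
  df <- as.data.frame(lapply(df, fullPrec), check.names = FALSE,
                      stringsAsFactors = FALSE)
  data.table::fwrite(df, path, quote = FALSE)
}

#' Read a CSV written by [writeTableCSV()]
#' @param path input file.
#' @return data.frame.
#' @export
readTableCSV <- function(path) as.data.frame(data.table::fread(path))

#' Write a BED file (0-based half-open) from a ranges table
#' @param df data.frame with `chrom`, `start`, `end`, `name`.
#' @param path output file.
#' @export
writeBed <- function(df, path) {
  data.table::fwrite(df[, c("chrom", "start", "end", "name")], path,
                     sep = "\t", col.names = FALSE)
}

#' Read a BED file (first four columns) into a ranges table
#' @param path input file.
#' @return data.frame with `chrom`, `start`, `end`, `name`.
#' @export
readBed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  df <- as.data.frame(dt[, 1:4])
  colnames(df) <- c("chrom", "start", "end", "name")
  df
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits `beta.tsv`, `detp.tsv` (probes x samples), `covariates.csv`,
#' `biomarkers.csv`, `probes.bed`, `genes.bed` (0-based half-open,
#' single-base probe intervals) and `truth.json`.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeMatrixTSV(methylation(cohort), file.path(dir, "beta.tsv"))
  writeMatrixTSV(detectionP(cohort), file.path(dir, "detp.tsv"))
  writeTableCSV(covariates(cohort), file.path(dir, "covariates.csv"))
  writeTableCSV(biomarkers(cohort), file.path(dir, "biomarkers.csv"))
  rr <- probePositions(cohort)
  writeBed(data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                      start = GenomicRanges::start(rr) - 1L,
                      end = GenomicRanges::start(rr),
                      name = rr$probe_id),
           file.path(dir, "probes.bed"))
  g <- geneAnnotation(cohort)
  writeBed(data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                      start = GenomicRanges::start(g) - 1L,
                      end = GenomicRanges::end(g),
                      name = g$gene_id),
           file.path(dir, "genes.bed"))
  tr <- cohortTruth(cohort)
  cfg <- tr$config
  jsonlite::write_json(
    list(seed = cfg@seed, nSamples = cfg@nSamples, nClusters = cfg@nClusters,
         probesPerCluster = cfg@probesPerCluster,
         blockCorrelation = cfg@blockCorrelation,
         corrTN = cfg@corrTN, corrAT = cfg@corrAT,
         cluster = tr$cluster),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
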