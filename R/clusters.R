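#' Build gene-anchored probe clusters
#'
#' A probe belongs to the cluster of gene g when it lies on the same
#' chromosome and its position falls in the window
#' `[start(g) - flank, end(g) + flank)` in 0-based half-open coordinates
#' (closed left, open right). Probes may belong to several clusters;
#' genes whose window contains no probe yield no cluster. Oversized
#' clusters are split into balanced consecutive parts of at most
#' `maxSize` probes via [splitCluster()].
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), or a [GenomicRanges::GRanges] with a `gene_id`
#'   column (1-based, as usual for GRanges).
#' @param probes data.frame with `probe_id`, `chrom`, `pos` (0-based
#'   single-base), or a GRanges with a `probe_id` column.
#' @param flank window extension in bp on each side (default 100 kb).
#' @param maxSize maximum cluster size after splitting (default 300).
#' @return data.frame with `cluster_id`, `gene_id`, `part`, `probe_id`,
#'   `chrom`, `pos` (0-based), members ordered by position within
#'   cluster.
#' @export
buildGeneClusters <- function(genes, probes, flank = 100000L, maxSize = 300L) {
  gr <- asGeneRanges(genes)
  pr <- asProbeRanges(probes)
  known <- GenomicRanges::seqnames(gr)
  badChr <- setdiff(as.character(unique(GenomicRanges::seqnames(pr))),
                    as.character(unique(known)))
  if (length(badChr))
    stop("probes on chromosomes absent from the gene annotation: ",
         paste(badChr, collapse = ", "))
  win <- suppressWarnings(GenomicRanges::resize(
    gr, width = GenomicRanges::width(gr) + 2L * flank, fix = "center"))
  win <- GenomicRanges::trim(win)
  hits <- GenomicRanges::findOverlaps(win, pr)
  if (!length(hits)) return(emptyClusterTable())
  gi <- S4Vectors::queryHits(hits)
  pi <- S4Vectors::subjectHits(hits)
  out <- data.frame(
    gene_id = gr$gene_id[gi],
    probe_id = pr$probe_id[pi],
    chrom = as.character(GenomicRanges::seqnames(pr))[pi],
    pos = GenomicRanges::start(pr)[pi] - 1L,   # back to 0-based
    stringsAsFactors = FALSE)
  out <- out[order(match(out$gene_id, gr$gene_id), out$pos, out$probe_id), ]
  pieces <- lapply(split(out, out$gene_id, drop = TRUE), splitCluster,
                   maxSize = maxSize)
  out <- do.call(rbind, pieces)
  out <- out[order(match(out$gene_id, gr$gene_id), out$pos), ]
  rownames(out) <- NULL
  out[, c("cluster_id", "gene_id", "part", "probe_id", "chrom", "pos")]
}

#' Split an oversized cluster into balanced consecutive parts
#'
#' Clusters of at most `maxSize` probes are returned unchanged (one part).
#' Larger clusters are partitioned into `k = ceiling(size / maxSize)`
#' consecutive runs in genomic order with sizes as equal as possible
#' (differing by at most 1, larger parts first). Part ids are
#' `gene#1 .. gene#k` in genomic order; an unsplit cluster keeps the bare
#' gene id.
#'
#' @param members data.frame with `gene_id`, `probe_id`, `chrom`, `pos`,
#'   ordered by position.
#' @param maxSize maximum part size.
#' @return the input with `cluster_id` and `part` columns added.
#' @export
splitCluster <- function(members, maxSize = 300L) {
  sz <- nrow(members)
  members <- members[order(members$pos, members$probe_id), , drop = FALSE]
  if (sz <= maxSize) {
    members$cluster_id <- members$gene_id
    members$part <- 1L
    return(members)
  }
  k <- ceiling(sz / maxSize)
  base <- sz %/% k
  extra <- sz %% k
  sizes <- c(rep(base + 1L, extra), rep(base, k - extra))
  part <- rep(seq_len(k), times = sizes)
  members$part <- part
  members$cluster_id <- paste0(members$gene_id, "#", part)
  members
}

asGeneRanges <- function(genes) {
  if (is(genes, "GRanges")) {
    if (is.null(genes$gene_id)) stop("gene GRanges needs a gene_id column")
    return(genes)
  }
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% colnames(genes)))
    stop("gene table needs columns: ", paste(need, collapse = ", "))
  if (any(genes$start >= genes$end)) stop("gene start must be < end")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start + 1L, genes$end),
                         gene_id = genes$gene_id)
}

asProbeRanges <- function(probes) {
  if (is(probes, "GRanges")) {
    if (is.null(probes$probe_id)) stop("probe GRanges needs a probe_id column")
    return(probes)
  }
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% colnames(probes)))
    stop("probe table needs columns: ", paste(need, collapse = ", "))
  GenomicRanges::GRanges(probes$chrom,
                         IRanges::IRanges(probes$pos + 1L, width = 1L),
                         probe_id = probes$probe_id)
}

emptyClusterTable <- function() {
  data.frame(cluster_id = character(), gene_id = character(),
             part = integer(), probe_id = character(),
             chrom = character(), pos = integer())
}

#' Summarize cluster sizes and probe coverage
#'
#' @param clusterTable output of [buildGeneClusters()].
#' @param allProbeIds optional vector of all probe ids, to report the
#'   fraction covered by at least one cluster.
#' @return list with `nClusters`, `sizeSummary`, and `coverage`.
#' @export
clusterSummary <- function(clusterTable, allProbeIds = NULL) {
  sizes <- table(clusterTable$cluster_id)
  cov <- if (is.null(allProbeIds)) NA_real_ else
    mean(allProbeIds %in% clusterTable$probe_id)
  list(nClusters = length(sizes),
       sizeSummary = summary(as.integer(sizes)),
       coverage = cov)
}
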