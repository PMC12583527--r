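test_that("window boundaries are closed-left open-right around the flank", {
  genes <- data.frame(gene_id = "G1", chrom = "chr1",
                      start = 200000L, end = 210000L)
  probes <- data.frame(probe_id = c("pL", "pLout", "pIn", "pR", "pRout"),
                       chrom = "chr1",
                       pos = c(100000L, 99999L, 205000L, 309999L, 310000L))
  tab <- buildGeneClusters(genes, probes, flank = 100000L)
  expect_setequal(tab$probe_id, c("pL", "pIn", "pR"))
  expect_true(all(tab$cluster_id == "G1"))
  expect_equal(tab$probe_id, tab$probe_id[order(tab$pos)])
})

test_that("a probe inside two overlapping windows joins both clusters", {
  genes <- data.frame(gene_id = c("G1", "G2"), chrom = "chr1",
                      start = c(100000L, 150000L), end = c(120000L, 170000L))
  probes <- data.frame(probe_id = "shared", chrom = "chr1", pos = 130000L)
  tab <- buildGeneClusters(genes, probes, flank = 100000L)
  expect_setequal(tab$cluster_id, c("G1", "G2"))
  expect_equal(nrow(tab), 2L)

  badProbes <- data.frame(probe_id = "x", chrom = "chrUn", pos = 5L)
  expect_error(buildGeneClusters(genes, badProbes), "chrUn")
})

test_that("oversized clusters split into balanced consecutive parts", {
  mk <- function(sz) data.frame(gene_id = "G", probe_id = sprintf("p%04d", 1:sz),
                                chrom = "chr1", pos = seq_len(sz) * 10L)
  s120 <- splitCluster(mk(120L), maxSize = 300L)
  expect_true(all(s120$cluster_id == "G"))

  s750 <- splitCluster(mk(750L), maxSize = 300L)
  expect_equal(unname(table(s750$cluster_id)[c("G#1", "G#2", "G#3")]),
               c(250L, 250L, 250L), ignore_attr = TRUE)

  s301 <- splitCluster(mk(301L), maxSize = 300L)
  expect_equal(unname(table(s301$cluster_id)[c("G#1", "G#2")]), c(151L, 150L),
               ignore_attr = TRUE)

  # partition invariants: parts disjoint, union equals parent, order kept
  expect_setequal(s750$probe_id, mk(750L)$probe_id)
  expect_equal(anyDuplicated(s750$probe_id), 0L)
  expect_equal(s750$pos, sort(s750$pos))
  expect_true(all(diff(s750$part) >= 0))            # consecutive runs
  parts <- split(s750$pos, s750$part)
  expect_true(all(sapply(seq_len(2), function(i)
    max(parts[[i]]) < min(parts[[i + 1]]))))        # non-overlapping
})

test_that("cluster coverage counts probes in at least one window", {
  ch <- tinyCohort(n = 20L, nClusters = 2L, ppc = 15L, seed = 44L)
  g <- geneAnnotation(ch)
  rr <- probePositions(ch)
  genes <- data.frame(gene_id = g$gene_id,
                      chrom = as.character(GenomicRanges::seqnames(g)),
                      start = GenomicRanges::start(g) - 1L,
                      end = GenomicRanges::end(g))
  probes <- data.frame(probe_id = rr$probe_id,
                       chrom = as.character(GenomicRanges::seqnames(rr)),
                       pos = GenomicRanges::start(rr) - 1L)
  tab <- buildGeneClusters(genes, probes)
  # generator places every probe within its gene's +/- 100 kb window
  expect_equal(clusterSummary(tab, probes$probe_id)$coverage, 1)
  expect_equal(clusterSummary(tab)$nClusters, 2L)
})
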