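# Panel with sites at hand-picked positions; one + strand and one - strand
# gene with exons/UTRs built explicitly.
regionFixture <- function() {
  sites <- data.frame(
    chrom = "chr1",
    pos = c(4500,   # 500 bp upstream of the + gene TSS (5000): promoter
            5050,   # inside 5' UTR of + gene
            5500,   # inside first exon, past the UTR: CDS
            6500,   # between exons: intron
            8200,   # 200 bp past + gene end (8000): downstream
            15500,  # 500 bp below the - gene start (16000): downstream
            17000,  # inside - gene exon: CDS
            20500,  # 500 bp beyond the end (20000) of the - gene: promoter
            30000), # far from everything: intergenic
    ref = "A", alt = "T")
  n <- 4L
  H <- matrix(rep(c(0L, 1L), each = n, times = nrow(sites)), nrow = 2 * n)
  panel <- PhasedPanel(sprintf("s%d", 1:n), rep("pop", n), sites, H,
                       c(chr1 = 50000))
  genesDf <- data.frame(
    gene_id = c("plus_gene", "minus_gene"), chrom = "chr1",
    start = c(5000L, 16000L), end = c(8000L, 20000L),
    strand = c("+", "-"))
  exonsDf <- data.frame(
    gene_id = c("plus_gene", "plus_gene", "minus_gene"),
    chrom = "chr1",
    start = c(5000L, 7000L, 16500L), end = c(6000L, 8000L, 18000L))
  utr5Df <- data.frame(gene_id = "plus_gene", chrom = "chr1",
                       start = 5000L, end = 5100L)
  genes <- DomestiScan:::.makeGeneModels(genesDf, exonsDf, NULL, utr5Df)
  list(panel = panel, genes = genes)
}

test_that("site region labels follow strand-aware promoter/downstream
           arithmetic with genic precedence", {
  fx <- regionFixture()
  lab <- assignSiteRegions(fx$panel, fx$genes, promoterBp = 2000,
                           downstreamBp = 2000)
  get <- function(pos) lab[lab$pos == pos, ]
  expect_equal(get(4500)$label, "promoter")
  expect_equal(get(4500)$gene_id, "plus_gene")
  expect_equal(get(5050)$label, "genic")
  expect_equal(get(5050)$sublabel, "UTR")
  expect_equal(get(5500)$sublabel, "CDS")
  expect_equal(get(6500)$sublabel, "intron")
  expect_equal(get(8200)$label, "downstream")
  # minus-strand gene: upstream is the high-coordinate side
  expect_equal(get(20500)$label, "promoter")
  expect_equal(get(20500)$gene_id, "minus_gene")
  expect_equal(get(15500)$label, "downstream")
  expect_equal(get(17000)$label, "genic")
  expect_equal(get(17000)$sublabel, "CDS")
  expect_equal(get(30000)$label, "intergenic")
  expect_true(is.na(get(30000)$gene_id))
  # deterministic relabelling
  expect_identical(lab, assignSiteRegions(fx$panel, fx$genes, 2000, 2000))
})

test_that("genic status beats a neighbouring gene's promoter and ties go
           to the nearest TSS", {
  sites <- data.frame(chrom = "chr1", pos = c(1500, 2950),
                      ref = "A", alt = "T")
  H <- matrix(c(0L, 1L), nrow = 2, ncol = 2)
  panel <- PhasedPanel("s1", "pop", sites, H, c(chr1 = 10000))
  genesDf <- data.frame(
    gene_id = c("left", "right"), chrom = "chr1",
    start = c(1000L, 3000L), end = c(2000L, 4000L),
    strand = c("+", "+"))
  genes <- DomestiScan:::.makeGeneModels(
    genesDf, data.frame(gene_id = c("left", "right"), chrom = "chr1",
                        start = c(1000L, 3000L), end = c(2000L, 4000L)))
  lab <- assignSiteRegions(panel, genes, promoterBp = 2000,
                           downstreamBp = 500)
  # 1500 is genic in `left` and in the promoter of `right`: genic wins
  expect_equal(lab$label[lab$pos == 1500], "genic")
  expect_equal(lab$gene_id[lab$pos == 1500], "left")
  # 2950 is in `right`'s promoter only (left's downstream is 2001-2500)
  expect_equal(lab$label[lab$pos == 2950], "promoter")
  expect_equal(lab$gene_id[lab$pos == 2950], "right")
})

test_that("segregating-site counts partition by region and subpopulation", {
  sites <- data.frame(chrom = "chr1", pos = c(1100, 1200, 5000),
                      ref = "A", alt = "T")
  # pop1: site1 segregating, site2 monomorphic-ref, site3 segregating
  # pop2: site1 monomorphic-alt, site2 segregating, site3 monomorphic
  H <- rbind(
    c(0L, 0L, 0L), c(1L, 0L, 1L),   # pop1 sample a
    c(0L, 0L, 0L), c(1L, 0L, 0L),   # pop1 sample b
    c(1L, 0L, 0L), c(1L, 1L, 0L),   # pop2 sample c
    c(1L, 0L, 0L), c(1L, 1L, 0L))   # pop2 sample d
  panel <- PhasedPanel(c("a", "b", "c", "d"),
                       rep(c("pop1", "pop2"), each = 2),
                       sites, H, c(chr1 = 10000))
  genesDf <- data.frame(gene_id = "g1", chrom = "chr1",
                        start = 1000L, end = 2000L, strand = "+")
  genes <- DomestiScan:::.makeGeneModels(
    genesDf, data.frame(gene_id = "g1", chrom = "chr1",
                        start = 1000L, end = 2000L))
  lab <- assignSiteRegions(panel, genes, 500, 500)
  cnt <- snpRegionCounts(lab, panel)
  pick <- function(p, l) cnt$n_sites[cnt$subpop == p & cnt$label == l]
  expect_equal(pick("pop1", "genic"), 1L)
  expect_equal(pick("pop1", "intergenic"), 1L)
  expect_equal(pick("pop2", "genic"), 1L)
  expect_equal(pick("pop2", "intergenic"), 0L)
  # totals equal segregating sites per subpopulation
  expect_equal(sum(cnt$n_sites[cnt$subpop == "pop1"]), 2L)
  expect_equal(sum(cnt$n_sites[cnt$subpop == "pop2"]), 1L)
})

test_that("gene-structure summaries contrast the two classes and flag a
           shorter focal class", {
  set.seed(6)
  nTf <- 12L; nOther <- 12L
  mkDf <- function(prefix, n, len, off) {
    start <- off + (seq_len(n) - 1L) * 10000L
    data.frame(gene_id = sprintf("%s%02d", prefix, seq_len(n)),
               chrom = "chr1", start = start, end = start + len - 1L,
               strand = "+")
  }
  tfDf <- mkDf("tf", nTf, 1000L, 1L)
  otDf <- mkDf("ot", nOther, 4000L, 500000L)
  genesDf <- rbind(tfDf, otDf)
  exonsDf <- genesDf[, c("gene_id", "chrom", "start", "end")]
  genes <- DomestiScan:::.makeGeneModels(genesDf, exonsDf)
  s <- geneStructureSummary(genes, tfIds = tfDf$gene_id)
  tl <- s[s$metric == "transcript_length", ]
  expect_lt(tl$median_tf, tl$median_other)
  expect_lt(tl$p, 0.01)
  cd <- s[s$metric == "cdna_length", ]
  expect_equal(cd$median_tf, 1000)   # single-exon genes: cDNA = span
  # identical classes have equal medians
  genes2 <- DomestiScan:::.makeGeneModels(
    rbind(tfDf, within(tfDf, gene_id <- sub("tf", "xx", gene_id))),
    rbind(tfDf[, c("gene_id", "chrom", "start", "end")],
          within(tfDf[, c("gene_id", "chrom", "start", "end")],
                 gene_id <- sub("tf", "xx", gene_id))))
  s2 <- geneStructureSummary(genes2, tfIds = tfDf$gene_id)
  expect_equal(s2$median_tf, s2$median_other)
  expect_error(geneStructureSummary(genes, tfIds = genesDf$gene_id),
               "non-empty")
})
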