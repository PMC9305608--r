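test_that("homozygous-reference samples give an all-reference diplotype
           string", {
  sites <- urartuSites()
  panel <- panelFromDiplotypes("CCAACCAA", list(pop = 1L), sites)
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(900, 4100))
  names(g) <- "g1"
  cat1 <- buildGeneHaplotypes(panel, g, flankBp = 2000)
  expect_equal(unname(cat1@diplotypes), "CCAACCAA")
  expect_equal(nchar(cat1@diplotypes[[1]]), 2L * nrow(sites))
})

test_that("a four-class 29-sample catalog reproduces published-style
           subgroup percentages", {
  cls <- c("CCAACCAA", "TTGGCCAA", "TTGGTTAA", "CTAGCTAA")
  panel <- panelFromDiplotypes(cls, list(urartu = c(24L, 3L, 1L, 1L)),
                               urartuSites())
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500, 4500))
  names(g) <- "NAC_gene"
  cat1 <- buildGeneHaplotypes(panel, g)
  fr <- haplotypeFrequencies(cat1)
  expect_equal(length(unique(fr$haplotype)), 4L)
  expect_equal(fr$pct, c(82.76, 10.34, 3.45, 3.45))
  expect_equal(fr$haplotype[1], "CCAACCAA")
  mj <- majorHaplotypes(fr)
  expect_equal(mj$haplotype, "CCAACCAA")
})

test_that("frequencies are per-sample fractions of the subpopulation", {
  panel <- panelFromDiplotypes("CCAA", list(solo = 1L), emmerSites())
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 3000))
  names(g) <- "g1"
  fr <- haplotypeFrequencies(buildGeneHaplotypes(panel, g))
  expect_equal(fr$pct, 100)
  expect_equal(fr$count, 1L)
})

test_that("the 28-sample wild-emmer catalog gives 75.00/21.43/3.57", {
  cls <- c("CCGG", "CCAA", "CCAG")
  panel <- panelFromDiplotypes(cls, list(wild_emmer = c(21L, 6L, 1L)),
                               emmerSites())
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 3000))
  names(g) <- "bZIP_gene"
  fr <- haplotypeFrequencies(buildGeneHaplotypes(panel, g))
  expect_equal(fr$pct, c(75.00, 21.43, 3.57))
  expect_equal(fr$haplotype[1], "CCGG")
})

test_that("major haplotype requires a strict majority and is unique", {
  ft <- data.frame(gene_id = "g", subpop = "p",
                   haplotype = c("A", "B"), count = c(5L, 5L),
                   frequency = c(0.5, 0.5), pct = c(50, 50))
  expect_true(is.na(majorHaplotypes(ft)$haplotype))
  ft$frequency <- c(0.51, 0.49)
  expect_equal(majorHaplotypes(ft)$haplotype, "A")
})

test_that("major-haplotype replacement is detected at the expected
           lineage step", {
  cls <- c("CCGG", "CCAA", "CCAG")
  counts <- list(wild_emmer = c(21L, 6L, 1L),
                 domesticated_emmer = c(3L, 26L, 0L),
                 durum = c(1L, 12L, 0L),
                 landrace = c(1L, 44L, 0L),
                 cultivar = c(0L, 25L, 0L))
  panel <- panelFromDiplotypes(cls, counts, emmerSites())
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 3000))
  names(g) <- "bZIP_gene"
  fr <- haplotypeFrequencies(buildGeneHaplotypes(panel, g))
  mj <- majorHaplotypes(fr)
  series <- c("wild_emmer", "domesticated_emmer", "durum",
              "landrace", "cultivar")
  expect_equal(mj$haplotype[match(series, mj$subpop)],
               c("CCGG", "CCAA", "CCAA", "CCAA", "CCAA"))
  expect_equal(roundHalfUp(100 * mj$frequency[
    mj$subpop == "domesticated_emmer"]), 89.66)
  sh <- trackMajorShifts(mj, series)
  expect_equal(nrow(sh$events), 1L)
  expect_equal(sh$events$from_lineage, "wild_emmer")
  expect_equal(sh$events$to_lineage, "domesticated_emmer")
  expect_equal(sh$events$from_hap, "CCGG")
  expect_equal(sh$events$to_hap, "CCAA")
})

test_that("a constant major yields no events; a gene with no major is
           counted in totals but not shifts", {
  mj <- rbind(
    data.frame(gene_id = "stable", subpop = c("a", "b", "c"),
               haplotype = "AA", frequency = 0.9),
    data.frame(gene_id = "nomajor", subpop = c("a", "b", "c"),
               haplotype = NA_character_, frequency = NA_real_))
  sh <- trackMajorShifts(mj, c("a", "b", "c"))
  expect_equal(nrow(sh$events), 0L)
  expect_equal(sh$summary$n_genes, 2L)
  expect_equal(sh$summary$n_with_major, 1L)
  expect_equal(sh$summary$n_with_shift, 0L)
  expect_error(trackMajorShifts(mj, c("a", "z")), "unknown lineage")
})

test_that("frequencies sum to one per subpopulation and are invariant to
           sample order", {
  cls <- c("CCGG", "CCAA", "CCAG")
  panel <- panelFromDiplotypes(cls, list(p1 = c(4L, 3L, 2L),
                                         p2 = c(1L, 5L, 0L)),
                               emmerSites())
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 3000))
  names(g) <- "g1"
  fr <- haplotypeFrequencies(buildGeneHaplotypes(panel, g))
  sums <- tapply(fr$frequency, fr$subpop, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # permute samples
  set.seed(9)
  perm <- sample(nSamples(panel))
  panel2 <- selectSamples(panel, samples = sampleIds(panel)[perm])
  fr2 <- haplotypeFrequencies(buildGeneHaplotypes(panel2, g))
  expect_equal(fr2, fr)
})

test_that("genes with no SNP in the flanked span are excluded from the
           catalog set", {
  panel <- panelFromDiplotypes("CCAA", list(p = 2L), emmerSites())
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50000, 60000))
  names(far) <- "far_gene"
  expect_null(buildGeneHaplotypes(panel, far, flankBp = 2000))
})
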