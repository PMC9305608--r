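cl1 <- c(chr1 = 50000)

test_that("the ancestral generator is deterministic and handles the
           empty-site case", {
  p0 <- simulateAncestralPanel(4, 0, cl1, seed = 1)
  expect_equal(nSites(p0), 0L)
  a <- simulateAncestralPanel(6, 100, cl1, seed = 9)
  b <- simulateAncestralPanel(6, 100, cl1, seed = 9)
  expect_identical(siteTable(a), siteTable(b))
  expect_identical(hapMatrix(a), hapMatrix(b))
  expect_error(simulateAncestralPanel(0, 10, cl1), "at least one sample")
})

test_that("derived-allele counts follow the neutral 1/i spectrum", {
  # pooled goodness-of-fit over 20 seeds, 2N = 60 haplotypes
  twoN <- 60L
  counts <- integer(twoN - 1)
  for (s in 1:20) {
    p <- simulateAncestralPanel(30, 500, cl1, seed = s)
    ac <- colSums(hapMatrix(p))
    counts <- counts + tabulate(ac, nbins = twoN - 1)
  }
  expected <- (1 / seq_len(twoN - 1)) / sum(1 / seq_len(twoN - 1))
  gof <- suppressWarnings(chisq.test(counts, p = expected))
  expect_gt(gof$p.value, 0.001)
})

test_that("a full-founder zero-generation bottleneck permutes the parent
           haplotypes", {
  parent <- simulateAncestralPanel(5, 60, cl1, seed = 3)
  child <- deriveBottleneckedPopulation(parent, nFounders = 10,
                                        nGenerations = 0, nOut = 5,
                                        seed = 4)
  sortRows <- function(H) H[do.call(order, as.data.frame(H)), ]
  expect_identical(sortRows(hapMatrix(child)),
                   sortRows(hapMatrix(parent)))
})

test_that("a single founder forces monomorphism and small founder sets
           lose diversity", {
  parent <- simulateAncestralPanel(8, 80, cl1, seed = 5)
  mono <- deriveBottleneckedPopulation(parent, nFounders = 1,
                                       nGenerations = 3, nOut = 8,
                                       seed = 6)
  expect_equal(length(unique(apply(hapMatrix(mono), 1, paste,
                                   collapse = ""))), 1L)
  expect_equal(sum(windowedPi(mono, "domesticated", 50000)$pi), 0)
  expect_error(deriveBottleneckedPopulation(parent, 0, 1, 4), "at least 1")
  expect_error(deriveBottleneckedPopulation(parent, 17, 1, 4),
               "exceeds parent")
  # pi reduction with 2 founders in at least 95% of 40 replicates
  ok <- 0
  for (s in 1:40) {
    par <- simulateAncestralPanel(8, 150, cl1, seed = 100 + s)
    der <- deriveBottleneckedPopulation(par, nFounders = 2,
                                        nGenerations = 2, nOut = 8,
                                        subpop = "dom", seed = 200 + s)
    piP <- sum(windowedPi(par, "wild", 50000)$pi)
    piD <- sum(windowedPi(der, "dom", 50000)$pi)
    ok <- ok + (piD <= piP)
  }
  expect_gte(ok / 40, 0.95)
})

test_that("sweep implantation fixes the region at frequency 1 and leaves
           flanking sites untouched", {
  panel <- simulateAncestralPanel(10, 200, cl1, seed = 8)
  swept <- implantSweep(panel, "chr1", 10000, 20000, finalFrequency = 1,
                        seed = 9)
  st <- siteTable(panel)
  inside <- st$pos >= 10000 & st$pos <= 20000
  expect_true(any(inside))
  H <- hapMatrix(swept)
  expect_true(all(apply(H[, inside, drop = FALSE], 2,
                        function(x) length(unique(x)) == 1)))
  expect_identical(H[, !inside], hapMatrix(panel)[, !inside])
  expect_error(implantSweep(panel, "chr1", 200, 100, 0.5), "empty")
  expect_error(implantSweep(panel, "chr1", 1, 10, 0), "finalFrequency")
})

test_that("a 0.9-frequency sweep lifts the window's pi ratio above the
           genome median", {
  cl <- setNames(rep(2e5, 2), c("chr1", "chr2"))
  wild <- simulateAncestralPanel(12, 800, cl, subpop = "wild", seed = 11)
  dom <- deriveBottleneckedPopulation(wild, 12, 4, 12, subpop = "dom",
                                      seed = 12)
  dom <- implantSweep(dom, "chr1", 50001, 100000, 0.9, seed = 13)
  panel <- mergePanels(wild, dom)
  pw <- windowedPi(panel, "wild", 50000)
  pd <- windowedPi(panel, "dom", 50000)
  # raw ratio with 0 denominators treated as maximal diversity loss
  ratio <- ifelse(pd$pi > 0, pw$pi / pd$pi, Inf)
  swIdx <- which(pw$chrom == "chr1" & pw$start == 50001)
  expect_gt(ratio[swIdx], median(ratio))
})

test_that("synthesized gene bodies never overlap and forced QTL overlap
           holds", {
  ann <- synthesizeAnnotations(c(chr1 = 2e6, chr2 = 2e6), nGenes = 200,
                               nQtls = 10, seed = 21)
  g <- geneRanges(ann$genes)
  expect_equal(length(g), 200L)
  self <- GenomicRanges::findOverlaps(g, g)
  expect_equal(length(self), length(g))  # only self-overlaps
  one <- synthesizeAnnotations(c(chr1 = 1e5), nGenes = 1, nQtls = 1,
                               qtlOverlapFraction = 1, seed = 22)
  ov <- GenomicRanges::findOverlaps(geneRanges(one$genes), one$qtls,
                                    ignore.strand = TRUE)
  expect_equal(length(ov), 1L)
  expect_true(all(GenomicRanges::start(geneRanges(one$genes)) >=
                  GenomicRanges::start(one$qtls)))
  expect_error(synthesizeAnnotations(c(chr1 = 1000), nGenes = 50,
                                     nQtls = 1, seed = 1),
               "too small")
})

test_that("expression classes behave as constructed and generation is
           deterministic", {
  ex <- synthesizeExpression(sprintf("g%03d", 1:60), nLibraries = 10,
                             seed = 30)
  ex2 <- synthesizeExpression(sprintf("g%03d", 1:60), nLibraries = 10,
                              seed = 30)
  expect_identical(ex$fpkm, ex2$fpkm)
  uni <- names(ex$class)[ex$class == "uniform"]
  sng <- names(ex$class)[ex$class == "single"]
  expect_true(all(apply(ex$fpkm[uni, , drop = FALSE], 1, tauIndex) == 0))
  expect_true(all(apply(ex$fpkm[sng, , drop = FALSE], 1, tauIndex) == 1))
  expect_true(all(rowSums(ex$fpkm[sng, , drop = FALSE] > 0) == 1))
  expect_error(synthesizeExpression("g1", 10,
                                    proportions = c(uniform = 0.5,
                                                    single = 0.2,
                                                    graded = 0.2)),
               "sum to 1")
  expect_error(synthesizeExpression("g1", 1), "two libraries")
})

test_that("the full fixture is deterministic, byte-identical on disk,
           and shows the wild-to-derived diversity loss", {
  cfg <- simulationConfig(genomeLength = 1e5, nChromosomes = 2,
                          nSites = 600, nGenes = 10, nQtls = 3,
                          nLibraries = 6, seed = 41)
  fx1 <- simulateFixture(cfg)
  fx2 <- simulateFixture(cfg)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  p1 <- exportFixture(fx1$panel, fx1$genes, fx1$qtls, fx1$expression, d1)
  p2 <- exportFixture(fx2$panel, fx2$genes, fx2$qtls, fx2$expression, d2)
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  piW <- mean(windowedPi(fx1$panel, "wild_emmer", 50000)$pi)
  piD <- mean(windowedPi(fx1$panel, "domesticated_emmer", 50000)$pi)
  expect_lt(piD, piW)
})

test_that("configuration invariants are enforced", {
  expect_error(simulationConfig(sweepSpec = data.frame(
    chrom = "chr1", start = 0, end = 10, target = "wild", freq = 0.9)),
    "within chromosome bounds")
  sp <- defaultSubpopSpec()
  sp$founders[2] <- 1000L
  expect_error(simulationConfig(subpopSpec = sp), "founder count")
  sp2 <- defaultSubpopSpec(); sp2$n[1] <- 0L
  expect_error(simulationConfig(subpopSpec = sp2), "at least one sample")
})
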