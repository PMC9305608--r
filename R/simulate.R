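#' Simulation configuration for a domestication-series fixture
#'
#' Bundles the parameters of the synthetic fixture generator: genome shape,
#' segregating-site count, the subpopulation pedigree (each derived
#' subpopulation descends from its parent through a founder bottleneck plus
#' Wright-Fisher drift), implanted sweep regions, and annotation/expression
#' sizes.  The default pedigree mirrors a nine-subpopulation wheat panel:
#' wild einkorn (31), domesticated einkorn (31), urartu (29), wild emmer
#' (28), domesticated emmer (29), durum (13), landrace (45), cultivar (25)
#' and Ae. tauschii (30), with the domesticated/improved groups derived
#' from their wild ancestors through founder bottlenecks.
#'
#' @param genomeLength bp per chromosome.
#' @param nChromosomes number of chromosomes (modelled as independent;
#'   subgenomes are just labelled chromosomes).
#' @param nSites total segregating sites, split across chromosomes.
#' @param subpopSpec data.frame with columns \code{name}, \code{n} (diploid
#'   samples), \code{parent} (\code{NA} for ancestral populations),
#'   \code{founders} (founder haplotypes drawn from the parent) and
#'   \code{generations} (Wright-Fisher generations of drift).
#' @param sweepSpec data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{target} (subpopulation name), \code{freq} (final
#'   donor-haplotype frequency); may have zero rows.
#' @param nGenes,nQtls,nLibraries annotation and expression sizes.
#' @param qtlOverlapFraction fraction of QTLs anchored on a gene so that the
#'   gene lies inside the QTL.
#' @param seed integer seed; the whole fixture is a pure function of the
#'   configuration including this seed.
#' @return A list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(genomeLength = 1e6, nChromosomes = 5,
                             nSites = 10000,
                             subpopSpec = defaultSubpopSpec(),
                             sweepSpec = NULL,
                             nGenes = 100, nQtls = 12, nLibraries = 80,
                             qtlOverlapFraction = 0.5, seed = 1L) {
  if (is.null(sweepSpec))
    sweepSpec <- data.frame(chrom = character(), start = integer(),
                            end = integer(), target = character(),
                            freq = numeric())
  stopifnot(nSites >= 0, genomeLength > 0, nChromosomes >= 1)
  if (any(subpopSpec$n < 1))
    stop("every subpopulation needs at least one sample")
  if (nrow(sweepSpec) &&
      (any(sweepSpec$start < 1) || any(sweepSpec$end > genomeLength)))
    stop("sweep intervals must lie within chromosome bounds")
  pn <- match(subpopSpec$parent, subpopSpec$name)
  derived <- !is.na(subpopSpec$parent)
  if (any(derived & is.na(pn)))
    stop("unknown parent subpopulation")
  if (any(derived & subpopSpec$founders > 2 * subpopSpec$n[pn], na.rm = TRUE))
    stop("founder count exceeds parent haplotype count")
  structure(list(genomeLength = genomeLength, nChromosomes = nChromosomes,
                 nSites = nSites, subpopSpec = subpopSpec,
                 sweepSpec = sweepSpec, nGenes = nGenes, nQtls = nQtls,
                 nLibraries = nLibraries,
                 qtlOverlapFraction = qtlOverlapFraction,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Default nine-subpopulation pedigree
#'
#' Sample sizes follow a wheat domestication panel (wild einkorn 31,
#' domesticated einkorn 31, urartu 29, wild emmer 28, domesticated emmer 29,
#' durum 13, landrace 45, cultivar 25, Ae. tauschii 30).  Founder counts and
#' drift generations are fixture choices producing a clear wild-to-derived
#' diversity loss.
#'
#' @return data.frame usable as `subpopSpec` in [simulationConfig()].
#' @export
defaultSubpopSpec <- function() {
  data.frame(
    name = c("wild_einkorn", "domesticated_einkorn", "urartu",
             "wild_emmer", "domesticated_emmer", "durum",
             "landrace", "cultivar", "ae_tauschii"),
    n = c(31L, 31L, 29L, 28L, 29L, 13L, 45L, 25L, 30L),
    parent = c(NA, "wild_einkorn", NA,
               NA, "wild_emmer", "domesticated_emmer",
               "durum", "landrace", NA),
    founders = c(NA, 16L, NA, NA, 16L, 10L, 24L, 14L, NA),
    generations = c(NA, 10L, NA, NA, 10L, 8L, 8L, 8L, NA),
    stringsAsFactors = FALSE
  )
}

.splitSites <- function(nSites, chromLengths) {
  # allocate sites to chromosomes proportionally to length
  p <- chromLengths / sum(chromLengths)
  n <- floor(nSites * p)
  rem <- nSites - sum(n)
  if (rem > 0) n[seq_len(rem)] <- n[seq_len(rem)] + 1
  n
}

#' Simulate an ancestral (wild) panel from a neutral frequency spectrum
#'
#' Sites are placed uniformly along each chromosome; the derived-allele
#' count at each site is drawn from the neutral site-frequency spectrum
#' (probability of count \eqn{i} among \eqn{2N} haplotypes proportional to
#' \eqn{1/i}, \eqn{i = 1, \dots, 2N-1}) and the derived allele is assigned
#' to a uniformly random subset of haplotypes.  This is a frequency-spectrum
#' generator, not a genealogical (coalescent) simulator: sites are
#' unlinked and exchangeable, which is sufficient to give downstream
#' diversity statistics their expected structure.
#'
#' @param nSamplesPer diploid sample count.
#' @param nSites number of segregating sites.
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param subpop subpopulation label for all samples.
#' @param seed integer seed (deterministic output).
#' @param prefix sample-id prefix.
#' @return A [PhasedPanel-class].
#' @export
simulateAncestralPanel <- function(nSamplesPer, nSites, chromLengths,
                                   subpop = "wild", seed = 1L,
                                   prefix = subpop) {
  if (nSamplesPer < 1) stop("need at least one sample")
  set.seed(as.integer(seed))
  twoN <- 2L * nSamplesPer
  perChrom <- .splitSites(nSites, chromLengths)
  nt <- c("A", "C", "G", "T")
  siteList <- lapply(seq_along(chromLengths), function(ci) {
    ns <- perChrom[ci]
    if (ns == 0)
      return(data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character()))
    pos <- sort(sample.int(chromLengths[ci], ns))
    ref <- sample(nt, ns, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), character(1))
    data.frame(chrom = names(chromLengths)[ci], pos = pos,
               ref = ref, alt = unname(alt))
  })
  sites <- do.call(rbind, siteList)
  ns <- nrow(sites)
  haps <- matrix(0L, nrow = twoN, ncol = ns)
  if (ns > 0 && twoN >= 2) {
    cnt <- sample(seq_len(twoN - 1L), ns, replace = TRUE,
                  prob = 1 / seq_len(twoN - 1L))
    for (j in seq_len(ns))
      haps[sample.int(twoN, cnt[j]), j] <- 1L
  }
  PhasedPanel(sprintf("%s_%02d", prefix, seq_len(nSamplesPer)),
              rep(subpop, nSamplesPer), sites, haps, chromLengths)
}

#' Derive a bottlenecked population by founder sampling plus drift
#'
#' A founder set of `nFounders` haplotypes is drawn without replacement from
#' the parent panel; `nGenerations` rounds of Wright-Fisher resampling (each
#' generation draws `2 * nOut` haplotypes with replacement from the previous
#' one) then produce the derived population.  With `nGenerations = 0` and
#' `nFounders` equal to both the parent haplotype count and `2 * nOut`, the
#' output is a permutation of the parent haplotypes.  Smaller founder sets
#' lose more diversity, emulating the domestication bottleneck.
#'
#' @param parent parent [PhasedPanel-class].
#' @param nFounders founder haplotypes (1 .. parent haplotype count).
#' @param nGenerations Wright-Fisher generations (>= 0).
#' @param nOut output diploid sample count.
#' @param subpop label for the derived samples.
#' @param seed integer seed.
#' @param prefix sample-id prefix.
#' @return A [PhasedPanel-class] over the same sites as `parent`.
#' @export
deriveBottleneckedPopulation <- function(parent, nFounders, nGenerations,
                                         nOut, subpop = "domesticated",
                                         seed = 1L, prefix = subpop) {
  twoNp <- nrow(hapMatrix(parent))
  if (nFounders < 1) stop("nFounders must be at least 1")
  if (nFounders > twoNp)
    stop("nFounders exceeds parent haplotype count")
  set.seed(as.integer(seed))
  pool <- hapMatrix(parent)[sample.int(twoNp, nFounders), , drop = FALSE]
  twoN <- 2L * nOut
  if (nGenerations > 0) {
    for (g in seq_len(nGenerations))
      pool <- pool[sample.int(nrow(pool), twoN, replace = TRUE), ,
                   drop = FALSE]
  } else if (nrow(pool) != twoN) {
    pool <- pool[sample.int(nrow(pool), twoN, replace = TRUE), ,
                 drop = FALSE]
  }
  PhasedPanel(sprintf("%s_%02d", prefix, seq_len(nOut)),
              rep(subpop, nOut), siteTable(parent), pool,
              parent@chromLengths)
}

#' Implant a selective-sweep signature into a genomic region
#'
#' Within `chrom:start-end`, a fraction `finalFrequency` of the panel's
#' haplotypes (rounded to the nearest count) is overwritten with the donor
#' haplotype's allele string, driving the donor lineage to high local
#' frequency.  Sites outside the region are untouched.  This reproduces the
#' reduced-diversity / elevated-differentiation signature of a sweep
#' without simulating hitchhiking dynamics.
#'
#' @param panel A [PhasedPanel-class].
#' @param chrom,start,end swept region (1-based inclusive).
#' @param finalFrequency target donor frequency in (0, 1].
#' @param donorHap haplotype row index of the donor; random when `NULL`.
#' @param seed integer seed.
#' @return The modified [PhasedPanel-class].
#' @export
implantSweep <- function(panel, chrom, start, end, finalFrequency,
                         donorHap = NULL, seed = 1L) {
  if (start > end) stop("empty sweep region")
  if (finalFrequency <= 0 || finalFrequency > 1)
    stop("finalFrequency must be in (0, 1]")
  st <- siteTable(panel)
  idx <- which(st$chrom == chrom & st$pos >= start & st$pos <= end)
  if (!length(idx)) return(panel)
  set.seed(as.integer(seed))
  H <- hapMatrix(panel)
  twoN <- nrow(H)
  if (is.null(donorHap)) donorHap <- sample.int(twoN, 1)
  nRep <- round(finalFrequency * twoN)
  recipients <- sample.int(twoN, nRep)
  H[recipients, idx] <- rep(H[donorHap, idx], each = nRep)
  PhasedPanel(panel@samples, panel@subpop, st, H, panel@chromLengths)
}

.TRAIT_CODES <- c("GY", "GC", "KNS", "KW", "KL", "SNS", "SR", "SP",
                  "LSD", "LR", "YR", "HT", "HD", "NWI")

.TF_FAMILIES <- c("NAC", "bZIP", "MYB", "WRKY", "bHLH", "AP2-ERF",
                  "GARP-G2-like", "MADS", "C2H2", "HSF", "GRAS", "TCP")

#' Synthesize gene models, QTL intervals and a family table
#'
#' Places non-overlapping gene bodies (1-12 exons each, with 5'/3' UTRs on
#' the terminal exons when long enough) along the chromosomes, labels each
#' gene with a transcription-factor family, and generates trait-labelled
#' QTL intervals, a configurable fraction of which are anchored on a gene
#' so that the gene lies inside the QTL.
#'
#' @param chromLengths named numeric vector of chromosome lengths.
#' @param nGenes,nQtls counts.
#' @param qtlOverlapFraction fraction of QTLs anchored on genes.
#' @param familyLabels family label set to draw from.
#' @param traitCodes trait code set for QTLs (14 agronomic-trait codes by
#'   default: GY, GC, KNS, KW, KL, SNS, SR, SP, LSD, LR, YR, HT, HD, NWI).
#' @param seed integer seed.
#' @return list with `genes` (a [GeneModels-class]), `qtls` (a
#'   `GRanges` with a `trait` column) and `familyTable`
#'   (data.frame gene_id, family).
#' @export
synthesizeAnnotations <- function(chromLengths, nGenes, nQtls,
                                  qtlOverlapFraction = 0.5,
                                  familyLabels = .TF_FAMILIES,
                                  traitCodes = .TRAIT_CODES,
                                  seed = 1L) {
  if (any(chromLengths <= 0)) stop("genome length must be positive")
  set.seed(as.integer(seed))
  nPer <- .splitSites(nGenes, chromLengths)
  geneRows <- list()
  exonRows <- list()
  utr5Rows <- list()
  utr3Rows <- list()
  gid <- 0L
  for (ci in seq_along(chromLengths)) {
    ng <- nPer[ci]
    if (ng == 0) next
    len <- sample(1500:6000, ng, replace = TRUE)
    slack <- chromLengths[ci] - sum(len)
    if (slack < ng)
      stop("genome too small for requested gene count")
    u <- sort(sample.int(slack, ng))
    start <- u + c(0, cumsum(len))[seq_len(ng)]
    end <- start + len - 1L
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    for (g in seq_len(ng)) {
      gid <- gid + 1L
      id <- sprintf("SynG%04d", gid)
      nex <- sample.int(12L, 1)
      # partition the gene body into alternating exon/intron blocks
      nblk <- 2L * nex - 1L
      if (len[g] < 60L * nblk) nex <- max(1L, len[g] %/% 120L)
      nblk <- 2L * nex - 1L
      cuts <- sort(sample.int(len[g] - 1L, nblk - 1L))
      bnd <- c(0L, cuts, len[g])
      es <- start[g] + bnd[seq(1, nblk, by = 2)]
      ee <- start[g] + bnd[seq(2, nblk + 1, by = 2)] - 1L
      geneRows[[gid]] <- data.frame(
        gene_id = id, chrom = names(chromLengths)[ci],
        start = start[g], end = end[g], strand = strand[g])
      exonRows[[gid]] <- data.frame(
        gene_id = id, chrom = names(chromLengths)[ci],
        start = es, end = ee)
      # UTRs: 100 bp at the transcript ends when the terminal exons allow
      first <- c(es[1], ee[1]); last <- c(es[length(es)], ee[length(ee)])
      leftU <- if (first[2] - first[1] + 1 >= 300)
        data.frame(gene_id = id, chrom = names(chromLengths)[ci],
                   start = first[1], end = first[1] + 99L) else NULL
      rightU <- if (last[2] - last[1] + 1 >= 300)
        data.frame(gene_id = id, chrom = names(chromLengths)[ci],
                   start = last[2] - 99L, end = last[2]) else NULL
      if (strand[g] == "+") {
        utr5Rows[[length(utr5Rows) + 1L]] <- leftU
        utr3Rows[[length(utr3Rows) + 1L]] <- rightU
      } else {
        utr5Rows[[length(utr5Rows) + 1L]] <- rightU
        utr3Rows[[length(utr3Rows) + 1L]] <- leftU
      }
    }
  }
  genesDf <- do.call(rbind, geneRows)
  exonsDf <- do.call(rbind, exonRows)
  utr5Df <- do.call(rbind, utr5Rows)
  utr3Df <- do.call(rbind, utr3Rows)
  fam <- sample(familyLabels, nrow(genesDf), replace = TRUE)
  familyTable <- data.frame(gene_id = genesDf$gene_id, family = fam)
  genes <- .makeGeneModels(genesDf, exonsDf, familyTable, utr5Df, utr3Df)

  # QTLs: anchored on a random gene with probability qtlOverlapFraction
  anchored <- runif(nQtls) <= qtlOverlapFraction
  qc <- character(nQtls); qs <- integer(nQtls); qe <- integer(nQtls)
  for (q in seq_len(nQtls)) {
    if (anchored[q] && nrow(genesDf)) {
      g <- genesDf[sample.int(nrow(genesDf), 1), ]
      pad <- sample(5000:50000, 2)
      qc[q] <- g$chrom
      qs[q] <- max(1L, g$start - pad[1])
      qe[q] <- min(chromLengths[[g$chrom]], g$end + pad[2])
    } else {
      ci <- sample.int(length(chromLengths), 1)
      w <- sample(20000:100000, 1)
      qc[q] <- names(chromLengths)[ci]
      qs[q] <- sample.int(max(1, chromLengths[ci] - w), 1)
      qe[q] <- qs[q] + w - 1L
    }
  }
  qtls <- GenomicRanges::GRanges(qc, IRanges::IRanges(qs, qe))
  qtls$trait <- sample(traitCodes, nQtls, replace = TRUE)
  list(genes = genes, qtls = qtls, familyTable = familyTable)
}

#' Synthesize a tissue-structured FPKM matrix
#'
#' Three gene classes by configurable proportions: `uniform` (the same
#' positive FPKM in all libraries), `single` (positive in exactly one
#' library), and `graded` (log-normal noise around a library-specific mean
#' that decays with distance from a randomly chosen peak library).  Class
#' membership is returned as ground truth for tissue-specificity tests.
#'
#' @param geneIds character gene ids (matrix rows).
#' @param nLibraries number of expression libraries (>= 2).
#' @param proportions named numeric vector over
#'   `c("uniform", "single", "graded")`, summing to 1.
#' @param seed integer seed.
#' @return list with `fpkm` (genes x libraries matrix) and `class`
#'   (named character ground-truth class per gene).
#' @export
synthesizeExpression <- function(geneIds, nLibraries = 80,
                                 proportions = c(uniform = 0.2,
                                                 single = 0.3,
                                                 graded = 0.5),
                                 seed = 1L) {
  if (nLibraries < 2) stop("need at least two libraries")
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("class proportions must sum to 1")
  set.seed(as.integer(seed))
  ng <- length(geneIds)
  cls <- sample(names(proportions), ng, replace = TRUE, prob = proportions)
  fpkm <- matrix(0, nrow = ng, ncol = nLibraries,
                 dimnames = list(geneIds,
                                 sprintf("lib%02d", seq_len(nLibraries))))
  for (i in seq_len(ng)) {
    if (cls[i] == "uniform") {
      fpkm[i, ] <- runif(1, 2, 50)
    } else if (cls[i] == "single") {
      fpkm[i, sample.int(nLibraries, 1)] <- runif(1, 5, 100)
    } else {
      peak <- sample.int(nLibraries, 1)
      d <- abs(seq_len(nLibraries) - peak)
      mu <- log(runif(1, 10, 80)) - d / runif(1, 3, 10)
      fpkm[i, ] <- exp(rnorm(nLibraries, mu, 0.3))
    }
  }
  list(fpkm = fpkm, class = setNames(cls, geneIds))
}

#' Run a full domestication-series simulation
#'
#' Executes the pedigree in the configuration: ancestral subpopulations are
#' drawn from the neutral frequency spectrum (sharing one site set per
#' independent ancestor), derived subpopulations descend through founder
#' bottlenecks and drift, and sweep regions are implanted into their target
#' subpopulations.  Annotations and expression are generated alongside.
#'
#' @param config A `SimulationConfig` from [simulationConfig()].
#' @return list with `panel` (merged [PhasedPanel-class] over all
#'   subpopulations), `genes`, `qtls`, `familyTable`, `expression`
#'   (list fpkm/class) and the `config`.
#' @export
simulateFixture <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cl <- setNames(rep(config$genomeLength, config$nChromosomes),
                 sprintf("chr%d", seq_len(config$nChromosomes)))
  sp <- config$subpopSpec
  panels <- list()
  # ancestral populations share the site set of the first ancestor so that
  # all subpopulations live on one common SNP scaffold
  anc <- which(is.na(sp$parent))
  base <- simulateAncestralPanel(sp$n[anc[1]], config$nSites, cl,
                                 subpop = sp$name[anc[1]],
                                 seed = config$seed)
  panels[[sp$name[anc[1]]]] <- base
  for (k in anc[-1]) {
    # independent wild lineage: fresh allele frequencies on the same sites
    p <- simulateAncestralPanel(sp$n[k], config$nSites, cl,
                                subpop = sp$name[k],
                                seed = config$seed + 7L * k)
    p@sites <- siteTable(base)
    panels[[sp$name[k]]] <- p
  }
  remaining <- which(!is.na(sp$parent))
  while (length(remaining)) {
    ready <- remaining[sp$parent[remaining] %in% names(panels)]
    if (!length(ready)) stop("cyclic subpopulation pedigree")
    for (k in ready) {
      panels[[sp$name[k]]] <- deriveBottleneckedPopulation(
        panels[[sp$parent[k]]], sp$founders[k], sp$generations[k],
        sp$n[k], subpop = sp$name[k], seed = config$seed + 101L * k)
    }
    remaining <- setdiff(remaining, ready)
  }
  if (nrow(config$sweepSpec)) {
    for (s in seq_len(nrow(config$sweepSpec))) {
      sw <- config$sweepSpec[s, ]
      panels[[sw$target]] <- implantSweep(
        panels[[sw$target]], sw$chrom, sw$start, sw$end, sw$freq,
        seed = config$seed + 211L * s)
    }
  }
  panel <- Reduce(mergePanels, panels)
  ann <- synthesizeAnnotations(cl, config$nGenes, config$nQtls,
                               config$qtlOverlapFraction,
                               seed = config$seed + 3L)
  expr <- synthesizeExpression(geneIds(ann$genes), config$nLibraries,
                               seed = config$seed + 4L)
  list(panel = panel, genes = ann$genes, qtls = ann$qtls,
       familyTable = ann$familyTable, expression = expr, config = config)
}

#' Merge two panels defined over the same site set
#'
#' @param a,b [PhasedPanel-class] objects with identical site tables.
#' @return combined [PhasedPanel-class].
#' @export
mergePanels <- function(a, b) {
  if (!identical(siteTable(a), siteTable(b)))
    stop("panels are not on the same site set")
  PhasedPanel(c(a@samples, b@samples), c(a@subpop, b@subpop),
              siteTable(a), rbind(hapMatrix(a), hapMatrix(b)),
              a@chromLengths)
}

#' Two-population sweep-recovery fixture
#'
#' The package's reference validation scenario: a wild population of 20
#' samples on 5 chromosomes of 1 Mb, a domesticated derivative of 20
#' samples obtained through a 12-founder bottleneck with 10 generations of
#' drift, and one 50-kb sweep implanted in the domesticated population at
#' donor frequency 0.95 (chr3:500,001-550,000).  Site density is 2,000
#' segregating sites per chromosome.
#'
#' @param seed integer seed.
#' @param nSitesPerChrom segregating sites per chromosome.
#' @return list with `panel` (wild + domesticated), `sweep` (data.frame
#'   chrom/start/end of the implanted region) and the subpopulation names.
#' @export
defaultSweepFixture <- function(seed = 1L, nSitesPerChrom = 2000) {
  cl <- setNames(rep(1e6, 5), sprintf("chr%d", 1:5))
  wild <- simulateAncestralPanel(20, nSitesPerChrom * 5, cl,
                                 subpop = "wild", seed = seed)
  dom <- deriveBottleneckedPopulation(wild, nFounders = 12,
                                      nGenerations = 10, nOut = 20,
                                      subpop = "domesticated",
                                      seed = seed + 1000L)
  sweep <- data.frame(chrom = "chr3", start = 500001L, end = 550000L)
  dom <- implantSweep(dom, sweep$chrom, sweep$start, sweep$end,
                      finalFrequency = 0.95, seed = seed + 2000L)
  list(panel = mergePanels(wild, dom), sweep = sweep,
       wild = "wild", derived = "domesticated")
}
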