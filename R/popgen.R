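#' Per-site nucleotide diversity from allele counts
#'
#' The mean pairwise difference at one biallelic site:
#' \deqn{\pi_{site} = \frac{n_{ref}\, n_{alt}}{\binom{n}{2}}}
#' with \eqn{n} the number of non-missing haplotypes.  Equivalent to the
#' unbiased heterozygosity \eqn{\frac{n}{n-1} 2p(1-p)}.
#'
#' @param refCount,altCount allele counts (vectors allowed).
#' @return per-site diversity; `NA` where fewer than 2 haplotypes.
#' @export
sitePi <- function(refCount, altCount) {
  n <- refCount + altCount
  out <- ifelse(n < 2, NA_real_, refCount * altCount / (n * (n - 1) / 2))
  out
}

.windowGrid <- function(chromLengths, windowBp, stepBp) {
  do.call(rbind, lapply(names(chromLengths), function(ch) {
    len <- chromLengths[[ch]]
    starts <- seq(1, len, by = stepBp)
    ends <- pmin(starts + windowBp - 1, len)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(ends))
  }))
}

.altCounts <- function(panel, subpop) {
  sub <- selectSamples(panel, subpop = subpop)
  colSums(hapMatrix(sub))
}

#' Windowed nucleotide diversity for one subpopulation
#'
#' Per-site diversities are summed within sliding windows and scaled by
#' the window length in bp (monomorphic and absent sites contribute 0),
#' following the convention of windowed-diversity tools.  The trailing
#' window of each chromosome is truncated at the chromosome end and scaled
#' by its actual span.
#'
#' @param panel A [PhasedPanel-class].
#' @param subpop subpopulation to use.
#' @param windowBp window size in bp (default 50 kb).
#' @param stepBp step between window starts; defaults to `windowBp`
#'   (non-overlapping windows).
#' @return data.frame: chrom, start, end, n_sites (segregating sites in
#'   the window for this subpopulation), pi (per-bp).
#' @export
windowedPi <- function(panel, subpop, windowBp = 50000,
                       stepBp = windowBp) {
  stopifnot(windowBp > 0, stepBp > 0)
  cl <- chromLengths(panel)
  grid <- .windowGrid(cl, windowBp, stepBp)
  st <- siteTable(panel)
  ac <- .altCounts(panel, subpop)
  twoN <- 2L * sum(panel@subpop == subpop)
  pis <- sitePi(twoN - ac, ac)
  seg <- ac > 0 & ac < twoN
  win <- GenomicRanges::GRanges(grid$chrom,
                                IRanges::IRanges(grid$start, grid$end))
  sgr <- GenomicRanges::GRanges(st$chrom, IRanges::IRanges(st$pos, st$pos))
  ov <- GenomicRanges::findOverlaps(sgr, win)
  pi <- numeric(nrow(grid))
  ns <- integer(nrow(grid))
  if (length(ov)) {
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    agg <- rowsum(pis[q], s)
    pi[as.integer(rownames(agg))] <- agg[, 1]
    nagg <- rowsum(as.integer(seg[q]), s)
    ns[as.integer(rownames(nagg))] <- nagg[, 1]
  }
  data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
             n_sites = ns, pi = pi / (grid$end - grid$start + 1))
}

#' Per-site Weir-Cockerham variance components for two subpopulations
#'
#' Computes the a (among-population), b (among-individual) and c
#' (within-individual) components of Weir & Cockerham's theta from diploid
#' genotypes, including the heterozygosity term.  Exposed so that windowed
#' estimates can be audited site by site.
#'
#' @param panel A [PhasedPanel-class].
#' @param popA,popB subpopulation names.
#' @return data.frame with one row per site: chrom, pos, a, b, c.
#' @export
wcSiteComponents <- function(panel, popA, popB) {
  compPop <- function(sp) {
    sub <- selectSamples(panel, subpop = sp)
    H <- hapMatrix(sub)
    n <- nSamples(sub)
    if (n < 1 || nrow(H) < 2) stop("empty subpopulation: ", sp)
    h1 <- H[seq(1, 2 * n, by = 2), , drop = FALSE]
    h2 <- H[seq(2, 2 * n, by = 2), , drop = FALSE]
    list(n = n, p = colMeans((h1 + h2) / 2), h = colMeans(h1 != h2))
  }
  A <- compPop(popA); B <- compPop(popB)
  r <- 2
  n1 <- A$n; n2 <- B$n
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * A$p + n2 * B$p) / (r * nbar)
  s2 <- (n1 * (A$p - pbar)^2 + n2 * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * A$h + n2 * B$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  st <- siteTable(panel)
  data.frame(chrom = st$chrom, pos = st$pos, a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham Fst between two subpopulations
#'
#' Per-site variance components are accumulated over each window and the
#' weighted estimator \eqn{F_{st} = \sum a / \sum(a+b+c)} reported.  Sites
#' with zero total variance are skipped; windows with no usable site get
#' `NA`.  Negative estimates are reported as computed, not clamped.
#'
#' @inheritParams wcSiteComponents
#' @param windowBp,stepBp window geometry as in [windowedPi()].
#' @return data.frame: chrom, start, end, n_sites (usable sites), fst.
#' @export
weirCockerhamFst <- function(panel, popA, popB, windowBp = 50000,
                             stepBp = windowBp) {
  comp <- wcSiteComponents(panel, popA, popB)
  tot <- comp$a + comp$b + comp$c
  usable <- is.finite(tot) & tot != 0
  cl <- chromLengths(panel)
  grid <- .windowGrid(cl, windowBp, stepBp)
  win <- GenomicRanges::GRanges(grid$chrom,
                                IRanges::IRanges(grid$start, grid$end))
  sgr <- GenomicRanges::GRanges(comp$chrom,
                                IRanges::IRanges(comp$pos, comp$pos))
  ov <- GenomicRanges::findOverlaps(sgr[usable], win)
  sumA <- numeric(nrow(grid)); sumT <- numeric(nrow(grid))
  ns <- integer(nrow(grid))
  if (length(ov)) {
    q <- which(usable)[S4Vectors::queryHits(ov)]
    s <- S4Vectors::subjectHits(ov)
    aggA <- rowsum(comp$a[q], s); aggT <- rowsum(tot[q], s)
    i <- as.integer(rownames(aggA))
    sumA[i] <- aggA[, 1]; sumT[i] <- aggT[, 1]
    nagg <- rowsum(rep(1L, length(q)), s)
    ns[as.integer(rownames(nagg))] <- nagg[, 1]
  }
  fst <- ifelse(ns > 0, sumA / sumT, NA_real_)
  data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
             n_sites = ns, fst = fst)
}

#' Windowed pi ratio between an ancestral and a derived population
#'
#' Ratio of per-window diversities on an aligned window grid (for the
#' domestication contrast: wild over domesticated; for improvement:
#' domesticated over cultivar).  Windows with fewer than `minSites`
#' segregating sites in either population, or zero diversity in the
#' denominator, are flagged `insufficient` and excluded from downstream
#' quantile ranking.
#'
#' @param wildStats,derivedStats window tables from [windowedPi()] on the
#'   same grid (numerator first).
#' @param minSites minimum segregating sites per window in each population.
#' @return data.frame: chrom, start, end, n_sites_num, n_sites_den,
#'   pi_num, pi_den, pi_ratio, insufficient.
#' @export
piRatioWindows <- function(wildStats, derivedStats, minSites = 1) {
  if (!identical(wildStats[c("chrom", "start", "end")],
                 derivedStats[c("chrom", "start", "end")]))
    stop("window grids are misaligned")
  ratio <- wildStats$pi / derivedStats$pi
  insufficient <- wildStats$n_sites < minSites |
    derivedStats$n_sites < minSites | derivedStats$pi == 0
  ratio[derivedStats$pi == 0] <- NA_real_
  data.frame(chrom = wildStats$chrom, start = wildStats$start,
             end = wildStats$end,
             n_sites_num = wildStats$n_sites,
             n_sites_den = derivedStats$n_sites,
             pi_num = wildStats$pi, pi_den = derivedStats$pi,
             pi_ratio = ratio, insufficient = insufficient)
}

#' Full diversity scan for one wild/derived contrast
#'
#' Convenience wrapper producing the per-window statistics consumed by
#' [callSweeps()]: pi in both subpopulations, their ratio and the weighted
#' Weir-Cockerham Fst on a common window grid.
#'
#' @param panel A [PhasedPanel-class].
#' @param popWild,popDerived subpopulation names (numerator/ancestral
#'   first).
#' @param windowBp,stepBp window geometry (50-kb non-overlapping default).
#' @param minSites per-window segregating-site minimum for the ratio.
#' @return data.frame: chrom, start, end, n_sites, pi_wild, pi_derived,
#'   pi_ratio, fst, insufficient.
#' @export
scanDiversity <- function(panel, popWild, popDerived, windowBp = 50000,
                          stepBp = windowBp, minSites = 1) {
  pw <- windowedPi(panel, popWild, windowBp, stepBp)
  pd <- windowedPi(panel, popDerived, windowBp, stepBp)
  rt <- piRatioWindows(pw, pd, minSites)
  fs <- weirCockerhamFst(panel, popWild, popDerived, windowBp, stepBp)
  data.frame(chrom = pw$chrom, start = pw$start, end = pw$end,
             n_sites = pmin(pw$n_sites, pd$n_sites),
             pi_wild = pw$pi, pi_derived = pd$pi,
             pi_ratio = rt$pi_ratio, fst = fs$fst,
             insufficient = rt$insufficient | is.na(fs$fst))
}
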