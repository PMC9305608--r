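# Build a PhasedPanel from diplotype class strings (2 letters per site,
# heterozygous letters in alphabetical order) with per-subpopulation class
# counts; the construction route is independent of buildGeneHaplotypes.
panelFromDiplotypes <- function(classes, countsBySubpop, sites,
                                chromLen = 100000) {
  samples <- character(); subpop <- character()
  hapRows <- list()
  for (sp in names(countsBySubpop)) {
    cnt <- countsBySubpop[[sp]]
    for (ci in seq_along(classes)) {
      if (cnt[ci] == 0) next
      for (r in seq_len(cnt[ci])) {
        samples <- c(samples, sprintf("%s_c%d_%02d", sp, ci, r))
        subpop <- c(subpop, sp)
        h1 <- integer(nrow(sites)); h2 <- integer(nrow(sites))
        for (j in seq_len(nrow(sites))) {
          l <- strsplit(substring(classes[ci], 2 * j - 1, 2 * j), "")[[1]]
          h1[j] <- as.integer(l[1] == sites$alt[j])
          h2[j] <- as.integer(l[2] == sites$alt[j])
        }
        hapRows[[length(hapRows) + 1L]] <- h1
        hapRows[[length(hapRows) + 1L]] <- h2
      }
    }
  }
  PhasedPanel(samples, subpop, sites, do.call(rbind, hapRows),
              setNames(chromLen, sites$chrom[1]))
}

# Small random panel with arbitrary allele frequencies (not the package
# generator): used as a neutral substrate for oracle comparisons.
randomToyPanel <- function(seed, nSamples = 8, nSites = 100,
                           chromLen = 10000, subpop = "pop") {
  set.seed(seed)
  pos <- sort(sample.int(chromLen, nSites))
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, nSites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), character(1))
  H <- matrix(rbinom(2 * nSamples * nSites, 1,
                     rep(runif(nSites, 0.05, 0.95), each = 2 * nSamples)),
              nrow = 2 * nSamples)
  PhasedPanel(sprintf("%s_%02d", subpop, seq_len(nSamples)),
              rep(subpop, nSamples),
              data.frame(chrom = "chr1", pos = pos, ref = ref,
                         alt = unname(alt)),
              H, c(chr1 = chromLen))
}

urartuSites <- function() {
  data.frame(chrom = "chr1", pos = c(1000, 2000, 3000, 4000),
             ref = c("C", "A", "C", "A"), alt = c("T", "G", "T", "G"))
}

emmerSites <- function() {
  data.frame(chrom = "chr1", pos = c(1500, 2500),
             ref = c("C", "G"), alt = c("A", "A"))
}
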