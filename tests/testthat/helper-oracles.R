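# --- Independent oracles -------------------------------------------------
# Each oracle re-derives a statistic by a different route than the package
# implementation, for cross-checking on small instances.

# Nucleotide diversity as the literal mean pairwise Hamming distance over
# all haplotype pairs, per bp of the spanned length.
bruteForcePi <- function(panel, subpop, lengthBp) {
  H <- hapMatrix(selectSamples(panel, subpop = subpop))
  n <- nrow(H)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      tot <- tot + sum(H[i, ] != H[j, ])
  tot / choose(n, 2) / lengthBp
}

# Weir-Cockerham variance components through the ANOVA mean-square route
# (MSP/MSI/MSG), an independent parameterisation of the 1984 estimator.
wcOracleSite <- function(gtA, gtB) {
  # gtA/gtB: per-sample matrices with columns = the two allele calls (0/1)
  pops <- list(gtA, gtB)
  N <- sum(vapply(pops, nrow, integer(1)))
  r <- 2
  allAll <- unlist(lapply(pops, as.vector))
  gm <- mean(allAll)
  SSG <- 0; SSI <- 0; SSP <- 0
  for (p in pops) {
    im <- rowMeans(p)
    pm <- mean(p)
    SSG <- SSG + sum((p - im)^2)
    SSI <- SSI + 2 * sum((im - pm)^2)
    SSP <- SSP + 2 * nrow(p) * (pm - gm)^2
  }
  MSG <- SSG / N
  MSI <- SSI / (N - r)
  MSP <- SSP / (r - 1)
  ns <- vapply(pops, nrow, integer(1))
  nc <- (sum(ns) - sum(ns^2) / sum(ns)) / (r - 1)
  c(a = (MSP - MSI) / (2 * nc), b = (MSI - MSG) / 2, c = MSG)
}

wcOraclePanel <- function(panel, popA, popB) {
  gt <- function(sp) {
    H <- hapMatrix(selectSamples(panel, subpop = sp))
    n <- nrow(H) / 2
    list(h1 = H[seq(1, 2 * n, 2), , drop = FALSE],
         h2 = H[seq(2, 2 * n, 2), , drop = FALSE])
  }
  A <- gt(popA); B <- gt(popB)
  t(vapply(seq_len(nSites(panel)), function(j)
    wcOracleSite(cbind(A$h1[, j], A$h2[, j]),
                 cbind(B$h1[, j], B$h2[, j])), numeric(3)))
}

# Nei-Gojobori oracle: site counts and pathway averaging re-derived through
# Biostrings translation, with recursive pathway enumeration.
ng86Oracle <- function(a, b) {
  tr <- function(codon)
    as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                       no.init.codon = TRUE))
  synSites <- function(codon) {
    nt <- c("A", "C", "G", "T")
    aa <- tr(codon)
    s <- 0
    for (p in 1:3) for (x in nt) {
      if (x == substr(codon, p, p)) next
      mut <- codon; substr(mut, p, p) <- x
      if (tr(mut) != "*" && tr(mut) == aa) s <- s + 1 / 3
    }
    s
  }
  pathways <- function(from, to, allowStops) {
    pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (!length(pos)) return(list(c(sd = 0, nd = 0)))
    out <- list()
    for (p in pos) {
      mid <- from; substr(mid, p, p) <- substr(to, p, p)
      if (!allowStops && tr(mid) == "*" && mid != to) next
      step <- if (tr(from) != "*" && tr(from) == tr(mid))
        c(sd = 1, nd = 0) else c(sd = 0, nd = 1)
      for (rest in pathways(mid, to, allowStops))
        out[[length(out) + 1L]] <- step + rest
    }
    out
  }
  nc <- nchar(a) / 3
  codA <- substring(a, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  codB <- substring(b, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  S <- (sum(vapply(codA, synSites, numeric(1))) +
        sum(vapply(codB, synSites, numeric(1)))) / 2
  N <- 3 * nc - S
  Sd <- 0; Nd <- 0
  for (i in seq_len(nc)) {
    pw <- pathways(codA[i], codB[i], allowStops = FALSE)
    if (!length(pw)) pw <- pathways(codA[i], codB[i], allowStops = TRUE)
    avg <- Reduce(`+`, pw) / length(pw)
    Sd <- Sd + unname(avg["sd"]); Nd <- Nd + unname(avg["nd"])
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(dS = jc(Sd / S), dN = jc(Nd / N), Sd = unname(Sd), Nd = unname(Nd),
       S = S, N = N)
}

# random stop-free codon, optionally mutated at m positions (stop-free)
randomCodonPair <- function() {
  nt <- c("A", "C", "G", "T")
  repeat {
    a <- paste(sample(nt, 3, replace = TRUE), collapse = "")
    if (Biostrings::GENETIC_CODE[[a]] != "*") break
  }
  repeat {
    b <- a
    for (p in sample(1:3, sample(0:3, 1)))
      substr(b, p, p) <- sample(nt, 1)
    if (Biostrings::GENETIC_CODE[[b]] != "*") break
  }
  c(a, b)
}

# Exhaustive hypergeometric tail: enumerate all cluster draws from the
# universe and count those with at least `overlap` family members.
hyperEnumOracle <- function(universe, familySize, clusterSize, overlap) {
  draws <- combn(universe, clusterSize)
  hits <- colSums(draws <= familySize)  # family = elements 1..familySize
  mean(hits >= overlap)
}
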