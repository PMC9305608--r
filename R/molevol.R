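#' Reciprocal-best-hit ortholog pairing from a similarity table
#'
#' A pair is retained when, after applying the E-value ceiling, each gene
#' is the other's single best-scoring hit — the gene pairs with the
#' highest degree of sequence similarity.  Score ties are broken by lower
#' E-value, then lexicographic subject id, so best hits are unique.
#'
#' @param table data.frame with columns `query`, `subject`, `score`,
#'   `evalue` (both search directions in one table).
#' @param evalueMax E-value ceiling (default 1e-5).
#' @return data.frame of unordered pairs: `gene_a`, `gene_b`
#'   (gene_a < gene_b), one row per pair; no gene appears twice.
#' @export
rbhPairs <- function(table, evalueMax = 1e-5) {
  tab <- table[table$evalue <= evalueMax & table$query != table$subject, ,
               drop = FALSE]
  if (!nrow(tab))
    return(data.frame(gene_a = character(), gene_b = character()))
  o <- order(tab$query, -tab$score, tab$evalue, tab$subject)
  tab <- tab[o, , drop = FALSE]
  best <- tab[!duplicated(tab$query), , drop = FALSE]
  bestOf <- setNames(best$subject, best$query)
  mutual <- !is.na(bestOf[bestOf]) & bestOf[bestOf] == names(bestOf)
  q <- names(bestOf)[mutual]
  s <- unname(bestOf[mutual])
  a <- pmin(q, s); b <- pmax(q, s)
  df <- unique(data.frame(gene_a = a, gene_b = b))
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a BLAST tabular (outfmt 6) similarity table
#'
#' @param path 12-column tab-separated file (qseqid sseqid pident length
#'   mismatch gapopen qstart qend sstart send evalue bitscore).
#' @return data.frame with columns `query`, `subject`, `score`
#'   (bitscore), `evalue`, usable by [rbhPairs()].
#' @export
readSimilarityTable <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("expected 12 outfmt-6 columns")
  data.frame(query = df[[1]], subject = df[[2]],
             score = df[[12]], evalue = df[[11]])
}

.perms <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

.codonSynSites <- function(codon, code) {
  nt <- c("A", "C", "G", "T")
  aa <- code[[codon]]
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(nt, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (code[[mut]] != "*" && code[[mut]] == aa) s <- s + 1 / 3
    }
  }
  s
}

.codonPairDiffs <- function(ca, cb, code) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  d <- length(pos)
  if (d == 0) return(c(sd = 0, nd = 0))
  countPath <- function(ord, allowStops) {
    cur <- ca; sd <- 0; nd <- 0
    for (p in pos[ord]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (!allowStops && code[[nxt]] == "*" && nxt != cb) return(NULL)
      if (code[[cur]] != "*" && code[[cur]] == code[[nxt]])
        sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  paths <- lapply(.perms[[d]], countPath, allowStops = FALSE)
  paths <- paths[!vapply(paths, is.null, logical(1))]
  if (!length(paths))  # all pathways blocked by stops: fall back to all
    paths <- lapply(.perms[[d]], countPath, allowStops = TRUE)
  Reduce(`+`, paths) / length(paths)
}

#' Nei-Gojobori (1986) dN/dS with Jukes-Cantor correction
#'
#' Counting-method estimator on a pair of aligned, gap-free CDS
#' sequences.  Synonymous and non-synonymous site counts are averaged
#' over the two sequences (each third of a codon position counts
#' fractionally by how many of its three possible changes are
#' synonymous; changes to stop codons count as non-synonymous).
#' Observed differences within a codon are resolved by averaging the
#' synonymous/non-synonymous step counts over all shortest substitution
#' pathways, excluding pathways through stop codons.  The proportions
#' pS and pN are corrected for multiple hits with Jukes-Cantor:
#' \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3}p)}; a proportion at or above
#' 3/4 leaves the corrected rate undefined (flagged).
#'
#' @param cdsA,cdsB character strings (or `DNAString`s) of equal length,
#'   a multiple of 3, A/C/G/T only, with no internal stop codon (a shared
#'   terminal stop codon is dropped).
#' @return list: `dN`, `dS`, `omega` (`NA` when `dS` is 0 or undefined),
#'   `pN`, `pS`, `Sd`, `Nd`, `S`, `N`, `flag` (`"ok"`, `"saturated"`).
#' @export
ng86dNdS <- function(cdsA, cdsB) {
  a <- toupper(as.character(cdsA)); b <- toupper(as.character(cdsB))
  if (nchar(a) != nchar(b)) stop("sequences must be aligned: length mismatch")
  if (nchar(a) %% 3 != 0) stop("length must be a multiple of 3")
  if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b))
    stop("sequences must contain only A/C/G/T (gap-free alignment)")
  code <- as.list(Biostrings::GENETIC_CODE)
  nc <- nchar(a) / 3
  codA <- substring(a, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  codB <- substring(b, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  aaA <- unlist(code[codA]); aaB <- unlist(code[codB])
  if (nc > 1 && aaA[nc] == "*" && aaB[nc] == "*") {
    codA <- codA[-nc]; codB <- codB[-nc]
    aaA <- aaA[-nc]; aaB <- aaB[-nc]
    nc <- nc - 1
  }
  if (any(aaA == "*") || any(aaB == "*"))
    stop("internal stop codon")
  sA <- sum(vapply(codA, .codonSynSites, numeric(1), code = code))
  sB <- sum(vapply(codB, .codonSynSites, numeric(1), code = code))
  S <- (sA + sB) / 2
  N <- 3 * nc - S
  diffs <- mapply(function(x, y) .codonPairDiffs(x, y, code), codA, codB)
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  dS <- jc(pS); dN <- jc(pN)
  flag <- if (is.na(dS) || is.na(dN)) "saturated" else "ok"
  omega <- if (!is.na(dN) && !is.na(dS) && dS > 0) dN / dS else NA_real_
  list(dN = dN, dS = dS, omega = omega, pN = pN, pS = pS,
       Sd = Sd, Nd = Nd, S = S, N = N, flag = flag)
}

#' Divergence time from synonymous substitution rate
#'
#' \eqn{T = dS / (2\lambda) \times 10^{-6}} million years, with
#' \eqn{\lambda} the synonymous mutation rate per site per year
#' (default \eqn{6.5 \times 10^{-9}}, a grass-lineage clock).
#'
#' @param dS synonymous substitution rate(s), non-negative.
#' @param lambda mutation rate per site per year (> 0).
#' @return divergence time(s) in Mya.
#' @export
divergenceTime <- function(dS, lambda = 6.5e-9) {
  if (any(dS < 0, na.rm = TRUE)) stop("dS must be non-negative")
  if (lambda <= 0) stop("lambda must be positive")
  dS / (2 * lambda) * 1e-6
}

#' Estimate dN/dS, omega and divergence time for ortholog pairs
#'
#' Runs [ng86dNdS()] on each aligned CDS pair, converts dS to divergence
#' time, and flags pairs with `dS >= dsMax` as excluded (the analysis set
#' is restricted to recent divergences where the counting estimator is
#' reliable).
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param cds named character vector (or `DNAStringSet`) of aligned CDS
#'   sequences, names covering all pair members.
#' @param lambda clock rate for [divergenceTime()].
#' @param dsMax exclusion threshold on dS (default 0.3).
#' @return data.frame: gene_a, gene_b, dN, dS, omega, t_mya, excluded,
#'   flag.
#' @export
orthologDnDs <- function(pairs, cds, lambda = 6.5e-9, dsMax = 0.3) {
  cds <- setNames(as.character(cds), names(cds))
  miss <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(cds))
  if (length(miss))
    stop("missing CDS for: ", paste(miss, collapse = ", "))
  res <- lapply(seq_len(nrow(pairs)), function(i)
    ng86dNdS(cds[[pairs$gene_a[i]]], cds[[pairs$gene_b[i]]]))
  dN <- vapply(res, `[[`, numeric(1), "dN")
  dS <- vapply(res, `[[`, numeric(1), "dS")
  data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
             dN = dN, dS = dS,
             omega = vapply(res, `[[`, numeric(1), "omega"),
             t_mya = ifelse(is.na(dS), NA_real_,
                            divergenceTime(pmax(dS, 0), lambda)),
             excluded = is.na(dS) | dS >= dsMax,
             flag = vapply(res, `[[`, character(1), "flag"))
}

#' Classify a homoeologous orthogroup by subgenome member counts
#'
#' @param members named list of member gene ids per subgenome (names
#'   `A`, `B`, `D`) or an integer vector of counts.
#' @return list: `counts` (named integer), `label` (e.g. `"1:1:1"`),
#'   `is_triad` (exactly one member in each subgenome), `is_singleton`
#'   (a single member in a single subgenome).
#' @export
classifyOrthogroup <- function(members) {
  counts <- if (is.list(members)) vapply(members, length, integer(1))
            else as.integer(members)
  if (is.null(names(counts))) names(counts) <- c("A", "B", "D")
  list(counts = counts,
       label = paste(counts, collapse = ":"),
       is_triad = all(counts == 1L),
       is_singleton = sum(counts > 0L) == 1L && max(counts) == 1L)
}

#' Classify many orthogroups from a gene table and a subgenome map
#'
#' @param groupTable data.frame with columns `group_id`, `gene_id`.
#' @param subgenomes named character vector mapping gene id to
#'   `"A"`/`"B"`/`"D"`; every gene must be labelled.
#' @return data.frame: group_id, A, B, D, label, is_triad, is_singleton.
#' @export
classifyOrthogroups <- function(groupTable, subgenomes) {
  sg <- subgenomes[groupTable$gene_id]
  if (anyNA(sg))
    stop("unlabelled gene(s): ",
         paste(groupTable$gene_id[is.na(sg)], collapse = ", "))
  rows <- lapply(split(as.character(sg), groupTable$group_id), function(s) {
    cnt <- vapply(c("A", "B", "D"), function(x) sum(s == x), integer(1))
    cl <- classifyOrthogroup(cnt)
    data.frame(A = cnt[["A"]], B = cnt[["B"]], D = cnt[["D"]],
               label = cl$label, is_triad = cl$is_triad,
               is_singleton = cl$is_singleton)
  })
  df <- do.call(rbind, rows)
  df <- cbind(group_id = rownames(df), df)
  rownames(df) <- NULL
  df
}
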