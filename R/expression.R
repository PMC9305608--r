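#' Filter expressed genes from an FPKM matrix
#'
#' A gene is kept when its FPKM is positive in at least `minLibraries`
#' libraries.  The default of 1 treats any detected expression as
#' expressed; pass 2 for the stricter "more than one sample" reading.
#'
#' @param fpkm genes x libraries matrix (non-negative).
#' @param minLibraries minimum libraries with FPKM > 0 (>= 1).
#' @return character vector of expressed gene ids.
#' @export
filterExpressed <- function(fpkm, minLibraries = 1) {
  stopifnot(minLibraries >= 1)
  rownames(fpkm)[rowSums(fpkm > 0) >= minLibraries]
}

#' Tissue-specificity index tau for one expression profile
#'
#' On log-transformed expression \eqn{\hat x_j = \log_2(FPKM_j + 1)}:
#' \deqn{\tau = \frac{\sum_{j=1}^{n} (1 - \hat x_j / \hat x_{max})}{n - 1}}
#' tau is 0 for a gene expressed equally in all libraries and approaches 1
#' as expression concentrates into a single library (exactly 1 under the
#' +1 offset when all other libraries are at zero).  The result is clamped
#' to [0, 1] against floating-point noise.
#'
#' @param fpkm numeric vector of FPKM values over >= 2 libraries.
#' @return tau in [0, 1]; `NA` for an all-zero profile.
#' @export
tauIndex <- function(fpkm) {
  if (length(fpkm) < 2) stop("tau needs at least two libraries")
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  x <- log2(fpkm + 1)
  xmax <- max(x)
  if (xmax == 0) return(NA_real_)
  tau <- sum(1 - x / xmax) / (length(x) - 1)
  min(max(tau, 0), 1)
}

#' Tau profile for every expressed gene of a matrix
#'
#' @param fpkm genes x libraries matrix.
#' @param minLibraries expressed-gene threshold for [filterExpressed()].
#' @return data.frame: gene_id, expressed, tau (`NA` for non-expressed
#'   genes).
#' @export
tauProfile <- function(fpkm, minLibraries = 1) {
  expressed <- rownames(fpkm) %in% filterExpressed(fpkm, minLibraries)
  tau <- rep(NA_real_, nrow(fpkm))
  tau[expressed] <- apply(fpkm[expressed, , drop = FALSE], 1, tauIndex)
  data.frame(gene_id = rownames(fpkm), expressed = expressed, tau = tau)
}

.zscoreLog <- function(fpkm) {
  x <- log2(fpkm + 1)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, sd)
  z <- (x - mu) / ifelse(sdv > 0, sdv, 1)  # flat profiles stay at zero
  z
}

#' Cluster expression profiles into k groups
#'
#' Hierarchical agglomerative clustering (Ward linkage on Euclidean
#' distances) of per-gene z-scored log2(FPKM + 1) profiles, with the tree
#' cut at `k`.  Deterministic: no random initialisation is involved.
#'
#' @param fpkm genes x libraries matrix (expressed genes only).
#' @param k number of clusters (default 7).
#' @return named integer vector of cluster labels (1..k).
#' @export
clusterProfiles <- function(fpkm, k = 7) {
  if (k < 2) stop("k must be at least 2")
  if (nrow(fpkm) < k) stop("fewer genes than clusters")
  z <- .zscoreLog(fpkm)
  hc <- hclust(dist(z, method = "euclidean"), method = "ward.D2")
  cutree(hc, k = k)
}

#' Family-in-cluster hypergeometric enrichment
#'
#' For every (family, cluster) pair, the one-sided hypergeometric tail
#' probability of drawing at least the observed overlap when the
#' cluster's genes are sampled from the expressed-gene universe, with
#' Benjamini-Hochberg FDR across all pairs; significance is called at
#' FDR < 0.05.
#'
#' @param labels named integer vector of cluster labels (the universe).
#' @param familyMap named character vector: family of every labelled
#'   gene.
#' @param alpha FDR significance level.
#' @return data.frame: family, cluster, overlap, family_size,
#'   cluster_size, universe, p, fdr, significant.
#' @export
familyClusterEnrichment <- function(labels, familyMap, alpha = 0.05) {
  fam <- familyMap[names(labels)]
  if (anyNA(fam))
    stop("labelled gene(s) without family: ",
         paste(names(labels)[is.na(fam)], collapse = ", "))
  U <- length(labels)
  rows <- list()
  for (f in sort(unique(fam))) {
    m <- sum(fam == f)
    for (cl in sort(unique(labels))) {
      kk <- sum(labels == cl)
      ov <- sum(fam == f & labels == cl)
      p <- phyper(ov - 1, m, U - m, kk, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        family = f, cluster = cl, overlap = ov, family_size = m,
        cluster_size = kk, universe = U, p = p)
    }
  }
  df <- do.call(rbind, rows)
  df$fdr <- p.adjust(df$p, method = "BH")
  df$significant <- df$fdr < alpha
  df
}

#' Correlation-ranked co-expression partners of a gene
#'
#' Partners are ranked by Pearson correlation of log2(FPKM + 1) profiles
#' with the target gene, descending, ties broken by gene id, self
#' excluded.  This is a transparent stand-in for network-based
#' intramodular connectivity rankings.
#'
#' @param fpkm genes x libraries matrix.
#' @param gene target gene id (must have a non-constant profile).
#' @param k number of partners (truncated to the available genes).
#' @return data.frame: gene_id, r, sorted by descending correlation.
#' @export
topCoexpressed <- function(fpkm, gene, k = 20) {
  stopifnot(k >= 1)
  if (!gene %in% rownames(fpkm)) stop("unknown gene: ", gene)
  x <- log2(fpkm + 1)
  target <- x[gene, ]
  if (sd(target) == 0)
    stop("constant expression profile: correlation undefined for ", gene)
  others <- setdiff(rownames(x), gene)
  sds <- apply(x[others, , drop = FALSE], 1, sd)
  others <- others[sds > 0]
  r <- as.vector(cor(target, t(x[others, , drop = FALSE])))
  df <- data.frame(gene_id = others, r = r)
  df <- df[order(-df$r, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  head(df, k)
}
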