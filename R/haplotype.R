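#' HaplotypeCatalog: per-gene diplotype strings across a sample panel
#'
#' For one gene, records the SNP sites used (genic plus upstream and
#' downstream flanks, which covers CDS, UTR and promoter SNPs) and each
#' sample's diplotype string: the two phased alleles at every site,
#' written as nucleotide letters, two letters per site in genomic order
#' (e.g. `"CCAACCAA"` for four sites).  Within a site the two letters are
#' written in alphabetical order, so the string represents the unordered
#' genotype and is independent of haplotype phase ordering — the
#' convention under which published per-subgroup haplotype percentages
#' count samples, not haploid genomes.
#'
#' @slot geneId gene identifier.
#' @slot sites data.frame of the SNPs used (chrom, pos, ref, alt).
#' @slot diplotypes named character vector, one string per sample.
#' @slot subpop named character vector of subpopulation labels.
#' @seealso [buildGeneHaplotypes()], [haplotypeFrequencies()]
#' @export
setClass("HaplotypeCatalog",
  representation(geneId = "character", sites = "data.frame",
                 diplotypes = "character", subpop = "character"))

setValidity("HaplotypeCatalog", function(object) {
  msg <- character()
  if (length(object@diplotypes) != length(object@subpop))
    msg <- c(msg, "diplotypes and subpop must be parallel")
  if (nrow(object@sites) &&
      any(nchar(object@diplotypes) != 2L * nrow(object@sites)))
    msg <- c(msg, "diplotype strings must have 2 letters per site")
  if (length(msg)) msg else TRUE
})

setMethod("show", "HaplotypeCatalog", function(object) {
  cat("HaplotypeCatalog for", object@geneId, "—",
      nrow(object@sites), "SNPs,",
      length(unique(object@diplotypes)), "distinct diplotypes across",
      length(object@diplotypes), "samples\n")
})

#' Build the diplotype catalog of one gene
#'
#' Selects the panel SNPs within the gene body extended by `flankBp` on
#' both sides (capturing upstream/promoter, downstream, CDS and UTR
#' variants) and concatenates, per sample, the nucleotide letters of its
#' two phased alleles at each site in genomic order.  Returns `NULL` when
#' no SNP falls in the selected span (such genes are excluded from
#' haplotype analysis).
#'
#' @param panel A [PhasedPanel-class] (fully phased by construction).
#' @param gene a length-1 named `GRanges` (the gene body) or a
#'   [GeneModels-class] together with `geneId`.
#' @param geneId gene id, required when `gene` is a [GeneModels-class].
#' @param flankBp flank in bp added on both sides (default 2000, the
#'   promoter/downstream convention of [assignSiteRegions()]).
#' @return A [HaplotypeCatalog-class], or `NULL` if no SNP is selected.
#' @export
buildGeneHaplotypes <- function(panel, gene, geneId = NULL,
                                flankBp = 2000) {
  if (is(gene, "GeneModels")) {
    if (is.null(geneId)) stop("geneId required with a GeneModels input")
    gene <- geneRanges(gene)[geneId]
  }
  if (length(gene) != 1 || is.null(names(gene)))
    stop("gene must be a single named range")
  chrom <- as.character(GenomicRanges::seqnames(gene))
  lo <- GenomicRanges::start(gene) - flankBp
  hi <- GenomicRanges::end(gene) + flankBp
  st <- siteTable(panel)
  idx <- which(st$chrom == chrom & st$pos >= lo & st$pos <= hi)
  if (!length(idx)) return(NULL)
  sites <- st[idx, , drop = FALSE]
  H <- hapMatrix(panel)
  ns <- nSamples(panel)
  h1 <- H[seq(1, 2 * ns, by = 2), idx, drop = FALSE]
  h2 <- H[seq(2, 2 * ns, by = 2), idx, drop = FALSE]
  refM <- matrix(sites$ref, nrow = ns, ncol = length(idx), byrow = TRUE)
  altM <- matrix(sites$alt, nrow = ns, ncol = length(idx), byrow = TRUE)
  l1 <- ifelse(h1 == 1L, altM, refM)
  l2 <- ifelse(h2 == 1L, altM, refM)
  # alphabetical order within a site: phase-order invariant genotype letters
  first <- ifelse(l1 <= l2, l1, l2)
  second <- ifelse(l1 <= l2, l2, l1)
  pair <- matrix(paste0(first, second), nrow = ns)
  diplo <- apply(pair, 1, paste, collapse = "")
  new("HaplotypeCatalog", geneId = names(gene), sites = sites,
      diplotypes = setNames(diplo, sampleIds(panel)),
      subpop = subpopLabels(panel))
}

#' Build catalogs for every gene of a model set
#'
#' @param panel A [PhasedPanel-class].
#' @param genes A [GeneModels-class].
#' @param flankBp flank in bp (see [buildGeneHaplotypes()]).
#' @return named list of [HaplotypeCatalog-class]; genes without any
#'   selected SNP are omitted.
#' @export
buildHaplotypeCatalogs <- function(panel, genes, flankBp = 2000) {
  g <- geneRanges(genes)
  out <- lapply(names(g), function(id)
    buildGeneHaplotypes(panel, g[id], flankBp = flankBp))
  names(out) <- names(g)
  out[!vapply(out, is.null, logical(1))]
}

#' Round half away from zero (display rounding for percentages)
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded values (exact .5 cases round up in magnitude).
#' @export
roundHalfUp <- function(x, digits = 2)
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits

#' Per-subpopulation haplotype frequency table
#'
#' Frequency of each diplotype class within each subpopulation: samples
#' carrying the diplotype divided by the subpopulation size.  `pct` is the
#' display percentage rounded half-up to two decimals; comparisons should
#' use the full-precision `frequency`.
#'
#' @param catalog A [HaplotypeCatalog-class].
#' @return data.frame: gene_id, subpop, haplotype, count, frequency, pct,
#'   sorted by subpop then descending frequency (ties by haplotype).
#' @export
haplotypeFrequencies <- function(catalog) {
  sp <- catalog@subpop
  if (!length(sp)) stop("empty panel")
  rows <- lapply(sort(unique(sp)), function(p) {
    d <- catalog@diplotypes[sp == p]
    tab <- table(d)
    data.frame(gene_id = catalog@geneId, subpop = p,
               haplotype = names(tab), count = as.integer(tab),
               frequency = as.numeric(tab) / length(d))
  })
  df <- do.call(rbind, rows)
  df$pct <- roundHalfUp(df$frequency * 100, 2)
  df <- df[order(df$subpop, -df$frequency, df$haplotype), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Major haplotype per subpopulation
#'
#' The major haplotype of a subpopulation is the (necessarily unique)
#' diplotype carried by strictly more than `threshold` of its samples;
#' `NA` when no class exceeds the threshold.
#'
#' @param freqTable output of [haplotypeFrequencies()] (may span several
#'   genes if row-bound).
#' @param threshold frequency threshold in (0, 1]; default 0.5 (the
#'   \"more than half\" rule).
#' @return data.frame: gene_id, subpop, haplotype (or NA), frequency.
#' @export
majorHaplotypes <- function(freqTable, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  key <- interaction(freqTable$gene_id, freqTable$subpop, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(freqTable)), key), function(i) {
    f <- freqTable[i, , drop = FALSE]
    j <- which(f$frequency > threshold)
    data.frame(gene_id = f$gene_id[1], subpop = f$subpop[1],
               haplotype = if (length(j)) f$haplotype[j[1]]
                           else NA_character_,
               frequency = if (length(j)) f$frequency[j[1]] else NA_real_)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df[order(df$gene_id, df$subpop), , drop = FALSE]
}

#' Track major-haplotype replacements along an ordered lineage series
#'
#' Given per-gene major haplotypes and an ordered series of lineages (for
#' example wild emmer, domesticated emmer, durum, landrace, cultivar),
#' reports every consecutive pair where the major haplotype differs,
#' including transitions between \"no major\" and \"some major\".  Genes
#' with no major haplotype in any listed lineage contribute no events but
#' are included in the totals.
#'
#' @param majorTable output of [majorHaplotypes()] (may span genes).
#' @param orderedLineages character vector of subpopulation names in
#'   series order; all must occur in `majorTable$subpop`.
#' @return list with `events` (data.frame gene_id, from_lineage,
#'   to_lineage, from_hap, to_hap) and `summary` (n_genes, n_with_major,
#'   n_with_shift).
#' @export
trackMajorShifts <- function(majorTable, orderedLineages) {
  unknown <- setdiff(orderedLineages, unique(majorTable$subpop))
  if (length(unknown))
    stop("unknown lineage(s): ", paste(unknown, collapse = ", "))
  genes <- unique(majorTable$gene_id)
  ev <- list()
  nWithMajor <- 0L; nWithShift <- 0L
  for (g in genes) {
    sub <- majorTable[majorTable$gene_id == g, , drop = FALSE]
    maj <- setNames(sub$haplotype, sub$subpop)[orderedLineages]
    if (all(is.na(maj))) next
    nWithMajor <- nWithMajor + 1L
    prev <- maj[-length(maj)]; nxt <- maj[-1]
    differ <- which((is.na(prev) != is.na(nxt)) |
                    (!is.na(prev) & !is.na(nxt) & prev != nxt))
    if (length(differ)) {
      nWithShift <- nWithShift + 1L
      ev[[g]] <- data.frame(
        gene_id = g,
        from_lineage = orderedLineages[differ],
        to_lineage = orderedLineages[differ + 1],
        from_hap = unname(prev[differ]), to_hap = unname(nxt[differ]))
    }
  }
  events <- if (length(ev)) do.call(rbind, c(ev, make.row.names = FALSE))
            else data.frame(gene_id = character(),
                            from_lineage = character(),
                            to_lineage = character(),
                            from_hap = character(), to_hap = character())
  list(events = events,
       summary = list(n_genes = length(genes),
                      n_with_major = nWithMajor,
                      n_with_shift = nWithShift))
}
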