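#' Assign each panel SNP to a gene-relative region class
#'
#' Labels every site as `genic`, `promoter`, `downstream` or
#' `intergenic`.  The promoter is `promoterBp` upstream of the
#' transcription start site, strand-aware (for a minus-strand gene the
#' upstream side is past the higher coordinate); `downstream` is the
#' symmetric flank past the gene end.  Genic status takes precedence over
#' the promoter/downstream flank of a neighbouring gene; when a site is
#' eligible for the same class from several genes, the gene whose TSS is
#' nearest wins, then the lexicographically smaller gene id.  For genic
#' sites a sub-label distinguishes `UTR` (inside an annotated UTR),
#' `CDS` (inside an exon outside the UTRs) and `intron`.
#'
#' @param panel A [PhasedPanel-class].
#' @param genes A [GeneModels-class].
#' @param promoterBp upstream flank in bp (> 0; default 2000).
#' @param downstreamBp downstream flank in bp (default 2000).
#' @return data.frame: site (index), chrom, pos, label, sublabel
#'   (`NA` unless genic), gene_id (`NA` for intergenic).
#' @export
assignSiteRegions <- function(panel, genes, promoterBp = 2000,
                              downstreamBp = 2000) {
  stopifnot(promoterBp > 0, downstreamBp > 0)
  st <- siteTable(panel)
  sgr <- GenomicRanges::GRanges(st$chrom, IRanges::IRanges(st$pos, st$pos))
  g <- geneRanges(genes)
  tss <- GenomicRanges::start(GenomicRanges::resize(g, 1, fix = "start"))
  label <- rep("intergenic", nrow(st))
  gene <- rep(NA_character_, nrow(st))
  sublabel <- rep(NA_character_, nrow(st))

  assign <- function(targets, class) {
    ov <- GenomicRanges::findOverlaps(sgr, targets, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    open <- label[q] == "intergenic"
    q <- q[open]; s <- s[open]
    if (!length(q)) return(invisible())
    # resolve multi-gene hits: nearest TSS, then lexicographic gene id
    d <- abs(st$pos[q] - tss[s])
    o <- order(q, d, names(g)[s])
    q <- q[o]; s <- s[o]
    first <- !duplicated(q)
    label[q[first]] <<- class
    gene[q[first]] <<- names(g)[s[first]]
    invisible()
  }
  assign(g, "genic")
  assign(GenomicRanges::trim(suppressWarnings(
    GenomicRanges::promoters(g, upstream = promoterBp, downstream = 0))),
    "promoter")
  assign(GenomicRanges::trim(suppressWarnings(
    GenomicRanges::flank(g, width = downstreamBp, start = FALSE))),
    "downstream")

  genic <- which(label == "genic")
  if (length(genic)) {
    inFeature <- function(i, grl) {
      gr <- grl[[gene[i]]]
      length(gr) && any(st$pos[i] >= GenomicRanges::start(gr) &
                        st$pos[i] <= GenomicRanges::end(gr))
    }
    for (i in genic) {
      sublabel[i] <-
        if (inFeature(i, utr5Ranges(genes)) ||
            inFeature(i, utr3Ranges(genes))) "UTR"
        else if (inFeature(i, exonRanges(genes))) "CDS"
        else "intron"
    }
  }
  data.frame(site = seq_len(nrow(st)), chrom = st$chrom, pos = st$pos,
             label = label, sublabel = sublabel, gene_id = gene)
}

#' Segregating-SNP counts per region class and subpopulation
#'
#' Counts, for each subpopulation, the sites that are polymorphic within
#' it (0 < alternate-allele count < 2N), broken down by the region label
#' from [assignSiteRegions()].
#'
#' @param labels output of [assignSiteRegions()].
#' @param panel the same [PhasedPanel-class].
#' @param bySubpopulation count per subpopulation (default) or over the
#'   whole panel (one row set labelled `"all"`).
#' @return data.frame: subpop, label, n_sites.
#' @export
snpRegionCounts <- function(labels, panel, bySubpopulation = TRUE) {
  classes <- c("genic", "promoter", "downstream", "intergenic")
  pops <- if (bySubpopulation) sort(unique(panel@subpop)) else "all"
  rows <- lapply(pops, function(p) {
    sub <- if (identical(p, "all")) panel
           else selectSamples(panel, subpop = p)
    ac <- colSums(hapMatrix(sub))
    seg <- ac > 0 & ac < nrow(hapMatrix(sub))
    data.frame(subpop = p, label = classes,
               n_sites = vapply(classes, function(cl)
                 sum(seg & labels$label == cl), integer(1)))
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' Gene-structure summary contrasting two gene classes
#'
#' Per class (`TF` = ids in `tfIds`, `non_TF` = the rest): exon count,
#' transcript (gene-span) length, cDNA (summed exon) length and 5'/3'
#' UTR lengths — medians and means — with a Wilcoxon rank-sum p-value for
#' each contrast.
#'
#' @param genes A [GeneModels-class].
#' @param tfIds character gene ids of the focal class.
#' @return data.frame: metric, median_tf, median_other, mean_tf,
#'   mean_other, p (rank-sum).
#' @export
geneStructureSummary <- function(genes, tfIds) {
  g <- geneRanges(genes)
  isTf <- names(g) %in% tfIds
  if (!any(isTf) || all(isTf))
    stop("both gene classes must be non-empty")
  exw <- vapply(exonRanges(genes), function(e)
    sum(GenomicRanges::width(e)), numeric(1))
  exn <- vapply(exonRanges(genes), length, integer(1))
  u5 <- vapply(utr5Ranges(genes), function(e)
    sum(GenomicRanges::width(e)), numeric(1))
  u3 <- vapply(utr3Ranges(genes), function(e)
    sum(GenomicRanges::width(e)), numeric(1))
  metrics <- list(exon_count = exn,
                  transcript_length = GenomicRanges::width(g),
                  cdna_length = ifelse(exn > 0, exw,
                                       GenomicRanges::width(g)),
                  utr5_length = u5, utr3_length = u3)
  rows <- lapply(names(metrics), function(m) {
    v <- metrics[[m]]
    p <- tryCatch(
      suppressWarnings(wilcox.test(v[isTf], v[!isTf])$p.value),
      error = function(e) NA_real_)
    data.frame(metric = m,
               median_tf = median(v[isTf]),
               median_other = median(v[!isTf]),
               mean_tf = mean(v[isTf]), mean_other = mean(v[!isTf]),
               p = p)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}
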