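#' Co-locate genes with QTL intervals
#'
#' A gene is considered potentially related to a trait when it overlaps
#' (any base pair) a QTL associated with that trait; a gene may carry
#' several traits.  QTLs on chromosomes absent from the gene set are
#' skipped with a warning.
#'
#' @param genes A [GeneModels-class] or named `GRanges`.
#' @param qtls `GRanges` with a `trait` metadata column.
#' @return data.frame of unique (gene_id, trait) pairs, plus a
#'   `"trait_counts"` attribute (genes per trait).
#' @export
colocateQtl <- function(genes, qtls) {
  g <- if (is(genes, "GeneModels")) geneRanges(genes) else genes
  known <- as.character(GenomicRanges::seqnames(qtls)) %in%
    unique(as.character(GenomicRanges::seqnames(g)))
  if (any(!known)) {
    warning(sum(!known), " QTL(s) on unknown chromosome(s) skipped")
    qtls <- qtls[known]
  }
  ov <- GenomicRanges::findOverlaps(g, qtls, ignore.strand = TRUE)
  df <- unique(data.frame(
    gene_id = names(g)[S4Vectors::queryHits(ov)],
    trait = qtls$trait[S4Vectors::subjectHits(ov)]))
  df <- df[order(df$gene_id, df$trait), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "trait_counts") <- table(df$trait)
  df
}

#' Multi-evidence candidate-gene report
#'
#' Combines the evidence layers of the pipeline into one row per gene:
#' membership in domestication/improvement selective regions, QTL
#' co-location (with the trait list), presence of a major haplotype, a
#' major-haplotype shift along the lineage series, expression, tau and
#' expression cluster.  The headline tier contains the genes supported by
#' all four evidence classes (selective region, QTL, major haplotype,
#' expressed) — the set-intersection logic of multi-omic candidate
#' screens; beyond that, genes are ordered by how many evidence flags
#' they carry, then by id.
#'
#' @param genes A [GeneModels-class] (defines the gene universe and
#'   families).
#' @param sweepDomestication,sweepImprovement character vectors of gene
#'   ids inside selective regions of each process (see
#'   [genesInRegions()]).
#' @param qtlMap data.frame from [colocateQtl()].
#' @param majorTable data.frame from [majorHaplotypes()] over all genes.
#' @param shiftEvents data.frame of events from [trackMajorShifts()]
#'   (may be `NULL`).
#' @param tauTable data.frame from [tauProfile()], optionally with a
#'   `cluster` column.
#' @return data.frame, one row per gene: gene_id, family, flags
#'   `in_sweep_domestication`, `in_sweep_improvement`, `in_qtl`,
#'   `has_major_haplotype`, `major_shift_observed`, `expressed`,
#'   plus `traits`, `tau`, `cluster`, `evidence_count`, `headline`;
#'   sorted by descending evidence count then gene id.
#' @export
prioritizeCandidates <- function(genes, sweepDomestication,
                                 sweepImprovement, qtlMap, majorTable,
                                 shiftEvents = NULL, tauTable = NULL) {
  ids <- geneIds(genes)
  checkIds <- function(x, what) {
    bad <- setdiff(x, ids)
    if (length(bad))
      stop("gene ids in ", what, " unknown to the gene set: ",
           paste(bad, collapse = ", "))
  }
  checkIds(sweepDomestication, "sweepDomestication")
  checkIds(sweepImprovement, "sweepImprovement")
  checkIds(qtlMap$gene_id, "qtlMap")
  checkIds(majorTable$gene_id, "majorTable")
  if (!is.null(tauTable)) checkIds(tauTable$gene_id, "tauTable")

  fam <- geneFamilies(genes)
  hasMajor <- tapply(!is.na(majorTable$haplotype), majorTable$gene_id, any)
  traits <- vapply(split(qtlMap$trait, qtlMap$gene_id),
                   function(x) paste(sort(unique(x)), collapse = ","),
                   character(1))
  shifted <- if (!is.null(shiftEvents) && nrow(shiftEvents))
    unique(shiftEvents$gene_id) else character()
  expressed <- setNames(rep(FALSE, length(ids)), ids)
  tau <- setNames(rep(NA_real_, length(ids)), ids)
  cluster <- setNames(rep(NA_integer_, length(ids)), ids)
  if (!is.null(tauTable)) {
    expressed[tauTable$gene_id] <- tauTable$expressed
    tau[tauTable$gene_id] <- tauTable$tau
    if ("cluster" %in% names(tauTable))
      cluster[tauTable$gene_id] <- tauTable$cluster
  }
  df <- data.frame(
    gene_id = ids,
    family = unname(fam[ids]),
    in_sweep_domestication = ids %in% sweepDomestication,
    in_sweep_improvement = ids %in% sweepImprovement,
    in_qtl = ids %in% qtlMap$gene_id,
    traits = ifelse(ids %in% names(traits), traits[ids], ""),
    has_major_haplotype = ids %in% names(hasMajor)[hasMajor %in% TRUE],
    major_shift_observed = ids %in% shifted,
    expressed = unname(expressed[ids]),
    tau = unname(tau[ids]),
    cluster = unname(cluster[ids]))
  flags <- c("in_sweep_domestication", "in_sweep_improvement", "in_qtl",
             "has_major_haplotype", "major_shift_observed", "expressed")
  df$evidence_count <- rowSums(df[flags])
  df$headline <- (df$in_sweep_domestication | df$in_sweep_improvement) &
    df$in_qtl & df$has_major_haplotype & df$expressed
  df <- df[order(-df$evidence_count, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}
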