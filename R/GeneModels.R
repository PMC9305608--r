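#' @importClassesFrom GenomicRanges GRanges GRangesList
NULL

#' GeneModels: located, stranded gene records with structure and family
#'
#' Holds gene bodies as a named `GRanges` (one range per gene, with a
#' `family` metadata column and a `subgenome` label derived from the
#' chromosome name), plus per-gene exon and 5'/3' UTR ranges.  Only one
#' transcript per gene is represented; when a GFF3 file carries several,
#' the reader keeps the first (lowest-sorting) transcript identifier.
#'
#' @slot genes `GRanges`, names are gene ids; metadata columns `family`
#'   and `subgenome`.
#' @slot exons `GRangesList` named by gene id; exons sorted,
#'   non-overlapping, within the gene body.
#' @slot utr5,utr3 `GRangesList` named by gene id (possibly empty
#'   elements).
#' @seealso [readGeneModels()], [synthesizeAnnotations()]
#' @export
setClass("GeneModels",
  representation(genes = "GRanges", exons = "GRangesList",
                 utr5 = "GRangesList", utr3 = "GRangesList"))

setValidity("GeneModels", function(object) {
  msg <- character()
  g <- object@genes
  if (is.null(names(g)) || anyDuplicated(names(g)))
    msg <- c(msg, "genes must be uniquely named by gene id")
  if (!all(names(object@exons) == names(g)))
    msg <- c(msg, "exons must be named parallel to genes")
  if (length(g)) {
    within <- vapply(seq_along(g), function(i) {
      ex <- object@exons[[i]]
      if (!length(ex)) return(TRUE)
      all(GenomicRanges::start(ex) >= GenomicRanges::start(g[i]) &
          GenomicRanges::end(ex) <= GenomicRanges::end(g[i]))
    }, logical(1))
    if (!all(within))
      msg <- c(msg, paste("exon outside gene body for:",
                          paste(names(g)[!within], collapse = ", ")))
    ok <- vapply(object@exons, function(ex) {
      if (length(ex) < 2) return(TRUE)
      s <- GenomicRanges::start(ex); e <- GenomicRanges::end(ex)
      all(diff(s) > 0) && all(s[-1] > e[-length(e)])
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, "exons must be sorted and non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' Infer the subgenome label from a chromosome name
#'
#' Wheat-style chromosome names ending in A, B or D (e.g. `chr1A`,
#' `Chr4D`) map to that subgenome; anything else is labelled
#' `"synthetic"`.
#'
#' @param chrom character chromosome names.
#' @return character vector of labels in `c("A","B","D","synthetic")`.
#' @export
subgenomeOf <- function(chrom) {
  suf <- toupper(substring(chrom, nchar(chrom)))
  ifelse(suf %in% c("A", "B", "D"), suf, "synthetic")
}

.makeGeneModels <- function(genesDf, exonsDf, familyTable = NULL,
                            utr5Df = NULL, utr3Df = NULL) {
  o <- order(genesDf$chrom, genesDf$start, genesDf$gene_id)
  genesDf <- genesDf[o, , drop = FALSE]
  g <- GenomicRanges::GRanges(genesDf$chrom,
         IRanges::IRanges(genesDf$start, genesDf$end),
         strand = genesDf$strand)
  names(g) <- genesDf$gene_id
  fam <- rep(NA_character_, length(g))
  if (!is.null(familyTable)) {
    m <- match(names(g), familyTable$gene_id)
    fam <- familyTable$family[m]
  }
  g$family <- fam
  g$subgenome <- subgenomeOf(as.character(GenomicRanges::seqnames(g)))
  mkList <- function(df) {
    if (is.null(df) || !nrow(df)) {
      grl <- GenomicRanges::GRangesList(lapply(names(g), function(x)
        GenomicRanges::GRanges()))
    } else {
      df <- df[order(df$gene_id, df$start), , drop = FALSE]
      sp <- split(seq_len(nrow(df)), df$gene_id)
      grl <- GenomicRanges::GRangesList(lapply(names(g), function(id) {
        i <- sp[[id]]
        if (is.null(i)) return(GenomicRanges::GRanges())
        GenomicRanges::GRanges(df$chrom[i],
                               IRanges::IRanges(df$start[i], df$end[i]))
      }))
    }
    names(grl) <- names(g)
    grl
  }
  new("GeneModels", genes = g, exons = mkList(exonsDf),
      utr5 = mkList(utr5Df), utr3 = mkList(utr3Df))
}

#' @describeIn GeneModels Gene ids.
#' @param x,object A `GeneModels`.
#' @export
geneIds <- function(x) names(x@genes)

#' @describeIn GeneModels Gene-body `GRanges` (named, with family and
#'   subgenome columns).
#' @export
geneRanges <- function(x) x@genes

#' @describeIn GeneModels Per-gene exon `GRangesList`.
#' @export
exonRanges <- function(x) x@exons

#' @describeIn GeneModels Per-gene 5' UTR `GRangesList`.
#' @export
utr5Ranges <- function(x) x@utr5

#' @describeIn GeneModels Per-gene 3' UTR `GRangesList`.
#' @export
utr3Ranges <- function(x) x@utr3

#' @describeIn GeneModels Family label per gene (named character).
#' @export
geneFamilies <- function(x) setNames(x@genes$family, names(x@genes))

setMethod("show", "GeneModels", function(object) {
  cat("GeneModels:", length(object@genes), "genes on",
      length(unique(as.character(
        GenomicRanges::seqnames(object@genes)))), "chromosome(s);",
      sum(!is.na(object@genes$family)), "with a family label\n")
})
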