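#' Top-quantile threshold (type-7)
#'
#' Linear-interpolation (type-7) quantile of the finite values; the
#' selection rule used throughout the package is value >= threshold.
#'
#' @param values numeric vector.
#' @param q quantile in [0, 1] (0.95 selects the top 5 percent).
#' @return the threshold value.
#' @export
quantileThreshold <- function(values, q) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values to rank")
  unname(quantile(values, q, type = 7))
}

#' Call candidate selective regions from window statistics
#'
#' A window is selected when its pi ratio and/or its Fst lies in the top
#' `1 - q` quantile of the usable windows (type-7 threshold, ties
#' included via >=).  The default rule is the intersection (both
#' statistics in their top tail), the stricter reading of a
#' two-statistic sweep criterion; `rule = "union"` selects on either.
#' Adjacent selected windows on the same chromosome are merged into one
#' region.  Windows flagged insufficient are never selected.  At
#' `q = 1` the top tail is empty by definition and no region is called.
#'
#' @param windowStats data.frame from [scanDiversity()] (columns
#'   chrom, start, end, pi_ratio, fst, insufficient).
#' @param q quantile (default 0.95, the top-5 percent rule).
#' @param rule `"intersection"` (default) or `"union"`.
#' @param contrast,process optional labels copied onto the regions
#'   (e.g. contrast "wild_emmer_vs_dom_emmer", process "domestication").
#' @return data.frame of regions: chrom, start, end, n_windows,
#'   max_pi_ratio, max_fst, contrast, process.
#' @export
callSweeps <- function(windowStats, q = 0.95,
                       rule = c("intersection", "union"),
                       contrast = NA_character_,
                       process = NA_character_) {
  rule <- match.arg(rule)
  ws <- windowStats
  usable <- !ws$insufficient & is.finite(ws$pi_ratio) & is.finite(ws$fst)
  sel <- rep(FALSE, nrow(ws))
  if (q < 1 && any(usable)) {
    thrR <- quantileThreshold(ws$pi_ratio[usable], q)
    thrF <- quantileThreshold(ws$fst[usable], q)
    inR <- usable & ws$pi_ratio >= thrR
    inF <- usable & ws$fst >= thrF
    sel <- if (rule == "intersection") inR & inF else inR | inF
  }
  mergeSelectedWindows(ws, sel, contrast, process)
}

#' Merge adjacent selected windows into regions
#'
#' Consecutive selected windows on the same chromosome whose spans touch
#' or overlap are merged.  Idempotent by construction.
#'
#' @param windowStats window table.
#' @param selected logical vector over its rows.
#' @param contrast,process labels carried onto regions.
#' @return region data.frame as in [callSweeps()].
#' @export
mergeSelectedWindows <- function(windowStats, selected,
                                 contrast = NA_character_,
                                 process = NA_character_) {
  ws <- windowStats[selected, , drop = FALSE]
  if (!nrow(ws))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      max_pi_ratio = numeric(), max_fst = numeric(),
                      contrast = character(), process = character()))
  ws <- ws[order(ws$chrom, ws$start), , drop = FALSE]
  newRun <- c(TRUE, ws$chrom[-1] != ws$chrom[-nrow(ws)] |
                ws$start[-1] > ws$end[-nrow(ws)] + 1L)
  run <- cumsum(newRun)
  agg <- function(f, col) vapply(split(ws[[col]], run), f, numeric(1))
  data.frame(chrom = vapply(split(ws$chrom, run), `[`, character(1), 1),
             start = as.integer(agg(min, "start")),
             end = as.integer(agg(max, "end")),
             n_windows = as.integer(vapply(split(run, run), length,
                                           integer(1))),
             max_pi_ratio = agg(max, "pi_ratio"),
             max_fst = agg(max, "fst"),
             contrast = contrast, process = process,
             row.names = NULL)
}

#' Map genes into candidate selective regions
#'
#' A gene is assigned to a region when any base pair overlaps (1-based
#' inclusive intervals); a gene may map to several regions.
#'
#' @param genes A [GeneModels-class] or a named `GRanges` of gene bodies.
#' @param regions region data.frame from [callSweeps()].
#' @return data.frame: gene_id, region (row index in `regions`), chrom,
#'   region_start, region_end.
#' @export
genesInRegions <- function(genes, regions) {
  g <- if (is(genes, "GeneModels")) geneRanges(genes) else genes
  if (!nrow(regions))
    return(data.frame(gene_id = character(), region = integer(),
                      chrom = character(), region_start = integer(),
                      region_end = integer()))
  rgr <- GenomicRanges::GRanges(regions$chrom,
           IRanges::IRanges(regions$start, regions$end))
  ov <- GenomicRanges::findOverlaps(g, rgr)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  data.frame(gene_id = names(g)[q], region = s,
             chrom = regions$chrom[s],
             region_start = regions$start[s],
             region_end = regions$end[s])
}

#' Genes shared between two processes' selective regions
#'
#' @param assignA,assignB outputs of [genesInRegions()] for two
#'   contrasts (e.g. domestication and improvement).
#' @return character vector of gene ids present in both.
#' @export
sharedSweepGenes <- function(assignA, assignB)
  sort(intersect(unique(assignA$gene_id), unique(assignB$gene_id)))
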