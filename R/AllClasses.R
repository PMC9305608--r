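#' @import methods
#' @importFrom stats quantile setNames p.adjust phyper wilcox.test cutree
#'   hclust dist cor sd median rbinom rnorm runif
#' @importFrom utils write.table read.table head combn
NULL

#' PhasedPanel: phased biallelic genotypes for a structured sample panel
#'
#' A `PhasedPanel` holds the substrate for all population-genetic
#' computations in the package: an ordered set of biallelic SNP sites and,
#' for every diploid sample, two fully resolved (phased) haplotype allele
#' sequences coded 0 (reference) / 1 (alternate).  Samples carry a
#' subpopulation label (e.g. \code{wild_emmer}, \code{domesticated_emmer})
#' so that diversity, differentiation and haplotype frequencies can be
#' computed per subpopulation or between pairs of them.
#'
#' Haplotypes are stored row-wise: rows \code{2i - 1} and \code{2i} of
#' \code{hapMatrix(x)} are the two haplotypes of sample \code{i}.  Sites are
#' sorted by chromosome then position; positions are 1-based and strictly
#' increasing within a chromosome.
#'
#' @slot samples character vector of sample identifiers.
#' @slot subpop character vector, parallel to \code{samples}, giving each
#'   sample's subpopulation.
#' @slot sites data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt} (single nucleotides).
#' @slot haps integer matrix of 0/1 alleles, \code{2 * length(samples)} rows
#'   by \code{nrow(sites)} columns.
#' @slot chromLengths named numeric vector of chromosome lengths in bp
#'   (may be empty; then lengths are inferred from the last site).
#'
#' @seealso [simulateAncestralPanel()], [readPhasedVcf()], [windowedPi()],
#'   [weirCockerhamFst()], [buildGeneHaplotypes()]
#' @export
setClass("PhasedPanel",
  representation(
    samples      = "character",
    subpop       = "character",
    sites        = "data.frame",
    haps         = "matrix",
    chromLengths = "numeric"
  )
)

setValidity("PhasedPanel", function(object) {
  msg <- character()
  ns <- length(object@samples)
  if (length(object@subpop) != ns)
    msg <- c(msg, "subpop must be parallel to samples")
  if (anyDuplicated(object@samples))
    msg <- c(msg, "duplicated sample ids")
  st <- object@sites
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(st)))
    msg <- c(msg, "sites must have columns chrom, pos, ref, alt")
  if (nrow(object@haps) != 2L * ns)
    msg <- c(msg, "haps must have 2 rows per sample")
  if (ncol(object@haps) != nrow(st))
    msg <- c(msg, "haps must have one column per site")
  if (length(object@haps) && !all(object@haps %in% c(0L, 1L)))
    msg <- c(msg, "haplotype alleles must be coded 0/1 with no missing data")
  if (nrow(st)) {
    bad <- unlist(lapply(split(st$pos, st$chrom),
                         function(p) any(diff(p) <= 0)))
    if (any(bad))
      msg <- c(msg, "positions must be strictly increasing within chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PhasedPanel
#'
#' @param samples character sample ids.
#' @param subpop character subpopulation labels, one per sample.
#' @param sites data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}.
#' @param haps integer 0/1 matrix, two rows per sample (sample i occupies
#'   rows 2i-1 and 2i), one column per site.
#' @param chromLengths optional named numeric vector of chromosome lengths.
#' @return A [PhasedPanel-class] object.
#' @export
PhasedPanel <- function(samples, subpop, sites, haps,
                        chromLengths = numeric()) {
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- as.character(sites$ref)
  sites$alt <- as.character(sites$alt)
  rownames(sites) <- NULL
  storage.mode(haps) <- "integer"
  new("PhasedPanel", samples = as.character(samples),
      subpop = as.character(subpop), sites = sites, haps = haps,
      chromLengths = chromLengths)
}

#' @describeIn PhasedPanel Number of diploid samples.
#' @param x,object A `PhasedPanel`.
#' @export
nSamples <- function(x) length(x@samples)

#' @describeIn PhasedPanel Number of SNP sites.
#' @export
nSites <- function(x) nrow(x@sites)

#' @describeIn PhasedPanel Sample identifiers.
#' @export
sampleIds <- function(x) x@samples

#' @describeIn PhasedPanel Subpopulation labels named by sample.
#' @export
subpopLabels <- function(x) setNames(x@subpop, x@samples)

#' @describeIn PhasedPanel Site table (chrom, pos, ref, alt).
#' @export
siteTable <- function(x) x@sites

#' @describeIn PhasedPanel The 0/1 haplotype matrix (2 rows per sample).
#' @export
hapMatrix <- function(x) x@haps

#' @describeIn PhasedPanel Chromosome lengths; inferred from the last site
#'   when not recorded at construction.
#' @export
chromLengths <- function(x) {
  if (length(x@chromLengths)) return(x@chromLengths)
  if (!nrow(x@sites)) return(numeric())
  vapply(split(x@sites$pos, x@sites$chrom), max, numeric(1))
}

#' Restrict a panel to a set of samples or to one subpopulation
#'
#' @param panel A [PhasedPanel-class].
#' @param samples character vector of sample ids to keep, or `NULL`.
#' @param subpop single subpopulation name to keep, or `NULL`.  Exactly one
#'   of `samples`/`subpop` must be given.
#' @return A `PhasedPanel` with the selected samples, sites unchanged.
#' @export
selectSamples <- function(panel, samples = NULL, subpop = NULL) {
  if (is.null(samples) == is.null(subpop))
    stop("give exactly one of 'samples' or 'subpop'")
  if (!is.null(subpop)) {
    if (!subpop %in% panel@subpop)
      stop("unknown subpopulation: ", subpop)
    keep <- which(panel@subpop == subpop)
  } else {
    keep <- match(samples, panel@samples)
    if (anyNA(keep))
      stop("samples not in panel: ",
           paste(samples[is.na(keep)], collapse = ", "))
  }
  hrows <- as.vector(rbind(2L * keep - 1L, 2L * keep))
  PhasedPanel(panel@samples[keep], panel@subpop[keep], panel@sites,
              panel@haps[hrows, , drop = FALSE], panel@chromLengths)
}

#' Restrict a panel to a subset of sites (by site index)
#'
#' @param panel A [PhasedPanel-class].
#' @param idx integer site indices (columns of the haplotype matrix).
#' @return A `PhasedPanel` over the selected sites.
#' @export
selectSites <- function(panel, idx) {
  idx <- sort(unique(as.integer(idx)))
  PhasedPanel(panel@samples, panel@subpop,
              panel@sites[idx, , drop = FALSE],
              panel@haps[, idx, drop = FALSE], panel@chromLengths)
}

setMethod("show", "PhasedPanel", function(object) {
  sp <- table(object@subpop)
  cat("PhasedPanel:", length(object@samples), "samples,",
      nrow(object@sites), "biallelic sites on",
      length(unique(object@sites$chrom)), "chromosome(s)\n")
  cat("subpopulations:",
      paste(sprintf("%s(%d)", names(sp), sp), collapse = ", "), "\n")
})
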