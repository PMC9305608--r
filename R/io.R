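#' Read gene models from GFF3 plus a family table
#'
#' Resolves the gene/transcript/exon/UTR hierarchy of a GFF3 file into a
#' [GeneModels-class].  When a gene carries several transcripts only the
#' first variant (lowest-sorting transcript ID) is retained.  Exons whose
#' Parent cannot be resolved, or that fall outside their gene body, raise
#' an error naming the offender.
#'
#' @param gffPath path to a GFF3 file (1-based inclusive coordinates).
#' @param familyTsv optional TSV with columns `gene_id`, `family`.
#' @return A [GeneModels-class].
#' @export
readGeneModels <- function(gffPath, familyTsv = NULL) {
  gr <- rtracklayer::import(gffPath, format = "gff3")
  if (!length(gr))
    return(.makeGeneModels(
      data.frame(gene_id = character(), chrom = character(),
                 start = integer(), end = integer(), strand = character()),
      NULL))
  typ <- as.character(gr$type)
  asDf <- function(x, id) data.frame(
    gene_id = id, chrom = as.character(GenomicRanges::seqnames(x)),
    start = GenomicRanges::start(x), end = GenomicRanges::end(x),
    strand = as.character(GenomicRanges::strand(x)))
  genes <- gr[typ == "gene"]
  gids <- genes$ID
  tx <- gr[typ %in% c("mRNA", "transcript")]
  txParent <- vapply(tx$Parent, function(p) p[1] %||% NA_character_,
                     character(1))
  if (anyNA(txParent) || !all(txParent %in% gids))
    stop("transcript with unresolvable Parent: ",
         paste(tx$ID[is.na(txParent) | !txParent %in% gids],
               collapse = ", "))
  allTxIds <- tx$ID
  # first transcript variant per gene (lowest-sorting ID)
  keep <- unlist(lapply(split(seq_along(tx), txParent),
                        function(i) i[order(tx$ID[i])][1]))
  tx <- tx[sort(keep)]
  txParent <- vapply(tx$Parent, `[`, character(1), 1)
  tx2gene <- setNames(txParent, tx$ID)
  pickChildren <- function(types) {
    ch <- gr[typ %in% types]
    if (!length(ch))
      return(data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer()))
    par <- vapply(ch$Parent, function(p) p[1] %||% NA_character_,
                  character(1))
    bad <- is.na(par) | !(par %in% c(allTxIds, gids))
    if (any(bad) && "exon" %in% types)
      stop("orphan exon (unresolvable Parent): ",
           paste(unique(par[bad]), collapse = ", "))
    # children of non-retained transcript variants are dropped
    gid <- ifelse(par %in% gids, par, unname(tx2gene[par]))
    ok <- !is.na(gid)
    df <- asDf(ch[ok], gid[ok])
    df[, c("gene_id", "chrom", "start", "end")]
  }
  exonsDf <- pickChildren("exon")
  utr5Df <- pickChildren("five_prime_UTR")
  utr3Df <- pickChildren("three_prime_UTR")
  fam <- NULL
  if (!is.null(familyTsv))
    fam <- read.table(familyTsv, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  gdf <- asDf(genes, gids)
  .makeGeneModels(gdf, exonsDf, fam, utr5Df, utr3Df)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Read phased genotypes from VCF restricted to a sample panel
#'
#' Multi-allelic and non-SNP records are skipped (a message reports how
#' many).  All retained calls must be phased (`|` separator) and complete;
#' an unphased or missing call is an error, since phasing/imputation is out
#' of scope.  Samples are restricted to the panel file and labelled with
#' its subpopulations.
#'
#' @param vcfPath path to a VCF (v4.x) file.
#' @param panelTsv TSV with columns `sample_id`, `subpopulation`.
#' @return A [PhasedPanel-class].
#' @export
readPhasedVcf <- function(vcfPath, panelTsv) {
  panel <- read.table(panelTsv, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  v <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  isSnp <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  nSkip <- sum(!isSnp)
  if (nSkip > 0)
    message(nSkip, " multi-allelic or non-SNP record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt <- gt[isSnp, , drop = FALSE]
  missing <- setdiff(panel$sample_id, colnames(gt))
  if (length(missing))
    stop("panel sample(s) absent from VCF: ",
         paste(missing, collapse = ", "))
  gt <- gt[, panel$sample_id, drop = FALSE]
  if (any(grepl("/", gt, fixed = TRUE)) || any(is.na(gt)) ||
      any(grepl(".", gt, fixed = TRUE)))
    stop("unphased or missing genotype call; input must be fully phased")
  sites <- data.frame(chrom = fix[isSnp, "CHROM"],
                      pos = as.integer(fix[isSnp, "POS"]),
                      ref = ref[isSnp], alt = alt[isSnp])
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  gt <- gt[o, , drop = FALSE]
  a1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))
  ns <- nrow(panel)
  haps <- matrix(0L, nrow = 2L * ns, ncol = nrow(sites))
  haps[seq(1, 2 * ns, by = 2), ] <- t(a1)
  haps[seq(2, 2 * ns, by = 2), ] <- t(a2)
  cl <- .contigLengths(v@meta)
  PhasedPanel(panel$sample_id, panel$subpopulation, sites, haps, cl)
}

.contigLengths <- function(meta) {
  ln <- grep("^##contig=", meta, value = TRUE)
  if (!length(ln)) return(numeric())
  id <- sub('.*ID=([^,>]+).*', "\\1", ln)
  len <- suppressWarnings(as.numeric(sub('.*length=([0-9]+).*', "\\1", ln)))
  setNames(len, id)[!is.na(len)]
}

#' Export a complete fixture (VCF, GFF3, panel, QTL, family, FPKM files)
#'
#' Writes the panel as a phased VCF v4.2 (GT separator `|`), the gene
#' models as GFF3 with gene/mRNA/exon/UTR hierarchy, and TSV files for the
#' sample panel, QTL intervals, family labels and the FPKM matrix.  All
#' files round-trip losslessly through [readPhasedVcf()] /
#' [readGeneModels()] and plain `read.table`.
#'
#' @param panel A [PhasedPanel-class].
#' @param genes A [GeneModels-class].
#' @param qtls `GRanges` with a `trait` column.
#' @param expression list with `fpkm` matrix (as from
#'   [synthesizeExpression()]) or a bare matrix.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
exportFixture <- function(panel, genes, qtls, expression, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "fixture.vcf"),
             gff = file.path(dir, "genes.gff3"),
             panel = file.path(dir, "panel.tsv"),
             qtl = file.path(dir, "qtl.tsv"),
             family = file.path(dir, "families.tsv"),
             fpkm = file.path(dir, "fpkm.tsv"))
  .writeVcf(panel, paths["vcf"])
  .writeGff3(genes, paths["gff"])
  write.table(data.frame(sample_id = sampleIds(panel),
                         subpopulation = panel@subpop),
              paths["panel"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(chrom = as.character(GenomicRanges::seqnames(qtls)),
                         start = GenomicRanges::start(qtls),
                         end = GenomicRanges::end(qtls),
                         trait = qtls$trait),
              paths["qtl"], sep = "\t", quote = FALSE, row.names = FALSE)
  fam <- geneFamilies(genes)
  write.table(data.frame(gene_id = names(fam), family = unname(fam)),
              paths["family"], sep = "\t", quote = FALSE, row.names = FALSE)
  fp <- if (is.list(expression)) expression$fpkm else expression
  write.table(data.frame(gene_id = rownames(fp), fp, check.names = FALSE),
              paths["fpkm"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

.writeVcf <- function(panel, path) {
  st <- siteTable(panel)
  H <- hapMatrix(panel)
  ns <- nSamples(panel)
  cl <- chromLengths(panel)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(cl),
                   as.integer(cl)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sampleIds(panel)), collapse = "\t"))
  if (nrow(st)) {
    a1 <- t(H[seq(1, 2 * ns, by = 2), , drop = FALSE])
    a2 <- t(H[seq(2, 2 * ns, by = 2), , drop = FALSE])
    gtBody <- matrix(paste(a1, a2, sep = "|"), nrow = nrow(st))
    body <- paste(st$chrom, st$pos, ".", st$ref, st$alt, ".", "PASS", ".",
                  "GT", apply(gtBody, 1, paste, collapse = "\t"),
                  sep = "\t")
  } else body <- character()
  writeLines(c(hdr, body), path)
}

.writeGff3 <- function(genes, path) {
  g <- geneRanges(genes)
  rows <- character()
  line <- function(chrom, type, start, end, strand, attrs)
    paste(chrom, "DomestiScan", type, start, end, ".", strand, ".",
          attrs, sep = "\t")
  for (i in seq_along(g)) {
    id <- names(g)[i]
    chrom <- as.character(GenomicRanges::seqnames(g[i]))
    strand <- as.character(GenomicRanges::strand(g[i]))
    if (strand == "*") strand <- "+"
    rows <- c(rows, line(chrom, "gene", GenomicRanges::start(g[i]),
                         GenomicRanges::end(g[i]), strand,
                         sprintf("ID=%s", id)))
    tid <- paste0(id, ".1")
    rows <- c(rows, line(chrom, "mRNA", GenomicRanges::start(g[i]),
                         GenomicRanges::end(g[i]), strand,
                         sprintf("ID=%s;Parent=%s", tid, id)))
    emit <- function(gr, type) {
      out <- character()
      for (k in seq_along(gr))
        out <- c(out, line(chrom, type, GenomicRanges::start(gr[k]),
                           GenomicRanges::end(gr[k]), strand,
                           sprintf("Parent=%s", tid)))
      out
    }
    rows <- c(rows, emit(exonRanges(genes)[[i]], "exon"),
              emit(utr5Ranges(genes)[[i]], "five_prime_UTR"),
              emit(utr3Ranges(genes)[[i]], "three_prime_UTR"))
  }
  writeLines(c("##gff-version 3", rows), path)
}

#' Read a QTL interval table
#'
#' @param path TSV with columns `chrom`, `start`, `end`, `trait`
#'   (1-based inclusive coordinates).
#' @return `GRanges` with a `trait` metadata column.
#' @export
readQtlTable <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  gr$trait <- df$trait
  gr
}

#' Read a gene x library FPKM matrix
#'
#' @param path TSV whose first column is `gene_id`, remaining columns are
#'   library FPKM values.
#' @return numeric matrix with gene rownames.
#' @export
readFpkmMatrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
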