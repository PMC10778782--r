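#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end strand
#'   granges reduce findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   colData rowData
NULL

#' GenotypeData: per-sample additive SNP dosages with coordinates
#'
#' Extends \linkS4class{RangedSummarizedExperiment}. Rows are biallelic SNPs
#' (a \code{GRanges} of width-1 positions carrying \code{ref}, \code{alt} and
#' \code{qual} in \code{mcols}); columns are samples; the single assay
#' \code{"dosage"} holds the additive ALT-allele count in \{0, 1, 2\} with
#' \code{NA} for missing genotypes.
#'
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- NULL
  if (!"dosage" %in% names(assays(object)))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    ok <- d[!is.na(d)]
    if (length(ok) && (any(ok < 0) || any(ok > 2) || any(ok != round(ok))))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  rr <- rowRanges(object)
  need <- c("ref", "alt", "qual")
  if (!all(need %in% names(mcols(rr))))
    msg <- c(msg, "rowRanges mcols must contain ref, alt, qual")
  else {
    if (any(!nzchar(mcols(rr)$ref)) || any(!nzchar(mcols(rr)$alt)))
      msg <- c(msg, "alleles must be non-empty")
    if (any(mcols(rr)$qual < 0, na.rm = TRUE))
      msg <- c(msg, "qual must be non-negative")
  }
  if (length(rr) && any(start(rr) < 1))
    msg <- c(msg, "positions must be >= 1 (1-based)")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypeData object
#'
#' @param dosages integer/numeric matrix, SNPs x samples, values 0/1/2/NA.
#' @param snps `GRanges` of SNP positions (width 1), one per row of
#'   `dosages`, with mcols `ref`, `alt`, `qual`. Names (or mcols `snp_id`)
#'   give SNP identifiers.
#' @return A `GenotypeData` object.
#' @export
GenotypeData <- function(dosages, snps) {
  dosages <- as.matrix(dosages)
  if (length(snps) != nrow(dosages))
    stop("length(snps) must equal nrow(dosages)")
  if (is.null(names(snps)) && !is.null(mcols(snps)$snp_id))
    names(snps) <- mcols(snps)$snp_id
  rownames(dosages) <- names(snps)
  se <- SummarizedExperiment(assays = list(dosage = dosages), rowRanges = snps)
  new("GenotypeData", se)
}

#' @describeIn GenotypeData the dosage matrix (SNPs x samples)
#' @param x a `GenotypeData`
#' @export
dosages <- function(x) assay(x, "dosage")

#' @describeIn GenotypeData per-SNP site quality
#' @export
snpQual <- function(x) mcols(rowRanges(x))$qual

#' ExpressionData: gene x sample abundance matrix with declared unit
#'
#' Extends \linkS4class{SummarizedExperiment}; the single assay holds the
#' values, and \code{metadata(x)$unit} is one of \code{"FPKM"},
#' \code{"normalized-score"} or \code{"raw-count"}. FPKM and raw counts must
#' be non-negative.
#'
#' @export
setClass("ExpressionData", contains = "SummarizedExperiment")

.expr_units <- c("FPKM", "normalized-score", "raw-count")

setValidity("ExpressionData", function(object) {
  msg <- NULL
  unit <- metadata(object)$unit
  if (is.null(unit) || !unit %in% .expr_units)
    msg <- c(msg, sprintf("metadata unit must be one of %s",
                          paste(.expr_units, collapse = ", ")))
  else if (unit %in% c("FPKM", "raw-count")) {
    v <- assay(object)
    if (any(v < 0, na.rm = TRUE))
      msg <- c(msg, sprintf("negative values not allowed for unit %s", unit))
  }
  if (nrow(object) > 0 &&
      (is.null(rownames(object)) || anyDuplicated(rownames(object))))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  if (is.null(msg)) TRUE else msg
})

#' Construct an ExpressionData object
#'
#' @param values numeric matrix, genes x samples, with gene ids as rownames
#'   and sample ids as colnames.
#' @param unit one of `"FPKM"`, `"normalized-score"`, `"raw-count"`.
#' @return An `ExpressionData` object.
#' @export
ExpressionData <- function(values, unit = c("FPKM", "normalized-score", "raw-count")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  se <- SummarizedExperiment(assays = list(values = values))
  md <- metadata(se); md$unit <- unit; metadata(se) <- md
  new("ExpressionData", se)
}

#' @describeIn ExpressionData the expression matrix (genes x samples)
#' @param x an `ExpressionData`
#' @export
exprValues <- function(x) assay(x, "values")

#' @describeIn ExpressionData the declared unit of the values
#' @export
exprUnit <- function(x) metadata(x)$unit

#' GeneModels: gene spans with CDS structure
#'
#' Holds one entry per gene: the gene body as a \code{GRanges} (strand-aware),
#' a parallel \code{GRangesList} of CDS intervals, and optionally the spliced
#' CDS sequences (a \code{DNAStringSet} named by gene id, 5'->3' of the
#' transcript) used for synonymous/nonsynonymous classification.
#'
#' @slot genes `GRanges`, one range per gene, names = gene ids.
#' @slot cds `GRangesList` parallel to `genes`; intervals sorted in
#'   transcription order (reverse genomic order on the minus strand),
#'   non-overlapping, contained in the gene span.
#' @slot cdsSeqs `DNAStringSet` of spliced CDS sequences (may be empty).
#' @export
setClass("GeneModels",
         representation(genes = "GRanges", cds = "GRangesList",
                        cdsSeqs = "DNAStringSet"))

setValidity("GeneModels", function(object) {
  msg <- NULL
  g <- object@genes
  if (is.null(names(g)) || anyDuplicated(names(g)))
    msg <- c(msg, "gene ids (names) must be present and unique")
  if (length(object@cds) != length(g))
    msg <- c(msg, "cds list must be parallel to genes")
  else if (length(g)) {
    flat <- unlist(object@cds, use.names = FALSE)
    gi <- rep(seq_along(g), lengths(object@cds))
    if (length(flat)) {
      bad <- as.character(seqnames(flat)) != as.character(seqnames(g))[gi] |
        start(flat) < start(g)[gi] | end(flat) > end(g)[gi]
      if (any(bad))
        msg <- c(msg, sprintf("CDS outside gene span for %s",
                              names(g)[gi[which(bad)[1]]]))
      # non-overlap within gene, checked on genomically sorted intervals
      o <- order(gi, start(flat))
      same <- diff(gi[o]) == 0
      if (any(same & start(flat)[o][-1] <= end(flat)[o][-length(o)]))
        msg <- c(msg, "overlapping CDS intervals within a gene")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a GeneModels object
#'
#' @param genes `GRanges` of gene bodies, named by gene id, with strand.
#' @param cds `GRangesList` parallel to `genes` (CDS intervals per gene);
#'   defaults to empty CDS for every gene. Intervals are re-sorted into
#'   transcription order.
#' @param cdsSeqs optional `DNAStringSet` of spliced CDS sequences named by
#'   gene id.
#' @return A `GeneModels` object.
#' @export
GeneModels <- function(genes, cds = NULL, cdsSeqs = NULL) {
  if (is.null(cds))
    cds <- GRangesList(rep(list(GRanges()), length(genes)))
  if (is.list(cds)) cds <- GRangesList(cds)
  # transcription order: genomic order on +, reverse on -
  minus <- as.character(strand(genes)) == "-"
  flat <- unlist(cds, use.names = FALSE)
  gi <- rep(seq_along(genes), lengths(cds))
  o <- order(gi, ifelse(minus[gi], -start(flat), start(flat)))
  cds <- S4Vectors::splitAsList(flat[o],
                                factor(gi[o], levels = seq_along(genes)))
  names(cds) <- names(genes)
  if (is.null(cdsSeqs)) cdsSeqs <- Biostrings::DNAStringSet()
  new("GeneModels", genes = genes, cds = cds, cdsSeqs = cdsSeqs)
}

#' @describeIn GeneModels gene body ranges
#' @param x a `GeneModels`
#' @export
geneRanges <- function(x) x@genes

#' @describeIn GeneModels CDS intervals per gene (transcription order)
#' @export
cdsByGene <- function(x) x@cds

#' @describeIn GeneModels spliced CDS sequences (may be empty)
#' @export
cdsSeqs <- function(x) x@cdsSeqs

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d SNPs x %d samples (%.2f%% missing)\n",
              nrow(object), ncol(object),
              100 * mean(is.na(assay(object, "dosage")))))
  callNextMethod()
})

setMethod("show", "ExpressionData", function(object) {
  cat(sprintf("ExpressionData: %d genes x %d samples, unit = %s\n",
              nrow(object), ncol(object), exprUnit(object)))
})

setMethod("show", "GeneModels", function(object) {
  n_cds <- sum(lengths(object@cds) > 0)
  cat(sprintf("GeneModels: %d genes on %d sequence(s), %d with CDS, %d with CDS sequence\n",
              length(object@genes),
              length(unique(as.character(seqnames(object@genes)))),
              n_cds, length(object@cdsSeqs)))
})
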