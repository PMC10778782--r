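#' Read genotypes from a VCF file
#'
#' Loads biallelic variant records and converts per-sample GT fields to
#' additive ALT-allele dosages (0/1/2). Phased (`|`) and unphased (`/`)
#' separators are treated identically; missing genotypes (`./.`) become
#' `NA`. Multi-allelic records and records without an ALT allele are skipped
#' and the skipped count reported via `message()`. Short indels and MNPs are
#' accepted as dosage-bearing biallelic records.
#'
#' @param path path to a VCF 4.x file (plain or gzipped).
#' @return A [GenotypeData] object; SNP records keep file order.
#' @export
readGenotypesVcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))  # single-record files come back as a bare vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0)
    stop("no variant records in ", path)
  if (!"GT" %in% unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":"))))
    stop("GT field absent from FORMAT; cannot derive dosages")
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & alt != "." & !grepl(",", alt, fixed = TRUE)
  n_skip <- sum(!biallelic)
  if (n_skip > 0)
    message(sprintf("readGenotypesVcf: skipped %d non-biallelic record(s)", n_skip))
  if (!any(biallelic))
    stop("no biallelic records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  dos <- .gtToDosage(gt)
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  qual[is.na(qual)] <- 0
  ids <- fix[, "ID"]
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(fix[blank, "CHROM"], "_", fix[blank, "POS"])
  snps <- GRanges(fix[, "CHROM"],
                  IRanges(as.integer(fix[, "POS"]), width = 1L),
                  ref = fix[, "REF"], alt = alt[biallelic], qual = qual)
  names(snps) <- ids
  GenotypeData(dos, snps)
}

.gtToDosage <- function(gt) {
  u <- unique(as.vector(gt))
  lut <- vapply(u, function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == "." | al == "")) return(NA_real_)
    sum(al == "1")
  }, numeric(1))
  m <- matrix(lut[match(as.vector(gt), u)], nrow = nrow(gt),
              dimnames = dimnames(gt))
  m
}

#' Write genotypes to a VCF file
#'
#' Emits a minimal deterministic VCF 4.2 with a GT-only FORMAT; dosages
#' 0/1/2/NA map to `0/0`, `0/1`, `1/1`, `./.`. Inverse of
#' [readGenotypesVcf()] for biallelic records.
#'
#' @param gd a [GenotypeData].
#' @param path output path.
#' @param contigs optional named vector of chromosome lengths for `##contig`
#'   header lines.
#' @export
writeGenotypesVcf <- function(gd, path, contigs = NULL) {
  rr <- rowRanges(gd)
  d <- dosages(gd)
  gt <- matrix("./.", nrow(d), ncol(d))
  gt[!is.na(d) & d == 0] <- "0/0"
  gt[!is.na(d) & d == 1] <- "0/1"
  gt[!is.na(d) & d == 2] <- "1/1"
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(d)), collapse = "\t"))
  body <- paste(as.character(seqnames(rr)), start(rr), names(rr),
                mcols(rr)$ref, mcols(rr)$alt,
                formatC(mcols(rr)$qual, format = "fg", digits = 6),
                ".", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
}

#' Read gene models from a GFF3 file
#'
#' Assembles one gene model per `gene` feature, attaching `CDS` features
#' linked by `Parent` (directly, or through an `mRNA`/transcript feature).
#' CDS intervals are stored in transcription order (reverse genomic order on
#' the minus strand). A CDS lying outside its parent gene span is a fatal
#' validation error.
#'
#' @param path path to a GFF3 file.
#' @param cdsFasta optional FASTA of spliced CDS sequences named by gene id.
#' @return A [GeneModels] object.
#' @export
readGeneModelsGff3 <- function(path, cdsFasta = NULL) {
  gr <- rtracklayer::import(path)
  genes <- gr[gr$type == "gene"]
  if (length(genes) == 0) {
    warning("no gene features in ", path)
    g <- GRanges()
    names(g) <- character(0)
    return(GeneModels(g))
  }
  names(genes) <- genes$ID
  cds <- gr[gr$type == "CDS"]
  # map CDS Parent -> gene id, resolving one level of mRNA if present
  tx <- gr[gr$type %in% c("mRNA", "transcript")]
  tx2gene <- structure(as.character(unlist(tx$Parent)), names = tx$ID)
  par <- as.character(unlist(cds$Parent))
  via_tx <- par %in% names(tx2gene)
  par[via_tx] <- tx2gene[par[via_tx]]
  keep <- par %in% names(genes)
  cds <- cds[keep]; par <- par[keep]
  cds_list <- rep(list(GRanges()), length(genes))
  names(cds_list) <- names(genes)
  if (length(cds)) {
    sp <- split(granges(cds), par)
    cds_list[names(sp)] <- as.list(sp)
  }
  seqs <- if (!is.null(cdsFasta)) Biostrings::readDNAStringSet(cdsFasta) else NULL
  gm <- GeneModels(granges(genes), GRangesList(cds_list), cdsSeqs = seqs)
  names(gm@genes) <- names(genes)
  validObject(gm)
  gm
}

#' Read an expression table
#'
#' Expects a TSV with a header row of sample ids and gene ids in the first
#' column. Duplicated gene ids, ragged rows, an empty data section, and
#' negative values under `unit = "FPKM"` or `"raw-count"` are fatal.
#'
#' @param path path to the TSV.
#' @param unit the declared unit of the values.
#' @return An [ExpressionData] object.
#' @export
readExpressionTsv <- function(path, unit = c("FPKM", "normalized-score", "raw-count")) {
  unit <- match.arg(unit)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = NA, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("empty data section in ", path)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicated gene ids in ", path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- ids
  ExpressionData(m, unit = unit)
}

#' Write pipeline result tables
#'
#' Writes eQTL blocks as TSV, hotspots as BED6 (0-based half-open) plus a TSV
#' carrying target-gene lists, and the regulatory network as node/edge TSVs.
#' All internal coordinates are 1-based inclusive; conversion to 0-based
#' half-open happens only at this BED boundary. Empty result sets produce
#' header-only files.
#'
#' @param results a list with any of `blocks`, `hotspots`, `network`
#'   (as returned by [clusterBlocks()], [mergeHotspots()], [buildNetwork()]).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeResults <- function(results, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir)
  if (file.access(out_dir, mode = 2) != 0)
    stop("output directory not writable: ", out_dir)
  paths <- character(0)
  tsv <- function(df, f) {
    p <- file.path(out_dir, f)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  if (!is.null(results$blocks)) {
    b <- results$blocks
    paths <- c(paths, tsv(b[, c("gene_id", "chrom", "start", "end", "lead_snp",
                                "lead_p", "n_snps", "cls")], "eqtl_blocks.tsv"))
  }
  if (!is.null(results$hotspots)) {
    h <- results$hotspots
    bed <- data.frame(chrom = h$chrom, start = h$start - 1L, end = h$end,
                      name = h$hotspot_id, score = h$n_trans_eqtls,
                      strand = rep(".", nrow(h)))
    p <- file.path(out_dir, "hotspots.bed")
    utils::write.table(bed, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    if (nrow(bed) == 0) cat("", file = p)  # header-less BED: empty file
    paths <- c(paths, p)
    ht <- data.frame(hotspot_id = h$hotspot_id, chrom = h$chrom,
                     start = h$start, end = h$end,
                     n_trans_eqtls = h$n_trans_eqtls,
                     n_target_genes = lengths(h$target_genes),
                     target_genes = vapply(h$target_genes, paste,
                                           character(1), collapse = ","))
    paths <- c(paths, tsv(ht, "hotspot_targets.tsv"))
  }
  if (!is.null(results$network)) {
    paths <- c(paths, tsv(results$network$edges, "network_edges.tsv"))
    paths <- c(paths, tsv(results$network$nodes, "network_nodes.tsv"))
  }
  invisible(paths)
}
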