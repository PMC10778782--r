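#' Filter genes by expression prevalence
#'
#' A gene is kept when its FPKM exceeds `fpkm_min` in strictly more than
#' `frac_min` of the samples (both inequalities strict), the usual
#' expressed-gene gate before eQTL mapping.
#'
#' @param expr an [ExpressionData] with unit `"FPKM"`.
#' @param fpkm_min,frac_min thresholds (defaults 1 and 0.20).
#' @return The filtered [ExpressionData].
#' @export
filterExpressed <- function(expr, fpkm_min = 1, frac_min = 0.20) {
  stopifnot(exprUnit(expr) == "FPKM")
  v <- exprValues(expr)
  keep <- rowSums(v > fpkm_min) / ncol(v) > frac_min
  ExpressionData(v[keep, , drop = FALSE], unit = "FPKM")
}

#' Rank-based inverse normal transform (per gene)
#'
#' Maps each gene's values through the Blom transform
#' `qnorm((rank - 3/8) / (n + 1/4))` with average ranks on ties — the
#' `qqnorm()` convention for n <= 10 and the standard choice for expression
#' normalization before linear-model eQTL mapping. A constant gene maps to
#' all zeros with a warning.
#'
#' @param expr an [ExpressionData]; values must be complete (no `NA`).
#' @return An [ExpressionData] with unit `"normalized-score"`; per gene the
#'   scores are a monotone function of the input ranks with mean ~0.
#' @export
inverseNormal <- function(expr) {
  v <- exprValues(expr)
  if (anyNA(v)) stop("missing expression values are not supported")
  n <- ncol(v)
  out <- t(apply(v, 1, function(x) {
    if (max(x) == min(x)) return(rep(0, n))
    stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  }))
  if (any(constant <- apply(v, 1, function(x) max(x) == min(x))))
    warning(sprintf("%d constant gene(s) mapped to all zeros",
                    sum(constant)))
  dimnames(out) <- dimnames(v)
  ExpressionData(out, unit = "normalized-score")
}

#' Call differentially expressed genes between two parents
#'
#' A light-weight two-group DEG test on count tables: counts are library-size
#' normalized by total-count scaling, `log2fc = log2((meanA + 0.5) /
#' (meanB + 0.5))`, p-values from a two-sample Welch t-test on
#' `log2(count + 0.5)`, and q-values by Benjamini-Hochberg. Status is `up`
#' iff `log2fc > min_abs_log2fc` and `q < q_max`, `down` iff
#' `log2fc < -min_abs_log2fc` and `q < q_max`, else `ns`.
#'
#' @param counts gene x sample matrix of raw counts.
#' @param groups factor of length `ncol(counts)` with two levels
#'   (A = first level, B = second); each level needs >= 2 replicates.
#' @param min_abs_log2fc,q_max thresholds (defaults 1 and 0.05).
#' @return data.frame with `gene_id`, `log2fc`, `p`, `q`, `status`.
#' @export
callDegs <- function(counts, groups, min_abs_log2fc = 1, q_max = 0.05) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2, length(groups) == ncol(counts))
  if (any(table(groups) < 2))
    stop("each parent needs at least 2 replicates")
  libsize <- colSums(counts)
  norm <- sweep(counts, 2, mean(libsize) / libsize, `*`)
  a <- groups == levels(groups)[1]
  mean_a <- rowMeans(norm[, a, drop = FALSE])
  mean_b <- rowMeans(norm[, !a, drop = FALSE])
  log2fc <- log2((mean_a + 0.5) / (mean_b + 0.5))
  lg <- log2(norm + 0.5)
  p <- vapply(seq_len(nrow(lg)), function(i) {
    x <- lg[i, a]; y <- lg[i, !a]
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(if (mean(x) == mean(y)) 1 else 0)
    stats::t.test(x, y)$p.value
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  status <- rep("ns", length(p))
  status[log2fc > min_abs_log2fc & q < q_max] <- "up"
  status[log2fc < -min_abs_log2fc & q < q_max] <- "down"
  data.frame(gene_id = rownames(counts), log2fc = log2fc, p = p, q = q,
             status = status, row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-dataset fold-change gates for regulators and targets
#'
#' For each dataset (two condition means per gene), computes the
#' direction-free fold change `max(meanA/meanB, meanB/meanA)` and flags
#' genes passing the regulator gate (>= `reg_fc`, default 1.2) and the
#' target gate (>= `tgt_fc`, default 1.5). Zero means get a +0.5 pseudocount
#' (applied to both conditions of that gene) so a (0, 0) gene has ratio 1.
#'
#' @param datasets named list; each element a data.frame/matrix with columns
#'   `mean_a`, `mean_b` and gene ids as rownames (or a `gene_id` column).
#' @param reg_fc,tgt_fc the two gates.
#' @return A list with logical gene x dataset matrices `regulator` and
#'   `target`, and the numeric `ratio` matrix.
#' @export
foldChangeFlags <- function(datasets, reg_fc = 1.2, tgt_fc = 1.5) {
  one <- function(d) {
    if (!is.null(d$gene_id)) {
      rn <- d$gene_id
      d <- as.matrix(d[, c("mean_a", "mean_b")])
      rownames(d) <- rn
    } else d <- as.matrix(d[, c("mean_a", "mean_b")])
    a <- d[, "mean_a"]; b <- d[, "mean_b"]
    z <- pmin(a, b) == 0
    a[z] <- a[z] + 0.5; b[z] <- b[z] + 0.5
    r <- pmax(a / b, b / a)
    names(r) <- rownames(d)
    r
  }
  ratios <- lapply(datasets, one)
  genes <- unique(unlist(lapply(ratios, names)))
  ratio <- matrix(NA_real_, length(genes), length(datasets),
                  dimnames = list(genes, names(datasets)))
  for (k in seq_along(ratios)) ratio[names(ratios[[k]]), k] <- ratios[[k]]
  list(regulator = !is.na(ratio) & ratio >= reg_fc,
       target = !is.na(ratio) & ratio >= tgt_fc,
       ratio = ratio)
}

#' Minor allele frequency of a dosage vector
#'
#' `min(p, 1 - p)` with `p = sum(dosages) / (2 * n_nonmissing)`.
#'
#' @param d numeric dosage vector (0/1/2, `NA` missing).
#' @return MAF in [0, 0.5], or `NA` if all dosages are missing.
#' @export
mafOf <- function(d) {
  d <- d[!is.na(d)]
  if (!length(d)) return(NA_real_)
  p <- sum(d) / (2 * length(d))
  min(p, 1 - p)
}

#' Filter SNPs by site quality, MAF and missingness
#'
#' Keeps SNPs with `qual >= qual_min`, MAF strictly greater than `maf_min`
#' and missing fraction strictly below `miss_max`. Sites where every dosage
#' is missing are dropped with a warning (MAF undefined). Idempotent.
#'
#' @param gd a [GenotypeData].
#' @param qual_min,maf_min,miss_max thresholds (defaults 50, 0.05, 0.10).
#' @return The filtered [GenotypeData].
#' @export
filterSnps <- function(gd, qual_min = 50, maf_min = 0.05, miss_max = 0.10) {
  d <- dosages(gd)
  miss <- rowMeans(is.na(d))
  maf <- apply(d, 1, mafOf)
  if (any(all_missing <- miss == 1))
    warning(sprintf("%d site(s) with all dosages missing dropped",
                    sum(all_missing)))
  keep <- !is.na(maf) & snpQual(gd) >= qual_min & maf > maf_min &
    miss < miss_max
  gd[keep, ]
}

.SPLICE_BP <- 2L  # canonical splice donor/acceptor dinucleotide

#' Classify SNPs by functional context
#'
#' Assigns each SNP exactly one category with most-severe-wins precedence:
#' coding (`cds_synonymous` / `cds_nonsynonymous`, or `cds_unknown` when no
#' CDS sequence is available) > `intron` / `utr_or_other` (inside a gene but
#' not coding) > `upstream` / `downstream` (within `flank_bp` of the nearest
#' gene, strand-aware) > `intergenic`. Coding single-base substitutions are
#' classified by rebuilding the reference codon from the spliced CDS
#' sequence and substituting the ALT base. `large_effect` marks stop-gain,
#' stop-loss, start-loss, frameshift-length indels in CDS, and variants on
#' the 2 bp splice dinucleotides.
#'
#' @param gd a [GenotypeData].
#' @param gm a [GeneModels]; CDS sequences enable synonymous /
#'   nonsynonymous calls.
#' @param flank_bp upstream/downstream window (default 5000).
#' @return data.frame with `snp_id`, `category`, `large_effect`, `gene_id`
#'   (the assigning gene or `NA`).
#' @export
annotateSnps <- function(gd, gm, flank_bp = 5000) {
  rr <- rowRanges(gd)
  fl <- .flattenModels(gm)
  n <- length(rr)
  snp_pos <- start(rr)
  ref <- mcols(rr)$ref; alt <- mcols(rr)$alt
  category <- rep("intergenic", n)
  large <- rep(FALSE, n)
  gene_of <- rep(NA_character_, n)

  ov <- findOverlaps(rr, geneRanges(gm), ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  GC <- Biostrings::GENETIC_CODE
  for (qi in unique(qh)) {
    hits <- sh[qh == qi]
    pos <- snp_pos[qi]
    assigned <- FALSE
    for (gi in hits) {
      rows <- fl$rows_by_gene[[gi]]
      if (is.null(rows)) next
      if (any(fl$cs[rows] <= pos & fl$ce[rows] >= pos)) {
        res <- .classifyCoding(fl, gi, pos, ref[qi], alt[qi], GC)
        category[qi] <- res$category; large[qi] <- res$large
        gene_of[qi] <- fl$gid[gi]; assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      # inside a gene but not coding: intron vs UTR/other; splice check
      gi <- hits[1]
      rows <- fl$rows_by_gene[[gi]]
      in_intron <- FALSE; at_splice <- FALSE
      if (length(rows) > 1) {
        rows <- rows[order(fl$cs[rows])]   # genomic order
        for (j in seq_len(length(rows) - 1)) {
          i_start <- fl$ce[rows[j]] + 1L; i_end <- fl$cs[rows[j + 1]] - 1L
          if (pos >= i_start && pos <= i_end) {
            in_intron <- TRUE
            at_splice <- pos <= i_start + .SPLICE_BP - 1L ||
              pos >= i_end - .SPLICE_BP + 1L
            break
          }
        }
      }
      category[qi] <- if (in_intron) "intron" else "utr_or_other"
      large[qi] <- at_splice
      gene_of[qi] <- fl$gid[hits[1]]
    }
  }

  # upstream/downstream for SNPs outside all genes
  out_idx <- which(category == "intergenic")
  if (length(out_idx) && length(fl$gid)) {
    snp_chr <- as.character(seqnames(rr))
    for (qi in out_idx) {
      same <- which(fl$gchr == snp_chr[qi])
      if (!length(same)) next
      pos <- snp_pos[qi]
      dist <- pmin(abs(fl$gs[same] - pos), abs(pos - fl$ge[same]))
      j <- same[which.min(dist)]
      dd <- min(dist)
      if (dd >= 1 && dd <= flank_bp) {
        before <- pos < fl$gs[j]   # SNP 5' of gene in genomic coords
        up <- if (fl$gminus[j]) !before else before
        category[qi] <- if (up) "upstream" else "downstream"
        gene_of[qi] <- fl$gid[j]
      }
    }
  }

  data.frame(snp_id = names(rr), category = category, large_effect = large,
             gene_id = gene_of, row.names = NULL, stringsAsFactors = FALSE)
}

# plain-vector view of a GeneModels object (S4 subsetting is too slow for
# per-SNP loops); CDS rows are in transcription order within each gene
.flattenModels <- function(gm) {
  g <- geneRanges(gm)
  cds <- cdsByGene(gm)
  flat <- unlist(cds, use.names = FALSE)
  cgene <- rep(seq_along(g), lengths(cds))
  w <- if (length(flat)) end(flat) - start(flat) + 1L else integer(0)
  cumoff <- integer(length(w))
  if (length(w)) {
    sp <- split(seq_along(w), cgene)
    for (idx in sp) cumoff[idx] <- c(0L, cumsum(w[idx][-length(idx)]))
  }
  list(gid = names(g), gchr = as.character(seqnames(g)),
       gs = start(g), ge = end(g),
       gminus = as.character(strand(g)) == "-",
       cs = if (length(flat)) start(flat) else integer(0),
       ce = if (length(flat)) end(flat) else integer(0),
       cumoff = cumoff,
       rows_by_gene = split(seq_along(cgene), factor(cgene, levels = seq_along(g))),
       seqs = stats::setNames(as.character(cdsSeqs(gm)), names(cdsSeqs(gm))))
}

.classifyCoding <- function(fl, gi, pos, ref, alt, GC) {
  indel <- nchar(ref) != nchar(alt)
  if (indel) {
    shift <- abs(nchar(ref) - nchar(alt)) %% 3L != 0L
    return(list(category = "cds_nonsynonymous", large = shift))
  }
  gid <- fl$gid[gi]
  if (nchar(ref) != 1L || !gid %in% names(fl$seqs))
    return(list(category = "cds_unknown", large = FALSE))
  rows <- fl$rows_by_gene[[gi]]        # transcription order
  j <- rows[fl$cs[rows] <= pos & fl$ce[rows] >= pos][1]
  if (is.na(j)) return(list(category = "cds_unknown", large = FALSE))
  minus <- fl$gminus[gi]
  idx <- fl$cumoff[j] +
    (if (minus) fl$ce[j] - pos + 1L else pos - fl$cs[j] + 1L)
  seq <- fl$seqs[[gid]]
  cod_i <- (idx - 1L) %/% 3L + 1L
  cod_from <- (cod_i - 1L) * 3L + 1L
  if (cod_from + 2L > nchar(seq))
    return(list(category = "cds_unknown", large = FALSE))
  ref_codon <- substr(seq, cod_from, cod_from + 2L)
  base <- if (minus) chartr("ACGT", "TGCA", alt) else alt
  off <- idx - cod_from + 1L
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- base
  aa_ref <- GC[ref_codon]; aa_alt <- GC[alt_codon]
  if (is.na(aa_ref) || is.na(aa_alt))
    return(list(category = "cds_unknown", large = FALSE))
  syn <- aa_ref == aa_alt
  large <- (aa_ref != "*" && aa_alt == "*") ||        # stop-gain
    (aa_ref == "*" && aa_alt != "*") ||               # stop-loss
    (cod_i == 1L && ref_codon == "ATG" && alt_codon != "ATG")  # start-loss
  list(category = if (syn) "cds_synonymous" else "cds_nonsynonymous",
       large = unname(large))
}
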