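#' Genome-wide SNP-gene association with an additive linear model
#'
#' Regresses each gene's normalized expression on each SNP's additive dosage
#' (simple OLS, no covariates), the fast-matrix equivalent of per-pair
#' `lm(expr ~ dosage)`. Missing dosages are mean-imputed per SNP before
#' testing, so `n_used` equals the sample count for every pair. The whole
#' SNP x gene grid is computed by one centered cross-product; slopes,
#' t statistics and two-sided p-values `2 * (1 - F_t(|t|; n - 2))` agree
#' with pairwise OLS to numerical precision.
#'
#' @param gd a [GenotypeData] (filtered).
#' @param expr an [ExpressionData] with unit `"normalized-score"` (or any
#'   complete numeric matrix unit).
#' @param p_max only pairs with `p <= p_max` are returned (default 1 keeps
#'   all); the count of tested pairs is attached regardless.
#' @return data.frame with `snp_id`, `gene_id`, `beta`, `t_stat`, `p`,
#'   `n_used`, plus attributes `n_tested` (pairs tested) and `n_skipped`
#'   (SNPs skipped for zero post-imputation variance).
#' @export
associateAll <- function(gd, expr, p_max = 1) {
  d <- dosages(gd)
  e <- exprValues(expr)
  stopifnot(ncol(d) == ncol(e))
  n <- ncol(d)
  if (n < 3) stop("need at least 3 samples")
  # mean-impute missing dosages per SNP
  if (anyNA(d)) {
    mu <- rowMeans(d, na.rm = TRUE)
    idx <- which(is.na(d))
    d[idx] <- mu[(idx - 1L) %% nrow(d) + 1L]
  }
  sd_g <- apply(d, 1, stats::sd)
  skip <- sd_g == 0 | is.na(sd_g)
  n_skipped <- sum(skip)
  d <- d[!skip, , drop = FALSE]
  sd_g <- sd_g[!skip]
  gc_ <- d - rowMeans(d)
  ec <- e - rowMeans(e)
  sd_e <- sqrt(rowSums(ec^2) / (n - 1))
  # correlation matrix SNP x gene via cross-product of standardized rows
  r <- tcrossprod(gc_ / (sd_g * sqrt(n - 1)), ec / (sd_e * sqrt(n - 1)))
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  keep <- which(p <= p_max, arr.ind = TRUE)
  beta <- r[keep] * (sd_e[keep[, 2]] / sd_g[keep[, 1]])
  res <- data.frame(snp_id = rownames(d)[keep[, 1]],
                    gene_id = rownames(e)[keep[, 2]],
                    beta = beta, t_stat = tt[keep], p = p[keep],
                    n_used = rep(n, nrow(keep)), stringsAsFactors = FALSE)
  res <- res[order(match(res$gene_id, rownames(e)),
                   match(res$snp_id, rownames(d))), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_tested") <- nrow(d) * nrow(e)
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Bonferroni-corrected genome-wide p-value threshold
#'
#' `alpha / (n_snps * n_genes)`, the family-wise gate over all SNP-gene
#' pairs.
#'
#' @param n_snps,n_genes positive test-dimension counts.
#' @param alpha family-wise error rate (default 0.05).
#' @return The p-value threshold.
#' @export
bonferroniThreshold <- function(n_snps, n_genes, alpha = 0.05) {
  if (n_snps <= 0 || n_genes <= 0) stop("counts must be positive")
  alpha / (n_snps * n_genes)
}

#' Chain significant SNPs into eQTL blocks
#'
#' For each gene and chromosome, significant SNPs sorted by position are
#' chained single-linkage: consecutive SNPs join one cluster iff their gap
#' is at most `max_gap_bp`. Clusters with fewer than `min_snps` members are
#' discarded. The block span is `[min pos, max pos]`; the lead SNP is the
#' minimum-p member, ties broken by smaller position. Output is invariant
#' to input row order.
#'
#' @param sig data.frame of significant associations (`snp_id`, `gene_id`,
#'   `p`) — i.e. rows of [associateAll()] with `p <= threshold`.
#' @param snp_pos a `GRanges` of SNP positions named by snp id (e.g.
#'   `rowRanges()` of the genotype object).
#' @param max_gap_bp chaining gap (default 10000).
#' @param min_snps minimum cluster size (default 3).
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `n_snps`,
#'   `lead_snp`, `lead_pos`, `lead_p`, one row per block.
#' @export
clusterBlocks <- function(sig, snp_pos, max_gap_bp = 10000, min_snps = 3) {
  empty <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), lead_snp = character(0),
                      lead_pos = integer(0), lead_p = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(sig) == 0) return(empty)
  m <- match(sig$snp_id, names(snp_pos))
  if (anyNA(m)) stop("significant SNPs missing from snp_pos")
  sig$chrom <- as.character(seqnames(snp_pos))[m]
  sig$pos <- start(snp_pos)[m]
  out <- list()
  for (key in split(seq_len(nrow(sig)),
                    paste(sig$gene_id, sig$chrom, sep = "\r"))) {
    s <- sig[key, , drop = FALSE]
    s <- s[order(s$pos, s$snp_id), , drop = FALSE]
    gap_break <- c(FALSE, diff(s$pos) > max_gap_bp)
    cl <- cumsum(gap_break)
    for (ci in split(seq_len(nrow(s)), cl)) {
      if (length(ci) < min_snps) next
      b <- s[ci, , drop = FALSE]
      lead <- b[order(b$p, b$pos), ][1, ]
      out[[length(out) + 1]] <-
        data.frame(gene_id = b$gene_id[1], chrom = b$chrom[1],
                   start = min(b$pos), end = max(b$pos),
                   n_snps = nrow(b), lead_snp = lead$snp_id,
                   lead_pos = lead$pos, lead_p = lead$p,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$gene_id, res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify eQTL blocks as cis or trans
#'
#' A block is cis iff its lead SNP lies on the target gene's chromosome
#' within `[gene start - window_bp, gene end + window_bp]` (boundaries
#' inclusive); otherwise trans. Blocks whose target gene has no model are
#' flagged `unclassified` with a message and should be excluded downstream.
#'
#' @param blocks data.frame from [clusterBlocks()].
#' @param gm a [GeneModels].
#' @param window_bp the cis window around the gene body (default 10000).
#' @return `blocks` with an added `cls` column (`cis`/`trans`/
#'   `unclassified`).
#' @export
classifyCisTrans <- function(blocks, gm, window_bp = 10000) {
  g <- geneRanges(gm)
  m <- match(blocks$gene_id, names(g))
  cls <- rep("unclassified", nrow(blocks))
  ok <- !is.na(m)
  if (any(!ok))
    message(sprintf("classifyCisTrans: %d block(s) without a gene model left unclassified",
                    sum(!ok)))
  same <- ok & blocks$chrom == as.character(seqnames(g))[m]
  inwin <- same & blocks$lead_pos >= (start(g)[m] - window_bp) &
    blocks$lead_pos <= (end(g)[m] + window_bp)
  cls[ok] <- "trans"
  cls[which(inwin)] <- "cis"
  blocks$cls <- cls
  blocks
}

#' Compare cis and trans lead p-value distributions
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction) on `-log10(lead_p)` of cis vs trans blocks.
#'
#' @param blocks classified blocks (column `cls`).
#' @return list with `statistic` (the rank-sum W for the cis sample) and
#'   `p.value`.
#' @export
compareCisTrans <- function(blocks) {
  x <- -log10(blocks$lead_p[blocks$cls == "cis"])
  y <- -log10(blocks$lead_p[blocks$cls == "trans"])
  if (!length(x) || !length(y))
    stop("need at least one block of each class")
  wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}
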