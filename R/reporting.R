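#' Percentage share of a count within a total
#'
#' The reporting primitive behind every "x of y (z%)" figure the pipeline
#' prints: `100 * count / total`.
#'
#' @param count,total non-negative; `total > 0`, `count <= total`.
#' @return The percentage (not rounded).
#' @export
percentShare <- function(count, total) {
  if (total <= 0) stop("total must be positive")
  if (count < 0 || count > total) stop("count must lie in [0, total]")
  100 * count / total
}

#' Summary statistics over classified eQTL blocks
#'
#' Recomputes the headline shares of an eQTL map: the trans share among
#' classified blocks, the share of eGenes with more than five eQTL blocks,
#' and the share with exactly one.
#'
#' @param blocks classified blocks (columns `gene_id`, `cls`).
#' @return list with `n_blocks`, `n_genes`, `n_cis`, `n_trans`,
#'   `trans_share_pct`, `genes_gt5_pct`, `single_eqtl_pct`.
#' @export
blockSummary <- function(blocks) {
  cl <- blocks$cls
  n_cis <- sum(cl == "cis"); n_trans <- sum(cl == "trans")
  per_gene <- table(blocks$gene_id)
  list(n_blocks = nrow(blocks),
       n_genes = length(per_gene),
       n_cis = n_cis, n_trans = n_trans,
       trans_share_pct = if (n_cis + n_trans > 0)
         percentShare(n_trans, n_cis + n_trans) else NA_real_,
       genes_gt5_pct = if (length(per_gene))
         percentShare(sum(per_gene > 5), length(per_gene)) else NA_real_,
       single_eqtl_pct = if (length(per_gene))
         percentShare(sum(per_gene == 1), length(per_gene)) else NA_real_)
}

#' eQTL coverage of a gene set
#'
#' Share of the set's genes controlled by at least one eQTL block, and of
#' those, the share regulated solely by trans-eQTLs.
#'
#' @param blocks classified blocks.
#' @param gene_set character vector of gene ids (e.g. WFRGs).
#' @return list with `n_set`, `n_with_eqtl`, `with_eqtl_pct`,
#'   `n_trans_only`, `trans_only_pct`.
#' @export
geneSetEqtlSummary <- function(blocks, gene_set) {
  b <- blocks[blocks$gene_id %in% gene_set, , drop = FALSE]
  with_eqtl <- unique(b$gene_id)
  cis_genes <- unique(b$gene_id[b$cls == "cis"])
  trans_only <- setdiff(unique(b$gene_id[b$cls == "trans"]), cis_genes)
  list(n_set = length(unique(gene_set)),
       n_with_eqtl = length(with_eqtl),
       with_eqtl_pct = if (length(gene_set))
         percentShare(length(with_eqtl), length(unique(gene_set))) else NA_real_,
       n_trans_only = length(trans_only),
       trans_only_pct = if (length(with_eqtl))
         percentShare(length(trans_only), length(with_eqtl)) else NA_real_)
}

#' DEG direction summary
#'
#' @param degs output of [callDegs()].
#' @return list with `n_deg`, `n_up`, `n_down`, `up_share_pct`.
#' @export
degSummary <- function(degs) {
  n_up <- sum(degs$status == "up"); n_down <- sum(degs$status == "down")
  list(n_deg = n_up + n_down, n_up = n_up, n_down = n_down,
       up_share_pct = if (n_up + n_down > 0)
         percentShare(n_up, n_up + n_down) else NA_real_)
}

#' SNP functional-category shares
#'
#' @param snp_ann output of [annotateSnps()].
#' @return list with the total, per-category counts, and the flanking
#'   (upstream + downstream) and coding shares in percent.
#' @export
snpCategorySummary <- function(snp_ann) {
  tab <- table(snp_ann$category)
  total <- nrow(snp_ann)
  flank <- sum(tab[intersect(c("upstream", "downstream"), names(tab))])
  coding <- sum(tab[grep("^cds_", names(tab))])
  list(n_total = total, counts = as.list(tab),
       flank_share_pct = percentShare(flank, total),
       coding_share_pct = percentShare(coding, total),
       n_large_effect = sum(snp_ann$large_effect))
}
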