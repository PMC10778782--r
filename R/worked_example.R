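#' A tiny fixed worked-example dataset
#'
#' Builds a hard-coded 6-sample, 2-chromosome (100 kb each), 8-gene, 30-SNP
#' dataset with one planted cis effect, one planted trans effect, and one
#' 3-target mini-hotspot. All values are fixed arithmetic (no RNG), so the
#' emitted files are byte-identical across calls. The cis SNP sits 1,354 bp
#' upstream of its target gene, a geometry typical of promoter-proximal
#' cis-eQTLs; the trans SNP cluster lies on the other chromosome, more than
#' 10 kb from every gene.
#'
#' @param out_dir optional directory; when given, the same files as
#'   [simulateDataset()] are written there.
#' @return A list shaped like the return of [simulateDataset()].
#' @export
makeWorkedExample <- function(out_dir = NULL) {
  samples <- paste0("S", 1:6)
  genome <- c(chr1 = 100000L, chr2 = 100000L)
  genes <- data.frame(
    gene_id = paste0("g", 1:8),
    chrom = rep(c("chr1", "chr2"), each = 4),
    start = c(20000L, 40000L, 60000L, 80000L, 5000L, 20000L, 40000L, 90000L),
    strand = c("+", "+", "-", "+", "+", "+", "-", "+"),
    stringsAsFactors = FALSE)
  genes$end <- genes$start + .GENE_LEN - 1L
  cds_seq <- paste0("ATG", strrep("GCT", 232L), "TAA")
  gm <- .geneModelsFromTable(genes, rep(cds_seq, 8))

  # dosage patterns
  A <- c(0, 0, 1, 1, 2, 2)        # cis causal (target g1)
  B <- c(2, 1, 0, 2, 1, 0)        # trans causal (target g2)
  H <- c(0, 1, 2, 2, 1, 0)        # hotspot causal (targets g3, g4, g6)
  bg <- list(c(0, 1, 0, 1, 0, 1), c(1, 0, 1, 0, 1, 0), c(1, 1, 0, 0, 1, 1),
             c(2, 1, 0, 1, 2, 0), c(0, 0, 1, 1, 0, 0), c(1, 2, 1, 0, 1, 2),
             c(0, 2, 0, 2, 0, 2))

  snp <- function(id, chrom, pos, dosage, qual = 99) {
    list(id = id, chrom = chrom, pos = as.integer(pos),
         dosage = dosage, qual = qual)
  }
  bg_pos1 <- c(1000, 5000, 10000, 15000, 25000, 30000, 35000, 45000,
               55000, 65000, 75000, 85000, 95000)
  bg_pos2 <- c(2000, 10000, 15000, 30000, 35000, 60000, 80000, 95000)
  snps <- c(
    list(snp("cis_1", "chr1", 18646, A, 250),   # 20000 - 1354
         snp("cis_2", "chr1", 19200, A, 250),
         snp("cis_3", "chr1", 19700, A, 250),
         snp("trans_1", "chr2", 70000, B, 250),
         snp("trans_2", "chr2", 70500, B, 250),
         snp("trans_3", "chr2", 71000, B, 250),
         snp("hot_1", "chr2", 50000, H, 250),
         snp("hot_2", "chr2", 50400, H, 250),
         snp("hot_3", "chr2", 50800, H, 250)),
    lapply(seq_along(bg_pos1), function(i)
      snp(sprintf("bg1_%02d", i), "chr1", bg_pos1[i],
          bg[[(i - 1) %% 7 + 1]],
          qual = if (i == 13) 30 else 99)),      # one low-quality site
    lapply(seq_along(bg_pos2), function(i)
      snp(sprintf("bg2_%02d", i), "chr2",  bg_pos2[i],
          if (i == 8) rep(0, 6) else bg[[(i + 2) %% 7 + 1]]))  # one monomorphic
  )
  stopifnot(length(snps) == 30)
  dos <- do.call(rbind, lapply(snps, `[[`, "dosage"))
  colnames(dos) <- samples
  gr <- GRanges(vapply(snps, `[[`, character(1), "chrom"),
                IRanges(vapply(snps, function(s) s$pos, integer(1)), width = 1L),
                ref = "A", alt = "G",
                qual = vapply(snps, function(s) as.numeric(s$qual), numeric(1)))
  names(gr) <- vapply(snps, `[[`, character(1), "id")
  ord <- order(as.character(seqnames(gr)), start(gr))
  gd <- GenotypeData(dos[ord, , drop = FALSE], gr[ord])

  # deterministic expression: base + planted effects + fixed sinusoid jitter;
  # the two null genes carry fixed rank patterns chosen to be weakly
  # correlated (|r| < 0.45) with every dosage pattern above
  mu <- c(1.0, 1.2, 0.8, 1.2, 1.0, 1.0, 0.8, 0.6)
  noise <- outer(1:8, 1:6, function(i, j) 0.1 * sin(3 * i + 2 * j))
  le <- matrix(rep(mu, 6), nrow = 8) + noise
  le[1, ] <- le[1, ] + 1.0 * A
  le[2, ] <- le[2, ] + 1.0 * B
  le[3, ] <- le[3, ] + 1.0 * H
  le[4, ] <- le[4, ] + 1.0 * H
  le[6, ] <- le[6, ] + 1.0 * H   # g6: third (non-WFRG) hotspot target
  le[7, ] <- le[7, ] + 1.0 * H   # g7: regulator gene next to the hotspot
  le[5, ] <- mu[5] + 0.05 * c(1, 5, 2, 4, 6, 3)   # null gene
  le[8, ] <- mu[8] + 0.05 * c(3, 6, 4, 2, 5, 1)   # null gene
  fpkm_m <- round(exp(le), 4)
  dimnames(fpkm_m) <- list(genes$gene_id, samples)
  fpkm <- ExpressionData(fpkm_m, unit = "FPKM")

  # parent counts: 3 replicates per parent, fixed multiplicative jitter;
  # fold changes are paired across equal-baseline genes so that the total
  # library sizes of the two parents balance (no composition bias after
  # total-count normalization)
  lfc <- c(g1 = 2, g2 = 0.8, g3 = 1.0, g4 = -0.8, g5 = -2, g6 = 0,
           g7 = -1, g8 = 0)
  base <- round(exp(mu) * 30)
  jit <- c(1.0, 1.1, 0.9)
  pc <- cbind(
    sapply(jit, function(f) round(base * 2^(lfc / 2) * f)),
    sapply(jit, function(f) round(base * 2^(-lfc / 2) * f)))
  dimnames(pc) <- list(genes$gene_id,
                       c(paste0("NF_", 1:3), paste0("LS_", 1:3)))
  parent_groups <- factor(rep(c("NF", "LS"), each = 3), levels = c("NF", "LS"))

  annotations <- data.frame(
    gene_id = genes$gene_id,
    class = c("other", "other", "other", "other", "hormone", "other",
              "TF", "other"),
    is_wfrg = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)

  truth <- list(
    cis = data.frame(snp_id = "cis_1", gene_id = "g1", r2 = NA_real_,
                     stringsAsFactors = FALSE),
    trans = data.frame(snp_id = "trans_1", gene_id = "g2", r2 = NA_real_,
                       stringsAsFactors = FALSE),
    hotspots = data.frame(chrom = "chr2", start = 50000L, end = 50800L,
                          targets = I(list(c("g3", "g4", "g6"))),
                          regulators = I(list("g7")),
                          stringsAsFactors = FALSE),
    parent_de = data.frame(gene_id = names(lfc)[lfc != 0],
                           log2fc = unname(lfc[lfc != 0]),
                           stringsAsFactors = FALSE),
    reg_pairs = data.frame(regulator = "g7", target = c("g3", "g4"),
                           stringsAsFactors = FALSE))

  out <- list(genotypes = gd, geneModels = gm, fpkm = fpkm,
              parentCounts = pc, parentGroups = parent_groups,
              annotations = annotations, genome = genome, truth = truth,
              config = NULL)
  if (!is.null(out_dir)) .writeSimulated(out, out_dir)
  out
}

#' Pipeline configuration scaled to the worked example
#'
#' The genome-wide defaults (1 Mb windows, Bonferroni over millions of
#' pairs) are meaningless on a 200 kb toy genome with 6 samples, where the
#' smallest attainable rank-normal association p is ~0.005. This config
#' substitutes a fixed suggestive threshold and window geometry
#' proportionate to the fixture.
#'
#' @param seed RNG seed for the permutation stage.
#' @return A `pipeline_config`.
#' @export
workedExampleConfig <- function(seed = 1) {
  pipelineConfig(p_threshold = 0.006, win_bp = 2000, step_bp = 500,
                 n_perm = 200, min_component = 3, seed = seed)
}
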