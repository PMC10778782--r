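test_that("expression prevalence gate is strict at both levels", {
  n <- 120
  m <- rbind(
    kept = c(rep(5, 25), rep(0.5, n - 25)),    # 25/120 = 20.8% > 20%
    dropped = c(rep(5, 24), rep(0.5, n - 24)), # exactly 20%: strict >
    zero = rep(0, n))
  colnames(m) <- sprintf("S%03d", seq_len(n))
  kept <- filterExpressed(ExpressionData(m, unit = "FPKM"))
  expect_identical(rownames(kept), "kept")
  # FPKM exactly 1 does not count as expressed (strict >)
  m2 <- rbind(a = rep(1, 10))
  colnames(m2) <- sprintf("S%d", 1:10)
  expect_equal(nrow(filterExpressed(ExpressionData(m2, unit = "FPKM"))), 0)
})

test_that("inverse normal transform follows the Blom formula", {
  v <- matrix(c(3.2, 0.1, 7.5, 1.1, 4.4), nrow = 1,
              dimnames = list("g1", paste0("S", 1:5)))
  out <- exprValues(inverseNormal(ExpressionData(v, unit = "FPKM")))
  # oracle: direct evaluation of qnorm((r - 3/8) / (n + 1/4))
  expected <- qnorm((rank(v[1, ]) - 3 / 8) / (5 + 1 / 4))
  expect_equal(unname(out[1, ]), unname(expected), tolerance = 1e-12)
  expect_equal(exprUnit(inverseNormal(ExpressionData(v, unit = "FPKM"))),
               "normalized-score")

  # two tied maxima among n = 4: both at the average rank 3.5
  v2 <- matrix(c(1, 2, 9, 9), nrow = 1,
               dimnames = list("g", paste0("S", 1:4)))
  out2 <- exprValues(inverseNormal(ExpressionData(v2, unit = "FPKM")))
  expect_equal(unname(out2[1, 3]), qnorm((3.5 - 0.375) / 4.25))
  expect_equal(out2[1, 3], out2[1, 4])
})

test_that("inverse normal is invariant to monotone transforms and preserves order", {
  set.seed(31)
  for (i in 1:10) {
    x <- matrix(rnorm(30), nrow = 1, dimnames = list("g", paste0("S", 1:30)))
    a <- exprValues(inverseNormal(ExpressionData(exp(x), unit = "FPKM")))
    b <- exprValues(inverseNormal(ExpressionData(exp(3 * x) + 7, unit = "FPKM")))
    expect_equal(a, b, tolerance = 1e-12)
    expect_identical(order(a[1, ]), order(x[1, ]))
  }
  cst <- matrix(rep(2, 6), nrow = 1, dimnames = list("g", paste0("S", 1:6)))
  expect_warning(out <- inverseNormal(ExpressionData(cst, unit = "FPKM")),
                 "constant")
  expect_equal(unname(exprValues(out)[1, ]), rep(0, 6))
})

test_that("DEG calling flags planted fold changes and controls the null", {
  groups <- factor(rep(c("A", "B"), each = 5), levels = c("A", "B"))
  # identical counts: log2fc 0, ns
  cts <- matrix(rep(c(50, 60, 40, 55, 45), 2), nrow = 1,
                dimnames = list("g", paste0("S", 1:10)))
  res <- callDegs(cts, groups)
  expect_equal(res$log2fc, 0)
  expect_equal(res$status, "ns")

  # power: planted |log2fc| = 3 at dispersion 0.1, 5 reps per parent; half
  # up, half down so the two libraries stay balanced
  set.seed(7)
  n_genes <- 400
  mu <- runif(n_genes, 50, 500)
  sgn <- rep(c(1, -1), length.out = n_genes)
  mu_a <- mu * 8^(sgn / 2); mu_b <- mu * 8^(-sgn / 2)
  planted <- cbind(
    matrix(rnbinom(n_genes * 5, size = 10, mu = rep(mu_a, 5)), ncol = 5),
    matrix(rnbinom(n_genes * 5, size = 10, mu = rep(mu_b, 5)), ncol = 5))
  dimnames(planted) <- list(sprintf("p%03d", seq_len(n_genes)),
                            paste0("S", 1:10))
  res_p <- callDegs(planted, groups)
  flagged <- ifelse(sgn > 0, res_p$status == "up", res_p$status == "down")
  expect_gte(mean(flagged), 0.90)

  # null FDR: fraction with q < 0.05 small in a pure-null table
  nulls <- matrix(rnbinom(n_genes * 10, size = 10, mu = rep(mu, 10)),
                  ncol = 10, dimnames = dimnames(planted))
  res_n <- callDegs(nulls, groups)
  expect_lte(mean(res_n$q < 0.05), 0.05)

  expect_error(callDegs(cts, factor(c("A", rep("B", 9)))), "replicates")
})

test_that("label-permuted parents rarely reach significance", {
  set.seed(12)
  groups <- factor(rep(c("A", "B"), each = 4), levels = c("A", "B"))
  mu <- runif(300, 50, 500)
  cts <- matrix(rnbinom(300 * 8, size = 10, mu = rep(mu, 8)), ncol = 8,
                dimnames = list(sprintf("g%03d", 1:300), paste0("S", 1:8)))
  fracs <- replicate(10, {
    perm <- sample(ncol(cts))
    mean(callDegs(cts[, perm], groups)$q < 0.05)
  })
  expect_lte(mean(fracs), 0.05)
})

test_that("fold-change gates use the documented ratios and pseudocounts", {
  ds <- list(d1 = data.frame(gene_id = c("a", "b", "c"),
                             mean_a = c(3.0, 1.3, 0),
                             mean_b = c(2.0, 1.0, 0)))
  fl <- foldChangeFlags(ds)
  expect_true(fl$regulator["a", "d1"])   # ratio 1.5 >= 1.2
  expect_true(fl$target["a", "d1"])      # boundary inclusive: 1.5 >= 1.5
  expect_true(fl$regulator["b", "d1"])   # 1.3 >= 1.2
  expect_false(fl$target["b", "d1"])     # 1.3 < 1.5
  expect_false(fl$regulator["c", "d1"])  # (0,0) -> pseudocount ratio 1
  expect_false(fl$target["c", "d1"])
  expect_equal(unname(fl$ratio["a", "d1"]), 1.5)
})

test_that("SNP filter applies quality, MAF and missingness gates strictly", {
  n <- 120
  d <- rbind(
    ok = rep(c(0, 1, 2, 1), 30),
    miss12 = c(rep(NA, 12), rep(c(0, 1), 54)),      # exactly 10% missing
    rare = c(rep(1, 12), rep(0, 108)),              # maf 0.05 exactly
    good_rare = c(rep(1, 13), rep(0, 107)),         # maf > 0.05
    allmiss = rep(NA_real_, n))
  colnames(d) <- sprintf("S%03d", seq_len(n))
  gd <- makeGeno(d, qual = c(99, 99, 99, 99, 99))
  expect_warning(kept <- filterSnps(gd), "all dosages missing")
  expect_setequal(rownames(kept), c("ok", "good_rare"))
  expect_equal(mafOf(d["ok", ]), 0.5)

  # qual 49.9 dropped, 50 kept
  gd2 <- makeGeno(rbind(a = rep(c(0, 1, 2), 40), b = rep(c(0, 1, 2), 40)),
                  qual = c(49.9, 50))
  expect_identical(rownames(filterSnps(gd2)), "b")

  # idempotent
  k1 <- suppressWarnings(filterSnps(gd))
  k2 <- filterSnps(k1)
  expect_identical(rownames(k1), rownames(k2))
  expect_identical(dosages(k1), dosages(k2))
})

test_that("coding SNPs classify by codon substitution, strand-aware", {
  # + strand gene at 1000, CDS 1000-1899; codon2 = TGG, codon3 = GAA
  seq <- paste0("ATG", "TGG", "GAA", strrep("GCT", 296), "TAA")
  gm <- makeCodingGene(seq = seq)
  # TGG -> TGA: third base of codon2 at 1005, G->A: stop-gain
  gd <- makeGeno(rbind(s1 = rep(1, 4), s2 = rep(1, 4), s3 = rep(1, 4)),
                 pos = c(1005L, 1008L, 1002L),
                 ref = c("G", "A", "G"), alt = c("A", "G", "C"),
                 ids = c("stopgain", "syn", "startloss"))
  ann <- annotateSnps(gd, gm)
  expect_equal(ann$category[ann$snp_id == "stopgain"], "cds_nonsynonymous")
  expect_true(ann$large_effect[ann$snp_id == "stopgain"])
  # GAA -> GAG: both Glu
  expect_equal(ann$category[ann$snp_id == "syn"], "cds_synonymous")
  expect_false(ann$large_effect[ann$snp_id == "syn"])
  # ATG -> ACG: start-loss
  expect_true(ann$large_effect[ann$snp_id == "startloss"])

  # minus strand: genomic 5897 is the third base of codon1 (ATG read 5899->)
  gm2 <- makeCodingGene(id = "gm", start = 5000L, strand = "-")
  # transcript ATG GCT ...: genomic bases at 5899,5898,5897 are complement
  gd2 <- makeGeno(rbind(s = rep(1, 4)), pos = 5897L, ref = "C", alt = "T",
                  ids = "minus_startloss")
  ann2 <- annotateSnps(gd2, gm2)
  expect_equal(ann2$category, "cds_nonsynonymous")  # ATG -> ATA (M -> I)
  expect_true(ann2$large_effect)
})

test_that("frameshift indels and splice dinucleotides are large-effect", {
  # gene 1000-1899 with two CDS and an intron 1300-1599
  cds <- GenomicRanges::GRangesList(list(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1000, 1600), c(1299, 1899)), strand = "+")))
  gm <- makeCodingGene(cds = cds, seq = paste0("ATG", strrep("GCT", 198), "TAA"))
  gd <- makeGeno(rbind(a = rep(1, 4), b = rep(1, 4), c = rep(1, 4)),
                 pos = c(1100L, 1301L, 1450L),
                 ref = c("GCT", "G", "A"), alt = c("G", "A", "C"),
                 ids = c("inframe_del", "splice_donor", "deep_intron"))
  ann <- annotateSnps(gd, gm)
  expect_equal(ann$category[1], "cds_nonsynonymous")
  expect_true(ann$large_effect[1])    # net 2 bp deletion: frameshift
  expect_equal(ann$category[2], "intron")
  expect_true(ann$large_effect[2])    # first intron base
  expect_equal(ann$category[3], "intron")
  expect_false(ann$large_effect[3])
})

test_that("flanking assignment respects strand and the 5 kb window", {
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20000, 21000),
                              strand = "+")
  names(g) <- "gp"
  gm <- GeneModels(g)
  gd <- makeGeno(rbind(a = rep(1, 4), b = rep(1, 4), c = rep(1, 4),
                       d = rep(1, 4)),
                 pos = c(15001L, 14999L, 25000L, 50000L),
                 ids = c("up4999", "beyond", "down", "far"))
  ann <- annotateSnps(gd, gm)
  expect_equal(ann$category, c("upstream", "intergenic", "downstream",
                               "intergenic"))

  # on a minus-strand gene the labels swap
  GenomicRanges::strand(g) <- "-"
  gm2 <- GeneModels(g)
  ann2 <- annotateSnps(gd, gm2)
  expect_equal(ann2$category[1], "downstream")
  expect_equal(ann2$category[3], "upstream")
})

test_that("annotation categories partition the SNP set", {
  sim <- simulateDataset(recoveryConfig(seed = 33))
  snps <- suppressWarnings(filterSnps(sim$genotypes))
  ann <- annotateSnps(snps, sim$geneModels)
  expect_equal(nrow(ann), nrow(snps))
  expect_equal(sum(table(ann$category)), nrow(snps))
  expect_false(anyNA(ann$category))
  # large effects only in coding or splice contexts
  le <- ann[ann$large_effect, ]
  expect_true(all(grepl("^cds_", le$category) | le$category == "intron"))
})
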