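# pairwise OLS oracle, independent of the matrix implementation
olsOracle <- function(g, e) {
  fit <- summary(stats::lm(e ~ g))
  co <- stats::coef(fit)
  list(beta = co["g", "Estimate"], t = co["g", "t value"],
       p = co["g", "Pr(>|t|)"])
}

test_that("matrix association equals pairwise OLS on a random fixture", {
  set.seed(101)
  n <- 30
  d <- matrix(rbinom(50 * n, 2, 0.3), nrow = 50,
              dimnames = list(sprintf("s%02d", 1:50), sprintf("I%02d", 1:n)))
  e <- matrix(rnorm(20 * n), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("I%02d", 1:n)))
  gd <- makeGeno(d)
  res <- associateAll(gd, ExpressionData(e, unit = "normalized-score"))
  expect_equal(nrow(res), 50 * 20)
  idx <- sample(nrow(res), 100)
  for (i in idx) {
    o <- olsOracle(d[res$snp_id[i], ], e[res$gene_id[i], ])
    expect_equal(res$t_stat[i], o$t, tolerance = 1e-10)
    expect_equal(res$beta[i], o$beta, tolerance = 1e-10)
    expect_equal(res$p[i], o$p, tolerance = 1e-10)
  }
})

test_that("the six-point worked association matches closed-form OLS", {
  g <- c(0, 0, 1, 1, 2, 2)
  e <- c(0.1, -0.1, 1.1, 0.9, 2.2, 1.8)
  gd <- makeGeno(matrix(g, nrow = 1, dimnames = list("s1", paste0("I", 1:6))))
  ed <- ExpressionData(matrix(e, nrow = 1,
                              dimnames = list("g1", paste0("I", 1:6))),
                       unit = "normalized-score")
  res <- associateAll(gd, ed)
  o <- olsOracle(g, e)
  expect_equal(res$beta, o$beta, tolerance = 1e-12)
  expect_equal(res$t_stat, o$t, tolerance = 1e-10)
  expect_equal(res$p, o$p, tolerance = 1e-10)
  expect_equal(res$n_used, 6L)
})

test_that("perfect fit gives beta 1 and an underflowing p", {
  g <- c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0)
  gd <- makeGeno(matrix(g, nrow = 1, dimnames = list("s1", paste0("I", 1:10))))
  ed <- ExpressionData(matrix(g, nrow = 1,
                              dimnames = list("g1", paste0("I", 1:10))),
                       unit = "normalized-score")
  res <- associateAll(gd, ed)
  expect_equal(res$beta, 1, tolerance = 1e-8)
  expect_true(is.finite(res$t_stat))
  expect_lt(res$p, 1e-12)
})

test_that("missing dosages are mean-imputed per SNP before testing", {
  set.seed(8)
  g <- c(0, 1, 2, NA, 1, 0, 2, NA, 1, 1)
  e <- rnorm(10)
  gd <- makeGeno(matrix(g, nrow = 1, dimnames = list("s1", paste0("I", 1:10))))
  ed <- ExpressionData(matrix(e, nrow = 1,
                              dimnames = list("g1", paste0("I", 1:10))),
                       unit = "normalized-score")
  res <- associateAll(gd, ed)
  gi <- g; gi[is.na(gi)] <- mean(g, na.rm = TRUE)
  o <- olsOracle(gi, e)
  expect_equal(res$t_stat, o$t, tolerance = 1e-10)
  expect_equal(res$n_used, 10L)
})

test_that("zero-variance dosages are skipped and counted", {
  d <- rbind(flat = rep(1, 6), ok = c(0, 1, 2, 0, 1, 2))
  colnames(d) <- paste0("I", 1:6)
  gd <- makeGeno(d)
  ed <- ExpressionData(matrix(rnorm(6), nrow = 1,
                              dimnames = list("g1", paste0("I", 1:6))),
                       unit = "normalized-score")
  res <- associateAll(gd, ed)
  expect_equal(attr(res, "n_skipped"), 1L)
  expect_identical(unique(res$snp_id), "ok")
})

test_that("Bonferroni threshold is alpha over the pair count", {
  expect_equal(bonferroniThreshold(1, 1, 0.05), 0.05)
  expect_equal(bonferroniThreshold(100, 10, 0.05), 5e-5)
  expect_error(bonferroniThreshold(0, 10), "positive")
})

# brute-force single-linkage clustering oracle
bruteBlocks <- function(pos, p, max_gap, min_snps) {
  o <- order(pos)
  pos <- pos[o]; p <- p[o]
  cl <- cumsum(c(FALSE, diff(pos) > max_gap))
  out <- list()
  for (k in unique(cl)) {
    i <- which(cl == k)
    if (length(i) < min_snps) next
    lead <- i[order(p[i], pos[i])][1]
    out[[length(out) + 1]] <- c(start = min(pos[i]), end = max(pos[i]),
                                n = length(i), lead_pos = pos[lead],
                                lead_p = p[lead])
  }
  out
}

test_that("block chaining matches the documented example and the oracle", {
  pos <- c(100L, 5000L, 12000L, 40000L)
  sig <- data.frame(snp_id = paste0("s", 1:4), gene_id = "g1",
                    p = c(1e-12, 1e-13, 1e-12, 1e-14))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1))
  names(gr) <- sig$snp_id
  b <- clusterBlocks(sig, gr)
  expect_equal(nrow(b), 1)             # {100, 5000, 12000}; 40000 a singleton
  expect_equal(b$start, 100)
  expect_equal(b$end, 12000)
  expect_equal(b$n_snps, 3)
  expect_equal(b$lead_snp, "s2")       # min p within the block

  # two SNPs only: below min_snps, no block
  b2 <- clusterBlocks(sig[1:2, ], gr[1:2])
  expect_equal(nrow(b2), 0)

  # three SNPs at an identical position: one zero-span block
  gr3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(rep(500L, 3), width = 1))
  names(gr3) <- paste0("t", 1:3)
  sig3 <- data.frame(snp_id = paste0("t", 1:3), gene_id = "g1",
                     p = c(1e-12, 1e-15, 1e-13))
  b3 <- clusterBlocks(sig3, gr3)
  expect_equal(nrow(b3), 1)
  expect_equal(b3$start, b3$end)
  expect_equal(b3$lead_snp, "t2")
})

test_that("block clustering agrees with brute-force single linkage", {
  set.seed(55)
  for (rep in 1:20) {
    m <- sample(3:25, 1)
    pos <- sort(sample.int(1e5, m))
    p <- 10^runif(m, -20, -12)
    perm <- sample(m)  # input order must not matter
    sig <- data.frame(snp_id = paste0("s", perm), gene_id = "gX",
                      p = p[perm])
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos[perm], width = 1))
    names(gr) <- sig$snp_id
    got <- clusterBlocks(sig, gr, max_gap_bp = 5000, min_snps = 3)
    want <- bruteBlocks(pos, p, 5000, 3)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      want_df <- do.call(rbind, want)
      o <- order(got$start)
      expect_equal(got$start[o], unname(want_df[, "start"]))
      expect_equal(got$end[o], unname(want_df[, "end"]))
      expect_equal(got$n_snps[o], unname(want_df[, "n"]))
      expect_equal(got$lead_pos[o], unname(want_df[, "lead_pos"]))
    }
  }
})

test_that("cis/trans classification uses an inclusive 10 kb gene window", {
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50000, 60000),
                              strand = "+")
  names(g) <- "gT"
  gm <- GeneModels(g)
  mk <- function(chrom, pos) {
    data.frame(gene_id = "gT", chrom = chrom, start = pos, end = pos,
               n_snps = 3L, lead_snp = "x", lead_pos = pos, lead_p = 1e-15,
               stringsAsFactors = FALSE)
  }
  b <- rbind(mk("chr1", 55000),   # inside gene body
             mk("chr1", 48646),   # 1354 bp upstream
             mk("chr1", 40000),   # exactly start - 10 kb: inclusive
             mk("chr1", 70000),   # exactly end + 10 kb: inclusive
             mk("chr1", 70001),   # one bp past: trans
             mk("chr2", 55000))   # other chromosome: trans
  cls <- classifyCisTrans(b, gm)$cls
  expect_equal(cls, c("cis", "cis", "cis", "cis", "trans", "trans"))

  # missing gene model: unclassified, with a message
  b2 <- mk("chr1", 1000); b2$gene_id <- "nope"
  expect_message(out <- classifyCisTrans(b2, gm), "unclassified")
  expect_equal(out$cls, "unclassified")
})

test_that("cis vs trans comparison matches exact rank-sum enumeration", {
  mk <- function(p, cls) data.frame(lead_p = p, cls = cls)
  # identical multisets: no shift
  b0 <- rbind(mk(c(1e-5, 1e-6, 1e-7), "cis"), mk(c(1e-5, 1e-6, 1e-7), "trans"))
  expect_gt(compareCisTrans(b0)$p.value, 0.99)

  # cis -log10 p (5,6,7) vs trans (1,2,3)
  b1 <- rbind(mk(10^-c(5, 6, 7), "cis"), mk(10^-c(1, 2, 3), "trans"))
  got <- compareCisTrans(b1)
  x <- c(5, 6, 7); y <- c(1, 2, 3)
  # oracle: rank-sum statistic and its exact tail over all C(6,3) splits
  W_obs <- sum(rank(c(x, y))[1:3]) - 3 * 4 / 2
  combos <- combn(6, 3)
  vals <- c(x, y)
  W_all <- apply(combos, 2, function(i)
    sum(rank(vals)[i]) - 3 * 4 / 2)
  expect_equal(got$statistic, W_obs)
  p_exact <- mean(abs(W_all - 4.5) >= abs(W_obs - 4.5))
  expect_equal(p_exact, 2 / 20)  # the enumeration itself
  expect_lt(got$p.value, 0.1)    # normal approximation flags the shift

  expect_error(compareCisTrans(mk(1e-5, "cis")), "each class")
})

set.seed(6060)  # drives the replicate seeds below deterministically
test_that("planted cis effects are stronger and Wilcoxon detects the shift", {
  hits <- replicate(20, {
    cfg <- simulationConfig(n_samples = 120, n_chromosomes = 2,
                            chrom_length_bp = 2e6, n_genes = 30, n_snps = 200,
                            n_cis_effects = 6, n_trans_effects = 6,
                            cis_r2 = 0.6, trans_r2 = 0.3,
                            hotspot_spec = list(), missing_rate = 0,
                            seed = sample.int(1e6, 1))
    sim <- simulateDataset(cfg)
    norm <- inverseNormal(filterExpressed(sim$fpkm))
    snps <- suppressWarnings(filterSnps(sim$genotypes))
    thr <- bonferroniThreshold(nrow(snps), nrow(norm))
    assoc <- associateAll(snps, norm, p_max = thr)
    blocks <- classifyCisTrans(clusterBlocks(assoc,
                                             SummarizedExperiment::rowRanges(snps)),
                               sim$geneModels)
    if (sum(blocks$cls == "cis") == 0 || sum(blocks$cls == "trans") == 0)
      return(NA)
    compareCisTrans(blocks)$p.value < 0.01
  })
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
})
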