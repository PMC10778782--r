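#' Simulation configuration for synthetic eQTL datasets
#'
#' Defines the study conditions the generator emulates: an F1 mapping
#' population of unrelated offspring genotyped at biallelic SNPs drawn from
#' Hardy-Weinberg proportions, gene expression driven by planted cis and
#' trans effects and hotspot loci, and two parental genotypes with
#' differentially expressed genes.
#'
#' @param n_samples offspring count (default 120, the mapping-population size).
#' @param n_chromosomes,chrom_length_bp genome shape.
#' @param n_genes,n_snps background gene and SNP counts (planted effect SNPs
#'   are added on top of `n_snps`).
#' @param maf_range minor-allele-frequency range for background SNPs,
#'   sampled uniformly per site.
#' @param missing_rate per-genotype missingness probability, in [0, 0.1).
#' @param n_cis_effects,n_trans_effects number of planted effects; each is a
#'   fully linked 3-SNP cluster (cis: within 10 kb of the target gene;
#'   trans: on a different chromosome).
#' @param cis_r2,trans_r2 fraction of expression variance the planted
#'   genotype explains, in (0, 1).
#' @param hotspot_spec list of `list(chrom, pos, n_target_genes, effect_r2)`
#'   hotspot loci; each is a 3-SNP cluster whose dosage feeds that many
#'   distant genes, plus up to 3 nearby regulator genes driven by the same
#'   locus (planted regulator -> target pairs).
#' @param parent_log2fc_sd SD of planted parental log2 fold changes.
#' @param n_parent_de number of randomly chosen parent-DE genes.
#' @param n_parent_reps replicates per parent for the count tables.
#' @param noise_sd residual SD of log expression.
#' @param seed RNG seed; all outputs are reproducible from it.
#' @return A validated `simulation_config` list.
#' @export
simulationConfig <- function(n_samples = 120, n_chromosomes = 5,
                             chrom_length_bp = 5e6, n_genes = 500,
                             n_snps = 5000, maf_range = c(0.05, 0.5),
                             missing_rate = 0.05,
                             n_cis_effects = 20, n_trans_effects = 20,
                             cis_r2 = 0.5, trans_r2 = 0.5,
                             hotspot_spec = list(list(chrom = "chr1",
                                                      pos = 2500000,
                                                      n_target_genes = 30,
                                                      effect_r2 = 0.5)),
                             parent_log2fc_sd = 1.5, n_parent_de = 50,
                             n_parent_reps = 5, noise_sd = 0.5, seed = 1) {
  cfg <- list(n_samples = n_samples, n_chromosomes = n_chromosomes,
              chrom_length_bp = chrom_length_bp, n_genes = n_genes,
              n_snps = n_snps, maf_range = maf_range,
              missing_rate = missing_rate, n_cis_effects = n_cis_effects,
              n_trans_effects = n_trans_effects, cis_r2 = cis_r2,
              trans_r2 = trans_r2, hotspot_spec = hotspot_spec,
              parent_log2fc_sd = parent_log2fc_sd, n_parent_de = n_parent_de,
              n_parent_reps = n_parent_reps, noise_sd = noise_sd, seed = seed)
  with(cfg, {
    stopifnot(n_samples > 0, n_chromosomes > 0, chrom_length_bp > 0,
              n_genes > 0, n_snps > 0,
              missing_rate >= 0, missing_rate < 0.1,
              maf_range[1] > 0, maf_range[2] <= 0.5,
              maf_range[1] <= maf_range[2],
              cis_r2 > 0, cis_r2 < 1, trans_r2 > 0, trans_r2 < 1,
              n_parent_reps >= 2)
    for (h in hotspot_spec)
      stopifnot(h$effect_r2 > 0, h$effect_r2 < 1, h$n_target_genes > 0)
  })
  class(cfg) <- "simulation_config"
  cfg
}

# gene architecture used throughout the simulator: 1201 bp body,
# CDS1 [start+100, start+399], intron [start+400, start+599],
# CDS2 [start+600, start+1001]; spliced CDS length 702 (234 codons)
.GENE_LEN <- 1201L
.CDS_OFF <- list(c(100L, 399L), c(600L, 1001L))

.senseCodons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

.randomCds <- function(n_codons = 234L) {
  sense <- .senseCodons()
  body <- sample(sense[sense != "ATG"], n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

.placeGenes <- function(cfg, chroms) {
  per <- diff(floor(seq(0, cfg$n_genes, length.out = cfg$n_chromosomes + 1)))
  out <- list(); gi <- 0L
  for (ci in seq_along(chroms)) {
    k <- per[ci]
    if (k == 0) next
    slot <- floor(cfg$chrom_length_bp / k)
    if (slot < .GENE_LEN + 2000L)
      stop("infeasible placement: too many genes for chromosome length")
    starts <- (seq_len(k) - 1L) * slot +
      floor(stats::runif(k, 1000, slot - .GENE_LEN - 1000))
    out[[ci]] <- data.frame(chrom = chroms[ci], start = as.integer(starts),
                            stringsAsFactors = FALSE)
    gi <- gi + k
  }
  genes <- do.call(rbind, out)
  genes$end <- genes$start + .GENE_LEN - 1L
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
  genes
}

.geneModelsFromTable <- function(genes, cds_seq_strings) {
  gr <- GRanges(genes$chrom, IRanges(genes$start, genes$end),
                strand = genes$strand)
  names(gr) <- genes$gene_id
  flat <- GRanges(rep(genes$chrom, each = 2),
                  IRanges(rep(genes$start, each = 2) +
                            c(.CDS_OFF[[1]][1], .CDS_OFF[[2]][1]),
                          rep(genes$start, each = 2) +
                            c(.CDS_OFF[[1]][2], .CDS_OFF[[2]][2])),
                  strand = rep(genes$strand, each = 2))
  cds <- S4Vectors::splitAsList(flat, factor(rep(seq_len(nrow(genes)), each = 2)))
  seqs <- Biostrings::DNAStringSet(cds_seq_strings)
  names(seqs) <- genes$gene_id
  GeneModels(gr, cds, cdsSeqs = seqs)
}

# ref/alt alleles for SNP positions, consistent with CDS sequences where a
# position falls inside a CDS; random elsewhere
.assignAlleles <- function(gm, chrom, pos) {
  fl <- .flattenModels(gm)
  n <- length(pos)
  ref <- rep(NA_character_, n)
  if (length(fl$cs)) {
    for (i in seq_len(n)) {
      gis <- which(fl$gchr == chrom[i] & fl$gs <= pos[i] & fl$ge >= pos[i])
      for (gi in gis) {
        rows <- fl$rows_by_gene[[gi]]
        j <- rows[fl$cs[rows] <= pos[i] & fl$ce[rows] >= pos[i]][1]
        if (is.na(j) || !fl$gid[gi] %in% names(fl$seqs)) next
        idx <- fl$cumoff[j] +
          (if (fl$gminus[gi]) fl$ce[j] - pos[i] + 1L else pos[i] - fl$cs[j] + 1L)
        b <- substr(fl$seqs[[fl$gid[gi]]], idx, idx)
        ref[i] <- if (fl$gminus[gi]) chartr("ACGT", "TGCA", b) else b
        break
      }
    }
  }
  bases <- c("A", "C", "G", "T")
  miss <- is.na(ref)
  ref[miss] <- sample(bases, sum(miss), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1),
                USE.NAMES = FALSE)
  cbind(ref, alt)
}

#' Simulate a genotype-expression dataset with planted regulatory structure
#'
#' Draws offspring dosages per site from Hardy-Weinberg proportions at a MAF
#' sampled uniformly from `maf_range`; places genes uniformly within
#' non-overlapping slots; generates baseline log expression
#' Normal(gene mean, `noise_sd`) and adds `beta * dosage` for every planted
#' effect, with `beta` set so the genotype explains `effect_r2` of the
#' expression variance; FPKM = exp(log expression). Parent counts are drawn
#' Negative-Binomial (dispersion 0.1) around means separated by the planted
#' log2 fold changes. Missingness is applied to the emitted genotypes only.
#'
#' @param config a [simulationConfig()].
#' @param out_dir optional directory; when given, writes `genotypes.vcf`,
#'   `genes.gff3`, `cds.fa`, `fpkm.tsv`, `parent_counts.tsv` and
#'   `annotations.tsv` (byte-identical for identical config + seed).
#' @return A list with `genotypes` ([GenotypeData]), `geneModels`
#'   ([GeneModels]), `fpkm` ([ExpressionData]), `parentCounts` (matrix),
#'   `parentGroups` (factor), `annotations` (data.frame), `genome` (named
#'   lengths) and `truth` (planted cis/trans pairs with r2, hotspot intervals
#'   and targets, parent-DE genes with true log2fc, regulator -> target
#'   pairs).
#' @export
simulateDataset <- function(config, out_dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  genome <- stats::setNames(rep(cfg$chrom_length_bp, cfg$n_chromosomes), chroms)

  genes <- .placeGenes(cfg, chroms)

  # seed each hotspot neighbourhood with regulator genes: relocate the three
  # nearest same-chromosome genes to within 100 kb of the locus, so the
  # candidate-regulator screen has material to find (real hotspots sit in
  # gene-bearing regions by construction)
  hs_reg_ids <- vector("list", length(cfg$hotspot_spec))
  for (k in seq_along(cfg$hotspot_spec)) {
    h <- cfg$hotspot_spec[[k]]
    on_chr <- which(genes$chrom == h$chrom)
    ord <- on_chr[order(abs((genes$start[on_chr] + genes$end[on_chr]) / 2 -
                              h$pos))]
    reloc <- utils::head(ord, 3)
    offs <- c(-60000L, -30000L, 30000L)
    for (j in seq_along(reloc)) {
      s <- max(1L, as.integer(h$pos) + offs[j])
      repeat {
        others <- setdiff(which(genes$chrom == h$chrom), reloc[j])
        clash <- any(abs(genes$start[others] - s) < .GENE_LEN + 200L)
        if (!clash) break
        s <- s + .GENE_LEN + 500L
      }
      genes$start[reloc[j]] <- s
      genes$end[reloc[j]] <- s + .GENE_LEN - 1L
    }
    hs_reg_ids[[k]] <- genes$gene_id[reloc]
  }
  reserved <- unique(unlist(hs_reg_ids))

  cds_seqs <- vapply(seq_len(nrow(genes)), function(i) .randomCds(), character(1))
  gm <- .geneModelsFromTable(genes, cds_seqs)

  n <- cfg$n_samples
  samples <- sprintf("S%03d", seq_len(n))

  # --- background SNPs -------------------------------------------------
  snp_chrom <- sample(chroms, cfg$n_snps, replace = TRUE,
                      prob = genome / sum(genome))
  snp_pos <- floor(stats::runif(cfg$n_snps, 1, genome[snp_chrom] + 1))
  maf <- stats::runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])
  dos <- matrix(stats::rbinom(cfg$n_snps * n, 2L,
                              rep(maf, each = n)),
                nrow = cfg$n_snps, ncol = n, byrow = TRUE)
  qual <- round(stats::runif(cfg$n_snps, 55, 999), 1)
  low <- stats::runif(cfg$n_snps) < 0.02
  qual[low] <- round(stats::runif(sum(low), 10, 49.9), 1)

  snp_tab <- data.frame(chrom = snp_chrom, pos = as.integer(snp_pos),
                        qual = qual, planted = FALSE,
                        stringsAsFactors = FALSE)

  # --- planted effects -------------------------------------------------
  used_genes <- character(0)
  truth <- list(cis = NULL, trans = NULL, hotspots = NULL,
                parent_de = NULL, reg_pairs = NULL)
  log_expr <- matrix(stats::rnorm(nrow(genes) * n,
                                  mean = rep(stats::runif(nrow(genes), 0.5, 3), n),
                                  sd = cfg$noise_sd),
                     nrow = nrow(genes), ncol = n,
                     dimnames = list(genes$gene_id, samples))

  plant <- function(target_row, positions, chrom, r2, prefix, k) {
    g <- stats::rbinom(n, 2L, 0.35)
    if (stats::var(g) == 0) g[1:2] <- c(0L, 2L)  # degenerate draw guard
    beta <- cfg$noise_sd * sqrt(r2 / (1 - r2)) / stats::sd(g)
    log_expr[target_row, ] <<- log_expr[target_row, ] + beta * g
    ids <- sprintf("%s_%d_%d", prefix, k, seq_along(positions))
    add <- data.frame(chrom = chrom, pos = as.integer(positions),
                      qual = rep(999, length(positions)), planted = TRUE,
                      stringsAsFactors = FALSE)
    snp_tab <<- rbind(snp_tab, add)
    dos <<- rbind(dos, matrix(rep(g, each = length(positions)),
                              nrow = length(positions)))
    planted_ids <<- c(planted_ids, ids)
    ids
  }
  planted_ids <- character(0)

  # each planted effect is a fully linked 5-SNP cluster: downstream block
  # calling needs >= 3 significant SNPs, and the missingness filter can
  # remove a member or two without destroying the cluster
  cis_genes <- if (cfg$n_cis_effects > 0)
    sample(setdiff(genes$gene_id, reserved), cfg$n_cis_effects) else character(0)
  used_genes <- c(used_genes, cis_genes)
  cis_rows <- list()
  for (k in seq_along(cis_genes)) {
    gi <- match(cis_genes[k], genes$gene_id)
    p0 <- max(1L, genes$start[gi] - 8000L)
    ids <- plant(gi, p0 + c(0L, 2000L, 4000L, 6000L, 7500L), genes$chrom[gi],
                 cfg$cis_r2, "cis", k)
    cis_rows[[k]] <- data.frame(snp_id = ids[1], gene_id = cis_genes[k],
                                r2 = cfg$cis_r2, stringsAsFactors = FALSE)
  }
  truth$cis <- if (length(cis_rows)) do.call(rbind, cis_rows) else
    data.frame(snp_id = character(0), gene_id = character(0), r2 = numeric(0))

  trans_genes <- if (cfg$n_trans_effects > 0)
    sample(setdiff(genes$gene_id, c(used_genes, reserved)),
           cfg$n_trans_effects) else character(0)
  used_genes <- c(used_genes, trans_genes)
  trans_rows <- list()
  for (k in seq_along(trans_genes)) {
    gi <- match(trans_genes[k], genes$gene_id)
    other <- if (cfg$n_chromosomes > 1)
      sample(setdiff(chroms, genes$chrom[gi]), 1) else genes$chrom[gi]
    p0 <- floor(stats::runif(1, 1, genome[other] - 10000))
    ids <- plant(gi, p0 + c(0L, 1500L, 3000L, 4500L, 6000L), other,
                 cfg$trans_r2, "trans", k)
    trans_rows[[k]] <- data.frame(snp_id = ids[1], gene_id = trans_genes[k],
                                  r2 = cfg$trans_r2, stringsAsFactors = FALSE)
  }
  truth$trans <- if (length(trans_rows)) do.call(rbind, trans_rows) else
    data.frame(snp_id = character(0), gene_id = character(0), r2 = numeric(0))

  # --- hotspots: one shared dosage feeding many distant genes ----------
  hs_rows <- list(); reg_rows <- list()
  forced_de <- list()
  for (k in seq_along(cfg$hotspot_spec)) {
    h <- cfg$hotspot_spec[[k]]
    g <- stats::rbinom(n, 2L, 0.4)
    if (stats::var(g) == 0) g[1:2] <- c(0L, 2L)
    positions <- h$pos + c(0L, 1500L, 3000L, 4500L, 6000L)
    ids <- sprintf("hot_%d_%d", k, seq_along(positions))
    snp_tab <- rbind(snp_tab,
                     data.frame(chrom = h$chrom, pos = as.integer(positions),
                                qual = rep(999, length(positions)),
                                planted = TRUE, stringsAsFactors = FALSE))
    dos <- rbind(dos, matrix(rep(g, each = length(positions)),
                             nrow = length(positions)))
    planted_ids <- c(planted_ids, ids)
    # distant targets: other chromosome, or >= 1 Mb away on the same one
    distant <- genes$chrom != h$chrom |
      pmin(abs(genes$start - h$pos), abs(genes$end - h$pos)) >= 1e6
    pool <- setdiff(genes$gene_id[distant], c(used_genes, reserved))
    targets <- sample(pool, min(h$n_target_genes, length(pool)))
    used_genes <- c(used_genes, targets)
    for (tg in targets) {
      gi <- match(tg, genes$gene_id)
      beta <- cfg$noise_sd * sqrt(h$effect_r2 / (1 - h$effect_r2)) / stats::sd(g)
      log_expr[gi, ] <- log_expr[gi, ] + beta * g
    }
    # regulator genes: the relocated neighbours of this hotspot
    regs <- setdiff(hs_reg_ids[[k]], used_genes)
    used_genes <- c(used_genes, regs)
    for (rg in regs) {
      gi <- match(rg, genes$gene_id)
      beta <- cfg$noise_sd * sqrt(0.8 / 0.2) / stats::sd(g)
      log_expr[gi, ] <- log_expr[gi, ] + beta * g
      forced_de[[rg]] <- 1.2   # log2fc >= ~1.2 passes both 1.2x and 1.5x gates
    }
    for (tg in targets) forced_de[[tg]] <- 1.5
    hs_rows[[k]] <- data.frame(chrom = h$chrom, start = min(positions),
                               end = max(positions),
                               targets = I(list(targets)),
                               regulators = I(list(regs)),
                               stringsAsFactors = FALSE)
    if (length(regs) && length(targets))
      reg_rows[[k]] <- expand.grid(regulator = regs, target = targets,
                                   stringsAsFactors = FALSE)
  }
  truth$hotspots <- if (length(hs_rows)) do.call(rbind, hs_rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  truth$reg_pairs <- if (length(reg_rows)) do.call(rbind, reg_rows) else
    data.frame(regulator = character(0), target = character(0))

  # --- parent differential expression ----------------------------------
  de_genes <- sample(setdiff(genes$gene_id, names(forced_de)),
                     min(cfg$n_parent_de, cfg$n_genes - length(forced_de)))
  lfc <- stats::setNames(stats::rnorm(length(de_genes), 0, cfg$parent_log2fc_sd),
                         de_genes)
  for (gn in names(forced_de))
    lfc[gn] <- forced_de[[gn]] * sample(c(-1, 1), 1)
  true_lfc <- stats::setNames(rep(0, nrow(genes)), genes$gene_id)
  true_lfc[names(lfc)] <- lfc
  truth$parent_de <- data.frame(gene_id = names(lfc), log2fc = unname(lfc),
                                stringsAsFactors = FALSE)
  base_mean <- exp(rowMeans(log_expr)) * 20
  mu_a <- base_mean * 2^(true_lfc / 2)
  mu_b <- base_mean * 2^(-true_lfc / 2)
  r <- cfg$n_parent_reps
  pc <- cbind(
    matrix(stats::rnbinom(nrow(genes) * r, size = 10,
                          mu = rep(mu_a, r)), ncol = r),
    matrix(stats::rnbinom(nrow(genes) * r, size = 10,
                          mu = rep(mu_b, r)), ncol = r))
  dimnames(pc) <- list(genes$gene_id,
                       c(sprintf("NF_%d", seq_len(r)), sprintf("LS_%d", seq_len(r))))
  parent_groups <- factor(rep(c("NF", "LS"), each = r), levels = c("NF", "LS"))

  # --- assemble genotype object (sorted by chrom, pos) -----------------
  n_bg <- cfg$n_snps
  ids <- c(sprintf("snp%05d", seq_len(n_bg)), planted_ids)
  alleles <- .assignAlleles(gm, snp_tab$chrom, snp_tab$pos)
  ord <- order(match(snp_tab$chrom, chroms), snp_tab$pos, ids)
  snps <- GRanges(snp_tab$chrom[ord], IRanges(snp_tab$pos[ord], width = 1L),
                  ref = alleles[ord, 1], alt = alleles[ord, 2],
                  qual = snp_tab$qual[ord])
  names(snps) <- ids[ord]
  dos <- dos[ord, , drop = FALSE]
  if (cfg$missing_rate > 0)
    dos[stats::runif(length(dos)) < cfg$missing_rate] <- NA
  colnames(dos) <- samples
  gd <- GenotypeData(dos, snps)

  fpkm <- ExpressionData(exp(log_expr), unit = "FPKM")

  # --- annotations: WFRG membership and regulator classes --------------
  wfrg <- unique(c(unlist(truth$hotspots$targets), cis_genes, trans_genes,
                   sample(genes$gene_id, ceiling(0.1 * nrow(genes)))))
  reg_ids <- unique(truth$reg_pairs$regulator)
  cls <- rep("other", nrow(genes))
  names(cls) <- genes$gene_id
  if (length(reg_ids))
    cls[reg_ids] <- sample(c("TF", "TR", "PK"), length(reg_ids), replace = TRUE)
  hormone <- sample(genes$gene_id, ceiling(0.05 * nrow(genes)))
  cls[setdiff(hormone, reg_ids)] <- "hormone"
  annotations <- data.frame(gene_id = genes$gene_id, class = unname(cls),
                            is_wfrg = genes$gene_id %in% wfrg,
                            stringsAsFactors = FALSE)

  out <- list(genotypes = gd, geneModels = gm, fpkm = fpkm,
              parentCounts = pc, parentGroups = parent_groups,
              annotations = annotations, genome = genome, truth = truth,
              config = cfg)
  if (!is.null(out_dir)) .writeSimulated(out, out_dir)
  out
}

.writeGff3 <- function(gm, path) {
  g <- geneRanges(gm)
  lines <- "##gff-version 3"
  for (i in seq_along(g)) {
    id <- names(g)[i]
    lines <- c(lines, paste(as.character(seqnames(g[i])), "sim", "gene",
                            start(g[i]), end(g[i]), ".",
                            as.character(strand(g[i])), ".",
                            sprintf("ID=%s", id), sep = "\t"))
    ci <- sort(cdsByGene(gm)[[i]])
    phase <- 0L
    # genomic order for emission; phase tracks transcription order
    ord <- if (as.character(strand(g[i])) == "-") rev(seq_along(ci)) else seq_along(ci)
    ph <- integer(length(ci)); cum <- 0L
    for (j in ord) {
      ph[j] <- (3L - cum %% 3L) %% 3L
      cum <- cum + (end(ci[j]) - start(ci[j]) + 1L)
    }
    for (j in seq_along(ci))
      lines <- c(lines, paste(as.character(seqnames(ci[j])), "sim", "CDS",
                              start(ci[j]), end(ci[j]), ".",
                              as.character(strand(g[i])), ph[j],
                              sprintf("ID=%s.cds%d;Parent=%s", id, j, id),
                              sep = "\t"))
  }
  writeLines(lines, path)
}

.writeMatrixTsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.writeSimulated <- function(sim, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  writeGenotypesVcf(sim$genotypes, file.path(out_dir, "genotypes.vcf"),
                    contigs = sim$genome)
  .writeGff3(sim$geneModels, file.path(out_dir, "genes.gff3"))
  Biostrings::writeXStringSet(cdsSeqs(sim$geneModels),
                              file.path(out_dir, "cds.fa"))
  .writeMatrixTsv(exprValues(sim$fpkm), file.path(out_dir, "fpkm.tsv"))
  .writeMatrixTsv(sim$parentCounts, file.path(out_dir, "parent_counts.tsv"))
  utils::write.table(sim$annotations, file.path(out_dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
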