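#' Pipeline configuration
#'
#' Collects every threshold of the pipeline with its default: expression
#' gate (`fpkm_min = 1`, `frac_min = 0.20`), SNP gate (`qual_min = 50`,
#' `maf_min = 0.05`, `miss_max = 0.10`), association (`alpha = 0.05`
#' Bonferroni over all pairs), block clustering (`max_gap_bp = 10000`,
#' `min_snps = 3`), cis window (`cis_window_bp = 10000`), hotspot scan
#' (`win_bp = 1e6`, `step_bp = 1e4`, `n_perm = 1000`,
#' `hotspot_alpha = 0.01`, `merge_gap_bp = 0`), network screen
#' (`bin_bp = 1e5`, `min_targets = 2`, `proximity_bp = 1e5`,
#' `pcc_min = 0.4`, `reg_fc = 1.2`, `tgt_fc = 1.5`, `min_component = 5`),
#' variant annotation (`flank_bp = 5000`) and the global `seed` (fanned out
#' to stage seeds by fixed offsets). `p_threshold` (default `NULL`)
#' substitutes a fixed suggestive p-value cutoff for the Bonferroni gate,
#' for small demonstration datasets where the family-wise gate is
#' unattainable.
#'
#' @param ... named overrides of the defaults.
#' @return A validated `pipeline_config` list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(fpkm_min = 1, frac_min = 0.20, qual_min = 50, maf_min = 0.05,
              miss_max = 0.10, alpha = 0.05, max_gap_bp = 10000,
              min_snps = 3, cis_window_bp = 10000, win_bp = 1e6,
              step_bp = 1e4, n_perm = 1000, hotspot_alpha = 0.01,
              merge_gap_bp = 0, bin_bp = 1e5, min_targets = 2,
              proximity_bp = 1e5, pcc_min = 0.4, reg_fc = 1.2,
              tgt_fc = 1.5, min_component = 5, flank_bp = 5000,
              p_threshold = NULL, seed = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  .validateConfig(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

.validateConfig <- function(cfg) {
  with(cfg, {
    if (maf_min <= 0 || maf_min >= 0.5) stop("maf_min must be in (0, 0.5)")
    if (miss_max <= 0 || miss_max > 1) stop("miss_max must be in (0, 1]")
    if (frac_min < 0 || frac_min >= 1) stop("frac_min must be in [0, 1)")
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    if (!is.null(p_threshold) && (p_threshold <= 0 || p_threshold >= 1))
      stop("p_threshold must be in (0, 1)")
    if (hotspot_alpha <= 0 || hotspot_alpha >= 1)
      stop("hotspot_alpha must be in (0, 1)")
    if (pcc_min < 0 || pcc_min >= 1) stop("pcc_min must be in [0, 1)")
    if (reg_fc < 1 || tgt_fc < 1) stop("fold-change gates must be >= 1")
    if (min_snps < 1 || min_component < 1 || min_targets < 1)
      stop("minimum counts must be >= 1")
    if (any(c(max_gap_bp, cis_window_bp, win_bp, step_bp, bin_bp,
              proximity_bp, flank_bp) <= 0))
      stop("window sizes must be positive")
    if (n_perm < 1) stop("n_perm must be >= 1")
  })
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Named fields in the YAML override the [pipelineConfig()] defaults;
#' unknown fields are an error.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

#' Load pipeline inputs from files
#'
#' Reads the standard input formats into the structure [runPipeline()]
#' consumes. Parent replicate groups are inferred from the prefix of the
#' count-table column names (text before the last underscore).
#'
#' @param vcf,gff3,fpkm_tsv,parent_counts_tsv,annotations_tsv input paths.
#' @param cds_fasta optional spliced-CDS FASTA (enables coding-SNP
#'   classification).
#' @param genome optional named chromosome lengths; when `NULL`, taken from
#'   the VCF `##contig` header lines, falling back to the maximum SNP
#'   position per chromosome.
#' @return A list shaped like the return of [simulateDataset()] (without
#'   `truth`).
#' @export
loadPipelineInputs <- function(vcf, gff3, fpkm_tsv, parent_counts_tsv,
                               annotations_tsv, cds_fasta = NULL,
                               genome = NULL) {
  gd <- readGenotypesVcf(vcf)
  gm <- readGeneModelsGff3(gff3, cdsFasta = cds_fasta)
  fpkm <- readExpressionTsv(fpkm_tsv, unit = "FPKM")
  pc_ed <- readExpressionTsv(parent_counts_tsv, unit = "raw-count")
  pc <- exprValues(pc_ed)
  groups <- factor(sub("_[^_]*$", "", colnames(pc)),
                   levels = unique(sub("_[^_]*$", "", colnames(pc))))
  ann <- utils::read.table(annotations_tsv, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (is.null(genome)) {
    meta <- readLines(vcf, n = 200)
    ct <- grep("^##contig=", meta, value = TRUE)
    if (length(ct)) {
      ids <- sub(".*ID=([^,>]+).*", "\\1", ct)
      lens <- as.numeric(sub(".*length=([0-9]+).*", "\\1", ct))
      genome <- stats::setNames(lens, ids)
    } else {
      rr <- rowRanges(gd)
      genome <- tapply(start(rr), as.character(seqnames(rr)), max)
      genome <- stats::setNames(as.numeric(genome), names(genome))
    }
  }
  list(genotypes = gd, geneModels = gm, fpkm = fpkm, parentCounts = pc,
       parentGroups = groups, annotations = ann, genome = genome,
       truth = NULL, config = NULL)
}

#' Run the full eQTL pipeline
#'
#' Executes preprocess -> map -> hotspots -> network on an input bundle
#' (from [loadPipelineInputs()], [simulateDataset()] or
#' [makeWorkedExample()]) and returns all stage results plus a manifest of
#' per-stage record counts. With `out_dir`, result tables and the manifest
#' (JSON) are written. The global seed is fanned out to the permutation
#' stage by a fixed offset so stages are reproducible standalone.
#'
#' @param data input bundle.
#' @param config a [pipelineConfig()].
#' @param out_dir optional output directory.
#' @return list with `normExpr`, `snps`, `snpAnnotation`, `degs`,
#'   `fcFlags`, `threshold`, `associations`, `blocks`, `windowCounts`,
#'   `hotspotThreshold`, `hotspots`, `bins`, `pairs`, `network`,
#'   `manifest`.
#' @export
runPipeline <- function(data, config = pipelineConfig(), out_dir = NULL) {
  .validateConfig(config)
  stage <- "preprocess"
  res <- tryCatch({
    expr_f <- filterExpressed(data$fpkm, config$fpkm_min, config$frac_min)
    norm <- inverseNormal(expr_f)
    snps <- filterSnps(data$genotypes, config$qual_min, config$maf_min,
                       config$miss_max)
    snp_ann <- annotateSnps(snps, data$geneModels, config$flank_bp)
    degs <- callDegs(data$parentCounts, data$parentGroups)
    lib <- colSums(data$parentCounts)
    normc <- sweep(data$parentCounts, 2, mean(lib) / lib, `*`)
    a <- data$parentGroups == levels(data$parentGroups)[1]
    parents_ds <- data.frame(gene_id = rownames(normc),
                             mean_a = rowMeans(normc[, a, drop = FALSE]),
                             mean_b = rowMeans(normc[, !a, drop = FALSE]))
    fc <- foldChangeFlags(list(parents = parents_ds),
                          reg_fc = config$reg_fc, tgt_fc = config$tgt_fc)

    stage <- "map"
    # default: Bonferroni over all pairs; a fixed "suggestive" threshold can
    # be supplied instead (the usual practice when the Bonferroni gate is
    # unattainable at small n)
    thr <- if (!is.null(config$p_threshold)) config$p_threshold
    else bonferroniThreshold(nrow(snps), nrow(norm), config$alpha)
    assoc <- associateAll(snps, norm, p_max = thr)
    blocks <- clusterBlocks(assoc, rowRanges(snps),
                            max_gap_bp = config$max_gap_bp,
                            min_snps = config$min_snps)
    blocks <- classifyCisTrans(blocks, data$geneModels,
                               window_bp = config$cis_window_bp)

    stage <- "hotspots"
    tb <- blocks[blocks$cls == "trans", , drop = FALSE]
    wc <- NULL; hthr <- NA_integer_
    hs <- data.frame(hotspot_id = character(0), chrom = character(0),
                     start = integer(0), end = integer(0),
                     n_trans_eqtls = integer(0),
                     source_window_count = integer(0),
                     target_genes = I(list()))
    if (nrow(tb) > 0) {
      wc <- windowScan(tb, data$genome, config$win_bp, config$step_bp)
      hthr <- suppressWarnings(
        permutationThreshold(nrow(tb), data$genome, config$win_bp,
                             config$step_bp, n_perm = config$n_perm,
                             alpha = config$hotspot_alpha,
                             seed = config$seed + 1000L))
      pre <- callHotspots(wc, hthr)
      hs <- mergeHotspots(pre, tb, merge_gap_bp = config$merge_gap_bp)
    }

    stage <- "network"
    wfrg <- data$annotations$gene_id[data$annotations$is_wfrg]
    bins <- binWfrgLoci(tb, wfrg, data$genome, bin_bp = config$bin_bp,
                        min_targets = config$min_targets)
    cands <- candidateRegulators(bins, data$geneModels,
                                 proximity_bp = config$proximity_bp)
    pairs <- screenPairs(bins, cands, norm, fc, pcc_min = config$pcc_min)
    net <- buildNetwork(pairs, data$annotations,
                        min_component = config$min_component)

    list(normExpr = norm, snps = snps, snpAnnotation = snp_ann, degs = degs,
         fcFlags = fc, threshold = thr, associations = assoc,
         blocks = blocks, windowCounts = wc, hotspotThreshold = hthr,
         hotspots = hs, bins = bins, pairs = pairs, network = net)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  cat_tab <- table(res$snpAnnotation$category)
  manifest <- list(
    config = unclass(config), seed = config$seed,
    counts = list(
      genes_in = nrow(data$fpkm), genes_kept = nrow(res$normExpr),
      snps_in = nrow(data$genotypes), snps_kept = nrow(res$snps),
      snp_categories = as.list(cat_tab),
      degs_up = sum(res$degs$status == "up"),
      degs_down = sum(res$degs$status == "down"),
      pairs_tested = attr(res$associations, "n_tested"),
      pairs_significant = nrow(res$associations),
      blocks = nrow(res$blocks),
      cis = sum(res$blocks$cls == "cis"),
      trans = sum(res$blocks$cls == "trans"),
      unclassified = sum(res$blocks$cls == "unclassified"),
      hotspot_threshold = as.integer(res$hotspotThreshold),
      hotspots = nrow(res$hotspots),
      network_bins = nrow(res$bins),
      regulatory_pairs = nrow(res$pairs),
      network_edges = nrow(res$network$edges),
      network_nodes = nrow(res$network$nodes),
      network_components = res$network$n_components))
  res$manifest <- manifest

  if (!is.null(out_dir)) {
    writeResults(list(blocks = res$blocks, hotspots = res$hotspots,
                      network = res$network), out_dir)
    cfg_path <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(unclass(config), cfg_path)
    manifest$config_md5 <- unname(tools::md5sum(cfg_path))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    res$manifest <- manifest
  }
  res
}
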