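# window starts tiling a chromosome at stride step_bp, starting at 1
.winStarts <- function(len, step_bp) seq.int(1L, as.integer(len), by = as.integer(step_bp))

# counts of positions falling in [s, min(s + win - 1, len)] for every start s
.winCounts <- function(pos, starts, win_bp, len) {
  pos <- sort(pos)
  ends <- pmin(starts + win_bp - 1, len)
  findInterval(ends, pos) - findInterval(starts - 1, pos)
}

#' Sliding-window counts of trans-eQTLs along the genome
#'
#' Tiles every chromosome with windows of `win_bp` starting at 1, 1 + step,
#' ... (final windows truncated at the chromosome end) and counts the trans
#' blocks whose lead SNP lies in `[win_start, win_end]`, collecting their
#' target genes.
#'
#' @param trans_blocks classified blocks restricted to `cls == "trans"`.
#' @param genome named vector of chromosome lengths (bp).
#' @param win_bp,step_bp window and step sizes (defaults 1 Mb / 10 kb).
#' @return data.frame with `chrom`, `win_start`, `win_end`,
#'   `n_trans_eqtls` and a `target_genes` list-column.
#' @export
windowScan <- function(trans_blocks, genome, win_bp = 1e6, step_bp = 1e4) {
  out <- list()
  for (chrom in names(genome)) {
    len <- genome[[chrom]]
    starts <- .winStarts(len, step_bp)
    ends <- pmin(starts + win_bp - 1, len)
    b <- trans_blocks[trans_blocks$chrom == chrom, , drop = FALSE]
    cnt <- .winCounts(b$lead_pos, starts, win_bp, len)
    tg <- vector("list", length(starts))
    nz <- which(cnt > 0)
    for (i in nz)
      tg[[i]] <- unique(b$gene_id[b$lead_pos >= starts[i] &
                                    b$lead_pos <= ends[i]])
    tg[cnt == 0] <- list(character(0))
    out[[chrom]] <- data.frame(chrom = chrom, win_start = starts,
                               win_end = ends, n_trans_eqtls = cnt,
                               stringsAsFactors = FALSE)
    out[[chrom]]$target_genes <- tg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Permutation threshold for hotspot calling
#'
#' Re-places the observed number of trans-eQTL lead positions uniformly at
#' random over the concatenated genome (chromosome chosen proportionally to
#' its length, position uniform within it), recomputes all window counts,
#' and records the genome-wide maximum per permutation. The returned
#' threshold is the smallest integer count declared significant: one more
#' than the `ceiling((1 - alpha) * n_perm)`-th order statistic of the
#' recorded maxima, so that a window count passing `>= threshold` is
#' strictly above the null quantile. Reproducible from `seed`.
#'
#' @param n_trans_eqtls observed trans block count (> 0).
#' @param genome named chromosome lengths.
#' @param win_bp,step_bp window geometry (as in [windowScan()]).
#' @param n_perm number of permutations (default 1000; a warning is issued
#'   below 100, where the tail quantile is unstable).
#' @param alpha genome-wide significance level (default 0.01).
#' @param seed RNG seed.
#' @return Integer threshold, with the permuted maxima as attribute
#'   `"maxima"`.
#' @export
permutationThreshold <- function(n_trans_eqtls, genome, win_bp = 1e6,
                                 step_bp = 1e4, n_perm = 1000, alpha = 0.01,
                                 seed = 1) {
  if (n_trans_eqtls <= 0) stop("n_trans_eqtls must be positive")
  if (n_perm < 100) warning("n_perm < 100: threshold estimate is unstable")
  set.seed(seed)
  chroms <- names(genome)
  lens <- as.numeric(genome)
  starts <- lapply(lens, .winStarts, step_bp = step_bp)
  maxima <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    ci <- sample.int(length(chroms), n_trans_eqtls, replace = TRUE,
                     prob = lens / sum(lens))
    pos <- floor(stats::runif(n_trans_eqtls, 1, lens[ci] + 1))
    mx <- 0L
    for (k in seq_along(chroms)) {
      p <- pos[ci == k]
      if (!length(p)) next
      mx <- max(mx, .winCounts(p, starts[[k]], win_bp, lens[k]))
    }
    maxima[b] <- mx
  }
  q <- sort(maxima)[ceiling((1 - alpha) * n_perm)]
  thr <- as.integer(q + 1L)
  attr(thr, "maxima") <- maxima
  thr
}

#' Call pre-merge hotspots from window counts
#'
#' Every window whose trans-eQTL count is at least `threshold` becomes a
#' pre-merge hotspot carrying its count and target-gene set.
#'
#' @param window_counts output of [windowScan()].
#' @param threshold integer from [permutationThreshold()].
#' @return data.frame of pre-merge hotspots (`chrom`, `start`, `end`,
#'   `n_trans_eqtls`, `target_genes`, `source_window_count`).
#' @export
callHotspots <- function(window_counts, threshold) {
  sel <- window_counts$n_trans_eqtls >= threshold
  h <- window_counts[sel, , drop = FALSE]
  out <- data.frame(chrom = h$chrom, start = h$win_start, end = h$win_end,
                    n_trans_eqtls = h$n_trans_eqtls,
                    source_window_count = rep(1L, nrow(h)),
                    stringsAsFactors = FALSE)
  out$target_genes <- h$target_genes
  rownames(out) <- NULL
  out
}

#' Merge overlapping or adjacent hotspots
#'
#' Unions same-chromosome intervals that overlap or lie within
#' `merge_gap_bp` of each other (default 0: touching or overlapping), then
#' recounts member trans blocks and unions their target sets over the merged
#' span. Output intervals are pairwise disjoint and sorted; the operation is
#' idempotent.
#'
#' @param hotspots pre-merge hotspots from [callHotspots()].
#' @param trans_blocks the trans blocks used for the scan (for recounting).
#' @param merge_gap_bp maximum gap still merged (default 0).
#' @return data.frame with `hotspot_id`, `chrom`, `start`, `end`,
#'   `n_trans_eqtls`, `source_window_count`, `target_genes`.
#' @export
mergeHotspots <- function(hotspots, trans_blocks, merge_gap_bp = 0) {
  if (nrow(hotspots) == 0)
    return(data.frame(hotspot_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_trans_eqtls = integer(0),
                      source_window_count = integer(0),
                      target_genes = I(list())))
  gr <- GRanges(hotspots$chrom, IRanges(hotspots$start, hotspots$end))
  red <- reduce(sort(gr), min.gapwidth = merge_gap_bp + 1)
  ov <- findOverlaps(gr, red)
  nsrc <- tabulate(S4Vectors::subjectHits(ov), nbins = length(red))
  out <- data.frame(hotspot_id = sprintf("hot%d", seq_along(red)),
                    chrom = as.character(seqnames(red)),
                    start = start(red), end = end(red),
                    n_trans_eqtls = 0L, source_window_count = nsrc,
                    stringsAsFactors = FALSE)
  tg <- vector("list", length(red))
  for (i in seq_along(red)) {
    inb <- trans_blocks$chrom == out$chrom[i] &
      trans_blocks$lead_pos >= out$start[i] &
      trans_blocks$lead_pos <= out$end[i]
    out$n_trans_eqtls[i] <- sum(inb)
    tg[[i]] <- sort(unique(trans_blocks$gene_id[inb]))
  }
  out$target_genes <- tg
  out
}

#' Hypergeometric enrichment of hotspot targets in gene sets
#'
#' One-sided hypergeometric upper-tail test for the overlap between a
#' hotspot's target genes and each user-supplied gene set, with
#' Benjamini-Hochberg correction across sets.
#'
#' @param target_genes character vector of hotspot target genes.
#' @param gene_sets named list of gene-id vectors.
#' @param universe all genes tested for eQTLs (non-empty).
#' @return data.frame with `set`, `overlap`, `set_size`, `n_targets`, `p`,
#'   `q`.
#' @export
enrichTargets <- function(target_genes, gene_sets, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  targets <- intersect(unique(target_genes), universe)
  N <- length(universe); k <- length(targets)
  res <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), universe)
    m <- length(s)
    ov <- length(intersect(targets, s))
    p <- stats::phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = m, n_targets = k, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}
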