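#' Genomic bins whose trans-eQTLs control multiple WFRGs
#'
#' Tiles the genome in non-overlapping bins of `bin_bp` and retains every
#' bin in which the lead SNPs of trans blocks target at least `min_targets`
#' distinct wood-formation-related genes (WFRGs).
#'
#' @param trans_blocks classified blocks with `cls == "trans"`.
#' @param wfrg character vector of WFRG gene ids.
#' @param genome named chromosome lengths.
#' @param bin_bp bin size (default 100 kb).
#' @param min_targets minimum distinct WFRG targets per bin (default 2).
#' @return data.frame with `bin_id`, `chrom`, `start`, `end`,
#'   `n_wfrg_targets`, and list-columns `wfrg_targets`, `lead_snps`,
#'   `lead_positions`, `target_of_lead` (target gene per member lead SNP).
#' @export
binWfrgLoci <- function(trans_blocks, wfrg, genome, bin_bp = 1e5,
                        min_targets = 2) {
  b <- trans_blocks[trans_blocks$gene_id %in% wfrg, , drop = FALSE]
  out <- list()
  if (nrow(b)) {
    bin_start <- (b$lead_pos - 1) %/% bin_bp * bin_bp + 1
    key <- paste(b$chrom, bin_start, sep = "\r")
    for (idx in split(seq_len(nrow(b)), key)) {
      g <- b[idx, , drop = FALSE]
      tg <- sort(unique(g$gene_id))
      if (length(tg) < min_targets) next
      s <- (g$lead_pos[1] - 1) %/% bin_bp * bin_bp + 1
      row <- data.frame(chrom = g$chrom[1], start = as.integer(s),
                        end = as.integer(min(s + bin_bp - 1,
                                             genome[[g$chrom[1]]])),
                        n_wfrg_targets = length(tg), stringsAsFactors = FALSE)
      row$wfrg_targets <- list(tg)
      row$lead_snps <- list(g$lead_snp)
      row$lead_positions <- list(g$lead_pos)
      row$target_of_lead <- list(g$gene_id)
      out[[length(out) + 1]] <- row
    }
  }
  if (!length(out))
    return(data.frame(bin_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_wfrg_targets = integer(0),
                      wfrg_targets = I(list()), lead_snps = I(list()),
                      lead_positions = I(list()), target_of_lead = I(list())))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res <- cbind(bin_id = sprintf("bin%d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Candidate regulator genes per WFRG-controlling bin
#'
#' For each retained bin, collects genes whose body overlaps the bin or
#' lies within `proximity_bp` of any member lead SNP. The target gene
#' itself may appear (self-feedback regulation is a real phenomenon and is
#' not excluded here).
#'
#' @param bins output of [binWfrgLoci()].
#' @param gm a [GeneModels].
#' @param proximity_bp distance gate to a member lead SNP (default 100 kb).
#' @return named list (by `bin_id`) of deduplicated gene-id vectors.
#' @export
candidateRegulators <- function(bins, gm, proximity_bp = 1e5) {
  g <- geneRanges(gm)
  gs <- as.character(seqnames(g))
  out <- stats::setNames(vector("list", nrow(bins)), bins$bin_id)
  for (i in seq_len(nrow(bins))) {
    same <- gs == bins$chrom[i]
    in_bin <- same & start(g) <= bins$end[i] & end(g) >= bins$start[i]
    near <- rep(FALSE, length(g))
    for (p in bins$lead_positions[[i]]) {
      d <- pmax(start(g) - p, p - end(g), 0)
      near <- near | (same & d <= proximity_bp)
    }
    out[[i]] <- unique(names(g)[in_bin | near])
  }
  out
}

#' Screen candidate regulator-target pairs
#'
#' Keeps a (regulator, target) pair iff the Pearson correlation of their
#' normalized expression across the mapping population is strictly above
#' `pcc_min` in absolute value, and there exists a dataset in which the
#' regulator passes the 1.2x fold-change gate while the target passes the
#' 1.5x gate (simultaneity = same dataset). Pairs with a constant
#' expression row are skipped with a message.
#'
#' @param bins output of [binWfrgLoci()].
#' @param candidates output of [candidateRegulators()].
#' @param expr normalized [ExpressionData] across the population.
#' @param fc_flags output of [foldChangeFlags()].
#' @param pcc_min correlation gate (default 0.4, strict).
#' @return data.frame with `regulator`, `target`, `supporting_block`
#'   (lead SNP id), `pcc`, `de_datasets` (comma-joined labels).
#' @export
screenPairs <- function(bins, candidates, expr, fc_flags, pcc_min = 0.4) {
  v <- exprValues(expr)
  out <- list()
  n_const <- 0L
  for (i in seq_len(nrow(bins))) {
    targets <- bins$wfrg_targets[[i]]
    lead_of <- stats::setNames(bins$lead_snps[[i]], bins$target_of_lead[[i]])
    for (r in candidates[[bins$bin_id[i]]]) {
      if (!r %in% rownames(v)) next
      for (tg in targets) {
        if (!tg %in% rownames(v)) next
        x <- v[r, ]; y <- v[tg, ]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) {
          n_const <- n_const + 1L
          next
        }
        pcc <- stats::cor(x, y)
        if (abs(pcc) <= pcc_min) next
        ds <- .simultaneousDatasets(fc_flags, r, tg)
        if (!length(ds)) next
        out[[length(out) + 1]] <-
          data.frame(regulator = r, target = tg,
                     supporting_block = unname(lead_of[tg]), pcc = pcc,
                     de_datasets = paste(ds, collapse = ","),
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (n_const > 0)
    message(sprintf("screenPairs: %d pair(s) skipped (constant expression)",
                    n_const))
  if (!length(out))
    return(data.frame(regulator = character(0), target = character(0),
                      supporting_block = character(0), pcc = numeric(0),
                      de_datasets = character(0)))
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

.simultaneousDatasets <- function(fc_flags, regulator, target) {
  rg <- fc_flags$regulator; tg <- fc_flags$target
  if (!regulator %in% rownames(rg) || !target %in% rownames(tg))
    return(character(0))
  ok <- rg[regulator, ] & tg[target, ]
  colnames(rg)[which(ok)]
}

#' Assemble the regulatory network
#'
#' Builds a directed regulator -> target graph from screened pairs, computes
#' connected components on the undirected skeleton, and drops components
#' with fewer than `min_component` nodes. Node class labels (TF/TR/PK/
#' hormone/other) and WFRG membership are joined from the annotation table;
#' missing annotations become class `other`.
#'
#' @param pairs output of [screenPairs()].
#' @param annotations data.frame with `gene_id`, `class`, `is_wfrg`.
#' @param min_component minimum component size in nodes (default 5).
#' @return list with `edges` (pairs restricted to kept components, plus
#'   `component`), `nodes` (`gene_id`, `role`, `class`, `is_wfrg`,
#'   `out_degree`, `in_degree`, `component`), and `n_components`.
#' @export
buildNetwork <- function(pairs, annotations, min_component = 5) {
  empty <- list(edges = cbind(pairs[0, ], component = integer(0)),
                nodes = data.frame(gene_id = character(0), role = character(0),
                                   class = character(0), is_wfrg = logical(0),
                                   out_degree = integer(0),
                                   in_degree = integer(0),
                                   component = integer(0)),
                n_components = 0L)
  if (nrow(pairs) == 0) return(empty)
  gr <- igraph::graph_from_data_frame(pairs[, c("regulator", "target")],
                                      directed = TRUE)
  comp <- igraph::components(gr, mode = "weak")
  keep_comp <- which(comp$csize >= min_component)
  if (!length(keep_comp)) return(empty)
  node_comp <- comp$membership
  keep_nodes <- names(node_comp)[node_comp %in% keep_comp]
  e_keep <- pairs$regulator %in% keep_nodes & pairs$target %in% keep_nodes
  edges <- pairs[e_keep, , drop = FALSE]
  edges$component <- unname(node_comp[edges$regulator])
  out_deg <- table(edges$regulator)
  in_deg <- table(edges$target)
  role <- ifelse(keep_nodes %in% edges$regulator &
                   keep_nodes %in% edges$target, "both",
                 ifelse(keep_nodes %in% edges$regulator, "regulator",
                        "target"))
  m <- match(keep_nodes, annotations$gene_id)
  cls <- ifelse(is.na(m), "other", annotations$class[m])
  if (anyNA(m))
    message(sprintf("buildNetwork: %d node(s) without annotation set to class 'other'",
                    sum(is.na(m))))
  nodes <- data.frame(gene_id = keep_nodes, role = role, class = cls,
                      is_wfrg = ifelse(is.na(m), FALSE,
                                       annotations$is_wfrg[m]),
                      out_degree = as.integer(out_deg[keep_nodes]),
                      in_degree = as.integer(in_deg[keep_nodes]),
                      component = unname(node_comp[keep_nodes]),
                      stringsAsFactors = FALSE)
  nodes$out_degree[is.na(nodes$out_degree)] <- 0L
  nodes$in_degree[is.na(nodes$in_degree)] <- 0L
  rownames(nodes) <- rownames(edges) <- NULL
  list(edges = edges, nodes = nodes, n_components = length(keep_comp))
}
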