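#' Collapse a probeset-level matrix to one row per gene symbol
#'
#' Keeps, for each symbol, the probeset with the highest mean expression;
#' ties break deterministically by probeset id.
#'
#' @param expr Probesets x samples matrix.
#' @param annot Data frame with `gene_id` (probeset) and `symbol`.
#' @return Genes x samples matrix with symbols as rownames.
#' @export
collapse_to_genes <- function(expr, annot) {
  expr <- as_expression_matrix(expr)
  ann <- annot[match(rownames(expr), annot$gene_id), ]
  sym <- as.character(ann$symbol)
  keep <- !is.na(sym) & nzchar(trimws(sym))
  expr <- expr[keep, , drop = FALSE]
  sym <- sym[keep]
  means <- rowMeans(expr)
  ord <- order(sym, -means, rownames(expr))
  first <- !duplicated(sym[ord])
  sel <- ord[first]
  out <- expr[sel, , drop = FALSE]
  rownames(out) <- sym[sel]
  out
}

#' Scale one TOM onto the reference's scale
#'
#' Raises the target TOM elementwise to the power
#' `log(q_ref) / log(q_target)`, where the q's are the off-diagonal
#' quantiles (default the 95th percentile) of reference and target. After
#' scaling, the target's chosen quantile equals the reference's; elementwise
#' ordering within the target is preserved (a monotone transform).
#'
#' @param tom_target,tom_reference TOM matrices over the same, identically
#'   ordered gene universe.
#' @param quantile Off-diagonal quantile matched between the matrices.
#' @return The scaled target TOM.
#' @export
scale_tom <- function(tom_target, tom_reference, quantile = 0.95) {
  if (!identical(dim(tom_target), dim(tom_reference))) {
    stop("TOM matrices differ in dimension", call. = FALSE)
  }
  if (!is.null(rownames(tom_target)) && !is.null(rownames(tom_reference)) &&
      !identical(rownames(tom_target), rownames(tom_reference))) {
    stop("TOM matrices are not aligned on the same gene universe", call. = FALSE)
  }
  off <- upper.tri(tom_target)
  # order-statistic (type 1) quantiles so the match is exact after the
  # monotone power transform
  q_t <- stats::quantile(tom_target[off], quantile, names = FALSE, type = 1)
  q_r <- stats::quantile(tom_reference[off], quantile, names = FALSE, type = 1)
  if (q_t <= 0 || q_t >= 1 || q_r <= 0 || q_r >= 1) {
    stop("degenerate scaling quantile (0 or 1); cannot scale", call. = FALSE)
  }
  expo <- log(q_r) / log(q_t)
  out <- tom_target^expo
  diag(out) <- 1
  out
}

#' Parallel-minimum consensus of two TOMs
#'
#' Elementwise minimum of two aligned (scaled) topological overlap
#' matrices: a gene pair is only as topologically overlapping as it is in
#' the weaker of the two datasets.
#'
#' @param tom_a,tom_b Aligned TOM matrices.
#' @return Consensus TOM.
#' @export
consensus_tom <- function(tom_a, tom_b) {
  if (!identical(dim(tom_a), dim(tom_b))) {
    stop("TOM matrices differ in dimension", call. = FALSE)
  }
  if (!is.null(rownames(tom_a)) && !is.null(rownames(tom_b)) &&
      !identical(rownames(tom_a), rownames(tom_b))) {
    stop("TOM matrices are not aligned on the same gene universe", call. = FALSE)
  }
  pmin(tom_a, tom_b)
}

#' Cross-species consensus (meta-) module analysis
#'
#' Restricts both expression matrices to the 1:1 homolog universe, builds a
#' network per species at the consensus power, scales species B's TOM onto
#' species A's, takes the parallel minimum, detects modules on the consensus
#' TOM, merges similar modules using the minimum of the two species'
#' eigengene correlations as similarity, and returns per-species eigengenes
#' over the shared assignment.
#'
#' @param expr_a,expr_b Genes x samples matrices for the two species.
#' @param homologs Data frame with columns `gene_a`, `gene_b`: a strict 1:1
#'   map between row ids of the two matrices.
#' @param power Soft threshold for both species (consensus convention: 8).
#' @param min_module_size,deep_split See [detect_modules()].
#' @param merge_cut_height Eigengene dissimilarity below which meta-modules
#'   merge (consensus convention: 0.2).
#' @param scale_quantile Quantile used by [scale_tom()].
#' @return Object of class `coex_consensus`: `assignment` (named by
#'   `gene_a|gene_b` pair ids), `pairs` (the homolog table restricted to the
#'   analyzed universe), per-species `eigengenes_a`/`eigengenes_b`, the
#'   `consensus` TOM, per-species networks, and `params`.
#' @export
detect_meta_modules <- function(expr_a, expr_b, homologs, power = 8,
                                min_module_size = 30L, deep_split = 3L,
                                merge_cut_height = 0.2,
                                scale_quantile = 0.95) {
  expr_a <- as_expression_matrix(expr_a)
  expr_b <- as_expression_matrix(expr_b)
  homologs <- validate_homolog_map(homologs)
  use <- homologs$gene_a %in% rownames(expr_a) &
    homologs$gene_b %in% rownames(expr_b)
  homologs <- homologs[use, , drop = FALSE]
  if (!nrow(homologs)) {
    stop("homolog map has no pairs present in both matrices", call. = FALSE)
  }
  xa <- expr_a[homologs$gene_a, , drop = FALSE]
  xb <- expr_b[homologs$gene_b, , drop = FALSE]
  pair_ids <- paste(homologs$gene_a, homologs$gene_b, sep = "|")
  rownames(xa) <- pair_ids
  rownames(xb) <- pair_ids

  net_a <- build_network(xa, power)
  net_b <- build_network(xb, power)
  tom_b_scaled <- scale_tom(net_b$tom, net_a$tom, quantile = scale_quantile)
  cons <- consensus_tom(net_a$tom, tom_b_scaled)

  assignment <- detect_modules(cons, min_module_size = min_module_size,
                               deep_split = deep_split)
  attr(assignment, "dendrogram") <- NULL
  if (any(assignment > 0L)) {
    assignment <- merge_similar_modules(list(xa, xb), assignment,
                                        cut_height = merge_cut_height)
    eg_a <- module_eigengenes(xa, assignment)$eigengenes
    eg_b <- module_eigengenes(xb, assignment)$eigengenes
  } else {
    eg_a <- eg_b <- NULL
  }
  structure(
    list(assignment = assignment, pairs = homologs,
         eigengenes_a = eg_a, eigengenes_b = eg_b,
         consensus = cons, network_a = net_a,
         tom_b_scaled = tom_b_scaled,
         params = list(power = power, min_module_size = min_module_size,
                       deep_split = deep_split,
                       merge_cut_height = merge_cut_height,
                       scale_quantile = scale_quantile)),
    class = "coex_consensus"
  )
}

#' @export
print.coex_consensus <- function(x, ...) {
  n_mod <- length(unique(x$assignment[x$assignment > 0L]))
  cat("Two-species consensus module analysis\n")
  cat(sprintf("  homolog pairs: %d   meta-modules: %d   unassigned: %d\n",
              length(x$assignment), n_mod, sum(x$assignment == 0L)))
  invisible(x)
}

#' Cross-tabulate two module assignments with overlap tests
#'
#' For every pair of a module from each assignment over a common gene
#' universe, reports the overlap count and the hypergeometric upper-tail
#' p-value, plus a significance flag at the stated threshold.
#'
#' @param assignment_a,assignment_b Named module labels over the same
#'   universe (names must match; label 0 is ignored as a module but its
#'   genes stay in the universe).
#' @param alpha Significance threshold recorded in the output.
#' @return Data frame: module_a, module_b, n_a, n_b, overlap, p, alpha,
#'   significant.
#' @export
cross_tabulate <- function(assignment_a, assignment_b, alpha = 0.05) {
  universe <- intersect(names(assignment_a), names(assignment_b))
  if (!length(universe)) stop("assignments share no genes", call. = FALSE)
  a <- assignment_a[universe]
  b <- assignment_b[universe]
  rows <- list()
  for (ma in sort(unique(a[a > 0L]))) {
    set_a <- universe[a == ma]
    for (mb in sort(unique(b[b > 0L]))) {
      set_b <- universe[b == mb]
      ov <- hypergeometric_overlap(set_a, set_b, universe)
      rows[[length(rows) + 1L]] <- data.frame(
        module_a = ma, module_b = mb, n_a = ov$n_a, n_b = ov$n_b,
        overlap = ov$overlap, p = ov$p, alpha = alpha,
        significant = ov$p <= alpha)
    }
  }
  do.call(rbind, rows)
}

# strict 1:1 validation of a homolog map
validate_homolog_map <- function(homologs) {
  if (!all(c("gene_a", "gene_b") %in% names(homologs))) {
    stop("homolog map needs columns gene_a, gene_b", call. = FALSE)
  }
  homologs <- unique(homologs[, c("gene_a", "gene_b")])
  if (anyDuplicated(homologs$gene_a) || anyDuplicated(homologs$gene_b)) {
    stop("homolog map is not 1:1 after collapsing duplicates", call. = FALSE)
  }
  homologs
}
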