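#' Group-wise connectivity within a module
#'
#' Builds the soft-thresholded adjacency separately from control-only and
#' treated-only samples over one module's genes and compares each gene's
#' intramodular connectivity between the groups: the quantity behind
#' circle-plot style displays of network reorganization under treatment,
#' including hub emergence (a gene weakly connected in controls becoming a
#' major hub in treated animals).
#'
#' @param expr Genes x samples matrix covering the module's genes.
#' @param info Sample table with `sample_id` and `group`.
#' @param assignment Named module labels.
#' @param module Module label to analyze.
#' @param power Soft threshold for both group networks.
#' @param edge_threshold Optional adjacency cutoff; when given, binarized
#'   degrees per group are reported alongside the weighted connectivities.
#'   There is deliberately no default: any cutoff is arbitrary and must be
#'   stated by the caller.
#' @return Data frame: gene_id, module, kim_control, kim_treated, delta_kim
#'   (treated - control), rank_control, rank_treated, rank_change
#'   (rank_control - rank_treated; positive = gained rank under treatment),
#'   and degree columns when `edge_threshold` is given.
#' @export
group_connectivity <- function(expr, info, assignment, module, power,
                               edge_threshold = NULL) {
  expr <- as_expression_matrix(expr)
  genes <- names(assignment)[assignment == module]
  genes <- intersect(rownames(expr), genes)
  if (length(genes) < 2L) {
    stop("module has fewer than 2 genes present in the matrix", call. = FALSE)
  }
  grp <- info$group[match(colnames(expr), info$sample_id)]
  ctl <- colnames(expr)[!is.na(grp) & grp == "control"]
  trt <- colnames(expr)[!is.na(grp) & grp == "treated"]
  if (length(ctl) < 4L || length(trt) < 4L) {
    stop("each group needs at least 4 samples for a group-wise network",
         call. = FALSE)
  }
  a_c <- adjacency_matrix(expr[genes, ctl, drop = FALSE], power)
  a_t <- adjacency_matrix(expr[genes, trt, drop = FALSE], power)
  kim_c <- rowSums(a_c) - 1
  kim_t <- rowSums(a_t) - 1
  rank_c <- rank(-kim_c, ties.method = "first")
  rank_t <- rank(-kim_t, ties.method = "first")
  out <- data.frame(gene_id = genes, module = module,
                    kim_control = unname(kim_c), kim_treated = unname(kim_t),
                    delta_kim = unname(kim_t - kim_c),
                    rank_control = unname(rank_c),
                    rank_treated = unname(rank_t),
                    rank_change = unname(rank_c - rank_t),
                    stringsAsFactors = FALSE)
  if (!is.null(edge_threshold)) {
    deg <- function(a) rowSums(a > edge_threshold) - (1 > edge_threshold)
    out$degree_control <- unname(deg(a_c))
    out$degree_treated <- unname(deg(a_t))
    attr(out, "edge_threshold") <- edge_threshold
  }
  out
}

#' Export per-group thresholded edge lists
#'
#' Writes (or returns) one edge list per group: all gene pairs whose
#' group-wise adjacency exceeds the threshold, ordered deterministically by
#' (gene_a, gene_b). Suitable input for external network/circle-plot tools.
#'
#' @inheritParams group_connectivity
#' @param genes Genes to include (e.g. one module's genes).
#' @param edge_threshold Adjacency cutoff; edges with weight strictly above
#'   it are kept.
#' @param path_control,path_treated Optional TSV output paths.
#' @return Invisibly, a list with the two edge data frames
#'   (gene_a, gene_b, weight, group).
#' @export
export_group_edgelists <- function(expr, info, genes, power, edge_threshold,
                                   path_control = NULL, path_treated = NULL) {
  expr <- as_expression_matrix(expr)
  genes <- intersect(rownames(expr), genes)
  grp <- info$group[match(colnames(expr), info$sample_id)]
  edges_for <- function(samples, label) {
    a <- adjacency_matrix(expr[genes, samples, drop = FALSE], power)
    idx <- which(upper.tri(a) & a > edge_threshold, arr.ind = TRUE)
    df <- data.frame(gene_a = genes[idx[, 1L]], gene_b = genes[idx[, 2L]],
                     weight = a[idx], group = rep(label, nrow(idx)),
                     stringsAsFactors = FALSE)
    df[order(df$gene_a, df$gene_b), , drop = FALSE]
  }
  ctl <- edges_for(colnames(expr)[grp == "control"], "control")
  trt <- edges_for(colnames(expr)[grp == "treated"], "treated")
  if (!is.null(path_control)) write_tsv_table(ctl, path_control)
  if (!is.null(path_treated)) write_tsv_table(trt, path_treated)
  invisible(list(control = ctl, treated = trt))
}
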