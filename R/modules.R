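#' Detect coexpression modules by dynamic tree cut
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' `1 - TOM`, followed by a two-phase branch cut: (i) a static cut close to
#' the top of the dendrogram separates well-isolated branches, and (ii) each
#' branch is recursively split wherever the merge-height gap between a node
#' and its taller child is large relative to the node height and both halves
#' retain at least `min_module_size` genes. The `deep_split` setting
#' (0 through 3) lowers the required relative gap, so higher values produce
#' more and smaller modules, and the partition at a higher setting is always
#' a refinement of the one below it. Branches smaller than `min_module_size`
#' are left unassigned (label 0, the "grey" pool).
#'
#' After labeling, each module is core-tightened: a member whose mean
#' topological overlap with the rest of the module falls below
#' `trim_frac` times the module's median member-to-module overlap is a
#' straggler (typically a background gene swept into the branch just below
#' the static cut) and is returned to the unassigned pool. Tightening never
#' shrinks a module below `min_module_size`, so the number of modules is
#' unaffected by it and remains non-decreasing in `deep_split`.
#'
#' @param net A `coex_network` from [build_network()], or a TOM matrix.
#' @param min_module_size Smallest allowed module.
#' @param deep_split Integer 0-3, splitting sensitivity.
#' @param cut_height_frac Static cut as a fraction of the maximum merge
#'   height.
#' @param trim_frac Core-tightening factor in `[0, 1)`; 0 disables it.
#' @return Named integer vector: module label per gene (0 = unassigned),
#'   labels ordered by decreasing module size. The dendrogram is attached as
#'   attribute `"dendrogram"`.
#' @export
detect_modules <- function(net, min_module_size = 30L, deep_split = 3L,
                           cut_height_frac = 0.99, trim_frac = 0.25) {
  tom <- if (inherits(net, "coex_network")) net$tom else net
  if (!is.matrix(tom) || nrow(tom) != ncol(tom)) {
    stop("'net' must be a coex_network or a square TOM matrix", call. = FALSE)
  }
  if (!deep_split %in% 0:3) {
    stop("'deep_split' must be an integer in 0..3", call. = FALSE)
  }
  n <- nrow(tom)
  ids <- rownames(tom)
  if (is.null(ids)) ids <- paste0("g", seq_len(n))
  if (n < min_module_size) {
    warning("fewer genes than 'min_module_size'; all genes left unassigned")
    out <- stats::setNames(integer(n), ids)
    return(out)
  }
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  labels_raw <- cut_tree_adaptive(h, min_module_size = min_module_size,
                                  deep_split = deep_split,
                                  cut_height_frac = cut_height_frac)
  if (trim_frac > 0) {
    labels_raw <- trim_module_cores(tom, labels_raw, min_module_size,
                                    trim_frac)
  }
  out <- stats::setNames(relabel_by_size(labels_raw), ids)
  attr(out, "dendrogram") <- h
  out
}

# Relative merge-height gap required to accept a split, by deep_split 0..3.
split_gap_fraction <- c(0.40, 0.25, 0.15, 0.075)

# Core of the tree cut: works on an hclust object, returns raw integer labels.
cut_tree_adaptive <- function(h, min_module_size, deep_split, cut_height_frac) {
  n <- length(h$order)
  merge <- h$merge
  height <- h$height
  cut_height <- cut_height_frac * max(height)
  gap_frac <- split_gap_fraction[deep_split + 1L]

  # leaves below each internal node (list indexed by node)
  members <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    left <- merge[i, 1L]
    right <- merge[i, 2L]
    members[[i]] <- c(if (left < 0) -left else members[[left]],
                      if (right < 0) -right else members[[right]])
  }
  node_height <- function(node) if (node < 0) 0 else height[node]
  node_size <- function(node) if (node < 0) 1L else length(members[[node]])

  labels <- integer(n)
  next_label <- 0L

  assign_module <- function(node) {
    next_label <<- next_label + 1L
    labels[members[[node]]] <<- next_label
  }

  # recursive gap-split of a branch; explicit stack to bound recursion depth
  split_branch <- function(root) {
    stack <- root
    while (length(stack)) {
      node <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (node < 0) next
      left <- merge[node, 1L]
      right <- merge[node, 2L]
      gap <- height[node] - max(node_height(left), node_height(right))
      splittable <- node_size(left) >= min_module_size &&
        node_size(right) >= min_module_size &&
        gap >= gap_frac * height[node]
      if (splittable) {
        stack <- c(stack, left, right)
      } else if (node_size(node) >= min_module_size) {
        assign_module(node)
      }
    }
  }

  # phase 1: descend from the top until below the static cut
  stack <- n - 1L
  while (length(stack)) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (node < 0) next            # singleton joining above the cut: unassigned
    if (height[node] > cut_height) {
      stack <- c(stack, merge[node, 1L], merge[node, 2L])
    } else if (node_size(node) >= min_module_size) {
      split_branch(node)          # phase 2
    }
  }
  labels
}

# Return stragglers (mean within-module TOM below trim_frac x module median)
# to label 0, weakest first, never shrinking a module below min_module_size.
trim_module_cores <- function(tom, labels, min_module_size, trim_frac) {
  for (m in unique(labels[labels > 0L])) {
    repeat {
      idx <- which(labels == m)
      if (length(idx) <= min_module_size) break
      sub <- tom[idx, idx, drop = FALSE]
      kt <- (rowSums(sub) - 1) / (length(idx) - 1)
      weak <- which(kt < trim_frac * stats::median(kt))
      if (!length(weak)) break
      n_trim <- min(length(weak), length(idx) - min_module_size)
      drop <- weak[order(kt[weak])][seq_len(n_trim)]
      labels[idx[drop]] <- 0L
      if (n_trim < length(weak)) break
    }
  }
  labels
}

# Relabel so module 1 is the largest; 0 stays 0.
relabel_by_size <- function(labels) {
  pos <- labels[labels > 0L]
  if (!length(pos)) return(labels)
  sizes <- sort(table(pos), decreasing = TRUE)
  map <- stats::setNames(seq_along(sizes), names(sizes))
  out <- labels
  out[labels > 0L] <- map[as.character(pos)]
  as.integer(out)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized (per-gene z-scored) expression: the first right-singular
#' vector of the module submatrix, sign-oriented so that its correlation
#' with the module's mean standardized expression is non-negative, and
#' scaled to unit variance.
#'
#' @param expr Genes x samples matrix.
#' @param assignment Named integer module labels (0 = unassigned).
#' @return List with `eigengenes` (modules x samples matrix, rows `ME<k>`)
#'   and `var_explained` (fraction of module variance carried by the first
#'   component).
#' @export
module_eigengenes <- function(expr, assignment) {
  expr <- as_expression_matrix(expr)
  assignment <- assignment[rownames(expr)]
  mods <- sort(unique(assignment[assignment > 0L]))
  if (!length(mods)) stop("no assigned modules", call. = FALSE)
  if (ncol(expr) < 3L) {
    stop("eigengenes require at least 3 samples", call. = FALSE)
  }
  me <- matrix(NA_real_, nrow = length(mods), ncol = ncol(expr),
               dimnames = list(paste0("ME", mods), colnames(expr)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    genes <- names(assignment)[assignment == mods[i]]
    x <- expr[genes, , drop = FALSE]
    sds <- apply(x, 1L, stats::sd)
    if (any(sds == 0)) {
      stop(sprintf("module %d contains a zero-variance gene; eigengene undefined",
                   mods[i]), call. = FALSE)
    }
    z <- (x - rowMeans(x)) / sds
    sv <- svd(z, nu = 0L, nv = 1L)
    e <- sv$v[, 1L]
    m <- colMeans(z)
    if (stats::sd(m) > 0 && stats::cor(e, m) < 0) e <- -e
    if (stats::sd(e) == 0) {
      stop(sprintf("module %d has no sample-to-sample variation", mods[i]),
           call. = FALSE)
    }
    me[i, ] <- e / stats::sd(e)
    d2 <- sv$d^2
    ve[i] <- d2[1L] / sum(d2)
  }
  list(eigengenes = me, var_explained = ve)
}

#' Module membership (kME)
#'
#' Pearson correlation of each gene's expression with each module eigengene.
#'
#' @param expr Genes x samples matrix.
#' @param eigengenes Modules x samples matrix (rows `ME<k>`).
#' @return Genes x modules correlation matrix.
#' @export
module_membership <- function(expr, eigengenes) {
  expr <- as_expression_matrix(expr)
  stats::cor(t(expr), t(eigengenes))
}

#' Intramodular connectivity (kIM) and its within-module scaling
#'
#' `kIM` of a gene is the sum of its adjacency to the other genes of its
#' module; the scaled version divides by the maximum observed kIM in that
#' module, so every non-empty module has a gene with scaled kIM 1.
#' Unassigned genes receive 0 for both.
#'
#' @param adjacency Adjacency matrix (unit diagonal).
#' @param assignment Named module labels over the adjacency's genes.
#' @return Data frame: gene_id, module, kim, kim_scaled.
#' @export
intramodular_connectivity <- function(adjacency, assignment) {
  ids <- rownames(adjacency)
  assignment <- assignment[ids]
  kim <- stats::setNames(numeric(length(ids)), ids)
  for (m in sort(unique(assignment[assignment > 0L]))) {
    genes <- ids[assignment == m]
    sub <- adjacency[genes, genes, drop = FALSE]
    kim[genes] <- rowSums(sub) - 1   # drop the self edge
  }
  kim_scaled <- kim
  for (m in sort(unique(assignment[assignment > 0L]))) {
    genes <- ids[assignment == m]
    mx <- max(kim[genes])
    kim_scaled[genes] <- if (mx > 0) kim[genes] / mx else 0
  }
  data.frame(gene_id = ids, module = as.integer(assignment),
             kim = unname(kim), kim_scaled = unname(kim_scaled),
             stringsAsFactors = FALSE)
}

#' Merge modules with similar eigengenes
#'
#' Average-linkage clustering of eigengene dissimilarity `1 - cor(ME_i,
#' ME_j)`; module groups joining below `cut_height` are merged, eigengenes
#' recomputed, and the procedure iterated until stable. For a consensus run,
#' pass a list of per-species expression matrices sharing the assignment's
#' gene universe: the similarity is then the parallel minimum of the
#' per-species eigengene correlations (a conservative consensus).
#'
#' @param expr Genes x samples matrix, or a list of such matrices.
#' @param assignment Named module labels.
#' @param cut_height Dissimilarity below which modules merge.
#' @return Updated named assignment (relabelled by size).
#' @export
merge_similar_modules <- function(expr, assignment, cut_height = 0.2) {
  expr_list <- if (is.list(expr) && !is.data.frame(expr)) expr else list(expr)
  repeat {
    mods <- sort(unique(assignment[assignment > 0L]))
    if (length(mods) < 2L) break
    sims <- lapply(expr_list, function(e) {
      me <- module_eigengenes(e, assignment)$eigengenes
      stats::cor(t(me))
    })
    sim <- Reduce(pmin, sims)
    h <- stats::hclust(stats::as.dist(1 - sim), method = "average")
    groups <- stats::cutree(h, h = cut_height)
    if (max(groups) == length(mods)) break
    map <- stats::setNames(groups, mods)
    newlab <- assignment
    newlab[assignment > 0L] <- map[as.character(assignment[assignment > 0L])]
    assignment <- stats::setNames(as.integer(newlab), names(assignment))
  }
  stats::setNames(relabel_by_size(assignment), names(assignment))
}

#' Fit a weighted coexpression network and its modules
#'
#' One-stop fit for a single dataset: soft-thresholded network, dynamic
#' tree-cut modules, eigengenes, module membership (kME) and intramodular
#' connectivity (kIM, scaled kIM).
#'
#' @param expr Genes x samples matrix.
#' @param power Soft threshold (default 6, the single-species convention).
#' @param min_module_size,deep_split,cut_height_frac See [detect_modules()].
#' @param merge_modules Merge similar modules after detection (off by
#'   default for single-species fits).
#' @param merge_cut_height Eigengene dissimilarity for merging.
#' @return Object of class `coex_fit` with elements `network`, `assignment`,
#'   `eigengenes`, `var_explained`, `kme`, `connectivity`, `dendrogram`,
#'   `params`, `call`.
#' @export
fit_coexpression_network <- function(expr, power = 6, min_module_size = 30L,
                                     deep_split = 3L, cut_height_frac = 0.99,
                                     merge_modules = FALSE,
                                     merge_cut_height = 0.2) {
  expr <- as_expression_matrix(expr)
  net <- build_network(expr, power)
  assignment <- detect_modules(net, min_module_size = min_module_size,
                               deep_split = deep_split,
                               cut_height_frac = cut_height_frac)
  dend <- attr(assignment, "dendrogram")
  attr(assignment, "dendrogram") <- NULL
  if (merge_modules && any(assignment > 0L)) {
    assignment <- merge_similar_modules(expr, assignment,
                                        cut_height = merge_cut_height)
  }
  if (any(assignment > 0L)) {
    eg <- module_eigengenes(expr, assignment)
    kme <- module_membership(expr, eg$eigengenes)
  } else {
    eg <- list(eigengenes = NULL, var_explained = NULL)
    kme <- NULL
  }
  conn <- intramodular_connectivity(net$adjacency, assignment)
  structure(
    list(network = net, assignment = assignment,
         eigengenes = eg$eigengenes, var_explained = eg$var_explained,
         kme = kme, connectivity = conn, dendrogram = dend,
         n_samples = ncol(expr),
         params = list(power = power, min_module_size = min_module_size,
                       deep_split = deep_split,
                       merge_modules = merge_modules,
                       merge_cut_height = merge_cut_height),
         call = match.call()),
    class = "coex_fit"
  )
}

#' @export
print.coex_fit <- function(x, ...) {
  n_mod <- length(unique(x$assignment[x$assignment > 0L]))
  cat("Weighted coexpression network fit\n")
  cat(sprintf("  genes: %d   samples: %d   power: %g\n",
              length(x$assignment), x$n_samples, x$params$power))
  cat(sprintf("  modules: %d   unassigned: %d\n",
              n_mod, sum(x$assignment == 0L)))
  invisible(x)
}

#' @export
summary.coex_fit <- function(object, ...) {
  a <- object$assignment
  mods <- sort(unique(a[a > 0L]))
  tab <- data.frame(
    module = mods,
    size = vapply(mods, function(m) sum(a == m), integer(1L)),
    var_explained = if (!is.null(object$var_explained))
      unname(object$var_explained[paste0("ME", mods)]) else NA_real_
  )
  structure(list(modules = tab, n_unassigned = sum(a == 0L),
                 params = object$params),
            class = "summary.coex_fit")
}

#' @export
print.summary.coex_fit <- function(x, ...) {
  cat(sprintf("Modules (min size %d, deep split %d):\n",
              x$params$min_module_size, x$params$deep_split))
  print(x$modules, row.names = FALSE)
  cat(sprintf("Unassigned genes: %d\n", x$n_unassigned))
  invisible(x)
}

#' @export
plot.coex_fit <- function(x, ...) {
  if (is.null(x$dendrogram)) {
    stop("fit carries no dendrogram", call. = FALSE)
  }
  op <- graphics::par(mfrow = c(2, 1), mar = c(1, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$dendrogram, labels = FALSE, hang = -1,
       main = "Gene dendrogram (1 - TOM)", xlab = "", sub = "")
  ord <- x$dendrogram$order
  cols <- c("grey80", grDevices::hcl.colors(max(1L, max(x$assignment)), "Dark 3"))
  graphics::par(mar = c(3, 4, 0, 1))
  graphics::image(matrix(seq_along(ord), ncol = 1),
                  col = cols[x$assignment[ord] + 1L],
                  axes = FALSE, ylab = "module")
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same genes;
#' 1 for identical partitions, about 0 for independent ones. Used to score
#' recovery of planted module labels (unassigned genes count as their own
#' class).
#'
#' @param a,b Integer/character label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length", call. = FALSE)
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  mx <- (ai + bj) / 2
  if (mx == expected) return(1)
  (nij - expected) / (mx - expected)
}
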