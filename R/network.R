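#' Soft-thresholded coexpression adjacency
#'
#' Computes the unsigned weighted adjacency `a_ij = |cor(x_i, x_j)|^power`
#' between all gene pairs, with unit diagonal. Pearson correlation is used
#' throughout the package.
#'
#' @param expr Numeric matrix, genes in rows, samples in columns. Rows must
#'   be named by gene identifiers.
#' @param power Positive soft-thresholding exponent (beta).
#' @return Symmetric numeric matrix in `[0, 1]` with unit diagonal.
#' @export
adjacency_matrix <- function(expr, power) {
  expr <- as_expression_matrix(expr)
  if (!is.numeric(power) || length(power) != 1L || power <= 0) {
    stop("'power' must be a single positive number", call. = FALSE)
  }
  if (ncol(expr) < 3L) {
    stop("at least 3 samples are required to estimate correlations",
         call. = FALSE)
  }
  v <- apply(expr, 1L, stats::var)
  if (any(v == 0 | !is.finite(v))) {
    bad <- rownames(expr)[which(v == 0 | !is.finite(v))[1L]]
    stop(sprintf("gene '%s' has zero (or undefined) variance; adjacency is undefined", bad),
         call. = FALSE)
  }
  a <- abs(stats::cor(t(expr)))^power
  # guard against tiny floating excursions outside [0, 1]
  a[a > 1] <- 1
  diag(a) <- 1
  a
}

#' Topological overlap from an adjacency matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' the diagonal is 1. For unsigned adjacency in `[0,1]` with unit diagonal
#' the result lies in `[0, 1]`.
#'
#' @param adjacency Symmetric matrix in `[0,1]` with unit diagonal.
#' @return Symmetric TOM matrix, same dimnames as `adjacency`.
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  if (!is.matrix(a) || nrow(a) != ncol(a)) {
    stop("'adjacency' must be a square matrix", call. = FALSE)
  }
  k <- rowSums(a) - 1
  # (A %*% A)_ij contains the u = i and u = j terms (a_ij each, since diag = 1)
  l <- a %*% a - 2 * a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Build a weighted coexpression network
#'
#' Soft-thresholded unsigned adjacency plus its topological overlap matrix.
#'
#' @inheritParams adjacency_matrix
#' @return An object of class `coex_network`: a list with `gene_ids`,
#'   `power`, `adjacency_type` (`"unsigned"`), `adjacency` and `tom`.
#' @export
build_network <- function(expr, power) {
  a <- adjacency_matrix(expr, power)
  structure(
    list(gene_ids = rownames(a), power = power,
         adjacency_type = "unsigned",
         adjacency = a, tom = tom_similarity(a)),
    class = "coex_network"
  )
}

#' @export
print.coex_network <- function(x, ...) {
  cat(sprintf("Weighted coexpression network: %d genes, %s adjacency, power = %g\n",
              length(x$gene_ids), x$adjacency_type, x$power))
  invisible(x)
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Discretizes the connectivities into `n_breaks` equal-width bins on the
#' raw `k` scale, then regresses `log10(p(k))` on `log10(mean k per bin)`
#' and reports the R-squared signed by the slope (positive when the slope
#' is negative, i.e. scale-free-like decay).
#'
#' @param k Non-negative connectivity values.
#' @param n_breaks Number of bins.
#' @return List with `r_squared` (signed), `slope`, and the bin table.
#' @export
scale_free_fit <- function(k, n_breaks = 10L) {
  k <- k[is.finite(k) & k > 0]
  if (length(k) < 10L || length(unique(k)) < 3L) {
    return(list(r_squared = NA_real_, slope = NA_real_, bins = NULL))
  }
  cuts <- cut(k, breaks = n_breaks, include.lowest = TRUE)
  freq <- tabulate(cuts, nbins = n_breaks) / length(k)
  xk <- tapply(k, cuts, mean)
  keep <- !is.na(xk) & freq > 0 & xk > 0
  if (sum(keep) < 3L) {
    return(list(r_squared = NA_real_, slope = NA_real_, bins = NULL))
  }
  x <- log10(as.numeric(xk[keep]))
  y <- log10(freq[keep])
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  r2 <- summary(fit)$r.squared
  list(r_squared = -sign(slope) * r2, slope = slope,
       bins = data.frame(log10_k = x, log10_p = y))
}

#' Choose the soft-thresholding power by scale-free topology fit
#'
#' For each candidate power the whole-network connectivity distribution is
#' assessed for scale-free behaviour; the smallest power whose signed fit
#' R-squared reaches `r2_target` is selected. If no candidate reaches the
#' target, the power with maximal fit is returned and the table flags
#' non-attainment.
#'
#' @inheritParams adjacency_matrix
#' @param candidate_powers Numeric vector of at least two candidate powers.
#' @param r2_target Scale-free fit R-squared considered adequate.
#' @param n_breaks Bins used by [scale_free_fit()].
#' @return List with `power` (selected) and `fit_table` (one row per
#'   candidate: power, r_squared, slope, mean_k, median_k, max_k, selected)
#'   plus a logical attribute-style column `r2_attained`.
#' @export
pick_soft_threshold <- function(expr, candidate_powers = c(1:10, 12, 14, 16, 18, 20),
                                r2_target = 0.8, n_breaks = 10L) {
  expr <- as_expression_matrix(expr)
  if (length(candidate_powers) < 2L) {
    stop("supply at least two candidate powers", call. = FALSE)
  }
  if (ncol(expr) < 4L) {
    stop("at least 4 samples are required for soft-threshold selection",
         call. = FALSE)
  }
  v <- apply(expr, 1L, stats::var)
  if (all(v == 0)) stop("expression matrix is constant; connectivity is undefined",
                        call. = FALSE)
  if (any(v == 0)) {
    bad <- rownames(expr)[which(v == 0)[1L]]
    stop(sprintf("gene '%s' has zero variance", bad), call. = FALSE)
  }
  cmat <- abs(stats::cor(t(expr)))
  candidate_powers <- sort(unique(candidate_powers))
  rows <- lapply(candidate_powers, function(p) {
    a <- cmat^p
    diag(a) <- 1
    k <- rowSums(a) - 1
    fit <- scale_free_fit(k, n_breaks = n_breaks)
    data.frame(power = p, r_squared = fit$r_squared, slope = fit$slope,
               mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$r_squared) & tab$r_squared >= r2_target)
  attained <- length(ok) > 0L
  sel <- if (attained) ok[1L] else which.max(tab$r_squared)
  tab$selected <- seq_len(nrow(tab)) == sel
  tab$r2_attained <- attained
  list(power = tab$power[sel], fit_table = tab)
}

# Coerce/validate the genes x samples expression matrix used everywhere.
as_expression_matrix <- function(expr) {
  if (is.data.frame(expr)) expr <- as.matrix(expr)
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(expr))) {
    stop("expression matrix must have gene identifiers as rownames", call. = FALSE)
  }
  if (anyDuplicated(rownames(expr))) {
    stop("duplicate gene identifiers in expression matrix", call. = FALSE)
  }
  if (!all(is.finite(expr))) {
    stop("expression matrix contains non-finite values", call. = FALSE)
  }
  expr
}
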