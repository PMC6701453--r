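#' Correlate profiles with a phenotype, skipping missing values
#'
#' Pearson correlation of each profile (gene or module eigengene) with a
#' phenotype column, using only samples with a non-missing phenotype value.
#' This implements the treated-only convention for phenotypes that are
#' undefined for controls: controls carry NA and are dropped, never entered
#' as zeros. Two-sided p-values come from the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param profiles Entities x samples numeric matrix (rownames = entity ids,
#'   colnames = sample ids).
#' @param info Sample table with `sample_id` and the phenotype column.
#' @param phenotype Name of the phenotype column in `info`.
#' @return Data frame: entity_id, phenotype, r, p, n_used.
#' @export
correlate_with_trait <- function(profiles, info, phenotype) {
  if (!is.matrix(profiles)) profiles <- rbind(profiles)
  if (!phenotype %in% names(info)) {
    stop(sprintf("phenotype '%s' not found in sample table", phenotype),
         call. = FALSE)
  }
  y <- info[[phenotype]][match(colnames(profiles), info$sample_id)]
  use <- !is.na(y)
  n <- sum(use)
  if (n < 3L) {
    stop("fewer than 3 samples carry the phenotype; correlation undefined",
         call. = FALSE)
  }
  r <- as.numeric(stats::cor(t(profiles[, use, drop = FALSE]), y[use]))
  p <- cor_pvalue(r, n)
  data.frame(entity_id = rownames(profiles) %||% seq_len(nrow(profiles)),
             phenotype = phenotype, r = r, p = p, n_used = n,
             stringsAsFactors = FALSE)
}

# two-sided p for a Pearson r at n observations
cor_pvalue <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  t <- ifelse(abs(r) == 1, Inf, r * sqrt((n - 2) / (1 - r^2)))
  2 * stats::pt(-abs(t), df = n - 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Empirical-Bayes moderated two-group t-test
#'
#' Per gene, a two-group comparison (treated minus control) with
#' empirical-Bayes variance moderation: gene-wise residual variances
#' `s_g^2` on `d` degrees of freedom are shrunk toward a prior `s0^2` with
#' prior degrees of freedom `d0` estimated by moment matching on the log
#' variances (matching the mean and variance of `log s_g^2` to the scaled
#' inverse-chi-square model via digamma/trigamma identities). The
#' moderated t uses posterior variance
#' `(d0 * s0^2 + d * s_g^2) / (d0 + d)` on `d0 + d` degrees of freedom.
#' P-values are two-sided; q-values are Benjamini-Hochberg.
#'
#' @param expr Genes x samples matrix.
#' @param info Sample table with `sample_id` and `group` in
#'   `{"control", "treated"}`.
#' @param alpha Significance level applied to the BH q-values.
#' @param prior_df Optional override of the estimated prior degrees of
#'   freedom `d0`; `0` gives the ordinary equal-variance t, `Inf` fixes
#'   every denominator variance at `s0^2`.
#' @return Data frame: gene_id, log_ratio, t, df_total, p, q, significant;
#'   estimated hyperparameters attached as attributes `d0` and `s0_sq`.
#' @export
moderated_t_test <- function(expr, info, alpha = 0.01, prior_df = NULL) {
  expr <- as_expression_matrix(expr)
  grp <- info$group[match(colnames(expr), info$sample_id)]
  if (any(is.na(grp)) || !all(grp %in% c("control", "treated"))) {
    stop("every sample needs group 'control' or 'treated'", call. = FALSE)
  }
  trt <- grp == "treated"
  n1 <- sum(trt); n2 <- sum(!trt)
  if (n1 < 2L || n2 < 2L) {
    stop("at least 2 samples per group are required", call. = FALSE)
  }
  d <- n1 + n2 - 2L
  m1 <- rowMeans(expr[, trt, drop = FALSE])
  m2 <- rowMeans(expr[, !trt, drop = FALSE])
  ss1 <- rowSums((expr[, trt, drop = FALSE] - m1)^2)
  ss2 <- rowSums((expr[, !trt, drop = FALSE] - m2)^2)
  s2 <- (ss1 + ss2) / d

  hyper <- estimate_variance_prior(s2, d)
  d0 <- if (is.null(prior_df)) hyper$d0 else prior_df
  s0_sq <- hyper$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else {
    (d0 * s0_sq + d * s2) / (d0 + d)
  }
  df_total <- if (is.infinite(d0)) Inf else d0 + d
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  lr <- m1 - m2
  t <- lr / se
  p <- 2 * stats::pt(-abs(t), df = df_total)
  q <- bh_fdr(p)
  out <- data.frame(gene_id = rownames(expr), log_ratio = lr, t = t,
                    df_total = df_total, p = p, q = q,
                    significant = q <= alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

# Moment matching of log variances to the scaled inverse-chi-square model:
# z = log(s^2) has E[z] = log(s0^2) + digamma(d/2) - log(d/2)
#                        - digamma(d0/2) + log(d0/2)
# and Var[z] = trigamma(d/2) + trigamma(d0/2).
estimate_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) stop("too few positive residual variances", call. = FALSE)
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  ev <- stats::var(z) - trigamma(d / 2)
  if (is.na(ev) || ev <= 0) {
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(ev)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton solve of trigamma(y) = x for y > 0 (x > 0), as used in variance
# moderation; monotone decreasing, so iterate on 1/trigamma.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; a thin validated wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted q-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Hypergeometric gene-set overlap
#'
#' Upper-tail probability `P(X >= observed overlap)` that two gene sets of
#' the given sizes drawn from the universe share at least the observed
#' number of genes.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe Character vector containing both sets.
#' @return One-row data frame: n_a, n_b, n_universe, overlap, p.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("both sets must be contained in the universe", call. = FALSE)
  }
  ov <- length(intersect(set_a, set_b))
  p <- stats::phyper(ov - 1, m = length(set_a),
                     n = length(universe) - length(set_a),
                     k = length(set_b), lower.tail = FALSE)
  data.frame(n_a = length(set_a), n_b = length(set_b),
             n_universe = length(universe), overlap = ov, p = p)
}

#' Permutation validation of module coherence
#'
#' For each module, compares its mean off-diagonal topological overlap with
#' the same statistic on `n_perm` random gene sets of equal size drawn
#' without replacement from the analyzed universe. The empirical p-value
#' uses the add-one convention `(1 + #{null >= observed}) / (n_perm + 1)`
#' and therefore can never be exactly zero.
#'
#' @param net A `coex_network` or TOM matrix.
#' @param assignment Named module labels over the network's genes.
#' @param n_perm Number of random modules per planted module.
#' @param seed Optional seed for the permutation draw.
#' @return Data frame: module, size, observed, null_mean, p.
#' @export
permutation_module_validation <- function(net, assignment, n_perm = 100L,
                                          seed = NULL) {
  tom <- if (inherits(net, "coex_network")) net$tom else net
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  ids <- rownames(tom)
  assignment <- assignment[ids]
  mods <- sort(unique(assignment[assignment > 0L]))
  mean_offdiag <- function(genes) {
    sub <- tom[genes, genes, drop = FALSE]
    m <- length(genes)
    (sum(sub) - m) / (m * (m - 1))
  }
  rows <- lapply(mods, function(m) {
    genes <- ids[assignment == m]
    if (length(genes) < 2L) {
      stop(sprintf("module %s has fewer than 2 genes", m), call. = FALSE)
    }
    obs <- mean_offdiag(genes)
    null <- vapply(seq_len(n_perm), function(i) {
      mean_offdiag(sample(ids, length(genes)))
    }, numeric(1L))
    data.frame(module = m, size = length(genes), observed = obs,
               null_mean = mean(null),
               p = (1 + sum(null >= obs)) / (n_perm + 1))
  })
  do.call(rbind, rows)
}

#' Module membership versus gene significance
#'
#' Pearson correlation across a module's genes between their membership
#' strength (e.g. kME or `-log10` membership p) and a gene-level
#' significance measure (trait correlation or `-log10` DE p). A significant
#' positive relationship supports the module's association with the trait.
#'
#' @param membership Numeric membership value per module gene.
#' @param significance Gene-level significance value, same genes and order.
#' @return One-row data frame: r, p, n.
#' @export
membership_significance <- function(membership, significance) {
  if (length(membership) != length(significance)) {
    stop("vectors differ in length", call. = FALSE)
  }
  ok <- is.finite(membership) & is.finite(significance)
  n <- sum(ok)
  if (n < 3L) stop("fewer than 3 usable genes", call. = FALSE)
  r <- stats::cor(membership[ok], significance[ok])
  data.frame(r = r, p = cor_pvalue(r, n), n = n)
}
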