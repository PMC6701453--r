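#' Filter probesets before network construction
#'
#' Applies, in order: removal of control probes; removal of unannotated
#' probes (missing/empty symbol); removal of very low expression probesets
#' (value below `low_expr_threshold` in at least
#' `ceiling(low_expr_fraction * n_samples)` samples); removal of
#' near-invariant probesets whose unscaled median absolute deviation across
#' all samples is below `mad_min`. The MAD here is the raw median of
#' absolute deviations from the median, without the 1.4826 normal
#' consistency factor. All four filters are per-gene predicates on the full
#' sample vector, so the surviving set does not depend on their order; the
#' report attributes each removal to the first filter that caught it.
#'
#' @param expr Genes x samples matrix of normalized log2 intensities.
#' @param annot Data frame with columns `gene_id`, `symbol`, `is_control`,
#'   covering every row of `expr`.
#' @param low_expr_threshold Intensity below which a value counts as low.
#' @param low_expr_fraction Fraction of samples that must be low to remove.
#' @param mad_min Minimum unscaled MAD.
#' @return List with `expr` (filtered matrix) and `report` (data frame of
#'   per-step removal counts; the step counts plus survivors sum to the
#'   input gene count).
#' @export
filter_probesets <- function(expr, annot,
                             low_expr_threshold = 3.5,
                             low_expr_fraction = 0.80,
                             mad_min = 0.065) {
  expr <- as_expression_matrix(expr)
  if (!all(c("gene_id", "symbol", "is_control") %in% names(annot))) {
    stop("'annot' needs columns gene_id, symbol, is_control", call. = FALSE)
  }
  if (anyDuplicated(annot$gene_id)) {
    stop("'annot' has duplicated gene_id rows", call. = FALSE)
  }
  missing_ann <- setdiff(rownames(expr), annot$gene_id)
  if (length(missing_ann)) {
    stop(sprintf("annotation missing for %d gene(s), e.g. '%s'",
                 length(missing_ann), missing_ann[1L]), call. = FALSE)
  }
  ann <- annot[match(rownames(expr), annot$gene_id), ]
  n_samp <- ncol(expr)
  n_low_required <- ceiling(low_expr_fraction * n_samp)

  is_control <- as.logical(ann$is_control)
  unannotated <- is.na(ann$symbol) | !nzchar(trimws(as.character(ann$symbol)))
  low_expr <- rowSums(expr < low_expr_threshold) >= n_low_required
  mads <- apply(expr, 1L, function(x) stats::median(abs(x - stats::median(x))))
  low_mad <- mads < mad_min

  removed_control <- is_control
  removed_unannotated <- unannotated & !removed_control
  removed_low <- low_expr & !removed_control & !removed_unannotated
  removed_mad <- low_mad & !removed_control & !removed_unannotated & !removed_low
  keep <- !(removed_control | removed_unannotated | removed_low | removed_mad)

  if (!any(keep)) {
    stop("no probesets survive filtering", call. = FALSE)
  }
  report <- data.frame(
    step = c("input", "control_probes", "unannotated", "low_expression",
             "low_mad", "passed"),
    n = c(nrow(expr), sum(removed_control), sum(removed_unannotated),
          sum(removed_low), sum(removed_mad), sum(keep)),
    stringsAsFactors = FALSE
  )
  list(expr = expr[keep, , drop = FALSE], report = report)
}
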