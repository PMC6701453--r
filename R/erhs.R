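#' Ethanol-related hub score (ERHS)
#'
#' Composite per-gene candidate score
#' `ERHS = scaled kIM + (1 - intake p) + (1 - DE p)`:
#' scaled intramodular connectivity plus one minus the p-value of the
#' gene's correlation with the intake phenotype plus one minus the
#' (raw) moderated-t p-value for treatment regulation. Each term lies in
#' `[0, 1]`, so the score lies in `[0, 3]`, is monotone non-decreasing in
#' connectivity and non-increasing in either p-value, and is comparable
#' across modules of different sizes.
#'
#' @param kim_scaled Scaled intramodular connectivity in `[0, 1]`
#'   (0 for unassigned genes).
#' @param intake_p Two-sided p of the gene-vs-intake correlation, in
#'   `[0, 1]`.
#' @param de_p Raw moderated-t p-value, in `[0, 1]`.
#' @return Numeric vector of scores in `[0, 3]`.
#' @export
compute_erhs <- function(kim_scaled, intake_p, de_p) {
  n <- max(length(kim_scaled), length(intake_p), length(de_p))
  if (!all(c(length(kim_scaled), length(intake_p), length(de_p)) %in% c(1L, n))) {
    stop("inputs must have equal length (or length 1)", call. = FALSE)
  }
  check01 <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0 | x > 1)) {
      stop(sprintf("'%s' must lie in [0, 1]", nm), call. = FALSE)
    }
  }
  check01(kim_scaled, "kim_scaled")
  check01(intake_p, "intake_p")
  check01(de_p, "de_p")
  kim_scaled + (1 - intake_p) + (1 - de_p)
}

#' Assemble the per-gene ERHS table
#'
#' @param gene_id Gene identifiers.
#' @param module Module label per gene (0 = unassigned; unassigned genes
#'   still receive a score, with scaled kIM 0).
#' @param kim_scaled,intake_p,de_p Component vectors, see [compute_erhs()].
#' @return Data frame: gene_id, module, kim_scaled, intake_p, de_p, erhs.
#' @export
erhs_table <- function(gene_id, module, kim_scaled, intake_p, de_p) {
  data.frame(gene_id = gene_id, module = as.integer(module),
             kim_scaled = kim_scaled, intake_p = intake_p, de_p = de_p,
             erhs = compute_erhs(kim_scaled, intake_p, de_p),
             stringsAsFactors = FALSE)
}

#' Rank hub-score candidates per module and study-wide
#'
#' Sorts by ERHS descending; ties are broken deterministically by gene id.
#'
#' @param table An [erhs_table()].
#' @param per_module_n Top genes reported per module.
#' @param global_n Top genes reported study-wide.
#' @return List with `global` (top `global_n` rows, with a `rank` column)
#'   and `per_module` (named list of top `per_module_n` rows per module).
#' @export
rank_candidates <- function(table, per_module_n = 25L, global_n = 250L) {
  if (!nrow(table)) stop("empty ERHS table", call. = FALSE)
  ord <- order(-table$erhs, table$gene_id)
  sorted <- table[ord, , drop = FALSE]
  sorted$rank <- seq_len(nrow(sorted))
  global <- utils::head(sorted, global_n)
  mods <- sort(unique(table$module[table$module > 0L]))
  per_module <- lapply(mods, function(m) {
    sub <- sorted[sorted$module == m, , drop = FALSE]
    sub$rank <- seq_len(nrow(sub))
    utils::head(sub, per_module_n)
  })
  names(per_module) <- paste0("module_", mods)
  list(global = global, per_module = per_module)
}
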