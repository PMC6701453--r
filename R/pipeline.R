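#' Pipeline configuration with study defaults
#'
#' All tunables of the end-to-end analysis with their conventional defaults:
#' expression filter at 3.5 in >= 80% of samples, unscaled MAD floor 0.065,
#' soft-thresholding power 6 for single-species and 8 for consensus
#' networks, deep split 3, minimum module size 30, eigengene merge cut 0.2
#' (applied in the consensus pathway), 100 permutations for module
#' validation, and moderated-t alpha 0.01. The seed drives every stochastic
#' stage.
#'
#' @param seed Integer seed.
#' @param low_expr_threshold,low_expr_fraction,mad_min See
#'   [filter_probesets()].
#' @param power_single,power_consensus Soft thresholds.
#' @param deep_split,min_module_size,merge_cut_height Module detection.
#' @param n_perm Permutations for module validation.
#' @param de_alpha Significance level on BH q-values.
#' @param intake_phenotype Phenotype column used for intake correlations.
#' @param edge_threshold Adjacency cutoff used when exporting group-wise
#'   edge lists; echoed into the outputs.
#' @return A named list of class `coex_config`.
#' @export
coex_config <- function(seed = 1L,
                        low_expr_threshold = 3.5, low_expr_fraction = 0.80,
                        mad_min = 0.065,
                        power_single = 6, power_consensus = 8,
                        deep_split = 3L, min_module_size = 30L,
                        merge_cut_height = 0.2,
                        n_perm = 100L, de_alpha = 0.01,
                        intake_phenotype = "intake",
                        edge_threshold = 0.1) {
  structure(list(seed = as.integer(seed),
                 low_expr_threshold = low_expr_threshold,
                 low_expr_fraction = low_expr_fraction,
                 mad_min = mad_min,
                 power_single = power_single,
                 power_consensus = power_consensus,
                 deep_split = as.integer(deep_split),
                 min_module_size = as.integer(min_module_size),
                 merge_cut_height = merge_cut_height,
                 n_perm = as.integer(n_perm),
                 de_alpha = de_alpha,
                 intake_phenotype = intake_phenotype,
                 edge_threshold = edge_threshold),
            class = "coex_config")
}

#' Run the coexpression pipeline on a working directory
#'
#' Stages: `simulate` writes a synthetic two-species study; `preprocess`
#' filters probesets; `network` fits the single-species (species A) network
#' and modules; `stats` computes eigengene-trait correlations, moderated-t
#' differential expression, module/DE-set overlaps and permutation module
#' validation; `erhs` builds and ranks the hub-score table; `consensus`
#' runs the two-species meta-module analysis and cross-tabulation;
#' `diffconn` compares control- vs treated-group connectivity in the module
#' most correlated with intake; `all` runs everything in order. Each stage
#' reads the previous stage's TSV artifacts from `dir` and writes its own
#' there, plus a machine-readable `manifest.json` (package version, config,
#' file checksums). Reruns with the same seed and config reproduce
#' identical artifacts.
#'
#' @param subcommand One of `simulate`, `preprocess`, `network`, `stats`,
#'   `erhs`, `consensus`, `diffconn`, `all`.
#' @param dir Working directory for artifacts.
#' @param config A [coex_config()].
#' @param sim A [sim_config()] used by the `simulate` stage.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "preprocess",
                                        "network", "stats", "erhs",
                                        "consensus", "diffconn"),
                         dir, config = coex_config(),
                         sim = sim_config(seed = config$seed)) {
  subcommand <- match.arg(subcommand)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stages <- if (subcommand == "all") {
    c("simulate", "preprocess", "network", "stats", "erhs", "consensus",
      "diffconn")
  } else subcommand
  for (s in stages) {
    switch(s,
           simulate   = stage_simulate(dir, config, sim),
           preprocess = stage_preprocess(dir, config),
           network    = stage_network(dir, config),
           stats      = stage_stats(dir, config),
           erhs       = stage_erhs(dir, config),
           consensus  = stage_consensus(dir, config),
           diffconn   = stage_diffconn(dir, config))
  }
  write_manifest(dir, config, stages)
}

need_artifact <- function(dir, name, produced_by) {
  p <- file.path(dir, name)
  if (!file.exists(p)) {
    stop(sprintf("missing artifact '%s' in %s; run the '%s' stage first",
                 name, dir, produced_by), call. = FALSE)
  }
  p
}

stage_log <- function(fmt, ...) message(sprintf(paste0("[coexnet] ", fmt), ...))

stage_simulate <- function(dir, config, sim) {
  study <- simulate_study(sim)
  write_simulation(study, dir)
  stage_log("simulate: %d genes x %d samples (A), %d x %d (B), %d homolog pairs",
            nrow(study$expr_a), ncol(study$expr_a),
            nrow(study$expr_b), ncol(study$expr_b),
            nrow(study$truth$homologs))
}

stage_preprocess <- function(dir, config) {
  for (sp in c("A", "B")) {
    expr <- read_expression(need_artifact(dir, sprintf("expression_%s.tsv", sp),
                                          "simulate"))
    annot <- read_annotation(need_artifact(dir, sprintf("annotation_%s.tsv", sp),
                                           "simulate"))
    f <- filter_probesets(expr, annot,
                          low_expr_threshold = config$low_expr_threshold,
                          low_expr_fraction = config$low_expr_fraction,
                          mad_min = config$mad_min)
    write_expression(f$expr, file.path(dir, sprintf("filtered_%s.tsv", sp)))
    write_tsv_table(f$report, file.path(dir, sprintf("filter_report_%s.tsv", sp)))
    stage_log("preprocess %s: %d of %d probesets passed all filters",
              sp, nrow(f$expr), nrow(expr))
  }
}

# single-species fit, recomputed deterministically where later stages need it
fit_species_a <- function(dir, config) {
  expr <- read_expression(need_artifact(dir, "filtered_A.tsv", "preprocess"))
  fit_coexpression_network(expr, power = config$power_single,
                           min_module_size = config$min_module_size,
                           deep_split = config$deep_split)
}

stage_network <- function(dir, config) {
  fit <- fit_species_a(dir, config)
  a <- fit$assignment
  kme_own <- rep(NA_real_, length(a))
  if (!is.null(fit$kme)) {
    has <- a > 0L
    kme_own[has] <- fit$kme[cbind(which(has), match(paste0("ME", a[has]),
                                                    colnames(fit$kme)))]
  }
  modules <- cbind(fit$connectivity[, c("gene_id", "module")],
                   kme_own_module = kme_own,
                   fit$connectivity[, c("kim", "kim_scaled")])
  write_tsv_table(modules, file.path(dir, "modules_A.tsv"))
  if (!is.null(fit$eigengenes)) {
    write_expression(fit$eigengenes, file.path(dir, "eigengenes_A.tsv"))
  }
  stage_log("network: %d modules, %d genes unassigned",
            length(unique(a[a > 0L])), sum(a == 0L))
}

stage_stats <- function(dir, config) {
  expr <- read_expression(need_artifact(dir, "filtered_A.tsv", "preprocess"))
  info <- read_sample_info(need_artifact(dir, "samples_A.tsv", "simulate"))
  modules <- utils::read.delim(need_artifact(dir, "modules_A.tsv", "network"))
  assignment <- stats::setNames(modules$module, modules$gene_id)
  eg <- read_expression(need_artifact(dir, "eigengenes_A.tsv", "network"))

  trait <- correlate_with_trait(eg, info, config$intake_phenotype)
  write_tsv_table(trait, file.path(dir, "module_trait_A.tsv"))

  de <- moderated_t_test(expr, info, alpha = config$de_alpha)
  write_tsv_table(de, file.path(dir, "de_A.tsv"))

  net <- build_network(expr, config$power_single)
  perm <- permutation_module_validation(net, assignment,
                                        n_perm = config$n_perm,
                                        seed = config$seed)
  write_tsv_table(perm, file.path(dir, "permutation_A.tsv"))

  de_set <- de$gene_id[de$significant]
  universe <- rownames(expr)
  rows <- lapply(sort(unique(assignment[assignment > 0L])), function(m) {
    ov <- hypergeometric_overlap(names(assignment)[assignment == m],
                                 de_set, universe)
    cbind(module = m, ov)
  })
  write_tsv_table(do.call(rbind, rows), file.path(dir, "module_de_overlap_A.tsv"))
  stage_log("stats: %d DE genes at q <= %g; %d modules validated",
            length(de_set), config$de_alpha, nrow(perm))
}

stage_erhs <- function(dir, config) {
  expr <- read_expression(need_artifact(dir, "filtered_A.tsv", "preprocess"))
  info <- read_sample_info(need_artifact(dir, "samples_A.tsv", "simulate"))
  modules <- utils::read.delim(need_artifact(dir, "modules_A.tsv", "network"))
  de <- utils::read.delim(need_artifact(dir, "de_A.tsv", "stats"))

  intake <- correlate_with_trait(expr, info, config$intake_phenotype)
  tab <- erhs_table(gene_id = modules$gene_id, module = modules$module,
                    kim_scaled = modules$kim_scaled,
                    intake_p = intake$p[match(modules$gene_id,
                                              intake$entity_id)],
                    de_p = de$p[match(modules$gene_id, de$gene_id)])
  write_tsv_table(tab, file.path(dir, "erhs_A.tsv"))
  ranked <- rank_candidates(tab)
  write_tsv_table(ranked$global, file.path(dir, "erhs_top_global.tsv"))
  stage_log("erhs: scored %d genes; top score %.3f", nrow(tab),
            max(tab$erhs))
}

stage_consensus <- function(dir, config) {
  expr_a <- read_expression(need_artifact(dir, "filtered_A.tsv", "preprocess"))
  expr_b <- read_expression(need_artifact(dir, "filtered_B.tsv", "preprocess"))
  homologs <- read_homolog_map(need_artifact(dir, "homologs.tsv", "simulate"))
  modules <- utils::read.delim(need_artifact(dir, "modules_A.tsv", "network"))

  cons <- detect_meta_modules(expr_a, expr_b, homologs,
                              power = config$power_consensus,
                              min_module_size = config$min_module_size,
                              deep_split = config$deep_split,
                              merge_cut_height = config$merge_cut_height)
  meta <- data.frame(gene_a = cons$pairs$gene_a, gene_b = cons$pairs$gene_b,
                     meta_module = as.integer(cons$assignment),
                     stringsAsFactors = FALSE)
  write_tsv_table(meta, file.path(dir, "meta_modules.tsv"))

  # cross-tabulation against species-A modules over the homolog universe
  meta_assign <- stats::setNames(as.integer(cons$assignment), cons$pairs$gene_a)
  species_assign <- stats::setNames(modules$module, modules$gene_id)
  species_assign <- species_assign[names(meta_assign)]
  xtab <- cross_tabulate(meta_assign, species_assign)
  write_tsv_table(xtab, file.path(dir, "cross_tabulation.tsv"))

  if (!is.null(cons$eigengenes_a)) {
    info_a <- read_sample_info(file.path(dir, "samples_A.tsv"))
    info_b <- read_sample_info(file.path(dir, "samples_B.tsv"))
    trait_a <- correlate_with_trait(cons$eigengenes_a, info_a,
                                    config$intake_phenotype)
    trait_b <- correlate_with_trait(cons$eigengenes_b, info_b,
                                    config$intake_phenotype)
    trait_a$species <- "A"; trait_b$species <- "B"
    write_tsv_table(rbind(trait_a, trait_b),
                    file.path(dir, "meta_module_trait.tsv"))
  }
  stage_log("consensus: %d meta-modules over %d homolog pairs",
            length(unique(cons$assignment[cons$assignment > 0L])),
            nrow(cons$pairs))
}

stage_diffconn <- function(dir, config) {
  expr <- read_expression(need_artifact(dir, "filtered_A.tsv", "preprocess"))
  info <- read_sample_info(need_artifact(dir, "samples_A.tsv", "simulate"))
  modules <- utils::read.delim(need_artifact(dir, "modules_A.tsv", "network"))
  trait <- utils::read.delim(need_artifact(dir, "module_trait_A.tsv", "stats"))
  assignment <- stats::setNames(modules$module, modules$gene_id)

  target <- as.integer(sub("^ME", "", trait$entity_id[which.min(trait$p)]))
  gc <- group_connectivity(expr, info, assignment, module = target,
                           power = config$power_single,
                           edge_threshold = config$edge_threshold)
  write_tsv_table(gc, file.path(dir, "group_connectivity.tsv"))
  export_group_edgelists(expr, info,
                         genes = modules$gene_id[modules$module == target],
                         power = config$power_single,
                         edge_threshold = config$edge_threshold,
                         path_control = file.path(dir, "edges_control.tsv"),
                         path_treated = file.path(dir, "edges_treated.tsv"))
  stage_log("diffconn: module %d (most intake-correlated), edge threshold %g",
            target, config$edge_threshold)
}

write_manifest <- function(dir, config, stages) {
  files <- setdiff(list.files(dir), "manifest.json")
  sums <- tools::md5sum(file.path(dir, files))
  manifest <- list(
    package = "coexnet",
    version = as.character(utils::packageVersion("coexnet")),
    stages = stages,
    config = unclass(config),
    files = stats::setNames(as.list(unname(sums)), files)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
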