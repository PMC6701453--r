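#' Configuration for a two-species synthetic coexpression study
#'
#' Defaults emulate the study design this package targets: a primate arm
#' with 32 treated (ethanol-drinking) and 11 control animals and a rodent
#' arm with 23 drinkers and 24 non-drinkers; six planted modules spanning
#' sizes 30-200 of which half are shared between species; a continuous
#' intake phenotype coupled to a subset of module factors and defined only
#' for treated samples; treatment-regulated (DE) modules disjoint from the
#' intake-coupled ones; 10% planted hub genes per module; and a partial 1:1
#' homolog map covering 70% of genes.
#'
#' @param seed Integer seed; all randomness in [simulate_study()] derives
#'   from it.
#' @param n_genes_per_species Total genes per species.
#' @param module_sizes Integer vector of planted module sizes.
#' @param shared_module_flags Logical per module: present in both species
#'   (on homologous genes, same loading template) or in species A only.
#' @param n_treated_a,n_control_a,n_treated_b,n_control_b Samples per arm.
#' @param trait_loading Per-module coupling of the module factor to the
#'   intake phenotype of treated samples.
#' @param de_effect Per-module mean shift of treated samples, in units of
#'   `noise_sd`.
#' @param hub_fraction Fraction of each module's genes planted as hubs
#'   (loading fixed at the top of `within_module_loading_range`).
#' @param within_module_loading_range Length-2 range the remaining member
#'   loadings are drawn from (uniformly).
#' @param noise_sd Standard deviation of the i.i.d. Gaussian noise.
#' @param homolog_fraction Fraction of genes covered by the 1:1 homolog map.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_genes_per_species = 2000L,
                       module_sizes = c(30L, 40L, 60L, 80L, 120L, 200L),
                       shared_module_flags = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                       n_treated_a = 32L, n_control_a = 11L,
                       n_treated_b = 23L, n_control_b = 24L,
                       trait_loading = c(1, 0.8, 0, 0, 0.6, 0),
                       de_effect = c(0, 0, 1.5, 1.5, 0, 0),
                       hub_fraction = 0.1,
                       within_module_loading_range = c(0.7, 1.0),
                       noise_sd = 0.6,
                       homolog_fraction = 0.7) {
  cfg <- list(seed = as.integer(seed),
              n_genes_per_species = as.integer(n_genes_per_species),
              module_sizes = as.integer(module_sizes),
              shared_module_flags = as.logical(shared_module_flags),
              n_treated_a = as.integer(n_treated_a),
              n_control_a = as.integer(n_control_a),
              n_treated_b = as.integer(n_treated_b),
              n_control_b = as.integer(n_control_b),
              trait_loading = as.numeric(trait_loading),
              de_effect = as.numeric(de_effect),
              hub_fraction = hub_fraction,
              within_module_loading_range = as.numeric(within_module_loading_range),
              noise_sd = noise_sd,
              homolog_fraction = homolog_fraction)
  k <- length(cfg$module_sizes)
  if (any(cfg$module_sizes < 1L)) {
    stop("module sizes must be >= 1", call. = FALSE)
  }
  if (sum(cfg$module_sizes) > cfg$n_genes_per_species) {
    stop("sum of module sizes exceeds the number of genes per species",
         call. = FALSE)
  }
  if (length(cfg$shared_module_flags) != k ||
      length(cfg$trait_loading) != k || length(cfg$de_effect) != k) {
    stop("per-module vectors must match the number of module sizes",
         call. = FALSE)
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (cfg$hub_fraction < 0 || cfg$hub_fraction > 1) {
    stop("hub_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (length(cfg$within_module_loading_range) != 2L ||
      diff(cfg$within_module_loading_range) < 0) {
    stop("within_module_loading_range must be an increasing pair", call. = FALSE)
  }
  if (cfg$homolog_fraction <= 0 || cfg$homolog_fraction > 1) {
    stop("homolog_fraction must lie in (0, 1]", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Generate a two-species synthetic expression study with planted truth
#'
#' Factor model per species: each planted module m has a latent factor
#' `f_m ~ N(0, 1)` per sample; a member gene g has expression
#' `base_g + lambda_g * f_m + noise`, with `lambda_g` uniform on the
#' configured loading range and planted hubs fixed at its maximum.
#' Background genes are pure noise around their baseline. Modules flagged
#' shared are planted in both species on homologous genes with the same
#' loading template; unshared modules exist in species A only. Treated
#' samples of modules with a nonzero `de_effect` are shifted by
#' `de_effect * noise_sd`. The continuous intake phenotype of each species
#' is `sum_m trait_loading_m * f_m + N(0, 1)` over treated samples and
#' missing (NA) for controls.
#'
#' @param config A [sim_config()].
#' @return List with `expr_a`, `expr_b` (genes x samples matrices),
#'   `samples_a`, `samples_b` (data frames: sample_id, species, group,
#'   intake), and `truth`: planted module labels per species, hub and DE
#'   flags, per-species factor matrices, and the 1:1 `homologs` table.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- length(config$module_sizes)
  lo <- config$within_module_loading_range[1L]
  hi <- config$within_module_loading_range[2L]

  # shared loading templates drawn once so both species use identical lambdas
  templates <- lapply(seq_len(k), function(m) {
    size <- config$module_sizes[m]
    n_hub <- round(config$hub_fraction * size)
    lam <- stats::runif(size, lo, hi)
    hubs <- rep(FALSE, size)
    if (n_hub > 0) {
      idx <- seq_len(n_hub)
      lam[idx] <- hi
      hubs[idx] <- TRUE
    }
    list(lambda = lam, hub = hubs)
  })

  module_layout <- function(sp, planted) {
    n_genes <- config$n_genes_per_species
    module_of <- integer(n_genes)
    offset <- 0L
    for (m in planted) {
      module_of[offset + seq_len(config$module_sizes[m])] <- m
      offset <- offset + config$module_sizes[m]
    }
    stats::setNames(module_of, sprintf("%s_g%05d", sp, seq_len(n_genes)))
  }

  gen_species <- function(sp, n_treated, n_control, planted, base = NULL) {
    n_genes <- config$n_genes_per_species
    n_samp <- n_treated + n_control
    gene_ids <- sprintf("%s_g%05d", sp, seq_len(n_genes))
    sample_ids <- sprintf("%s_s%02d", sp, seq_len(n_samp))
    group <- rep(c("treated", "control"), c(n_treated, n_control))

    module_of <- unname(module_layout(sp, planted))
    hub <- logical(n_genes)
    lambda <- numeric(n_genes)
    for (m in planted) {
      idx <- which(module_of == m)
      lambda[idx] <- templates[[m]]$lambda
      hub[idx] <- templates[[m]]$hub
    }

    f <- matrix(stats::rnorm(k * n_samp), nrow = k,
                dimnames = list(paste0("F", seq_len(k)), sample_ids))
    if (is.null(base)) base <- stats::runif(n_genes, 4, 10)
    x <- base + matrix(stats::rnorm(n_genes * n_samp, sd = config$noise_sd),
                       nrow = n_genes)
    for (m in planted) {
      idx <- which(module_of == m)
      x[idx, ] <- x[idx, ] + lambda[idx] %o% f[m, ]
      if (config$de_effect[m] != 0) {
        trt <- group == "treated"
        x[idx, trt] <- x[idx, trt] + config$de_effect[m] * config$noise_sd
      }
    }
    dimnames(x) <- list(gene_ids, sample_ids)

    intake <- rep(NA_real_, n_samp)
    trt <- group == "treated"
    intake[trt] <- as.numeric(config$trait_loading[planted] %*%
                                f[planted, trt, drop = FALSE]) +
      stats::rnorm(sum(trt))

    list(expr = x,
         samples = data.frame(sample_id = sample_ids, species = sp,
                              group = group, intake = intake,
                              stringsAsFactors = FALSE),
         module_of = stats::setNames(module_of, gene_ids),
         hub = stats::setNames(hub & module_of > 0L, gene_ids),
         de = stats::setNames(config$de_effect[pmax(module_of, 1L)] != 0 &
                                module_of > 0L, gene_ids),
         factors = f,
         base = stats::setNames(base, gene_ids))
  }

  shared <- which(config$shared_module_flags)
  a <- gen_species("A", config$n_treated_a, config$n_control_a,
                   planted = seq_len(k))

  # 1:1 homolog map: shared-module genes pair positionally; remaining pairs
  # fill in id order from the yet-unpaired genes of each species. The layout
  # is deterministic given the config, so it can be fixed before species B
  # is generated.
  layout_a <- module_layout("A", seq_len(k))
  layout_b <- module_layout("B", shared)
  n_pairs <- round(config$homolog_fraction * config$n_genes_per_species)
  pair_a <- names(layout_a)[layout_a %in% shared]
  pair_b <- names(layout_b)[layout_b %in% shared]
  stopifnot(length(pair_a) == length(pair_b))
  rest_a <- setdiff(names(layout_a), pair_a)
  rest_b <- setdiff(names(layout_b), pair_b)
  extra <- max(0L, n_pairs - length(pair_a))
  extra <- min(extra, length(rest_a), length(rest_b))
  homologs <- data.frame(gene_a = c(pair_a, rest_a[seq_len(extra)]),
                         gene_b = c(pair_b, rest_b[seq_len(extra)]),
                         stringsAsFactors = FALSE)

  # homologous genes share a conserved baseline expression level (small
  # species jitter), so ranked expression of homolog pairs correlates
  # across species as in real cross-species data
  base_b <- stats::runif(config$n_genes_per_species, 4, 10)
  names(base_b) <- names(layout_b)
  base_b[homologs$gene_b] <- a$base[homologs$gene_a] +
    stats::rnorm(nrow(homologs), sd = 0.3)
  b <- gen_species("B", config$n_treated_b, config$n_control_b,
                   planted = shared, base = unname(base_b))

  list(expr_a = a$expr, expr_b = b$expr,
       samples_a = a$samples, samples_b = b$samples,
       truth = list(module_a = a$module_of, module_b = b$module_of,
                    hub_a = a$hub, hub_b = b$hub,
                    de_a = a$de, de_b = b$de,
                    factors_a = a$factors, factors_b = b$factors,
                    shared_modules = shared,
                    homologs = homologs,
                    config = config))
}

#' Write a simulated study to a directory as TSV files
#'
#' Emits the standard pipeline inputs: per-species expression, sample and
#' annotation tables, the homolog map, and the planted truth tables.
#'
#' @param sim Result of [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(obj, name, writer) {
    p <- file.path(dir, name)
    writer(obj, p)
    paths <<- c(paths, p)
  }
  wr(sim$expr_a, "expression_A.tsv", write_expression)
  wr(sim$expr_b, "expression_B.tsv", write_expression)
  wr(sim$samples_a, "samples_A.tsv", write_tsv_table)
  wr(sim$samples_b, "samples_B.tsv", write_tsv_table)
  ann <- function(expr) data.frame(gene_id = rownames(expr),
                                   symbol = rownames(expr),
                                   is_control = FALSE,
                                   stringsAsFactors = FALSE)
  wr(ann(sim$expr_a), "annotation_A.tsv", write_tsv_table)
  wr(ann(sim$expr_b), "annotation_B.tsv", write_tsv_table)
  wr(sim$truth$homologs, "homologs.tsv", write_tsv_table)
  truth_tab <- function(which) {
    data.frame(gene_id = names(sim$truth[[paste0("module_", which)]]),
               module = as.integer(sim$truth[[paste0("module_", which)]]),
               hub = sim$truth[[paste0("hub_", which)]],
               de = sim$truth[[paste0("de_", which)]],
               stringsAsFactors = FALSE)
  }
  wr(truth_tab("a"), "truth_A.tsv", write_tsv_table)
  wr(truth_tab("b"), "truth_B.tsv", write_tsv_table)
  invisible(paths)
}
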