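test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 5L, n_genes_per_species = 300L,
                    module_sizes = c(30L, 40L),
                    shared_module_flags = c(TRUE, FALSE),
                    trait_loading = c(1, 0), de_effect = c(0, 1.5))
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_study(sim_config(seed = 6L, n_genes_per_species = 300L,
                                  module_sizes = c(30L, 40L),
                                  shared_module_flags = c(TRUE, FALSE),
                                  trait_loading = c(1, 0),
                                  de_effect = c(0, 1.5)))
  expect_false(identical(s1$expr_a, s3$expr_a))
})

test_that("study layout matches the configured design", {
  cfg <- sim_config(seed = 2L)
  s <- simulate_study(cfg)
  expect_equal(dim(s$expr_a), c(2000L, 43L))
  expect_equal(dim(s$expr_b), c(2000L, 47L))
  # treated-only trait: exactly n_treated non-missing values
  expect_equal(sum(!is.na(s$samples_a$intake)), 32L)
  expect_equal(sum(!is.na(s$samples_b$intake)), 23L)
  expect_true(all(is.na(s$samples_a$intake[s$samples_a$group == "control"])))
  # homolog map is 1:1 and covers the configured fraction
  h <- s$truth$homologs
  expect_equal(nrow(h), round(0.7 * 2000))
  expect_false(anyDuplicated(h$gene_a) > 0)
  expect_false(anyDuplicated(h$gene_b) > 0)
  # shared modules planted in both species on homologous genes
  shared_a <- names(s$truth$module_a)[s$truth$module_a %in% s$truth$shared_modules]
  expect_true(all(shared_a %in% h$gene_a))
  mapped <- h$gene_b[match(shared_a, h$gene_a)]
  expect_equal(unname(s$truth$module_b[mapped]),
               unname(s$truth$module_a[shared_a]))
  # species-private modules absent from species B
  expect_false(any(s$truth$module_b %in%
                     setdiff(seq_along(cfg$module_sizes), s$truth$shared_modules)))
  # hubs only inside modules
  expect_true(all(s$truth$module_a[s$truth$hub_a] > 0))
})

test_that("planted modules are strongly intra-correlated against background", {
  cfg <- sim_config(seed = 3L, n_genes_per_species = 200L,
                    module_sizes = 50L, shared_module_flags = TRUE,
                    trait_loading = 1, de_effect = 0,
                    within_module_loading_range = c(0.9, 1.0), noise_sd = 0.5)
  s <- simulate_study(cfg)
  cm <- abs(cor(t(s$expr_a)))
  inmod <- s$truth$module_a == 1L
  within <- mean(cm[inmod, inmod][upper.tri(cm[inmod, inmod])])
  backgr <- mean(cm[!inmod, !inmod][upper.tri(cm[!inmod, !inmod])])
  expect_gte(within - backgr, 0.4)
})

test_that("within-module correlation exceeds between-module correlation for strong loadings", {
  for (seed in c(11L, 12L, 13L)) {
    cfg <- sim_config(seed = seed, n_genes_per_species = 250L,
                      module_sizes = c(40L, 40L),
                      shared_module_flags = c(TRUE, TRUE),
                      trait_loading = c(0, 0), de_effect = c(0, 0),
                      within_module_loading_range = c(0.7, 1.0), noise_sd = 1)
    s <- simulate_study(cfg)
    cm <- abs(cor(t(s$expr_a)))
    m1 <- s$truth$module_a == 1L
    m2 <- s$truth$module_a == 2L
    within <- mean(c(cm[m1, m1][upper.tri(cm[m1, m1])],
                     cm[m2, m2][upper.tri(cm[m2, m2])]))
    between <- mean(cm[m1, m2])
    expect_gt(within, between)
  }
})

test_that("uncoupled trait shows no spurious factor correlation (type-I-like)", {
  hits <- 0L
  for (seed in seq_len(50L)) {
    cfg <- sim_config(seed = seed, n_genes_per_species = 60L,
                      module_sizes = 40L, shared_module_flags = TRUE,
                      trait_loading = 0, de_effect = 0,
                      n_treated_a = 32L, n_control_a = 11L)
    s <- simulate_study(cfg)
    trt <- s$samples_a$group == "treated"
    ct <- cor.test(s$truth$factors_a[1L, trt], s$samples_a$intake[trt])
    hits <- hits + (ct$p.value <= 0.01)
  }
  # Bin(50, 0.01): P(X >= 4) < 1e-4
  expect_lte(hits, 3L)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(module_sizes = c(100L, 200L),
                          shared_module_flags = c(TRUE, TRUE),
                          trait_loading = c(0, 0), de_effect = c(0, 0),
                          n_genes_per_species = 250L),
               "exceeds")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(module_sizes = c(30L, 30L),
                          shared_module_flags = TRUE,
                          trait_loading = c(0, 0), de_effect = c(0, 0)),
               "per-module")
  expect_error(sim_config(homolog_fraction = 0), "homolog_fraction")
})

test_that("simulated studies round-trip through the TSV writers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 4L, n_genes_per_species = 80L,
                    module_sizes = 30L, shared_module_flags = TRUE,
                    trait_loading = 1, de_effect = 0)
  s <- simulate_study(cfg)
  write_simulation(s, dir)
  back <- read_expression(file.path(dir, "expression_A.tsv"))
  expect_identical(back, s$expr_a)
  info <- read_sample_info(file.path(dir, "samples_A.tsv"))
  expect_equal(info$group, s$samples_a$group)
  h <- read_homolog_map(file.path(dir, "homologs.tsv"))
  expect_equal(h, s$truth$homologs, ignore_attr = TRUE)
})
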