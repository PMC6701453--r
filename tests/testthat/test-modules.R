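test_that("two separated correlation blocks are recovered exactly", {
  g <- make_block_expr(sizes = c(50L, 50L), n_samples = 40L, loading = 0.95,
                       seed = 1L)
  net <- build_network(g$expr, 6)
  mod <- detect_modules(net, min_module_size = 30L, deep_split = 3L)
  expect_equal(length(unique(mod[mod > 0])), 2L)
  expect_equal(adjusted_rand_index(mod, g$truth), 1)
})

test_that("pure noise leaves nearly all genes unassigned", {
  frac_unassigned <- vapply(1:20, function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(200 * 40), 200,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:40)))
    mod <- detect_modules(build_network(x, 6), 30L, 3L)
    mean(mod == 0)
  }, numeric(1))
  expect_gte(mean(frac_unassigned), 0.9)
})

test_that("blocks below the minimum module size stay unassigned", {
  g <- make_block_expr(sizes = 20L, n_background = 30L, n_samples = 30L,
                       seed = 2L)
  mod <- detect_modules(build_network(g$expr, 6), min_module_size = 30L)
  expect_true(all(mod == 0))
  expect_warning(detect_modules(build_network(g$expr[1:10, ], 6),
                                min_module_size = 30L),
                 "unassigned")
})

test_that("module count is non-decreasing in deep split on a fixed network", {
  cfg <- sim_config(seed = 11L, n_genes_per_species = 600L,
                    module_sizes = c(40L, 60L, 80L, 100L),
                    shared_module_flags = rep(TRUE, 4),
                    trait_loading = rep(0, 4), de_effect = rep(0, 4),
                    within_module_loading_range = c(0.6, 1.0), noise_sd = 0.8)
  s <- simulate_study(cfg)
  net <- build_network(s$expr_a, 6)
  counts <- vapply(0:3, function(ds) {
    m <- detect_modules(net, 30L, ds)
    length(unique(m[m > 0]))
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("eigengene is the first principal component with the sign convention", {
  # rank-1 module: identical profiles -> eigengene = standardized profile
  set.seed(4)
  prof <- rnorm(20)
  x <- matrix(rep(prof, each = 5), 5, byrow = FALSE) * c(1, 2, 3, 4, 5)
  dimnames(x) <- list(paste0("g", 1:5), paste0("s", 1:20))
  asn <- setNames(rep(1L, 5), rownames(x))
  eg <- module_eigengenes(x, asn)
  z <- (prof - mean(prof)) / sd(prof)
  expect_equal(unname(eg$eigengenes[1, ]), z, tolerance = 1e-8)
  expect_equal(unname(eg$var_explained[1]), 1)
  # sign orientation survives global negation of the member genes
  eg_neg <- module_eigengenes(-x, asn)
  zneg <- apply(-x, 1, scale)
  expect_gte(cor(eg_neg$eigengenes[1, ], rowMeans(zneg)), 0)
  # SVD oracle on a random module
  set.seed(5)
  y <- matrix(rnorm(30 * 25), 30,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:25)))
  eg2 <- module_eigengenes(y, setNames(rep(1L, 30), rownames(y)))
  zc <- t(scale(t(y)))
  pc1 <- svd(zc)$v[, 1]
  got <- eg2$eigengenes[1, ] / sd(eg2$eigengenes[1, ])
  expect_lt(min(max(abs(got - pc1 / sd(pc1))),
                max(abs(got + pc1 / sd(pc1)))), 1e-8)
})

test_that("eigengene computation rejects degenerate modules", {
  x <- matrix(5, 4, 10, dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  expect_error(module_eigengenes(x, setNames(rep(1L, 4), rownames(x))),
               "zero-variance")
})

test_that("intramodular connectivity and scaling match hand evaluation", {
  a <- matrix(c(1, .9, .9,
                .9, 1, .1,
                .9, .1, 1), 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  conn <- intramodular_connectivity(a, setNames(rep(1L, 3), rownames(a)))
  expect_equal(conn$kim, c(1.8, 1.0, 1.0))
  expect_equal(conn$kim_scaled, c(1, 1 / 1.8, 1 / 1.8), tolerance = 1e-12)
  # the maximally connected gene of each module scales to exactly 1
  set.seed(6)
  a2 <- random_adjacency(40)
  asn <- setNames(rep(1:2, each = 20), rownames(a2))
  conn2 <- intramodular_connectivity(a2, asn)
  for (m in 1:2) expect_equal(max(conn2$kim_scaled[conn2$module == m]), 1)
  # unassigned genes get zero
  asn[1:3] <- 0L
  conn3 <- intramodular_connectivity(a2, asn)
  expect_true(all(conn3$kim[conn3$module == 0] == 0))
})

test_that("planted hubs carry the highest scaled connectivity", {
  cfg <- sim_config(seed = 21L, n_genes_per_species = 300L,
                    module_sizes = c(50L, 60L), shared_module_flags = c(TRUE, TRUE),
                    trait_loading = c(0, 0), de_effect = c(0, 0),
                    within_module_loading_range = c(0.7, 1.0), noise_sd = 0.6)
  s <- simulate_study(cfg)
  fit <- fit_coexpression_network(s$expr_a, power = 6)
  conn <- setNames(fit$connectivity$kim_scaled, fit$connectivity$gene_id)
  for (m in 1:2) {
    genes <- names(s$truth$module_a)[s$truth$module_a == m]
    hubs <- genes[s$truth$hub_a[genes]]
    non <- setdiff(genes, hubs)
    expect_gt(mean(conn[hubs]), mean(conn[non]))
  }
})

test_that("eigengene-similar modules merge and dissimilar ones do not", {
  set.seed(9)
  ns <- 40L
  f1 <- rnorm(ns)
  # identical eigengenes -> merged
  x <- rbind(t(sapply(1:10, function(i) f1 + rnorm(ns, sd = .1))),
             t(sapply(1:10, function(i) f1 + rnorm(ns, sd = .1))))
  dimnames(x) <- list(paste0("g", 1:20), paste0("s", 1:ns))
  asn <- setNames(rep(1:2, each = 10), rownames(x))
  merged <- merge_similar_modules(x, asn, cut_height = 0.2)
  expect_equal(length(unique(merged)), 1L)
  # eigengene correlation -0.5 (dissimilarity 1.5) -> unchanged
  f2 <- -0.5 * f1 + sqrt(1 - 0.25) * rnorm(ns)
  y <- rbind(t(sapply(1:10, function(i) f1 + rnorm(ns, sd = .05))),
             t(sapply(1:10, function(i) f2 + rnorm(ns, sd = .05))))
  dimnames(y) <- dimnames(x)
  kept <- merge_similar_modules(y, asn, cut_height = 0.2)
  expect_equal(length(unique(kept)), 2L)
  # correlation ~0.9 (dissimilarity ~0.1 < 0.2) -> merged
  f3 <- 0.9 * f1 + sqrt(1 - 0.81) * rnorm(ns)
  z <- rbind(t(sapply(1:10, function(i) f1 + rnorm(ns, sd = .05))),
             t(sapply(1:10, function(i) f3 + rnorm(ns, sd = .05))))
  dimnames(z) <- dimnames(x)
  expect_equal(length(unique(merge_similar_modules(z, asn, 0.2))), 1L)
})

test_that("the fit object prints, summarizes and exposes kME", {
  g <- make_block_expr(sizes = c(35L, 35L), n_background = 30L,
                       n_samples = 30L, seed = 10L)
  fit <- fit_coexpression_network(g$expr, power = 6)
  expect_s3_class(fit, "coex_fit")
  expect_output(print(fit), "modules: 2")
  sm <- summary(fit)
  expect_equal(nrow(sm$modules), 2L)
  expect_equal(dim(fit$kme), c(100L, 2L))
  # a module's own members correlate strongly with their eigengene
  own <- abs(fit$kme[fit$assignment == 1L, "ME1"])
  expect_gt(mean(own), 0.8)
})

test_that("adjusted Rand index agrees with the mclust reference", {
  set.seed(12)
  for (i in 1:5) {
    a <- sample(0:3, 60, replace = TRUE)
    b <- sample(0:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
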