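test_that("trait correlation drops missing phenotypes, never zero-fills", {
  set.seed(1)
  n_trt <- 32L; n_ctl <- 11L
  trait <- c(rnorm(n_trt, 3), rep(NA_real_, n_ctl))
  info <- data.frame(sample_id = paste0("s", 1:43),
                     group = rep(c("treated", "control"), c(n_trt, n_ctl)),
                     intake = trait)
  prof <- matrix(rnorm(2 * 43), 2,
                 dimnames = list(c("ME1", "ME2"), info$sample_id))
  prof[1, 1:n_trt] <- trait[1:n_trt]   # eigengene equal to the trait
  res <- correlate_with_trait(prof, info, "intake")
  expect_equal(res$n_used, c(32L, 32L))
  expect_equal(res$r[1], 1)
  expect_lt(res$p[1], 1e-12)
})

test_that("correlation p matches the exact t-transform oracle", {
  set.seed(2)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    x <- rnorm(n); y <- rnorm(n)
    info <- data.frame(sample_id = paste0("s", 1:n), group = "treated",
                       ph = y)
    prof <- matrix(x, 1, dimnames = list("g1", info$sample_id))
    res <- correlate_with_trait(prof, info, "ph")
    ct <- cor.test(x, y)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-10)
    expect_equal(res$p, ct$p.value, tolerance = 1e-10)
  }
  expect_error(correlate_with_trait(matrix(rnorm(4), 1,
                                           dimnames = list("g", paste0("s", 1:4))),
                                    data.frame(sample_id = paste0("s", 1:4),
                                               ph = c(1, 2, NA, NA)),
                                    "ph"),
               "fewer than 3")
})

test_that("moderated t collapses to the classical t when the prior is empty", {
  set.seed(3)
  x <- matrix(rnorm(100 * 14), 100,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:14)))
  info <- data.frame(sample_id = colnames(x),
                     group = rep(c("treated", "control"), each = 7))
  r0 <- moderated_t_test(x, info, prior_df = 0)
  classic <- apply(x, 1, function(v) {
    t.test(v[1:7], v[8:14], var.equal = TRUE)$statistic
  })
  expect_equal(r0$t, unname(classic), tolerance = 1e-10)
})

test_that("infinite prior fixes every denominator at the prior variance", {
  set.seed(4)
  x <- matrix(rnorm(50 * 12), 50,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  info <- data.frame(sample_id = colnames(x),
                     group = rep(c("treated", "control"), each = 6))
  rInf <- moderated_t_test(x, info, prior_df = Inf)
  s0 <- attr(rInf, "s0_sq")
  lr <- rowMeans(x[, 1:6]) - rowMeans(x[, 7:12])
  expect_equal(rInf$t, unname(lr / sqrt(s0 * (1 / 6 + 1 / 6))),
               tolerance = 1e-12)
})

test_that("moderated t agrees closely with the limma reference", {
  set.seed(5)
  n1 <- 9L; n2 <- 8L
  x <- matrix(rnorm(300 * (n1 + n2), sd = rep(sqrt(rchisq(300, 8) / 8), n1 + n2)),
              300, dimnames = list(paste0("g", 1:300), paste0("s", 1:(n1 + n2))))
  x[1:30, 1:n1] <- x[1:30, 1:n1] + 1.2
  info <- data.frame(sample_id = colnames(x),
                     group = rep(c("treated", "control"), c(n1, n2)))
  mine <- moderated_t_test(x, info)
  design <- cbind(1, rep(c(1, 0), c(n1, n2)))
  ref <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(attr(mine, "d0"), ref$df.prior, tolerance = 0.05)
  expect_equal(attr(mine, "s0_sq"), ref$s2.prior, tolerance = 0.02)
  expect_gt(cor(mine$t, ref$t[, 2]), 0.9999)
  expect_lt(max(abs(mine$p - ref$p.value[, 2])), 1e-3)
  expect_error(moderated_t_test(x[, 1:10],
                                data.frame(sample_id = paste0("s", 1:10),
                                           group = c("treated",
                                                     rep("control", 9)))),
               "2 samples per group")
})

test_that("BH adjustment matches hand step-up computation and is stable", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(6)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("hypergeometric overlap matches exact enumeration", {
  u <- paste0("g", 1:10)
  res <- hypergeometric_overlap(u[1:4], u[c(1, 2, 3, 5, 6)], u)
  expect_equal(res$overlap, 3L)
  expect_equal(res$p, 66 / 252, tolerance = 1e-12)
  # overlap 0 when 0 is achievable -> p = 1
  expect_equal(hypergeometric_overlap(u[1:2], u[3:4], u)$p, 1)
  # degenerate certainty
  expect_equal(hypergeometric_overlap(u, u, u)$p, 1)
  expect_error(hypergeometric_overlap(c(u[1], "zz"), u[1:2], u), "contained")
})

test_that("permutation module validation behaves at both extremes", {
  g <- make_block_expr(sizes = 50L, n_background = 100L, n_samples = 40L,
                       loading = 0.9, noise_sd = 0.5, seed = 7L)
  net <- build_network(g$expr, 6)
  asn <- setNames(ifelse(g$truth == 1L, 1L, 0L), rownames(g$expr))
  res <- permutation_module_validation(net, asn, n_perm = 100L, seed = 1L)
  expect_equal(res$p, 1 / 101)
  expect_gt(res$observed, res$null_mean)
  # module = whole universe: observed equals every null draw exactly
  all_asn <- setNames(rep(1L, nrow(g$expr)), rownames(g$expr))
  res_all <- permutation_module_validation(net, all_asn, n_perm = 50L, seed = 1L)
  expect_equal(res_all$p, 1)
  expect_equal(res_all$observed, res_all$null_mean)
  tiny <- setNames(c(1L, rep(0L, nrow(g$expr) - 1L)), rownames(g$expr))
  expect_error(permutation_module_validation(net, tiny, 10L), "fewer than 2")
})

test_that("random gene sets give approximately uniform permutation p", {
  set.seed(8)
  x <- matrix(rnorm(80 * 30), 80,
              dimnames = list(paste0("g", 1:80), paste0("s", 1:30)))
  tom <- build_network(x, 6)$tom
  ps <- vapply(1:200, function(i) {
    asn <- setNames(integer(80), rownames(x))
    asn[sample(80, 10)] <- 1L
    permutation_module_validation(tom, asn, n_perm = 100L)$p
  }, numeric(1))
  frac <- mean(ps <= 0.05)
  half_width <- 2.576 * sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(frac - 5 / 101), half_width)
  expect_true(all(ps > 0))
})

test_that("membership-significance validation finds planted relationships", {
  cfg <- sim_config(seed = 31L, n_genes_per_species = 150L,
                    module_sizes = 60L, shared_module_flags = TRUE,
                    trait_loading = 2, de_effect = 0,
                    within_module_loading_range = c(0.5, 1.0), noise_sd = 0.6)
  s <- simulate_study(cfg)
  fit <- fit_coexpression_network(s$expr_a, power = 6)
  genes <- names(fit$assignment)[fit$assignment == 1L]
  gene_sig <- correlate_with_trait(s$expr_a[genes, ], s$samples_a, "intake")
  kme_own <- fit$kme[genes, "ME1"]
  # orient membership and significance consistently before correlating
  res <- membership_significance(abs(kme_own), abs(gene_sig$r))
  expect_gt(res$r, 0)
  expect_lte(res$p, 0.01)
  # shuffled membership kills the relationship most of the time
  set.seed(9)
  shuf_p <- vapply(1:100, function(i) {
    membership_significance(sample(abs(kme_own)), abs(gene_sig$r))$p
  }, numeric(1))
  expect_lt(mean(shuf_p <= 0.05), 0.15)
  expect_error(membership_significance(c(1, 2), c(1, 2)), "fewer than 3")
})
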