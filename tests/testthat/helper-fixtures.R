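# Shared fixture builders: small factor-model expression matrices with known
# planted structure, built in code at test time.

# blocks of genes each driven by an independent latent factor; remaining
# genes are pure noise
make_block_expr <- function(sizes, n_background = 0L, n_samples = 40L,
                            loading = 0.95, noise_sd = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(noise_sd)) noise_sd <- sqrt(1 - loading^2)
  n <- sum(sizes) + n_background
  x <- matrix(rnorm(n * n_samples, sd = noise_sd), n, n_samples)
  off <- 0L
  for (s in sizes) {
    f <- rnorm(n_samples)
    x[off + seq_len(s), ] <- x[off + seq_len(s), ] + loading * rep(1, s) %o% f
    off <- off + s
  }
  rownames(x) <- sprintf("g%04d", seq_len(n))
  colnames(x) <- sprintf("s%03d", seq_len(n_samples))
  list(expr = x + 6,
       truth = rep(c(seq_along(sizes), 0L), c(sizes, n_background)))
}

# expression whose connectivity at the design power follows a truncated
# Pareto (planted scale-free topology)
make_scalefree_expr <- function(n = 1500L, n_samples = 120L, gamma = 2.5,
                                w_min = 0.02, beta = 6, seed = 1L) {
  set.seed(seed)
  u <- runif(n)
  w <- w_min / (1 - u * (1 - w_min^(gamma - 1)))^(1 / (gamma - 1))
  r <- w^(1 / beta)
  f <- rnorm(n_samples)
  x <- r %o% f + sqrt(1 - r^2) * matrix(rnorm(n * n_samples), n)
  rownames(x) <- sprintf("g%04d", seq_len(n))
  colnames(x) <- sprintf("s%03d", seq_len(n_samples))
  x
}

# one module with a planted hub-emergence gene: zero loading in controls,
# maximal loading in treated samples; other genes stable across groups
make_emergence_expr <- function(n_treated = 32L, n_control = 11L,
                                module_size = 30L, loading_range = c(0.7, 1),
                                noise_sd = 0.6) {
  ft <- rnorm(n_treated)
  fc <- rnorm(n_control)
  lam <- runif(module_size, loading_range[1], loading_range[2])
  xt <- lam %o% ft + matrix(rnorm(module_size * n_treated, sd = noise_sd),
                            module_size)
  xc <- lam %o% fc + matrix(rnorm(module_size * n_control, sd = noise_sd),
                            module_size)
  xt[1L, ] <- loading_range[2] * ft + rnorm(n_treated, sd = noise_sd)
  xc[1L, ] <- rnorm(n_control, sd = noise_sd)
  x <- cbind(xt, xc) + 6
  rownames(x) <- sprintf("g%02d", seq_len(module_size))
  colnames(x) <- sprintf("s%02d", seq_len(n_treated + n_control))
  info <- data.frame(sample_id = colnames(x),
                     group = rep(c("treated", "control"),
                                 c(n_treated, n_control)))
  list(expr = x, info = info, emergent = "g01")
}

# random symmetric adjacency in [0,1] with unit diagonal
random_adjacency <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}

# triple-loop reference evaluation of the TOM formula
brute_force_tom <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
      ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
      tom[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  tom
}

# hypergeometric upper-tail by explicit enumeration of all size-b subsets
enumerate_overlap_tail <- function(n_universe, n_a, n_b, min_overlap) {
  if (n_b == 0L) return(as.numeric(min_overlap <= 0))
  subsets <- utils::combn(n_universe, n_b)
  hits <- colSums(subsets <= n_a)   # universe 1..N, A = first n_a elements
  mean(hits >= min_overlap)
}
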