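# Benchmark datasets built in code for classifier contract tests.

# Two well-separated Gaussian classes with shared covariance; Bayes error
# is negligible by construction (||delta mu|| >= 10 sigma).
make_separated_gaussians <- function(n_per_class = 100, p = 4, sep = 10,
                                     seed = 1) {
  set.seed(seed)
  x1 <- matrix(stats::rnorm(n_per_class * p), ncol = p)
  x2 <- matrix(stats::rnorm(n_per_class * p), ncol = p)
  x2[, 1] <- x2[, 1] + sep
  x <- rbind(x1, x2)
  colnames(x) <- paste0("t", seq_len(p))
  list(x = x, y = factor(rep(c("A", "B"), each = n_per_class)))
}

# XOR-pattern: four clusters at the corners of a square, classes on the
# diagonals — linearly inseparable by construction.
make_xor_data <- function(n_per_cluster = 100, noise = 0.08, seed = 1) {
  set.seed(seed)
  corners <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  cls <- c("A", "A", "B", "B")
  x <- do.call(rbind, lapply(1:4, function(i) {
    cbind(stats::rnorm(n_per_cluster, corners[i, 1], noise),
          stats::rnorm(n_per_cluster, corners[i, 2], noise))
  }))
  colnames(x) <- c("t1", "t2")
  list(x = x, y = factor(rep(cls, each = n_per_cluster)))
}

# Four spherical clusters, one per class, clearly separated.
make_four_clusters <- function(n_per_cluster = 50, noise = 0.05, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  x <- do.call(rbind, lapply(1:4, function(i) {
    cbind(stats::rnorm(n_per_cluster, centers[i, 1], noise),
          stats::rnorm(n_per_cluster, centers[i, 2], noise))
  }))
  colnames(x) <- c("t1", "t2")
  list(x = x, y = factor(rep(paste0("E", 1:4), each = n_per_cluster)))
}

# Dataset where each of 4 designated traits is elevated only in its own
# class (every signal trait is individually necessary to recognize one
# class) plus pure-noise traits; used by the importance-recovery tests.
make_four_signal_data <- function(n_per_class = 30, n_noise = 8, shift = 3,
                                  noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  K <- 4
  n <- n_per_class * K
  y <- factor(rep(paste0("E", 1:K), each = n_per_class))
  sig <- matrix(stats::rnorm(n * K, 0, noise_sd), n, K)
  for (k in 1:K) sig[as.integer(y) == k, k] <- sig[as.integer(y) == k, k] + shift
  nz <- matrix(stats::rnorm(n * n_noise), n, n_noise)
  x <- cbind(sig, nz)
  colnames(x) <- c(paste0("signal", 1:K), paste0("noise", seq_len(n_noise)))
  df <- as.data.frame(x)
  df$environment <- y
  df
}

# small fixture-shaped dataset shared across tests (kept cheap)
fixture_dataset <- function(n_per_env = 22, seed = 42) {
  generate_phenotypes(coffee_trait_specs(), n_per_env = n_per_env, seed = seed)
}
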