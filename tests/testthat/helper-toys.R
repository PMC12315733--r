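# small fixtures shared across test files; everything is built in code

# symmetric zero-diagonal matrix with random nonnegative weights
rand_sc <- function(K, density = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0, K, K)
  ut <- upper.tri(m)
  present <- ut & (matrix(runif(K * K), K, K) < density)
  m[present] <- rlnorm(sum(present))
  m + t(m)
}

# symmetric zero-diagonal matrix with standard normal edge values
rand_sym <- function(K, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0, K, K)
  m[upper.tri(m)] <- rnorm(K * (K - 1) / 2)
  m + t(m)
}

# path graph adjacency on K nodes with unit weights
path_graph <- function(K) {
  m <- matrix(0, K, K)
  for (i in seq_len(K - 1)) m[i, i + 1] <- m[i + 1, i] <- 1
  m
}

# minimal region-metadata table for forward-model toys
toy_meta <- function(K) {
  pts <- sfcoupling:::fibonacci_sphere(K)
  tibble::tibble(
    region_id = seq_len(K),
    hemisphere = rep(c("left", "right"), length.out = K),
    axis_rank = seq_len(K),
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    volume = rep(100, K)
  )
}

# row-major upper-triangle oracle, written independently of the package
ut_oracle <- function(m) {
  K <- nrow(m)
  out <- c()
  for (i in seq_len(K - 1)) for (j in (i + 1):K) out <- c(out, m[i, j])
  out
}

# brute-force Pearson correlation from the covariance formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2 / (n - 1))) * sqrt(sum((y - mean(y))^2 / (n - 1))))
}

# small trainable cohort for quick GNN tests
tiny_cohort <- function(K = 16L, N = 8L, seed = 5L, ...) {
  args <- utils::modifyList(
    list(n_subjects = N, n_regions = K, n_modules = 2L,
         p_within = 0.8, p_between = 0.25, seed = seed),
    list(...)
  )
  generate_cohort(do.call(cohort_spec, args))
}
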