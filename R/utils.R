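#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor quantile rnorm runif rlnorm sd var setNames
#' @importFrom rlang abort warn .data
#' @importFrom generics tidy glance
#' @importFrom Rcpp evalCpp
#' @useDynLib sfcoupling, .registration = TRUE
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# row-major upper-triangle extraction: entries (i, j) with i < j ordered by
# row, i.e. (1,2), (1,3), ..., (1,K), (2,3), ...
ut_rowmajor <- function(m) {
  t(m)[lower.tri(m)]
}

# index pairs matching ut_rowmajor() ordering
ut_index_pairs <- function(K) {
  i <- rep.int(seq_len(K - 1L), times = (K - 1L):1L)
  j <- unlist(lapply(seq_len(K - 1L), function(a) (a + 1L):K), use.names = FALSE)
  cbind(i = i, j = j)
}

# all ordered off-diagonal pairs (i != j), row-major
ordered_pairs <- function(K) {
  i <- rep(seq_len(K), each = K - 1L)
  j <- unlist(lapply(seq_len(K), function(a) seq_len(K)[-a]), use.names = FALSE)
  cbind(i = i, j = j)
}

check_symmetric <- function(m, tol = 1e-9, arg = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(sprintf("`%s` must be a square matrix.", arg), class = "sfc_invalid_input")
  }
  if (max(abs(m - t(m))) > tol) {
    abort(sprintf("`%s` must be symmetric (tolerance %g).", arg, tol),
          class = "sfc_invalid_input")
  }
  invisible(m)
}

check_connectome <- function(m, nonneg = FALSE, arg = "matrix") {
  check_symmetric(m, arg = arg)
  if (any(diag(m) != 0)) abort(sprintf("`%s` must have a zero diagonal.", arg), class = "sfc_invalid_input")
  if (nonneg && any(m < 0)) abort(sprintf("`%s` must be nonnegative.", arg), class = "sfc_invalid_input")
  invisible(m)
}

# force exact symmetry / zero diagonal after floating-point assembly
symmetrize <- function(m) {
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# Pearson r between columns of Y (n x m) and a single vector x, vectorized.
cor_vec_mat <- function(x, Y) {
  x <- x - mean(x)
  Y <- sweep(Y, 2L, colMeans(Y))
  num <- drop(crossprod(x, Y))
  den <- sqrt(sum(x^2)) * sqrt(colSums(Y^2))
  num / den
}

# deterministic sub-seed derivation: small string hash folded with the master
# seed, kept inside the 32-bit signed range
stage_seed <- function(master_seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(master_seed) * 2654435 + h * 97 + 1) %% 2147483629)
}
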