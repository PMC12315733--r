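#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive average ranks).
#'
#' @param x,y Equal-length numeric vectors (>= 3, non-constant).
#' @return Spearman's rho.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("Need equal-length vectors of length >= 3.", class = "sfc_invalid_input")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Constant vector: correlation undefined.", class = "sfc_degenerate_input")
  }
  cor(x, y, method = "spearman")
}

#' Outlier mask at k standard deviations
#'
#' Keeps values within `mean +/- k * sd` of the full (finite) vector; with a
#' constant vector the sd is zero and everything equal to the mean is kept.
#' Missing values are marked not-kept.
#'
#' @param values Numeric vector (length >= 3).
#' @param k Number of standard deviations (default 3).
#' @return Logical vector, `TRUE` where the value is retained.
#' @export
outlier_mask <- function(values, k = 3) {
  if (length(values) < 3L) abort("Need length >= 3.", class = "sfc_invalid_input")
  ok <- is.finite(values)
  mu <- mean(values[ok])
  s <- sd(values[ok])
  ok & (abs(values - mu) <= k * s)
}

#' Alignment of a regional map with the cortical axis
#'
#' Excludes outliers of the map (`mean +/- k * sd`), computes Spearman's rho
#' between the surviving regional values and their axis ranks, and assesses
#' significance with the spin test: each rotation permutes the full-length
#' map, then the same outlier/missing exclusion is applied.
#'
#' @param map Length-K vector of regional values (e.g. an effect map column).
#' @param axis_ranks Length-K integer vector of axis ranks.
#' @param permutations List of permutations from [spin_rotations()].
#' @param k Outlier cutoff in standard deviations (default 3).
#' @return An `sfc_alignment` tibble row: `rho`, `p_spin`, `n_regions_used`,
#'   `n_outliers`, plus attribute `outliers_excluded` (region indices).
#' @export
align_map <- function(map, axis_ranks, permutations, k = 3) {
  ok <- is.finite(map)
  keep <- outlier_mask(map, k = k)
  if (sum(keep) < 3L) {
    abort("Fewer than 3 regions survive outlier exclusion.", class = "sfc_invalid_input")
  }
  spin <- spin_pvalue(map, axis_ranks, permutations, keep = keep)
  out <- tibble::tibble(
    rho = spin$empirical,
    p_spin = spin$p_spin,
    n_regions_used = sum(keep),
    n_outliers = sum(ok & !keep)
  )
  attr(out, "outliers_excluded") <- which(ok & !keep)
  class(out) <- c("sfc_alignment", class(out))
  out
}
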