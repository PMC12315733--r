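# Fibonacci lattice: n quasi-uniform points on the unit sphere
fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  phi <- pi * (1 + sqrt(5)) * k
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Build synthetic region metadata
#'
#' Lays out `K/2` regions per hemisphere quasi-uniformly on each hemisphere's
#' unit sphere (Fibonacci lattice, mirrored in x across hemispheres), assigns
#' an axis rank that is spatially smooth on the sphere (regions are ranked by
#' decreasing z, so rank 1 sits at the "sensorimotor-like" north pole and rank
#' K at the opposite pole), and draws log-normal region volumes. The smooth
#' spatial layout of the ranks is what makes the spin test meaningful on
#' synthetic data.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `region_id`, `hemisphere`, `axis_rank`,
#'   `x`, `y`, `z` (unit sphere coordinates) and `volume`.
#' @export
build_region_meta <- function(spec) {
  validate_cohort_spec(spec)
  K <- spec$n_regions
  half <- K %/% 2L
  pts <- fibonacci_sphere(half)
  # mirror x across hemispheres, like left/right surface spheres
  coords <- rbind(pts, cbind(-pts[, 1L], pts[, 2L:3L]))
  hemisphere <- rep(c("left", "right"), each = half)
  # axis rank: smooth in space; ties between mirrored hemispheres broken by
  # hemisphere order, deterministically
  ord <- order(-coords[, 3L], hemisphere, seq_len(K))
  axis_rank <- integer(K)
  axis_rank[ord] <- seq_len(K)
  volume <- rlnorm(K, meanlog = log(100), sdlog = 0.2)
  tibble::tibble(
    region_id = seq_len(K),
    hemisphere = hemisphere,
    axis_rank = axis_rank,
    x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
    volume = volume
  )
}

validate_region_meta <- function(meta) {
  K <- nrow(meta)
  if (!setequal(meta$axis_rank, seq_len(K))) {
    abort("`axis_rank` must be a permutation of 1..K.", class = "sfc_invalid_meta")
  }
  nrm <- sqrt(meta$x^2 + meta$y^2 + meta$z^2)
  if (any(abs(nrm - 1) > 1e-9)) {
    abort("Sphere coordinates must be unit-norm.", class = "sfc_invalid_meta")
  }
  if (any(meta$volume <= 0)) abort("Volumes must be positive.", class = "sfc_invalid_meta")
  invisible(meta)
}
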