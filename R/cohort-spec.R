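#' Specification of a synthetic connectome cohort
#'
#' Bundles every knob of the synthetic cohort generator: the shared structural
#' backbone (stochastic block model with hubs and log-normal weights), the
#' subject-level structural jitter, and the structural-to-functional forward
#' model that mixes a multi-hop topological signal with a group-common
#' component, an axis-graded individual component, and observation noise.
#'
#' The defaults define the package's reference study conditions: a cohort of
#' `n_subjects = 80` subjects on `n_regions = 60` regions whose functional
#' connectivity is a two-hop function of structural topology
#' (`beta = c(0.5, 0.5)`), with a shared non-structural component of scale
#' `gamma_g = 0.3`, an individual component whose per-region scale grows from
#' `gamma_i` at the sensorimotor-like pole to `gamma_i * (1 + axis_slope)` at
#' the association-like pole, and Gaussian observation noise `noise_sd`.
#'
#' @param n_subjects Number of subjects N (>= 2).
#' @param n_regions Number of regions K (even, >= 6).
#' @param n_modules Number of planted modules in the structural backbone.
#' @param p_within,p_between Within- and between-module edge probabilities.
#' @param hub_frac Fraction of nodes promoted to hubs; edges incident to a hub
#'   are drawn at the within-module probability regardless of module, producing
#'   a densely interconnected core.
#' @param w_logmean,w_logsd Log-mean and log-sd of the log-normal edge weights.
#' @param tau_sc Subject-level multiplicative jitter sd on log edge weights.
#' @param flip_rate Per-edge probability of deleting an existing edge, and
#'   per-pair probability of creating an absent one, in a subject's matrix.
#' @param beta Numeric vector of multi-hop mapping coefficients; `beta[p]`
#'   weights the p-th power of the normalized structural adjacency.
#' @param gamma_g Scale of the group-common non-structural component.
#' @param gamma_i Base scale of the individual-specific component.
#' @param indiv_struct_share Fraction of the individual component's variance
#'   that is structurally expressed (drawn from the subject's own latent
#'   deviation from the backbone) rather than i.i.d. noise; see
#'   [forward_fc()].
#' @param axis_slope Slope s of the individual scale along the axis: region r
#'   has scale `sigma(r) = gamma_i * (1 + s * (rank(r) - 1) / (K - 1))`.
#' @param noise_sd Observation noise sd.
#' @param seed Integer seed; fully determines the generated cohort.
#'
#' @return An object of class `cohort_spec` (a named list).
#' @export
cohort_spec <- function(n_subjects = 80L,
                        n_regions = 60L,
                        n_modules = 4L,
                        p_within = 0.7,
                        p_between = 0.08,
                        hub_frac = 0.1,
                        w_logmean = 0,
                        w_logsd = 0.5,
                        tau_sc = 0.1,
                        flip_rate = 0.02,
                        beta = c(0.5, 0.5),
                        gamma_g = 0.3,
                        gamma_i = 0.5,
                        indiv_struct_share = 0.8,
                        axis_slope = 2,
                        noise_sd = 0.1,
                        seed = 1L) {
  spec <- list(
    n_subjects = as.integer(n_subjects), n_regions = as.integer(n_regions),
    n_modules = as.integer(n_modules), p_within = p_within,
    p_between = p_between, hub_frac = hub_frac, w_logmean = w_logmean,
    w_logsd = w_logsd, tau_sc = tau_sc, flip_rate = flip_rate, beta = beta,
    gamma_g = gamma_g, gamma_i = gamma_i,
    indiv_struct_share = indiv_struct_share, axis_slope = axis_slope,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$n_subjects < 2L) abort("`n_subjects` must be >= 2.", class = "sfc_invalid_spec")
  if (spec$n_regions < 6L) abort("`n_regions` must be >= 6.", class = "sfc_invalid_spec")
  if (spec$n_regions %% 2L != 0L) {
    abort("`n_regions` must be even (two equal hemispheres).", class = "sfc_invalid_spec")
  }
  probs <- c(spec$p_within, spec$p_between, spec$hub_frac, spec$flip_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("Probabilities must lie in [0, 1].", class = "sfc_invalid_spec")
  }
  scales <- c(spec$tau_sc, spec$gamma_g, spec$gamma_i, spec$axis_slope, spec$noise_sd, spec$w_logsd)
  if (spec$indiv_struct_share < 0 || spec$indiv_struct_share > 1) {
    abort("`indiv_struct_share` must lie in [0, 1].", class = "sfc_invalid_spec")
  }
  if (any(scales < 0)) abort("Scales must be nonnegative.", class = "sfc_invalid_spec")
  if (length(spec$beta) < 1L) abort("`beta` must have at least one coefficient.", class = "sfc_invalid_spec")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  N = %d subjects, K = %d regions, %d modules, seed = %d\n",
              x$n_subjects, x$n_regions, x$n_modules, x$seed))
  cat(sprintf("  backbone: p_within = %.2f, p_between = %.2f, hubs = %.2f\n",
              x$p_within, x$p_between, x$hub_frac))
  cat(sprintf("  forward: beta = (%s), gamma_g = %.2f, gamma_i = %.2f, slope = %.2f, noise = %.2f\n",
              paste(format(x$beta), collapse = ", "),
              x$gamma_g, x$gamma_i, x$axis_slope, x$noise_sd))
  invisible(x)
}

#' Per-region individual-component scale along the axis
#'
#' `sigma(r) = gamma_i * (1 + s * (axis_rank - 1) / (K - 1))`: the sd scale of
#' the individual-specific functional component at each region, increasing
#' from the sensorimotor-like pole (rank 1) to the association-like pole
#' (rank K) when `axis_slope > 0`.
#'
#' @param axis_rank Integer vector of axis ranks (a permutation of 1..K).
#' @param gamma_i Base scale.
#' @param axis_slope Axis slope s.
#' @return Numeric vector of per-region scales.
#' @export
region_sigma <- function(axis_rank, gamma_i, axis_slope) {
  K <- length(axis_rank)
  gamma_i * (1 + axis_slope * (axis_rank - 1) / (K - 1))
}
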