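#' Sample the shared structural backbone
#'
#' Draws a symmetric, nonnegative, zero-diagonal weighted adjacency from a
#' stochastic block model with `n_modules` contiguous modules, promotes a
#' fraction of nodes to hubs (every pair incident to a hub is drawn at the
#' within-module probability, giving a densely interconnected core), and
#' assigns i.i.d. log-normal weights to present edges. Resamples up to
#' `max_retries` times until the graph is connected.
#'
#' Consumes the current RNG stream; seed it (or call via [generate_cohort()])
#' for reproducibility.
#'
#' @param spec A [cohort_spec()].
#' @param max_retries Resampling budget for connectivity.
#' @return A K x K weighted adjacency matrix.
#' @export
sample_group_sc <- function(spec, max_retries = 100L) {
  validate_cohort_spec(spec)
  K <- spec$n_regions
  module <- ceiling(seq_len(K) * spec$n_modules / K)
  n_hubs <- ceiling(spec$hub_frac * K)
  for (attempt in seq_len(max_retries)) {
    hubs <- if (n_hubs > 0L) sample.int(K, n_hubs) else integer(0)
    p <- matrix(spec$p_between, K, K)
    p[outer(module, module, "==")] <- spec$p_within
    if (n_hubs > 0L) {
      p[hubs, ] <- pmax(p[hubs, ], spec$p_within)
      p[, hubs] <- pmax(p[, hubs], spec$p_within)
    }
    ut <- upper.tri(p)
    present <- ut & (matrix(runif(K * K), K, K) < p)
    sc <- matrix(0, K, K)
    n_edges <- sum(present)
    if (n_edges > 0L) {
      sc[present] <- rlnorm(n_edges, meanlog = spec$w_logmean, sdlog = spec$w_logsd)
    }
    sc <- sc + t(sc)
    g <- igraph::graph_from_adjacency_matrix(sc > 0, mode = "undirected")
    if (n_edges > 0L && igraph::is_connected(g)) {
      dimnames(sc) <- NULL
      return(sc)
    }
  }
  abort(sprintf("Could not sample a connected backbone in %d attempts.", max_retries),
        class = "sfc_generation_error")
}

#' Jitter the backbone into a subject-level structural matrix
#'
#' Each existing edge weight is multiplied by `exp(N(0, tau_sc))`; each
#' existing edge is then independently deleted, and each absent pair
#' independently created with a fresh backbone-scale log-normal weight, at
#' probability `flip_rate`. Consumes the current RNG stream; the log-normal
#' multipliers are drawn first, one per existing edge in row-major
#' upper-triangle order.
#'
#' @param group_sc Backbone adjacency from [sample_group_sc()].
#' @param spec A [cohort_spec()].
#' @return A K x K subject structural matrix.
#' @export
sample_subject_sc <- function(group_sc, spec) {
  check_connectome(group_sc, nonneg = TRUE, arg = "group_sc")
  K <- nrow(group_sc)
  ut_vals <- ut_rowmajor(group_sc)
  present <- ut_vals > 0
  n_edges <- sum(present)
  new_vals <- ut_vals
  if (n_edges > 0L && spec$tau_sc >= 0) {
    eps <- rnorm(n_edges, mean = 0, sd = spec$tau_sc)
    new_vals[present] <- ut_vals[present] * exp(eps)
  }
  if (spec$flip_rate > 0) {
    if (n_edges > 0L) {
      del <- runif(n_edges) < spec$flip_rate
      new_vals[present][del] <- 0
    }
    absent <- !present
    n_absent <- sum(absent)
    if (n_absent > 0L) {
      create <- runif(n_absent) < spec$flip_rate
      if (any(create)) {
        w <- rlnorm(sum(create), meanlog = spec$w_logmean, sdlog = spec$w_logsd)
        tmp <- new_vals[absent]
        tmp[create] <- w
        new_vals[absent] <- tmp
      }
    }
  }
  sc <- matrix(0, K, K)
  idx <- ut_index_pairs(K)
  sc[idx] <- new_vals
  sc + t(sc)
}

# raw latent topological signal: polynomial in the symmetrically normalized
# adjacency
latent_raw <- function(sc, beta) {
  K <- nrow(sc)
  d <- rowSums(sc)
  if (any(d <= 0)) {
    abort("Isolated node (zero strength) in `sc`.", class = "sfc_degenerate_input")
  }
  dm <- 1 / sqrt(d)
  abar <- sc * tcrossprod(dm)
  latent <- matrix(0, K, K)
  pow <- diag(K)
  for (b in beta) {
    pow <- pow %*% abar
    latent <- latent + b * pow
  }
  latent
}

# off-diagonal standardized to zero mean, unit variance
latent_signal <- function(sc, beta) {
  latent <- latent_raw(sc, beta)
  off <- ut_rowmajor(latent)
  latent <- (latent - mean(off)) / sd(off)
  diag(latent) <- 0
  latent
}

#' Map a structural matrix to functional connectivity
#'
#' The forward model of the synthetic cohort. The structural matrix is
#' symmetrically normalized, `Abar = D^(-1/2) SC D^(-1/2)` with `D` the
#' diagonal of row sums; the latent topological signal is the polynomial
#' `sum_p beta[p] * Abar^p`, standardized to zero mean and unit variance over
#' off-diagonal entries. Functional connectivity is then
#'
#' `latent + gamma_g * group_component + sqrt(sigma_u * sigma_v) * C +
#' N(0, noise_sd)`,
#'
#' symmetrized by averaging with its transpose, zero-diagonal. The per-region
#' scales `sigma` come from [region_sigma()] applied to the axis ranks in
#' `region_meta`. The individual component `C` blends a structurally
#' expressed part with i.i.d. noise:
#' `C = sqrt(share) * D_i + sqrt(1 - share) * subject_component`, where `D_i`
#' is the standardized deviation of the subject's latent signal from the
#' backbone's (`ref_sc`), and `share = indiv_struct_share`. The structural
#' part makes the individual component recoverable from the subject's own
#' structural matrix — without it no structure-based predictor could detect
#' individual coupling effects. When `ref_sc` is `NULL` (or the deviation is
#' identically zero, e.g. `tau_sc = 0, flip_rate = 0`), `C` falls back to the
#' noise part alone.
#'
#' @param sc Subject structural matrix (no isolated nodes).
#' @param spec A [cohort_spec()].
#' @param group_component Symmetric zero-diagonal matrix shared by the cohort.
#' @param subject_component Symmetric zero-diagonal matrix, i.i.d. per subject.
#' @param region_meta Region metadata from [build_region_meta()].
#' @param ref_sc Optional backbone structural matrix defining the group
#'   latent from which the subject's structural deviation is measured.
#' @return A K x K functional connectivity matrix.
#' @export
forward_fc <- function(sc, spec, group_component, subject_component, region_meta,
                       ref_sc = NULL) {
  check_connectome(sc, nonneg = TRUE, arg = "sc")
  K <- nrow(sc)
  latent <- latent_signal(sc, spec$beta)
  sig <- region_sigma(region_meta$axis_rank, spec$gamma_i, spec$axis_slope)
  share <- spec$indiv_struct_share %||% 0
  indiv <- sqrt(1 - share) * subject_component
  beta_indirect <- spec$beta
  beta_indirect[1L] <- 0  # individual deviations ride on indirect communication
  if (!is.null(ref_sc) && share > 0 && spec$gamma_i > 0 && any(beta_indirect != 0)) {
    dev <- latent_raw(sc, beta_indirect) - latent_raw(ref_sc, beta_indirect)
    s_dev <- sd(ut_rowmajor(dev))
    if (s_dev > 0) {
      dev <- (dev - mean(ut_rowmajor(dev))) / s_dev
      diag(dev) <- 0
      indiv <- indiv + sqrt(share) * dev
    }
  }
  fc <- latent + spec$gamma_g * group_component + sqrt(tcrossprod(sig)) * indiv
  if (spec$noise_sd > 0) {
    fc <- fc + matrix(rnorm(K * K, sd = spec$noise_sd), K, K)
  }
  symmetrize(fc)
}

# symmetric zero-diagonal matrix of i.i.d. standard normal edge values
sym_normal <- function(K) {
  m <- matrix(0, K, K)
  m[upper.tri(m)] <- rnorm(K * (K - 1) / 2)
  m + t(m)
}

#' Generate a synthetic connectome cohort
#'
#' Draws one group structural backbone and one shared group functional
#' component, then per subject a jittered structural matrix, a fresh
#' individual component, and the functional matrix via [forward_fc()]. The
#' spec's seed fully determines the output.
#'
#' @param spec A [cohort_spec()].
#' @return An `sfc_cohort`: list with `subjects` (each with `subject_id`,
#'   `sc`, `fc`), `region_meta`, `spec` and `seed`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  K <- spec$n_regions
  meta <- build_region_meta(spec)
  group_sc <- sample_group_sc(spec)
  group_component <- sym_normal(K)
  subjects <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    sc <- NULL
    for (try in 1:100) {
      cand <- sample_subject_sc(group_sc, spec)
      if (all(rowSums(cand) > 0)) {
        sc <- cand
        break
      }
    }
    if (is.null(sc)) {
      abort("Subject structural matrix kept isolating nodes.", class = "sfc_generation_error")
    }
    subj_component <- sym_normal(K)
    fc <- forward_fc(sc, spec, group_component, subj_component, meta,
                     ref_sc = group_sc)
    check_connectome(sc, nonneg = TRUE, arg = "sc")
    check_connectome(fc, arg = "fc")
    subjects[[s]] <- list(subject_id = sprintf("sub-%03d", s), sc = sc, fc = fc)
  }
  structure(
    list(subjects = subjects, region_meta = meta, spec = spec, seed = spec$seed,
         group_sc = group_sc),
    class = "sfc_cohort"
  )
}

#' @export
print.sfc_cohort <- function(x, ...) {
  cat(sprintf("<sfc_cohort> %d subjects, %d regions (seed %d)\n",
              length(x$subjects), nrow(x$region_meta), x$seed))
  invisible(x)
}

#' Synthetic framewise-displacement trace
#'
#' Each frame sits at `base_fd` mm and, with probability `spike_prob`,
#' excurses to `spike_fd` mm. Consumes one `runif(n_frames)` draw from the
#' current RNG stream.
#'
#' @param n_frames Number of frames (>= 1).
#' @param base_fd Baseline framewise displacement (mm, >= 0).
#' @param spike_prob Per-frame spike probability.
#' @param spike_fd Spike displacement (mm, >= 0).
#' @return Numeric vector of length `n_frames`.
#' @export
generate_fd_trace <- function(n_frames, base_fd = 0.05, spike_prob = 0.05, spike_fd = 0.4) {
  if (n_frames < 1 || base_fd < 0 || spike_fd < 0 || spike_prob < 0 || spike_prob > 1) {
    abort("Invalid FD trace parameters.", class = "sfc_invalid_spec")
  }
  spikes <- runif(n_frames) < spike_prob
  ifelse(spikes, spike_fd, base_fd)
}
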