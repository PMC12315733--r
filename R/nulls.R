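#' Degree- and strength-preserving rewiring of a structural matrix
#'
#' Randomizes the binary topology with repeated double-edge swaps (each swap
#' preserves every node's degree), then reassigns the original weight
#' multiset to the rewired edges by rank: edges are ordered by the sum of
#' their endpoints' original strengths and receive the sorted weights, so
#' nodal strengths are approximately preserved while the weight multiset and
#' degree sequence are exactly preserved. Graphs with no feasible swap (e.g.
#' complete graphs) are returned unchanged with a warning attribute.
#'
#' @param sc K x K symmetric zero-diagonal weighted matrix (>= 4 edges).
#' @param swaps_per_edge Number of attempted swaps per edge (default 10).
#' @return Rewired matrix; attribute `rewired` is `FALSE` when no swap was
#'   possible.
#' @export
rewire_sc <- function(sc, swaps_per_edge = 10) {
  check_connectome(sc, nonneg = TRUE, arg = "sc")
  K <- nrow(sc)
  n_edges <- sum(sc > 0) / 2
  if (n_edges < 4) abort("Need at least 4 edges to rewire.", class = "sfc_invalid_input")
  g <- igraph::graph_from_adjacency_matrix(sc > 0, mode = "undirected")
  complete <- n_edges == K * (K - 1) / 2
  if (!complete) {
    g <- igraph::rewire(g, igraph::keeping_degseq(niter = ceiling(swaps_per_edge * n_edges)))
  }
  adj_new <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
  if (complete || identical(adj_new, unname(sc > 0))) {
    out <- sc
    attr(out, "rewired") <- FALSE
    if (complete) warn("No valid double-edge swap exists; returning input.")
    return(out)
  }
  # rank-matched weight reassignment
  strengths <- rowSums(sc)
  idx <- ut_index_pairs(K)
  new_edges <- which(ut_rowmajor(adj_new))
  score <- strengths[idx[new_edges, 1L]] + strengths[idx[new_edges, 2L]]
  weights <- sort(ut_rowmajor(sc)[ut_rowmajor(sc > 0) > 0], decreasing = TRUE)
  assign <- numeric(length(new_edges))
  assign[order(score, decreasing = TRUE)] <- weights
  out <- matrix(0, K, K)
  out[idx[new_edges, , drop = FALSE]] <- assign
  out <- out + t(out)
  attr(out, "rewired") <- TRUE
  out
}

#' Topology-null comparison: GNN trained on rewired structural matrices
#'
#' Rewires every training subject's structural matrix (test matrices are left
#' intact), trains a GNN of the same configuration on the rewired training
#' set with empirical functional targets unchanged, and compares per-subject
#' test couplings of the empirical-SC model and the topology-null model. The
#' drop in variance accounted for is `mean(r_emp^2) - mean(r_null^2)`.
#'
#' @param cohort An `sfc_cohort`.
#' @param split List with `train`/`test` indices (from [split_cohort()]).
#' @param config A [gnn_config()].
#' @param model Optional pre-trained empirical model (retrained if `NULL`).
#' @param sc_mask Optional consistency mask applied to the coupling edges.
#' @param swaps_per_edge Swaps per edge for [rewire_sc()].
#' @param seed Seed for the rewiring randomization.
#' @return List: `r_empirical`, `r_null` (per test subject), `r2_drop`,
#'   `null_model`.
#' @export
rewired_training_run <- function(cohort, split, config, model = NULL,
                                 sc_mask = NULL, swaps_per_edge = 10,
                                 seed = config$seed) {
  train <- subset_cohort(cohort, split$train)
  test <- subset_cohort(cohort, split$test)
  if (is.null(model)) model <- train_model(train, config)
  set.seed(seed)
  null_train <- train
  null_train$subjects <- purrr::map(null_train$subjects, function(s) {
    s$sc <- rewire_sc(s$sc, swaps_per_edge)
    s
  })
  null_model <- train_model(null_train, config)
  couple <- function(mod) {
    vapply(test$subjects, function(s) {
      coupling_pair(predict_fc(s$sc, mod), s$fc, approach = "gnn", sc_mask = sc_mask)
    }, numeric(1))
  }
  r_emp <- couple(model)
  r_null <- couple(null_model)
  list(r_empirical = r_emp, r_null = r_null,
       r2_drop = mean(r_emp^2) - mean(r_null^2),
       null_model = null_model)
}

# uniform random 3D rotation matrix (QR of a Gaussian matrix, sign-corrected)
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_dec)
  Q <- Q %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# greedy nearest-neighbour bijection: rotated points -> original points
greedy_assign <- function(rotated, original) {
  n <- nrow(rotated)
  d <- as.matrix(stats::dist(rbind(rotated, original)))[seq_len(n), n + seq_len(n), drop = FALSE]
  perm <- integer(n)
  for (k in seq_len(n)) {
    best <- arrayInd(which.min(d), dim(d))
    perm[best[1L]] <- best[2L]
    d[best[1L], ] <- Inf
    d[, best[2L]] <- Inf
  }
  perm
}

#' Spin rotations of the regional layout
#'
#' Per rotation: a uniform random 3D rotation is applied to the left
#' hemisphere's sphere coordinates and its x-mirrored counterpart to the
#' right hemisphere's; each rotated region is then greedily reassigned to the
#' nearest unclaimed original region of the same hemisphere, yielding a true
#' permutation of region ids that preserves spatial autocorrelation.
#'
#' @param region_meta Region metadata from [build_region_meta()].
#' @param n_rotations Number of rotations.
#' @param seed Seed for the rotation stream.
#' @return List of integer permutations of `1..K`; `perm[k]` is the original
#'   region whose value region `k` receives.
#' @export
spin_rotations <- function(region_meta, n_rotations = 10000L, seed = 1L) {
  coords <- as.matrix(region_meta[, c("x", "y", "z")])
  nrm <- sqrt(rowSums(coords^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    abort("Sphere coordinates must be unit-norm.", class = "sfc_invalid_input")
  }
  hemi <- region_meta$hemisphere
  mirror <- diag(c(-1, 1, 1))
  set.seed(seed)
  hemis <- unique(hemi)
  idx_h <- lapply(hemis, function(h) which(hemi == h))
  names(idx_h) <- hemis
  purrr::map(seq_len(n_rotations), function(r) {
    R <- random_rotation()
    perm <- integer(nrow(coords))
    for (h in hemis) {
      Rh <- if (h == hemis[[1L]]) R else mirror %*% R %*% mirror
      idx <- idx_h[[h]]
      rotated <- coords[idx, , drop = FALSE] %*% t(Rh)
      perm[idx] <- idx[greedy_assign(rotated, coords[idx, , drop = FALSE])]
    }
    perm
  })
}

# tail rule: proportion of null correlations at least as extreme as the
# empirical one in the direction of its sign (or |null| >= |emp| two-sided)
spin_tail_p <- function(nulls, emp, two_sided = FALSE) {
  if (two_sided) {
    mean(abs(nulls) >= abs(emp))
  } else if (emp >= 0) {
    mean(nulls >= emp)
  } else {
    mean(nulls <= emp)
  }
}

#' Spin-test p-value for the spatial correspondence of two maps
#'
#' The empirical statistic is the Spearman correlation of the two maps; the
#' null distribution correlates rotation-permuted versions of the first map
#' with the second. The p-value is the proportion of null correlations at
#' least as extreme as the empirical one in the direction of its sign
#' (`null >= rho` when `rho >= 0`, `null <= rho` otherwise); set
#' `two_sided = TRUE` to compare `|null| >= |rho|` instead.
#'
#' @param map_a,map_b Length-K region vectors (pairwise-complete; regions
#'   missing in either map are dropped).
#' @param permutations List of permutations from [spin_rotations()].
#' @param keep Optional logical vector; regions excluded from the correlation
#'   (after permuting the full-length map), e.g. outliers.
#' @param two_sided Use the absolute-value tail rule.
#' @return An `sfc_spin` list: `empirical`, `null_correlations`, `p_spin`,
#'   `n_rotations`.
#' @export
spin_pvalue <- function(map_a, map_b, permutations, keep = NULL, two_sided = FALSE) {
  ok <- is.finite(map_a) & is.finite(map_b)
  if (!is.null(keep)) ok <- ok & keep
  if (sd(map_a[ok]) == 0 || sd(map_b[ok]) == 0) {
    abort("Constant map: correlation undefined.", class = "sfc_degenerate_input")
  }
  emp <- spearman_rho(map_a[ok], map_b[ok])
  nulls <- vapply(permutations, function(p) {
    pa <- map_a[p]
    o <- is.finite(pa) & is.finite(map_b)
    if (!is.null(keep)) o <- o & keep
    spearman_rho(pa[o], map_b[o])
  }, numeric(1))
  p <- spin_tail_p(nulls, emp, two_sided)
  structure(list(empirical = emp, null_correlations = nulls, p_spin = p,
                 n_rotations = length(permutations)),
            class = "sfc_spin")
}

#' @export
print.sfc_spin <- function(x, ...) {
  p_note <- if (x$p_spin == 0) sprintf(" (< %.2g)", 1 / x$n_rotations) else ""
  cat(sprintf("<sfc_spin> rho = %.3f, p_spin = %.4g%s over %d rotations\n",
              x$empirical, x$p_spin, p_note, x$n_rotations))
  invisible(x)
}
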