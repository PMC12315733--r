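#' Functional connectivity from regional time series
#'
#' Pearson correlation between every pair of regional signals, Fisher
#' z-transformed (`atanh`), with `|r|` clipped to `1 - 1e-7` so perfectly
#' correlated pairs stay finite. Diagonal is zero.
#'
#' @param ts A frames x K matrix of regional signal (>= 3 frames).
#' @return A K x K symmetric Fisher-z connectivity matrix.
#' @export
compute_fc <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) abort("Need at least 3 frames.", class = "sfc_invalid_input")
  v <- apply(ts, 2L, stats::var)
  if (any(v == 0)) {
    abort(sprintf("Zero-variance region(s): %s.",
                  paste(which(v == 0), collapse = ", ")),
          class = "sfc_degenerate_input")
  }
  r <- stats::cor(ts)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  symmetrize(z)
}

#' Volume-normalize and log-transform streamline counts
#'
#' Each edge weight is divided by the average volume of its two endpoint
#' regions, then log-transformed. The default `log1p` mode uses
#' `log(1 + w)`, which keeps absent edges at exactly zero and all weights
#' nonnegative (volume normalization can push weights below 1);
#' `log_nonzero` applies `log(w)` to nonzero entries only, a literal reading
#' that can produce negative weights.
#'
#' @param counts K x K symmetric nonnegative matrix of raw streamline counts.
#' @param volumes Length-K vector of positive region volumes.
#' @param log_mode `"log1p"` (default) or `"log_nonzero"`.
#' @return K x K normalized, log-transformed structural matrix.
#' @export
normalize_and_log_sc <- function(counts, volumes, log_mode = c("log1p", "log_nonzero")) {
  log_mode <- match.arg(log_mode)
  check_connectome(counts, nonneg = TRUE, arg = "counts")
  if (length(volumes) != nrow(counts) || any(volumes <= 0)) {
    abort("`volumes` must be positive and match the matrix dimension.",
          class = "sfc_invalid_input")
  }
  avg_vol <- outer(volumes, volumes, "+") / 2
  w <- counts / avg_vol
  if (log_mode == "log1p") {
    w <- log1p(w)
  } else {
    nz <- w > 0
    w[nz] <- log(w[nz])
  }
  diag(w) <- 0
  symmetrize(w)
}

#' Group-consistency mask of structural edges
#'
#' For every unique edge present (nonzero) in at least one subject, the
#' coefficient of variation (sd / mean) of its weight across subjects is
#' computed, counting subjects lacking the edge as zero-weight observations.
#' Edges whose CV exceeds the stated percentile of the CV distribution are
#' masked out, as are edges absent in all subjects; the mask is symmetric.
#'
#' @param scs List of node-aligned K x K structural matrices (>= 2 subjects).
#' @param percentile CV percentile above which edges are removed (default 75).
#' @param quantile_type Quantile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return List of class `sfc_consistency_mask`: `keep` (K x K logical),
#'   `cv` (K x K, `NA` on never-present edges), `threshold`, `n_evaluated`,
#'   `n_removed`.
#' @export
consistency_mask <- function(scs, percentile = 75, quantile_type = 7) {
  if (length(scs) < 2L) abort("Need >= 2 subjects.", class = "sfc_invalid_input")
  K <- nrow(scs[[1L]])
  stack <- vapply(scs, ut_rowmajor, numeric(K * (K - 1) / 2))
  present <- rowSums(stack > 0) > 0
  mu <- rowMeans(stack)
  s <- apply(stack, 1L, sd)
  cv <- ifelse(present, s / mu, NA_real_)
  thr <- quantile(cv[present], percentile / 100, type = quantile_type, names = FALSE)
  keep_vec <- present & (cv <= thr)
  idx <- ut_index_pairs(K)
  keep <- matrix(FALSE, K, K)
  keep[idx] <- keep_vec
  keep <- keep | t(keep)
  cvm <- matrix(NA_real_, K, K)
  cvm[idx] <- cv
  cvm[idx[, c(2, 1)]] <- cv
  structure(
    list(keep = keep, cv = cvm, threshold = thr,
         n_evaluated = sum(present), n_removed = sum(present & !keep_vec)),
    class = "sfc_consistency_mask"
  )
}

#' Apply a consistency mask to a structural matrix
#'
#' @param sc K x K structural matrix.
#' @param mask An `sfc_consistency_mask` (or K x K logical matrix).
#' @return The matrix with masked-out edges set to zero.
#' @export
apply_mask <- function(sc, mask) {
  keep <- if (inherits(mask, "sfc_consistency_mask")) mask$keep else mask
  out <- sc
  out[!keep] <- 0
  diag(out) <- 0
  out
}

#' Motion-based run filtering
#'
#' Three rules, applied in this fixed order:
#' 1. drop any run in which more than `frame_frac` of frames have
#'    FD > `fd_thresh` mm;
#' 2. pool the mean FD of all surviving runs across subjects, compute Q3 and
#'    IQR of that distribution, and drop runs with mean FD > Q3 + 1.5 * IQR;
#' 3. exclude subjects left with fewer than `min_runs` runs.
#'
#' @param fd_runs_per_subject Named list; one list of per-run FD vectors (mm)
#'   per subject.
#' @param fd_thresh Frame-level FD threshold in mm (default 0.2).
#' @param frame_frac Maximum tolerated fraction of high-FD frames (default 0.25).
#' @param min_runs Minimum surviving runs per retained subject (default 4).
#' @param quantile_type Quantile convention for Q3 (default 7).
#' @return List: `kept_runs` (per subject, indices of surviving runs),
#'   `excluded_subjects`, `runs_dropped_rule1`, `runs_dropped_rule2`,
#'   `mean_fd_threshold`.
#' @export
qc_filter_runs <- function(fd_runs_per_subject, fd_thresh = 0.2,
                           frame_frac = 0.25, min_runs = 4,
                           quantile_type = 7) {
  for (runs in fd_runs_per_subject) {
    for (fd in runs) {
      if (length(fd) == 0L || any(fd < 0)) {
        abort("FD vectors must be nonempty and nonnegative.", class = "sfc_invalid_input")
      }
    }
  }
  n_subj <- length(fd_runs_per_subject)
  ids <- names(fd_runs_per_subject)
  if (is.null(ids)) ids <- as.character(seq_len(n_subj))
  surviving <- purrr::map(fd_runs_per_subject, function(runs) {
    keep <- vapply(runs, function(fd) mean(fd > fd_thresh) <= frame_frac, logical(1))
    which(keep)
  })
  dropped1 <- sum(lengths(fd_runs_per_subject)) - sum(lengths(surviving))
  mean_fds <- unlist(purrr::map2(fd_runs_per_subject, surviving, function(runs, idx) {
    vapply(runs[idx], mean, numeric(1))
  }), use.names = FALSE)
  if (length(mean_fds) > 0) {
    q3 <- quantile(mean_fds, 0.75, type = quantile_type, names = FALSE)
    iqr <- q3 - quantile(mean_fds, 0.25, type = quantile_type, names = FALSE)
    thr <- q3 + 1.5 * iqr
  } else {
    thr <- NA_real_
  }
  dropped2 <- 0L
  kept <- purrr::map2(fd_runs_per_subject, surviving, function(runs, idx) {
    if (length(idx) == 0L) return(idx)
    mfd <- vapply(runs[idx], mean, numeric(1))
    ok <- mfd <= thr
    dropped2 <<- dropped2 + sum(!ok)
    idx[ok]
  })
  names(kept) <- ids
  excluded <- ids[lengths(kept) < min_runs]
  list(kept_runs = kept, excluded_subjects = excluded,
       runs_dropped_rule1 = dropped1, runs_dropped_rule2 = dropped2,
       mean_fd_threshold = thr)
}
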