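# closed-form paired t-test (two-sided), oracle-testable against stats::t.test
paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  if (n < 3L) return(list(statistic = NA_real_, p_value = NA_real_, df = n - 1L))
  tstat <- mean(d) / (sd(d) / sqrt(n))
  list(statistic = tstat,
       p_value = 2 * stats::pt(-abs(tstat), df = n - 1L),
       df = n - 1L)
}

#' Decompose a coupling matrix into group and individual effects
#'
#' Total effect = mean of the diagonal (matched couplings); group-common
#' effect = mean of the off-diagonal (mismatched couplings); individual-
#' specific effect = total - group. Per subject, the matched coupling is the
#' diagonal entry and the mismatched coupling is
#' `(1 / (2(N-1))) * sum_{j != i} (cp[i,j] + cp[j,i])` (its row and column,
#' excluding the diagonal). Matched and mismatched vectors are compared with
#' a two-sided paired t-test.
#'
#' @param cp An `sfc_coupling_matrix` (or plain N x N matrix), N >= 2.
#' @return An `sfc_decomposition`: list with `total`, `group`, `individual`,
#'   `individual_fraction`, `matched`, `mismatched`, `t_statistic`,
#'   `p_value`, `n`, `approach`, `level`.
#' @export
decompose_coupling <- function(cp) {
  m <- unclass(cp)
  N <- nrow(m)
  if (is.null(N) || N < 2L || ncol(m) != N) {
    abort("Need a square coupling matrix with N >= 2.", class = "sfc_invalid_input")
  }
  dg <- diag(m)
  total <- mean(dg)
  off <- m[row(m) != col(m)]
  group <- mean(off)
  individual <- total - group
  mismatched <- (rowSums(m) + colSums(m) - 2 * dg) / (2 * (N - 1))
  tt <- paired_t(dg, mismatched)
  structure(
    list(total = total, group = group, individual = individual,
         individual_fraction = if (total != 0) individual / total else NA_real_,
         matched = dg, mismatched = mismatched,
         t_statistic = tt$statistic, p_value = tt$p_value, n = N,
         approach = attr(cp, "approach"), level = attr(cp, "level")),
    class = "sfc_decomposition"
  )
}

#' @export
print.sfc_decomposition <- function(x, ...) {
  cat(sprintf("<sfc_decomposition> %s%s\n",
              x$approach %||% "coupling",
              if (!is.null(x$level)) sprintf(" (level %s)", x$level) else ""))
  cat(sprintf("  total %.4f = group %.4f + individual %.4f (%.2f%% individual)\n",
              x$total, x$group, x$individual, 100 * x$individual_fraction))
  cat(sprintf("  paired t(%d) = %.3f, p = %.3g\n", x$n - 1L, x$t_statistic, x$p_value))
  invisible(x)
}

#' @method glance sfc_decomposition
#' @export
glance.sfc_decomposition <- function(x, ...) {
  tibble::tibble(
    total = x$total, group = x$group, individual = x$individual,
    individual_fraction = x$individual_fraction,
    t_statistic = x$t_statistic, p_value = x$p_value, n = x$n,
    approach = x$approach %||% NA_character_
  )
}

#' @method tidy sfc_decomposition
#' @export
tidy.sfc_decomposition <- function(x, ...) {
  tibble::tibble(
    subject = seq_len(x$n),
    matched = x$matched,
    mismatched = x$mismatched,
    approach = x$approach %||% NA_character_
  )
}

#' Individual effect as a fraction of the total coupling
#'
#' @param dec An `sfc_decomposition`.
#' @return `individual / total`; `NA` with a warning when the total is zero.
#' @export
normalized_individual <- function(dec) {
  if (dec$total == 0) {
    warn("Total coupling is zero; normalized individual effect undefined.")
    return(NA_real_)
  }
  dec$individual / dec$total
}

#' Regional effect maps
#'
#' Builds the region-level cross-participant coupling matrix for every
#' region, decomposes each, and returns the per-region total, group,
#' individual and normalized-individual effects. Regions whose profiles are
#' degenerate (fewer than 3 usable edges, or constant) are reported as
#' missing rather than failing.
#'
#' @inheritParams cross_coupling_matrix
#' @return A tibble with one row per region: `region_id`, `approach`,
#'   `total`, `group`, `individual`, `normalized_individual`, `t_statistic`,
#'   `p_value`.
#' @export
regional_effect_maps <- function(sources, fcs,
                                 approach = c("correlation", "gnn"),
                                 sc_mask = NULL) {
  approach <- match.arg(approach)
  K <- nrow(sources[[1L]])
  rows <- purrr::map(seq_len(K), function(r) {
    dec <- tryCatch({
      cp <- cross_coupling_matrix(sources, fcs, approach, level = r, sc_mask = sc_mask)
      if (any(!is.finite(unclass(cp)))) abort("degenerate", class = "sfc_degenerate_input")
      decompose_coupling(cp)
    }, sfc_degenerate_input = function(e) NULL)
    if (is.null(dec)) {
      tibble::tibble(region_id = r, approach = approach, total = NA_real_,
                     group = NA_real_, individual = NA_real_,
                     normalized_individual = NA_real_,
                     t_statistic = NA_real_, p_value = NA_real_)
    } else {
      tibble::tibble(region_id = r, approach = approach, total = dec$total,
                     group = dec$group, individual = dec$individual,
                     normalized_individual = if (dec$total != 0) dec$individual / dec$total else NA_real_,
                     t_statistic = dec$t_statistic, p_value = dec$p_value)
    }
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
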