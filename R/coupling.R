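#' Upper-triangle edge vector of a symmetric matrix
#'
#' Row-major upper-triangle values (`i < j`), optionally restricted to a
#' logical mask; length `K(K-1)/2` when unmasked.
#'
#' @param m K x K symmetric matrix (asymmetry beyond 1e-9 is an error).
#' @param mask Optional K x K logical matrix; only mask-true edges are kept.
#' @return Numeric vector of unique edge values.
#' @export
edge_vector <- function(m, mask = NULL) {
  check_symmetric(m, tol = 1e-9, arg = "m")
  v <- ut_rowmajor(m)
  if (!is.null(mask)) {
    keep <- if (inherits(mask, "sfc_consistency_mask")) mask$keep else mask
    v <- v[ut_rowmajor(keep) > 0]
  }
  v
}

#' Structure-function coupling between one source and one functional matrix
#'
#' For the correlation approach, the Pearson correlation between structural
#' and functional edge vectors restricted to edges with nonzero structural
#' weight in the source matrix (intersected with `sc_mask` if given). For the
#' GNN approach, the Pearson correlation between predicted and empirical
#' functional matrices over all (unmasked) unique edges.
#'
#' @param source K x K structural matrix (correlation approach) or predicted
#'   functional matrix (GNN approach).
#' @param fc K x K empirical functional matrix.
#' @param approach `"correlation"` or `"gnn"`.
#' @param sc_mask Optional consistency mask (or logical matrix).
#' @return Pearson r.
#' @export
coupling_pair <- function(source, fc, approach = c("correlation", "gnn"),
                          sc_mask = NULL) {
  approach <- match.arg(approach)
  x <- edge_vector(source, sc_mask)
  y <- edge_vector(fc, sc_mask)
  if (approach == "correlation") {
    nz <- x != 0
    x <- x[nz]
    y <- y[nz]
  }
  if (length(x) < 3L) {
    abort("Fewer than 3 edges after masking.", class = "sfc_degenerate_input")
  }
  cor(x, y)
}

#' Regional structure-function coupling
#'
#' Pearson correlation between row `region` of the source and functional
#' matrices, excluding the diagonal entry; the correlation approach is
#' additionally restricted to nonzero source entries of the row.
#'
#' @inheritParams coupling_pair
#' @param region Region index (row).
#' @return Pearson r for that region.
#' @export
regional_coupling <- function(source, fc, region,
                              approach = c("correlation", "gnn"),
                              sc_mask = NULL) {
  approach <- match.arg(approach)
  x <- source[region, -region]
  y <- fc[region, -region]
  if (!is.null(sc_mask)) {
    keep <- if (inherits(sc_mask, "sfc_consistency_mask")) sc_mask$keep else sc_mask
    k <- keep[region, -region] > 0
    x <- x[k]
    y <- y[k]
  }
  if (approach == "correlation") {
    nz <- x != 0
    x <- x[nz]
    y <- y[nz]
  }
  if (length(x) < 3L) {
    abort(sprintf("Region %d has fewer than 3 usable entries.", region),
          class = "sfc_degenerate_input")
  }
  cor(x, y)
}

#' Cross-participant coupling matrix
#'
#' `values[i, j]` is the coupling between the source of subject i (structural
#' matrix for the correlation approach, predicted functional matrix for the
#' GNN approach) and the empirical functional matrix of subject j. Diagonal
#' entries are "matched", off-diagonal "mismatched" couplings; the matrix is
#' asymmetric in general.
#'
#' @param sources List of N source matrices.
#' @param fcs List of N empirical functional matrices.
#' @param approach `"correlation"` or `"gnn"`.
#' @param level `"global"` or a region index.
#' @param sc_mask Optional shared consistency mask.
#' @return An `sfc_coupling_matrix`: N x N matrix with attributes `approach`
#'   and `level`.
#' @export
cross_coupling_matrix <- function(sources, fcs,
                                  approach = c("correlation", "gnn"),
                                  level = "global", sc_mask = NULL) {
  approach <- match.arg(approach)
  N <- length(sources)
  stopifnot(length(fcs) == N)
  keep <- if (inherits(sc_mask, "sfc_consistency_mask")) sc_mask$keep else sc_mask
  if (identical(level, "global")) {
    xs <- purrr::map(sources, edge_vector, mask = keep)
    ys <- purrr::map(fcs, edge_vector, mask = keep)
  } else {
    r <- level
    pick <- function(m) {
      v <- m[r, -r]
      if (!is.null(keep)) v <- v[keep[r, -r] > 0]
      v
    }
    xs <- purrr::map(sources, pick)
    ys <- purrr::map(fcs, pick)
  }
  Ymat <- do.call(cbind, ys)
  vals <- matrix(NA_real_, N, N)
  for (i in seq_len(N)) {
    x <- xs[[i]]
    Yi <- Ymat
    if (approach == "correlation") {
      nz <- x != 0
      x <- x[nz]
      Yi <- Ymat[nz, , drop = FALSE]
    }
    if (length(x) < 3L) {
      abort("Fewer than 3 usable edges for a source subject.",
            class = "sfc_degenerate_input")
    }
    vals[i, ] <- cor_vec_mat(x, Yi)
  }
  structure(vals, class = c("sfc_coupling_matrix", "matrix"),
            approach = approach, level = level)
}

#' @method tidy sfc_coupling_matrix
#' @export
tidy.sfc_coupling_matrix <- function(x, ...) {
  N <- nrow(x)
  tibble::tibble(
    source = rep(seq_len(N), times = N),
    target = rep(seq_len(N), each = N),
    coupling = as.vector(unclass(x)),
    matched = rep(seq_len(N), times = N) == rep(seq_len(N), each = N),
    approach = attr(x, "approach"),
    level = as.character(attr(x, "level"))
  )
}
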