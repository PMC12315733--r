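#' Configuration of the graph neural network
#'
#' A two-layer (by default) graph convolutional encoder over the structural
#' adjacency with one-hot node inputs, followed by a two-layer perceptron
#' edge decoder. `gcn_dims` gives the embedding width of each layer starting
#' from the input (which must equal K, the number of regions, because inputs
#' are one-hot); `mlp_dims` gives the decoder widths, whose input must be
#' twice the final embedding width (two concatenated node embeddings) and
#' whose output must be 1.
#'
#' At atlas scale (400 regions, hundreds of training subjects, 79,800 unique
#' edges) the usual configuration is a 400 x 256 x 256 GCN with a
#' 512 x 64 x 1 MLP, learning rate 0.001 and 400 epochs. The
#' desk-scale defaults used here are `K x 64 x 64` / `2C x 64 x 1`, learning
#' rate 0.01 and 200 epochs: with tens of training subjects a 200-epoch run
#' takes only ~4,000 Adam steps, and these values are the smallest
#' configuration that fits the synthetic forward family itself (training
#' loss below 10% of the target variance on a noise-free one-hop cohort).
#' Batch size 2 and the L2 penalty 1e-4 on decoder weights are common to
#' both scales.
#'
#' @param n_regions Number of regions K.
#' @param gcn_dims Integer vector of encoder dims `C_0..C_L` (default
#'   `c(K, 64, 64)`).
#' @param mlp_dims Integer vector of decoder dims (default `c(2*C_L, 64, 1)`).
#' @param batch_size Subjects per gradient step (default 2).
#' @param learning_rate Adam learning rate (default 0.01).
#' @param l2_lambda L2 penalty on decoder weight matrices (default 1e-4).
#' @param epochs Training epochs (default 200).
#' @param seed Seed for initialization and batch shuffling.
#' @return An object of class `gnn_config`.
#' @export
gnn_config <- function(n_regions,
                       gcn_dims = c(n_regions, 64L, 64L),
                       mlp_dims = c(2L * gcn_dims[length(gcn_dims)], 64L, 1L),
                       batch_size = 2L,
                       learning_rate = 0.01,
                       l2_lambda = 1e-4,
                       epochs = 200L,
                       seed = 1L) {
  cfg <- list(
    n_regions = as.integer(n_regions),
    gcn_dims = as.integer(gcn_dims),
    mlp_dims = as.integer(mlp_dims),
    n_layers = length(gcn_dims) - 1L,
    batch_size = as.integer(batch_size),
    learning_rate = learning_rate,
    l2_lambda = l2_lambda,
    epochs = as.integer(epochs),
    seed = as.integer(seed)
  )
  class(cfg) <- "gnn_config"
  if (cfg$gcn_dims[1L] != cfg$n_regions) {
    abort("`gcn_dims[1]` must equal the number of regions (one-hot inputs).",
          class = "sfc_config_error")
  }
  if (cfg$mlp_dims[1L] != 2L * cfg$gcn_dims[length(cfg$gcn_dims)]) {
    abort("MLP input dim must be twice the final embedding dim.",
          class = "sfc_config_error")
  }
  if (cfg$mlp_dims[length(cfg$mlp_dims)] != 1L || length(cfg$mlp_dims) != 3L) {
    abort("MLP must be two layers ending in a single output.",
          class = "sfc_config_error")
  }
  if (any(cfg$gcn_dims < 1L) || any(cfg$mlp_dims < 1L)) {
    abort("All dims must be >= 1.", class = "sfc_config_error")
  }
  if (cfg$l2_lambda < 0) abort("`l2_lambda` must be >= 0.", class = "sfc_config_error")
  cfg
}

# Glorot-style scaled uniform init
init_weight <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialize model parameters
#'
#' Draws all trainable parameters (GCN weight stack, one PReLU slope per
#' layer initialized at 0.25, decoder weights and biases) from the current
#' RNG stream with fan-scaled uniform initialization.
#'
#' @param config A [gnn_config()].
#' @return An object of class `sfc_gnn`.
#' @export
init_gnn <- function(config) {
  L <- config$n_layers
  gcn_weights <- lapply(seq_len(L), function(l) {
    init_weight(config$gcn_dims[l], config$gcn_dims[l + 1L])
  })
  m1 <- config$mlp_dims
  model <- list(
    gcn_weights = gcn_weights,
    prelu_slopes = rep(0.25, L),
    W1 = init_weight(m1[1L], m1[2L]),
    b1 = rep(0, m1[2L]),
    W2 = init_weight(m1[2L], m1[3L]),
    b2 = 0,
    config = config
  )
  class(model) <- "sfc_gnn"
  model
}

#' @export
print.sfc_gnn <- function(x, ...) {
  cat(sprintf("<sfc_gnn> GCN %s | MLP %s%s\n",
              paste(x$config$gcn_dims, collapse = "x"),
              paste(x$config$mlp_dims, collapse = "x"),
              if (is.null(x$loss_trace)) " (untrained)" else
                sprintf(" | final loss %.4g", x$loss_trace[length(x$loss_trace)])))
  invisible(x)
}

# D^{-1/2} (A + I) D^{-1/2} with D the diagonal of row sums of A + I
norm_adjacency <- function(A) {
  Ahat <- A + diag(nrow(A))
  d <- rowSums(Ahat)
  if (any(d <= 0)) abort("Node with nonpositive strength after self-loops.",
                         class = "sfc_degenerate_input")
  Ahat * tcrossprod(1 / sqrt(d))
}

prelu <- function(x, alpha) {
  pos <- x >= 0
  x * (pos + alpha * (1 - pos))
}

#' One graph convolution layer
#'
#' `PReLU(D^(-1/2) (A + I) D^(-1/2) H W)` with a single trainable slope
#' `alpha` for the negative part.
#'
#' @param H K x C_l input embeddings.
#' @param A K x K symmetric nonnegative adjacency (self-loops added here).
#' @param W C_l x C_{l+1} weight matrix.
#' @param alpha PReLU slope.
#' @return K x C_{l+1} embeddings.
#' @export
gcn_layer <- function(H, A, W, alpha) {
  if (!all(is.finite(H)) || !all(is.finite(A)) || !all(is.finite(W))) {
    abort("Nonfinite input to GCN layer.", class = "sfc_numeric_error")
  }
  prelu(norm_adjacency(A) %*% H %*% W, alpha)
}

#' Encode a structural matrix into node embeddings
#'
#' Applies the GCN stack starting from one-hot inputs (`H^0 = I_K`), so the
#' final embedding of each node summarizes its L-hop topological
#' neighborhood.
#'
#' @param sc K x K structural adjacency.
#' @param model An `sfc_gnn`.
#' @return List of embedding matrices `H^0 .. H^L`.
#' @export
encode <- function(sc, model) {
  K <- nrow(sc)
  if (K != model$config$n_regions) {
    abort("Matrix size does not match the model config.", class = "sfc_config_error")
  }
  S <- norm_adjacency(sc)
  H <- vector("list", model$config$n_layers + 1L)
  H[[1L]] <- diag(K)
  for (l in seq_len(model$config$n_layers)) {
    H[[l + 1L]] <- prelu(S %*% H[[l]] %*% model$gcn_weights[[l]],
                         model$prelu_slopes[l])
  }
  H
}

#' Decode one edge from a pair of node embeddings
#'
#' `W2 . ReLU(W1 . concat(h_i, h_j) + b1) + b2`: the first decoder layer is
#' ReLU-activated, the second is linear.
#'
#' @param h_i,h_j Embedding vectors of the two nodes (length C_L).
#' @param model An `sfc_gnn`.
#' @return A single predicted connectivity value.
#' @export
decode_edge <- function(h_i, h_j, model) {
  if (length(h_i) + length(h_j) != nrow(model$W1)) {
    abort("Embedding length does not match the decoder input.",
          class = "sfc_config_error")
  }
  x <- c(h_i, h_j)
  a1 <- drop(crossprod(model$W1, x)) + model$b1
  drop(crossprod(model$W2, pmax(a1, 0))) + model$b2
}

# vectorized decode over all ordered pairs; returns vector aligned with
# ordered_pairs(K)
decode_all_pairs <- function(HL, model, pairs = NULL) {
  K <- nrow(HL)
  if (is.null(pairs)) pairs <- ordered_pairs(K)
  C <- ncol(HL)
  W1a <- model$W1[seq_len(C), , drop = FALSE]
  W1b <- model$W1[C + seq_len(C), , drop = FALSE]
  Ha <- HL %*% W1a
  Hb <- HL %*% W1b
  A1 <- Ha[pairs[, 1L], , drop = FALSE] + Hb[pairs[, 2L], , drop = FALSE]
  A1 <- sweep(A1, 2L, model$b1, "+")
  drop(pmax(A1, 0) %*% model$W2) + model$b2
}

#' Predict a functional connectivity matrix from structural input
#'
#' Decodes every ordered pair of node embeddings and symmetrizes as
#' `(pFC_ij + pFC_ji) / 2`; the diagonal is zero.
#'
#' @param sc K x K structural adjacency.
#' @param model An `sfc_gnn`.
#' @return K x K symmetric predicted connectivity matrix.
#' @export
predict_fc <- function(sc, model) {
  K <- nrow(sc)
  H <- encode(sc, model)
  HL <- H[[length(H)]]
  pairs <- ordered_pairs(K)
  pred <- decode_all_pairs(HL, model, pairs)
  P <- matrix(0, K, K)
  P[pairs] <- pred
  symmetrize(P)
}

#' Training loss: mean squared error with decoder L2 penalty
#'
#' `(1/N_b) * sum_subjects (1/(K(K-1))) * sum_{i != j} (pFC_ij - eFC_ij)^2 +
#' lambda * (|W1|^2 + |W2|^2)`; the penalty covers decoder weight matrices
#' only, not biases and not GCN weights.
#'
#' @param pfc_batch,efc_batch Lists of node-aligned K x K matrices.
#' @param model An `sfc_gnn` (for the penalized weights).
#' @param lambda L2 coefficient (>= 0).
#' @return Scalar loss.
#' @export
mse_l2_loss <- function(pfc_batch, efc_batch, model, lambda = model$config$l2_lambda) {
  if (lambda < 0) abort("`lambda` must be >= 0.", class = "sfc_config_error")
  stopifnot(length(pfc_batch) == length(efc_batch))
  mses <- purrr::map2_dbl(pfc_batch, efc_batch, function(p, e) {
    K <- nrow(p)
    off <- row(p) != col(p)
    mean((p[off] - e[off])^2)
  })
  mean(mses) + lambda * (sum(model$W1^2) + sum(model$W2^2))
}
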