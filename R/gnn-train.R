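# ---- internal: flat parameter list <-> model ----------------------------

model_params <- function(model) {
  p <- list()
  for (l in seq_along(model$gcn_weights)) p[[paste0("Wg", l)]] <- model$gcn_weights[[l]]
  p$alpha <- model$prelu_slopes
  p$W1 <- model$W1
  p$b1 <- model$b1
  p$W2 <- model$W2
  p$b2 <- model$b2
  p
}

set_model_params <- function(model, p) {
  for (l in seq_along(model$gcn_weights)) model$gcn_weights[[l]] <- p[[paste0("Wg", l)]]
  model$prelu_slopes <- p$alpha
  model$W1 <- p$W1
  model$b1 <- p$b1
  model$W2 <- p$W2
  model$b2 <- p$b2
  model
}

# precompute per-subject quantities used at every step
prep_subject <- function(sc, fc, pairs) {
  list(S = norm_adjacency(sc), efc = fc[pairs])
}

# loss and analytic gradients for a batch of prepped subjects.
# Returns list(loss, grads) with grads aligned to model_params().
# The ordered-pair list is row-major (pairs grouped by source node i, and the
# (i,j) -> (j,i) permutation is precomputable), which lets both aggregation
# passes run as contiguous block column sums instead of generic rowsum().
gnn_loss_grad <- function(model, batch, pairs, lambda, perm_ji = NULL) {
  L <- model$config$n_layers
  K <- model$config$n_regions
  P <- nrow(pairs)
  C <- ncol(model$gcn_weights[[L]])
  m2 <- ncol(model$W1)
  ii <- pairs[, 1L]
  jj <- pairs[, 2L]
  if (is.null(perm_ji)) perm_ji <- order(jj, ii)
  W1a <- model$W1[seq_len(C), , drop = FALSE]
  W1b <- model$W1[C + seq_len(C), , drop = FALSE]
  # column sums over the K contiguous blocks of (K-1) rows (valid because
  # rows are sorted by ii)
  block_colsum <- function(x) {
    dim(x) <- c(K - 1L, K, m2)
    colSums(x, dims = 1L)  # K x m2
  }
  g <- purrr::map(model_params(model), function(x) x * 0)
  loss <- 0
  nb <- length(batch)
  for (sub in batch) {
    S <- sub$S
    # forward
    H <- vector("list", L + 1L)
    Z <- vector("list", L)
    H[[1L]] <- diag(K)
    for (l in seq_len(L)) {
      SH <- if (l == 1L) S else S %*% H[[l]]
      Z[[l]] <- SH %*% model$gcn_weights[[l]]
      H[[l + 1L]] <- prelu(Z[[l]], model$prelu_slopes[l])
    }
    HL <- H[[L + 1L]]
    Hb <- HL %*% W1b
    Hb <- Hb + rep(model$b1, each = K)
    A1 <- (HL %*% W1a)[ii, , drop = FALSE] + Hb[jj, , drop = FALSE]
    pos <- A1 > 0
    R1 <- A1 * pos
    pred <- drop(R1 %*% model$W2) + model$b2
    resid <- pred - sub$efc
    loss <- loss + mean(resid^2)
    # backward
    dpred <- matrix(2 * resid / (P * nb), ncol = 1L)
    g$W2 <- g$W2 + crossprod(R1, dpred)
    g$b2 <- g$b2 + sum(dpred)
    dA1 <- tcrossprod(dpred, model$W2) * pos
    agg_i <- block_colsum(dA1)                            # grouped by ii
    agg_j <- block_colsum(dA1[perm_ji, , drop = FALSE])   # grouped by jj
    g$W1[seq_len(C), ] <- g$W1[seq_len(C), ] + crossprod(HL, agg_i)
    g$W1[C + seq_len(C), ] <- g$W1[C + seq_len(C), ] + crossprod(HL, agg_j)
    g$b1 <- g$b1 + colSums(agg_i)
    dH <- agg_i %*% t(W1a) + agg_j %*% t(W1b)
    for (l in rev(seq_len(L))) {
      neg <- Z[[l]] < 0
      g$alpha[l] <- g$alpha[l] + sum(dH * Z[[l]] * neg)
      dZ <- dH * (1 - (1 - model$prelu_slopes[l]) * neg)
      SH <- if (l == 1L) S else S %*% H[[l]]
      g[[paste0("Wg", l)]] <- g[[paste0("Wg", l)]] + crossprod(SH, dZ)
      if (l > 1L) dH <- S %*% tcrossprod(dZ, model$gcn_weights[[l]])
    }
  }
  loss <- loss / nb + lambda * (sum(model$W1^2) + sum(model$W2^2))
  g$W1 <- g$W1 + 2 * lambda * model$W1
  g$W2 <- g$W2 + 2 * lambda * model$W2
  list(loss = loss, grads = g)
}

# compiled fast path for the training loop; numerically identical to
# gnn_loss_grad() (asserted in the test suite)
gnn_loss_grad_fast <- function(model, batch, idx0, lambda) {
  res <- .gnn_loss_grad_cpp(
    lapply(batch, `[[`, "S"), lapply(batch, `[[`, "efc"),
    model$gcn_weights, model$prelu_slopes, model$W1, model$b1,
    as.vector(model$W2), model$b2, lambda,
    idx0$ii, idx0$jj, idx0$perm, model$config$n_regions
  )
  g <- list()
  for (l in seq_along(model$gcn_weights)) g[[paste0("Wg", l)]] <- res$gWg[[l]]
  g$alpha <- as.vector(res$galpha)
  g$W1 <- res$gW1
  g$b1 <- as.vector(res$gb1)
  g$W2 <- matrix(res$gW2, ncol = 1L)
  g$b2 <- res$gb2
  list(loss = res$loss, grads = g)
}

adam_init <- function(params) {
  list(m = purrr::map(params, ~ .x * 0), v = purrr::map(params, ~ .x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# ---- public API ----------------------------------------------------------

#' Split a cohort into training and test halves
#'
#' @param cohort An `sfc_cohort`.
#' @param fraction Training fraction (default 0.5).
#' @param seed Seed for the random split.
#' @return List with integer vectors `train` and `test` (subject indices);
#'   sizes differ by at most one.
#' @export
split_cohort <- function(cohort, fraction = 0.5, seed = 1L) {
  N <- length(cohort$subjects)
  if (N < 4L) abort("Need at least 4 subjects to split.", class = "sfc_invalid_input")
  set.seed(seed)
  n_train <- round(N * fraction)
  train <- sort(sample.int(N, n_train))
  list(train = train, test = setdiff(seq_len(N), train))
}

#' Subset a cohort by subject index
#'
#' @param cohort An `sfc_cohort`.
#' @param idx Integer subject indices.
#' @return An `sfc_cohort` restricted to those subjects.
#' @export
subset_cohort <- function(cohort, idx) {
  cohort$subjects <- cohort$subjects[idx]
  cohort
}

#' Train the graph neural network
#'
#' Initializes all parameters from the config's seed, then minimizes
#' [mse_l2_loss()] with Adam over shuffled batches of subjects for the
#' configured number of epochs. Fully deterministic given the seed (and a
#' fixed BLAS thread count).
#'
#' @param cohort An `sfc_cohort` whose subjects form the training set.
#' @param config A [gnn_config()].
#' @return A trained `sfc_gnn` with a per-epoch `loss_trace`.
#' @export
train_model <- function(cohort, config) {
  subjects <- cohort$subjects
  K <- config$n_regions
  if (any(vapply(subjects, function(s) nrow(s$sc), 0L) != K)) {
    abort("Training matrices are not aligned with the config.", class = "sfc_config_error")
  }
  set.seed(config$seed)
  model <- init_gnn(config)
  pairs <- ordered_pairs(K)
  idx0 <- list(ii = pairs[, 1L] - 1L, jj = pairs[, 2L] - 1L,
               perm = order(pairs[, 2L], pairs[, 1L]) - 1L)
  prepped <- purrr::map(subjects, ~ prep_subject(.x$sc, .x$fc, pairs))
  params <- model_params(model)
  state <- adam_init(params)
  n <- length(prepped)
  trace <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    batch_losses <- numeric(length(starts))
    for (b in seq_along(starts)) {
      idx <- ord[starts[b]:min(starts[b] + config$batch_size - 1L, n)]
      model <- set_model_params(model, params)
      lg <- gnn_loss_grad_fast(model, prepped[idx], idx0, config$l2_lambda)
      if (!is.finite(lg$loss)) {
        abort(sprintf("Training diverged (nonfinite loss at epoch %d).", epoch),
              class = "sfc_training_error")
      }
      batch_losses[b] <- lg$loss
      upd <- adam_step(params, lg$grads, state, config$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    trace[epoch] <- mean(batch_losses)
  }
  model <- set_model_params(model, params)
  model$loss_trace <- trace
  model
}

#' Save and load a model checkpoint
#'
#' A checkpoint is a single JSON file holding every parameter matrix, the
#' config, and the loss trace, so trained models round-trip losslessly
#' through plain text.
#'
#' @param model A trained `sfc_gnn`.
#' @param path Checkpoint file path.
#' @return `save_gnn()` the path, invisibly; `load_gnn()` an `sfc_gnn`.
#' @export
save_gnn <- function(model, path) {
  payload <- list(
    config = unclass(model$config),
    gcn_weights = lapply(model$gcn_weights, unclass),
    prelu_slopes = model$prelu_slopes,
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
    loss_trace = model$loss_trace
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_gnn
#' @export
load_gnn <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(gnn_config, p$config[c("n_regions", "gcn_dims", "mlp_dims",
                                        "batch_size", "learning_rate",
                                        "l2_lambda", "epochs", "seed")])
  model <- list(
    gcn_weights = lapply(p$gcn_weights, function(w) matrix(unlist(w), nrow = nrow(w))),
    prelu_slopes = p$prelu_slopes,
    W1 = as.matrix(p$W1), b1 = as.numeric(p$b1),
    W2 = as.matrix(p$W2), b2 = as.numeric(p$b2),
    config = cfg,
    loss_trace = p$loss_trace
  )
  class(model) <- "sfc_gnn"
  model
}

#' Group-level prediction
#'
#' Averages the test subjects' structural matrices elementwise, predicts
#' from the average, and returns it alongside the elementwise mean empirical
#' functional matrix.
#'
#' @param model A trained `sfc_gnn`.
#' @param cohort An `sfc_cohort` of test subjects.
#' @return List with `pred_fc` and `mean_fc`.
#' @export
group_level_predict <- function(model, cohort) {
  if (length(cohort$subjects) == 0L) {
    abort("Empty test set.", class = "sfc_invalid_input")
  }
  mean_sc <- Reduce(`+`, purrr::map(cohort$subjects, "sc")) / length(cohort$subjects)
  mean_fc <- Reduce(`+`, purrr::map(cohort$subjects, "fc")) / length(cohort$subjects)
  list(pred_fc = predict_fc(mean_sc, model), mean_fc = mean_fc)
}

#' @method glance sfc_gnn
#' @export
glance.sfc_gnn <- function(x, ...) {
  tibble::tibble(
    n_layers = x$config$n_layers,
    n_params = sum(lengths(purrr::map(model_params(x), as.numeric))),
    epochs = x$config$epochs,
    initial_loss = if (is.null(x$loss_trace)) NA_real_ else x$loss_trace[1L],
    final_loss = if (is.null(x$loss_trace)) NA_real_ else x$loss_trace[length(x$loss_trace)]
  )
}

#' @method tidy sfc_gnn
#' @export
tidy.sfc_gnn <- function(x, ...) {
  if (is.null(x$loss_trace)) {
    return(tibble::tibble(epoch = integer(), loss = numeric()))
  }
  tibble::tibble(epoch = seq_along(x$loss_trace), loss = x$loss_trace)
}
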