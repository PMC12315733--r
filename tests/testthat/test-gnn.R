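toy_model <- function(K = 3L, C = 2L, mh = 2L, seed = 1L) {
  cfg <- gnn_config(K, gcn_dims = c(K, C, C), mlp_dims = c(2L * C, mh, 1L),
                    seed = seed)
  set.seed(seed)
  init_gnn(cfg)
}

test_that("config validation enforces one-hot input and decoder shape", {
  expect_error(gnn_config(10, gcn_dims = c(8, 4, 4)), class = "sfc_config_error")
  expect_error(gnn_config(10, mlp_dims = c(10, 4, 1)), class = "sfc_config_error")
  expect_error(gnn_config(10, mlp_dims = c(8, 4, 2)), class = "sfc_config_error")
  expect_error(gnn_config(10, l2_lambda = -1), class = "sfc_config_error")
  expect_s3_class(gnn_config(10, gcn_dims = c(10, 4, 4), mlp_dims = c(8, 3, 1)),
                  "gnn_config")
})

test_that("graph convolution matches hand arithmetic on a two-node toy", {
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  # Ahat = A + I, Dhat = diag(2, 2); normalized operator is all 0.5
  out <- gcn_layer(diag(2), A, diag(2), alpha = 0.7)
  expect_equal(out, matrix(0.5, 2, 2), tolerance = 1e-12)
  expect_equal(gcn_layer(diag(2), A, matrix(0, 2, 2), 0.25), matrix(0, 2, 2))
})

test_that("unit PReLU slope makes the layer exactly linear", {
  set.seed(2)
  A <- rand_sc(5, density = 0.8)
  H <- matrix(rnorm(15), 5, 3)
  W <- matrix(rnorm(6), 3, 2)
  Ahat <- A + diag(5)
  Dm <- diag(1 / sqrt(rowSums(Ahat)))
  expect_equal(gcn_layer(H, A, W, alpha = 1), Dm %*% Ahat %*% Dm %*% H %*% W,
               tolerance = 1e-12)
})

test_that("two-layer embeddings only see the two-hop neighbourhood", {
  model <- toy_model(K = 6L, C = 4L, seed = 3L)
  A <- path_graph(6)
  A2 <- A
  A2[5, 6] <- A2[6, 5] <- 0  # >= 3 hops from node 1
  H <- encode(A, model)
  H2 <- encode(A2, model)
  expect_equal(H[[3]][1, ], H2[[3]][1, ], tolerance = 1e-12)
  # but nodes within reach of the removed edge do change
  expect_false(isTRUE(all.equal(H[[3]][6, ], H2[[3]][6, ])))
})

test_that("embeddings are equivariant when features permute with the nodes", {
  model <- toy_model(K = 5L, C = 3L, seed = 4L)
  A <- rand_sc(5, density = 0.8, seed = 5)
  perm <- c(3, 1, 5, 2, 4)
  P <- diag(5)[perm, ]
  W <- model$gcn_weights[[1]]
  lhs <- gcn_layer(P, P %*% A %*% t(P), W, model$prelu_slopes[1])
  rhs <- P %*% gcn_layer(diag(5), A, W, model$prelu_slopes[1])
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_identical(encode(A, model), encode(A, model))
})

test_that("edge decoding follows the two-layer ReLU form", {
  model <- toy_model(K = 3L, C = 1L, mh = 1L)
  model$W1 <- matrix(c(1, 1), 2, 1)
  model$b1 <- 0
  model$W2 <- matrix(1, 1, 1)
  model$b2 <- 0
  expect_equal(decode_edge(0.3, 0.4, model), 0.7)
  expect_equal(decode_edge(-0.3, -0.4, model), 0)
  model$W1[] <- 0; model$W2[] <- 0
  expect_equal(decode_edge(0.3, 0.4, model), 0)
  expect_error(decode_edge(c(1, 2), 3, model), class = "sfc_config_error")
})

test_that("predicted matrices are symmetric with zero diagonal and match a double-loop oracle", {
  model <- toy_model(K = 3L, C = 2L, mh = 2L, seed = 6L)
  A <- rand_sc(3, density = 1, seed = 7)
  pfc <- predict_fc(A, model)
  expect_identical(pfc, t(pfc))
  expect_true(all(diag(pfc) == 0))
  H <- encode(A, model)
  HL <- H[[length(H)]]
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    expected <- (decode_edge(HL[i, ], HL[j, ], model) +
                 decode_edge(HL[j, ], HL[i, ], model)) / 2
    expect_equal(pfc[i, j], expected, tolerance = 1e-12)
  }
  model$W1[] <- 0; model$W2[] <- 0; model$b1[] <- 0; model$b2 <- 0
  expect_equal(predict_fc(A, model), matrix(0, 3, 3))
})

test_that("the training loss matches its printed formula and a naive oracle", {
  model <- toy_model(K = 2L, C = 1L, mh = 1L)
  pfc <- matrix(c(0, 1, 1, 0), 2, 2)
  efc <- matrix(0, 2, 2)
  expect_equal(mse_l2_loss(list(pfc), list(pfc), model, lambda = 0), 0)
  expect_equal(mse_l2_loss(list(pfc), list(efc), model, lambda = 0), 1)
  w2 <- sum(model$W1^2) + sum(model$W2^2)
  expect_equal(mse_l2_loss(list(pfc), list(efc), model, lambda = 0.1),
               1 + 0.1 * w2)
  # naive double-loop oracle on random batches
  set.seed(10)
  pb <- list(rand_sym(4), rand_sym(4))
  eb <- list(rand_sym(4), rand_sym(4))
  oracle <- 0
  for (s in 1:2) {
    acc <- 0
    for (i in 1:4) for (j in 1:4) if (i != j) acc <- acc + (pb[[s]][i, j] - eb[[s]][i, j])^2
    oracle <- oracle + acc / (4 * 3)
  }
  oracle <- oracle / 2 + 1e-4 * w2
  expect_equal(mse_l2_loss(pb, eb, model, lambda = 1e-4), oracle, tolerance = 1e-12)
  expect_error(mse_l2_loss(pb, eb, model, lambda = -1), class = "sfc_config_error")
})

test_that("analytic gradients agree with finite differences and the compiled kernel", {
  co <- tiny_cohort(K = 6L, N = 2L, seed = 8L, p_within = 0.9, p_between = 0.5)
  cfg <- gnn_config(6, gcn_dims = c(6L, 5L, 5L), mlp_dims = c(10L, 4L, 1L), seed = 9L)
  set.seed(9)
  model <- init_gnn(cfg)
  pairs <- sfcoupling:::ordered_pairs(6L)
  batch <- lapply(co$subjects, function(s) sfcoupling:::prep_subject(s$sc, s$fc, pairs))
  ref <- sfcoupling:::gnn_loss_grad(model, batch, pairs, 1e-4)
  idx0 <- list(ii = pairs[, 1] - 1L, jj = pairs[, 2] - 1L,
               perm = order(pairs[, 2], pairs[, 1]) - 1L)
  fast <- sfcoupling:::gnn_loss_grad_fast(model, batch, idx0, 1e-4)
  expect_equal(fast$loss, ref$loss, tolerance = 1e-12)
  for (nm in names(ref$grads)) {
    expect_equal(as.vector(fast$grads[[nm]]), as.vector(ref$grads[[nm]]),
                 tolerance = 1e-12)
  }
  # finite differences on a random parameter subset
  params <- sfcoupling:::model_params(model)
  h <- 1e-6
  set.seed(11)
  for (nm in names(params)) {
    for (k in sample(length(params[[nm]]), min(2, length(params[[nm]])))) {
      bump <- function(delta) {
        p <- params
        p[[nm]][k] <- p[[nm]][k] + delta
        m <- sfcoupling:::set_model_params(model, p)
        sfcoupling:::gnn_loss_grad(m, batch, pairs, 1e-4)$loss
      }
      fd <- (bump(h) - bump(-h)) / (2 * h)
      an <- ref$grads[[nm]][k]
      expect_equal(an, fd, tolerance = 1e-4)
    }
  }
})

test_that("cohort splits are disjoint, exhaustive and reproducible", {
  co <- tiny_cohort(K = 10L, N = 10L, seed = 12L)
  s1 <- split_cohort(co, seed = 5)
  s2 <- split_cohort(co, seed = 5)
  expect_identical(s1, s2)
  expect_equal(length(s1$train), 5)
  expect_length(intersect(s1$train, s1$test), 0)
  expect_setequal(c(s1$train, s1$test), 1:10)
  co3 <- subset_cohort(co, 1:3)
  expect_error(split_cohort(co3), class = "sfc_invalid_input")
})

test_that("training descends, is seed-deterministic, and fits its own forward family", {
  co <- generate_cohort(cohort_spec(n_subjects = 20, n_regions = 20,
                                    beta = c(1), gamma_g = 0, gamma_i = 0,
                                    noise_sd = 0, seed = 77))
  cfg <- gnn_config(20, epochs = 200L, seed = 8L)
  m1 <- train_model(co, cfg)
  expect_lt(m1$loss_trace[length(m1$loss_trace)], m1$loss_trace[1])
  # the variance the model must explain: off-diagonal FC variance
  v <- var(ut_oracle(co$subjects[[1]]$fc))
  expect_lt(m1$loss_trace[length(m1$loss_trace)], 0.1 * v)
  m2 <- train_model(co, cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_equal(m1$W1, m2$W1)
  gl <- glance(m1)
  expect_equal(gl$final_loss, m1$loss_trace[200])
  expect_equal(nrow(tidy(m1)), 200)
})

test_that("group-level prediction averages inputs and stays symmetric", {
  co <- tiny_cohort(K = 10L, N = 4L, seed = 13L)
  cfg <- gnn_config(10, epochs = 2L, seed = 2L)
  model <- train_model(co, cfg)
  single <- group_level_predict(model, subset_cohort(co, 1))
  expect_equal(single$pred_fc, predict_fc(co$subjects[[1]]$sc, model))
  expect_equal(single$mean_fc, co$subjects[[1]]$fc)
  two <- group_level_predict(model, subset_cohort(co, 1:2))
  hand_mean <- (co$subjects[[1]]$sc + co$subjects[[2]]$sc) / 2
  expect_equal(two$pred_fc, predict_fc(hand_mean, model))
  expect_identical(two$pred_fc, t(two$pred_fc))
  expect_error(group_level_predict(model, subset_cohort(co, integer(0))),
               class = "sfc_invalid_input")
})

test_that("model checkpoints round-trip through JSON", {
  co <- tiny_cohort(K = 10L, N = 4L, seed = 17L)
  cfg <- gnn_config(10, epochs = 3L, seed = 2L)
  model <- train_model(co, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_gnn(model, path)
  back <- load_gnn(path)
  expect_equal(back$W1, model$W1, tolerance = 1e-12)
  expect_equal(back$gcn_weights, model$gcn_weights, tolerance = 1e-12)
  expect_equal(back$prelu_slopes, model$prelu_slopes)
  expect_equal(back$config$gcn_dims, model$config$gcn_dims)
  sc <- co$subjects[[1]]$sc
  expect_equal(predict_fc(sc, back), predict_fc(sc, model), tolerance = 1e-10)
})
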