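test_that("cohort spec validation rejects degenerate settings", {
  expect_error(cohort_spec(n_regions = 7), class = "sfc_invalid_spec")
  expect_error(cohort_spec(n_subjects = 1), class = "sfc_invalid_spec")
  expect_error(cohort_spec(p_within = 1.2), class = "sfc_invalid_spec")
  expect_error(cohort_spec(gamma_i = -0.1), class = "sfc_invalid_spec")
})

test_that("axis-graded individual scale spans gamma_i to gamma_i*(1+s)", {
  sig <- region_sigma(1:8, gamma_i = 0.1, axis_slope = 1)
  expect_equal(sig[1], 0.1)
  expect_equal(sig[8], 0.2)
  expect_true(all(diff(sig[order(1:8)]) > 0))
})

test_that("region metadata is deterministic, unit-norm, and hemispherically balanced", {
  spec <- cohort_spec(n_regions = 60, seed = 3)
  set.seed(3); m1 <- build_region_meta(spec)
  set.seed(3); m2 <- build_region_meta(spec)
  expect_identical(m1, m2)
  expect_equal(sqrt(m1$x^2 + m1$y^2 + m1$z^2), rep(1, 60), tolerance = 1e-9)
  expect_setequal(m1$axis_rank, 1:60)
  expect_equal(sum(m1$hemisphere == "left"), 30)
  expect_true(all(m1$volume > 0))
})

test_that("complete-graph probabilities give a complete weighted backbone", {
  spec <- cohort_spec(n_regions = 10, p_within = 1, p_between = 1, hub_frac = 0)
  set.seed(1)
  sc <- sample_group_sc(spec)
  expect_equal(sum(ut_oracle(sc) > 0), 10 * 9 / 2)
  expect_true(all(diag(sc) == 0))
  expect_identical(sc, t(sc))
})

test_that("edge-free spec cannot produce a connected backbone", {
  spec <- cohort_spec(n_regions = 10, p_within = 0, p_between = 0, hub_frac = 0)
  set.seed(1)
  expect_error(sample_group_sc(spec, max_retries = 5), class = "sfc_generation_error")
})

test_that("planted modules beat a random equal partition on brute-force modularity", {
  spec <- cohort_spec(n_regions = 20, n_modules = 4, p_within = 0.8,
                      p_between = 0.05, hub_frac = 0)
  set.seed(42)
  sc <- sample_group_sc(spec)
  A <- (sc > 0) * 1
  modularity_oracle <- function(A, membership) {
    m <- sum(A) / 2
    k <- rowSums(A)
    q <- 0
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A))) {
      if (membership[i] == membership[j]) q <- q + A[i, j] - k[i] * k[j] / (2 * m)
    }
    q / (2 * m)
  }
  planted <- ceiling(seq_len(20) * 4 / 20)
  set.seed(7)
  random_part <- sample(planted)
  expect_gt(modularity_oracle(A, planted), modularity_oracle(A, random_part))
})

test_that("subject jitter reduces to identity when all perturbation is off", {
  spec <- cohort_spec(n_regions = 12, tau_sc = 0, flip_rate = 0)
  set.seed(2)
  g <- sample_group_sc(spec)
  set.seed(9)
  s <- sample_subject_sc(g, spec)
  expect_equal(s, g)
})

test_that("zero flip rate preserves the edge support exactly", {
  spec <- cohort_spec(n_regions = 12, tau_sc = 0.3, flip_rate = 0)
  set.seed(2)
  g <- sample_group_sc(spec)
  set.seed(9)
  s <- sample_subject_sc(g, spec)
  expect_identical(s > 0, g > 0)
})

test_that("jitter multipliers regenerate from the same seeded stream", {
  spec <- cohort_spec(n_regions = 10, tau_sc = 0.1, flip_rate = 0)
  set.seed(2)
  g <- sample_group_sc(spec)
  set.seed(31)
  s <- sample_subject_sc(g, spec)
  edges <- ut_oracle(g) > 0
  ratio <- ut_oracle(s)[edges] / ut_oracle(g)[edges]
  set.seed(31)
  eps <- rnorm(sum(edges), 0, 0.1)
  expect_equal(ratio, exp(eps), tolerance = 1e-12)
})

test_that("one-hop forward model returns the standardized normalized adjacency", {
  spec <- cohort_spec(n_regions = 8, beta = c(1), gamma_g = 0, gamma_i = 0,
                      noise_sd = 0)
  set.seed(4)
  sc <- rand_sc(8, density = 0.9)
  meta <- toy_meta(8)
  fc <- forward_fc(sc, spec, matrix(0, 8, 8), matrix(0, 8, 8), meta)
  # independent oracle: normalize, standardize off-diagonal
  d <- rowSums(sc)
  ab <- diag(1 / sqrt(d)) %*% sc %*% diag(1 / sqrt(d))
  off <- ut_oracle(ab)
  expected <- (ab - mean(off)) / sd(off)
  diag(expected) <- 0
  expect_equal(fc, expected, tolerance = 1e-12)
})

test_that("pure two-hop forward model peaks at the path's two-hop pair", {
  # 3-node path: Abar^2 has its largest off-diagonal entry at (1, 3)
  spec <- cohort_spec(n_regions = 8, beta = c(0, 1), gamma_g = 0, gamma_i = 0,
                      noise_sd = 0)
  sc <- path_graph(3)
  meta <- toy_meta(3)
  fc <- forward_fc(sc, spec, matrix(0, 3, 3), matrix(0, 3, 3), meta)
  # hand computation: d = (1, 2, 1); Abar^2 off-diagonals are (0, 1/2, 0)
  offs <- ut_oracle(fc)
  expect_equal(which.max(offs), 2L)  # the (1,3) entry in row-major order
  ab2_02 <- 1 / 2
  expect_equal(offs[2], (ab2_02 - mean(c(0, 0.5, 0))) / sd(c(0, 0.5, 0)))
})

test_that("noise-free forward model is deterministic and rejects isolated nodes", {
  spec <- cohort_spec(n_regions = 8, noise_sd = 0, gamma_i = 0)
  set.seed(4)
  sc <- rand_sc(8, density = 0.9)
  meta <- toy_meta(8)
  g <- rand_sym(8, seed = 1)
  s <- rand_sym(8, seed = 2)
  expect_identical(forward_fc(sc, spec, g, s, meta),
                   forward_fc(sc, spec, g, s, meta))
  sc_iso <- sc
  sc_iso[1, ] <- 0
  sc_iso[, 1] <- 0
  expect_error(forward_fc(sc_iso, spec, g, s, meta),
               class = "sfc_degenerate_input")
})

test_that("cohorts with no individual sources give identical subjects", {
  spec <- cohort_spec(n_subjects = 2, n_regions = 12, tau_sc = 0,
                      flip_rate = 0, gamma_i = 0, noise_sd = 0, seed = 6)
  co <- generate_cohort(spec)
  expect_equal(co$subjects[[1]]$fc, co$subjects[[2]]$fc)
  expect_equal(co$subjects[[1]]$sc, co$subjects[[2]]$sc)
})

test_that("cohort generation is bit-reproducible from its seed", {
  spec <- cohort_spec(n_subjects = 6, n_regions = 20, seed = 11)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
})

test_that("generated matrices satisfy the connectome invariants", {
  co <- generate_cohort(cohort_spec(n_subjects = 5, n_regions = 20, seed = 12))
  for (s in co$subjects) {
    expect_identical(s$sc, t(s$sc))
    expect_identical(s$fc, t(s$fc))
    expect_true(all(diag(s$sc) == 0))
    expect_true(all(diag(s$fc) == 0))
    expect_true(all(s$sc >= 0))
    expect_true(all(rowSums(s$sc) > 0))
  }
})

test_that("individual variation lowers similarity to the cohort-mean FC", {
  mean_fc_similarity <- function(gamma_i) {
    co <- generate_cohort(cohort_spec(n_subjects = 10, n_regions = 20,
                                      gamma_i = gamma_i, seed = 13))
    fcs <- lapply(co$subjects, `[[`, "fc")
    mfc <- Reduce(`+`, fcs) / length(fcs)
    mean(vapply(fcs, function(f) cor(ut_oracle(f), ut_oracle(mfc)), 0))
  }
  expect_lt(mean_fc_similarity(0.5), mean_fc_similarity(0))
})

test_that("FD traces follow the spike model and regenerate from the stream", {
  set.seed(1)
  expect_equal(generate_fd_trace(50, base_fd = 0.05, spike_prob = 0),
               rep(0.05, 50))
  set.seed(1)
  expect_true(all(generate_fd_trace(50, spike_prob = 1, spike_fd = 0.5) >= 0.5))
  set.seed(21)
  tr <- generate_fd_trace(100, base_fd = 0.05, spike_prob = 0.3, spike_fd = 0.4)
  set.seed(21)
  expected_spikes <- sum(runif(100) < 0.3)
  expect_equal(sum(tr == 0.4), expected_spikes)
  expect_error(generate_fd_trace(0, 0.05, 0.1, 0.4), class = "sfc_invalid_spec")
  expect_error(generate_fd_trace(10, -0.1, 0.1, 0.4), class = "sfc_invalid_spec")
})

test_that("cohort serialization round-trips through the text layout", {
  co <- generate_cohort(cohort_spec(n_subjects = 3, n_regions = 10, seed = 14))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "cohort.json")))
  expect_true(file.exists(file.path(dir, "regions.tsv")))
  back <- read_cohort(dir)
  expect_equal(length(back$subjects), 3)
  for (i in 1:3) {
    expect_equal(back$subjects[[i]]$sc, co$subjects[[i]]$sc, tolerance = 1e-12)
    expect_equal(back$subjects[[i]]$fc, co$subjects[[i]]$fc, tolerance = 1e-12)
    expect_identical(back$subjects[[i]]$subject_id, co$subjects[[i]]$subject_id)
  }
  expect_equal(back$region_meta$axis_rank, co$region_meta$axis_rank)
  expect_equal(back$spec$gamma_i, co$spec$gamma_i)
})

test_that("raising gamma_i raises the downstream estimated individual effect", {
  # reduced-scale ground-truth monotonicity: N = 40, K = 40, short training
  est_individual <- function(gamma_i, seed) {
    co <- generate_cohort(cohort_spec(n_subjects = 40, n_regions = 40,
                                      gamma_i = gamma_i, seed = 700L + seed))
    split <- split_cohort(co, seed = 710L + seed)
    cfg <- gnn_config(40, epochs = 60L, seed = 720L + seed)
    model <- train_model(subset_cohort(co, split$train), cfg)
    test <- subset_cohort(co, split$test)
    preds <- lapply(test$subjects, function(s) predict_fc(s$sc, model))
    fcs <- lapply(test$subjects, `[[`, "fc")
    decompose_coupling(cross_coupling_matrix(preds, fcs, "gnn"))$individual
  }
  lo <- mean(vapply(0:4, function(s) est_individual(0, s), 0))
  hi <- mean(vapply(0:4, function(s) est_individual(0.5, s), 0))
  expect_gt(hi, lo)
})
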