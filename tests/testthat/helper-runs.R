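# Memoised full-scale study runs shared by the acceptance tests and the
# heavier property tests. Conditions are the package's reference study
# conditions: N = 80 subjects, K = 60 regions, 200-epoch training.

.sfc_run_cache <- new.env(parent = emptyenv())

# one complete fold: cohort -> mask -> split -> train -> test predictions
study_run <- function(gamma_i, seed) {
  key <- sprintf("g%g_s%d", gamma_i, seed)
  if (!is.null(.sfc_run_cache[[key]])) return(.sfc_run_cache[[key]])
  spec <- cohort_spec(gamma_i = gamma_i, seed = 100L + seed)
  co <- generate_cohort(spec)
  split <- split_cohort(co, seed = 200L + seed)
  mask <- consistency_mask(lapply(co$subjects[split$train], `[[`, "sc"))
  masked <- co
  masked$subjects <- lapply(co$subjects, function(s) {
    s$sc <- apply_mask(s$sc, mask)
    s
  })
  cfg <- gnn_config(spec$n_regions, epochs = 200L, seed = 300L + seed)
  model <- train_model(subset_cohort(masked, split$train), cfg)
  test <- subset_cohort(masked, split$test)
  preds <- lapply(test$subjects, function(s) predict_fc(s$sc, model))
  fcs <- lapply(test$subjects, `[[`, "fc")
  scs <- lapply(test$subjects, `[[`, "sc")
  run <- list(
    co = co, split = split, mask = mask, masked = masked, cfg = cfg,
    model = model, preds = preds, fcs = fcs, scs = scs,
    dec_gnn = decompose_coupling(cross_coupling_matrix(preds, fcs, "gnn", sc_mask = mask)),
    dec_corr = decompose_coupling(cross_coupling_matrix(scs, fcs, "correlation", sc_mask = mask))
  )
  .sfc_run_cache[[key]] <- run
  run
}

# regional GNN effect maps + axis alignment for a default-cohort run
study_alignment <- function(seed, n_rotations = 1000L) {
  key <- sprintf("align_s%d", seed)
  if (!is.null(.sfc_run_cache[[key]])) return(.sfc_run_cache[[key]])
  run <- study_run(0.5, seed)
  maps <- regional_effect_maps(run$preds, run$fcs, "gnn", sc_mask = run$mask)
  perms <- spin_rotations(run$co$region_meta, n_rotations, seed = 500L + seed)
  ranks <- run$co$region_meta$axis_rank
  out <- list(
    maps = maps,
    group = align_map(maps$group, ranks, perms),
    individual = align_map(maps$individual, ranks, perms)
  )
  .sfc_run_cache[[key]] <- out
  out
}

# rewired-training topology null for a default-cohort run
study_null <- function(seed) {
  key <- sprintf("null_s%d", seed)
  if (!is.null(.sfc_run_cache[[key]])) return(.sfc_run_cache[[key]])
  run <- study_run(0.5, seed)
  out <- rewired_training_run(run$masked, run$split, run$cfg,
                              model = run$model, sc_mask = run$mask,
                              seed = 400L + seed)
  .sfc_run_cache[[key]] <- out
  out
}
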