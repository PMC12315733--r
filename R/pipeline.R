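#' Configuration of a full study run
#'
#' Bundles the cohort source, preparation options, GNN hyperparameters and
#' analysis options for [run_study()] / [run_repeated_cv()]. A single master
#' seed deterministically derives one sub-seed per stage (cohort, split,
#' training, rewiring, spin) via a small string hash, so stages are
#' individually reproducible.
#'
#' @param spec A [cohort_spec()] for cohort generation, or `NULL` when
#'   loading from `cohort_path`.
#' @param cohort_path Optional path to a cohort manifest ([read_cohort()]).
#' @param seed Master seed.
#' @param gnn Named list of [gnn_config()] overrides (e.g. `epochs`).
#' @param percentile Consistency-mask CV percentile (default 75).
#' @param mask_scope `"train"` (mask computed on training subjects only,
#'   applied to all) or `"all"`.
#' @param approaches Coupling approaches to run.
#' @param n_rotations Spin rotations for alignment p-values (default 1000).
#' @param swaps_per_edge Rewiring swaps per edge (default 10).
#' @param outlier_k Outlier cutoff for alignment (default 3).
#' @param cv_repeats Repeats for [run_repeated_cv()] (default 10).
#' @param run_null Run the rewired-training null (default `TRUE`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(spec = cohort_spec(), cohort_path = NULL, seed = 1L,
                       gnn = list(), percentile = 75,
                       mask_scope = c("train", "all"),
                       approaches = c("correlation", "gnn"),
                       n_rotations = 1000L, swaps_per_edge = 10,
                       outlier_k = 3, cv_repeats = 10L, run_null = TRUE) {
  structure(
    list(spec = spec, cohort_path = cohort_path, seed = as.integer(seed),
         gnn = gnn, percentile = percentile,
         mask_scope = match.arg(mask_scope), approaches = approaches,
         n_rotations = as.integer(n_rotations),
         swaps_per_edge = swaps_per_edge, outlier_k = outlier_k,
         cv_repeats = as.integer(cv_repeats), run_null = isTRUE(run_null)),
    class = "run_config"
  )
}

load_or_generate_cohort <- function(config) {
  if (!is.null(config$cohort_path)) {
    read_cohort(config$cohort_path)
  } else {
    spec <- config$spec
    spec$seed <- stage_seed(config$seed, "cohort")
    generate_cohort(spec)
  }
}

make_gnn_config <- function(config, K) {
  args <- config$gnn
  args$n_regions <- K
  args$seed <- stage_seed(config$seed, "train")
  do.call(gnn_config, args)
}

# shared core: mask, split, train, predict; reused by run_study and CV folds
fit_fold <- function(cohort, train_idx, test_idx, config) {
  masked <- cohort
  mask_subjects <- if (config$mask_scope == "train") train_idx else seq_along(cohort$subjects)
  mask <- consistency_mask(purrr::map(cohort$subjects[mask_subjects], "sc"),
                           percentile = config$percentile)
  masked$subjects <- purrr::map(cohort$subjects, function(s) {
    s$sc <- apply_mask(s$sc, mask)
    s
  })
  gcfg <- make_gnn_config(config, nrow(cohort$region_meta))
  model <- train_model(subset_cohort(masked, train_idx), gcfg)
  test <- subset_cohort(masked, test_idx)
  pred_fcs <- purrr::map(test$subjects, ~ predict_fc(.x$sc, model))
  list(mask = mask, model = model, gcfg = gcfg, masked = masked,
       test = test, pred_fcs = pred_fcs)
}

fold_couplings <- function(fit, config) {
  test_scs <- purrr::map(fit$test$subjects, "sc")
  test_fcs <- purrr::map(fit$test$subjects, "fc")
  out <- list()
  if ("correlation" %in% config$approaches) {
    out$correlation <- cross_coupling_matrix(test_scs, test_fcs, "correlation",
                                             sc_mask = fit$mask)
  }
  if ("gnn" %in% config$approaches) {
    out$gnn <- cross_coupling_matrix(fit$pred_fcs, test_fcs, "gnn",
                                     sc_mask = fit$mask)
  }
  out
}

#' Run the full structure-function coupling study
#'
#' Generates (or loads) a cohort, applies group-consistency thresholding,
#' splits subjects 50/50, trains the GNN on the training half, and on the
#' test half computes: global coupling matrices and decompositions for the
#' correlation and GNN approaches, group-level prediction accuracy, regional
#' effect maps, the rewired-training topology null, and the spin-tested
#' alignment of regional group/individual/normalized-individual maps with
#' the cortical axis.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, writes `report.json`,
#'   dense coupling matrices, `regional_effects.tsv` and `alignment.tsv`.
#' @return An `sfc_report` list; see the elements of the returned object.
#' @export
run_study <- function(config, out_dir = NULL) {
  cohort <- load_or_generate_cohort(config)
  K <- nrow(cohort$region_meta)
  split <- split_cohort(cohort, 0.5, seed = stage_seed(config$seed, "split"))
  fit <- fit_fold(cohort, split$train, split$test, config)
  cps <- fold_couplings(fit, config)
  decomps <- purrr::map(cps, decompose_coupling)

  glp <- group_level_predict(fit$model, fit$test)
  group_level <- list(
    gnn_r = coupling_pair(glp$pred_fc, glp$mean_fc, "gnn", sc_mask = fit$mask)
  )
  if ("correlation" %in% config$approaches) {
    mean_sc <- Reduce(`+`, purrr::map(fit$test$subjects, "sc")) / length(fit$test$subjects)
    group_level$correlation_r <- coupling_pair(mean_sc, glp$mean_fc, "correlation",
                                               sc_mask = fit$mask)
  }

  test_fcs <- purrr::map(fit$test$subjects, "fc")
  regional <- dplyr::bind_rows(purrr::map(config$approaches, function(ap) {
    sources <- if (ap == "gnn") fit$pred_fcs else purrr::map(fit$test$subjects, "sc")
    regional_effect_maps(sources, test_fcs, ap, sc_mask = fit$mask)
  }))

  null_run <- NULL
  if (config$run_null) {
    null_run <- rewired_training_run(
      fit$masked, split, fit$gcfg, model = fit$model, sc_mask = fit$mask,
      swaps_per_edge = config$swaps_per_edge,
      seed = stage_seed(config$seed, "rewire")
    )
    null_run$null_model <- NULL
  }

  perms <- spin_rotations(cohort$region_meta, config$n_rotations,
                          seed = stage_seed(config$seed, "spin"))
  axis_ranks <- cohort$region_meta$axis_rank
  alignment <- dplyr::bind_rows(purrr::map(config$approaches, function(ap) {
    maps <- dplyr::filter(regional, .data$approach == ap)
    dplyr::bind_rows(purrr::map(
      c("total", "group", "individual", "normalized_individual"),
      function(nm) {
        al <- align_map(maps[[nm]], axis_ranks, perms, k = config$outlier_k)
        dplyr::mutate(al, map = nm, approach = ap, .before = 1L)
      }
    ))
  }))

  report <- structure(
    list(
      config = config,
      seeds = list(master = config$seed,
                   cohort = stage_seed(config$seed, "cohort"),
                   split = stage_seed(config$seed, "split"),
                   train = stage_seed(config$seed, "train"),
                   rewire = stage_seed(config$seed, "rewire"),
                   spin = stage_seed(config$seed, "spin")),
      n_subjects = length(cohort$subjects), n_regions = K,
      split = split,
      mask = list(threshold = fit$mask$threshold,
                  n_evaluated = fit$mask$n_evaluated,
                  n_removed = fit$mask$n_removed),
      model_glance = glance(fit$model),
      group_level = group_level,
      coupling = cps,
      decomposition = decomps,
      regional = regional,
      rewiring = if (is.null(null_run)) NULL else list(
        mean_r_empirical = mean(null_run$r_empirical),
        mean_r_null = mean(null_run$r_null),
        r2_drop = null_run$r2_drop,
        r_empirical = null_run$r_empirical,
        r_null = null_run$r_null
      ),
      alignment = alignment
    ),
    class = "sfc_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (ap in names(report$coupling)) {
    utils::write.table(unclass(report$coupling[[ap]]),
                       file.path(out_dir, sprintf("coupling_matrix_%s.txt", ap)),
                       row.names = FALSE, col.names = FALSE)
  }
  global <- dplyr::bind_rows(purrr::map(report$decomposition, tidy))
  readr::write_tsv(global, file.path(out_dir, "coupling_global.tsv"))
  if (!is.null(report$rewiring)) {
    jsonlite::write_json(report$rewiring,
                         file.path(out_dir, "rewired_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  readr::write_tsv(report$regional, file.path(out_dir, "regional_effects.tsv"))
  readr::write_tsv(report$alignment, file.path(out_dir, "alignment.tsv"))
  dec <- purrr::map(report$decomposition, function(d) {
    d[c("total", "group", "individual", "individual_fraction",
        "t_statistic", "p_value", "n")]
  })
  jsonlite::write_json(dec, file.path(out_dir, "decomposition.json"),
                       auto_unbox = TRUE, digits = NA)
  summary <- list(
    seeds = report$seeds,
    n_subjects = report$n_subjects, n_regions = report$n_regions,
    mask = report$mask,
    group_level = report$group_level,
    decomposition = dec,
    rewiring = report$rewiring[c("mean_r_empirical", "mean_r_null", "r2_drop")],
    alignment = report$alignment
  )
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.sfc_report <- function(x, ...) {
  cat(sprintf("<sfc_report> N = %d, K = %d\n", x$n_subjects, x$n_regions))
  for (ap in names(x$decomposition)) {
    d <- x$decomposition[[ap]]
    cat(sprintf("  %-11s total %.3f group %.3f individual %.4f (%.2f%%), t = %.2f, p = %.2g\n",
                ap, d$total, d$group, d$individual,
                100 * d$individual_fraction, d$t_statistic, d$p_value))
  }
  if (!is.null(x$rewiring)) {
    cat(sprintf("  rewired null: r %.3f -> %.3f, R2 drop %.3f\n",
                x$rewiring$mean_r_empirical, x$rewiring$mean_r_null,
                x$rewiring$r2_drop))
  }
  invisible(x)
}

#' Repeated two-fold cross-validation
#'
#' Per repeat, subjects are split into random halves; the GNN is trained on
#' each half and evaluated on the other (two fold evaluations per repeat).
#' Global GNN coupling, the individual fraction and the alignment rhos of the
#' group and individual maps are collected per fold and aggregated as mean
#' and sd.
#'
#' @param config A [run_config()].
#' @param repeats Number of repeats (default from the config).
#' @return List with `folds` (per-fold tibble) and `aggregate`
#'   (metric/mean/sd tibble).
#' @export
run_repeated_cv <- function(config, repeats = config$cv_repeats) {
  cohort <- load_or_generate_cohort(config)
  axis_ranks <- cohort$region_meta$axis_rank
  perms <- NULL
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    split <- split_cohort(cohort, 0.5, seed = stage_seed(config$seed, paste0("cv", rep_i)))
    halves <- list(list(train = split$train, test = split$test),
                   list(train = split$test, test = split$train))
    for (f in seq_along(halves)) {
      fit <- fit_fold(cohort, halves[[f]]$train, halves[[f]]$test, config)
      test_fcs <- purrr::map(fit$test$subjects, "fc")
      cp <- cross_coupling_matrix(fit$pred_fcs, test_fcs, "gnn", sc_mask = fit$mask)
      dec <- decompose_coupling(cp)
      maps <- regional_effect_maps(fit$pred_fcs, test_fcs, "gnn", sc_mask = fit$mask)
      rho_group <- spearman_rho(maps$group[outlier_mask(maps$group)],
                                axis_ranks[outlier_mask(maps$group)])
      rho_indiv <- spearman_rho(maps$individual[outlier_mask(maps$individual)],
                                axis_ranks[outlier_mask(maps$individual)])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        repeat_id = rep_i, fold = f,
        coupling = dec$total, group = dec$group, individual = dec$individual,
        individual_fraction = dec$individual_fraction,
        rho_group = rho_group, rho_individual = rho_indiv
      )
    }
  }
  folds <- dplyr::bind_rows(rows)
  aggregate <- folds |>
    tidyr::pivot_longer(-c("repeat_id", "fold"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value), .groups = "drop")
  list(folds = folds, aggregate = aggregate)
}
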