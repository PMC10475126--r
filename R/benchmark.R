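#' Default model configuration for the synthetic benchmark
#'
#' A scaled-down instance of the architecture (embedding 24, hidden 32,
#' 2 bidirectional layers, dropout 0.5, head 192 -> 96 -> 1) sized so
#' the full synthetic benchmark trains in minutes on one CPU while
#' keeping every structural element of the full model. The reference
#' architecture itself is the [model_config()] default.
#'
#' @param seed Integer seed.
#' @param max_epochs Epoch cap for the benchmark.
#' @return A [model_config()].
#' @export
benchmark_model_config <- function(seed = 1L, max_epochs = 30L) {
  # editing_window spans the whole protospacer to match the generator's
  # editing model (conversions are planted protospacer-wide), so the
  # no-editable-nucleotide override agrees with the synthetic truth
  model_config(embedding_dim = 24L, hidden = 32L, layers = 2L,
               dropout = 0.5, batch_size = 512L,
               max_epochs = max_epochs, lr_patience = 3L,
               stop_patience = 8L, editing_window = c(1L, 20L),
               seed = seed)
}

#' Run the end-to-end synthetic benchmark
#'
#' Generates the default synthetic screen (known ground truth), makes a
#' group-aware 10-fold split, trains the deep regressor on one fold's
#' training side, and evaluates held-out predictions against the
#' generator's true off:on ratios. Optionally fits baseline models on
#' the same split and computes the positional attribution profile of
#' the held-out set.
#'
#' @param seed Master seed for generator, split, and model.
#' @param generator A [generator_config()]; defaults to the study-scale
#'   generator under `seed`.
#' @param config Model configuration; defaults to
#'   [benchmark_model_config()].
#' @param test_fold Fold held out for testing (of 10).
#' @param baselines Character vector of baseline models to fit
#'   (`NULL` to skip).
#' @param search_budget TPE trials per baseline model.
#' @param attribution_steps Integrated-gradients steps for the held-out
#'   attribution profile (0 to skip).
#' @param verbose Print progress.
#' @return List: `model`, `metrics` (tibble of held-out Spearman/
#'   Pearson vs truth and vs observed ratios, per model), `by_type`
#'   (deep-model Spearman stratified by mutation type), `efficiencies`,
#'   `pairs`, `test` (logical mask), `attribution` (profile or NULL).
#' @export
run_synthetic_benchmark <- function(seed = 1L,
                                    generator = generator_config(seed = seed),
                                    config = benchmark_model_config(seed = seed),
                                    test_fold = 1L,
                                    baselines = "xgboost",
                                    search_budget = 8L,
                                    attribution_steps = 16L,
                                    verbose = FALSE) {
  lib <- generate_library(generator)
  eff <- generate_efficiencies(lib, generator)
  pairs <- lib$pairs
  y_obs <- eff$off_on_ratio
  y_true <- eff$true_ratio_val
  folds <- group_kfold(pairs$group_id, k = 10L, seed = seed)
  sp <- split_fold(pairs, folds, test_fold)
  assert_group_disjoint(pairs$group_id[sp$train], pairs$group_id[sp$test])
  model <- new_model(config)
  model <- train_model(model, pairs[sp$train, ], y_obs[sp$train],
                       test_groups = sp$test_groups, verbose = verbose)
  test_pairs <- pairs[sp$test, ]
  pred <- predict_pairs(model, test_pairs, editor = generator$editor)
  met <- function(label, p) {
    tibble::tibble(
      model = label,
      spearman_truth = suppressWarnings(
        stats::cor(p, y_true[sp$test], method = "spearman")),
      spearman_observed = suppressWarnings(
        stats::cor(p, y_obs[sp$test], method = "spearman")),
      pearson_truth = suppressWarnings(
        stats::cor(p, y_true[sp$test], method = "pearson")))
  }
  metrics <- met("deep", pred$predicted_ratio)
  if (length(baselines) > 0) {
    X <- featurize_pairs(pairs)
    bl <- fit_baselines(X, pmin(pmax(y_obs, 0), 1), pairs$group_id,
                        test = sp$test, search_budget = search_budget,
                        models = baselines, seed = seed)
    for (nm in names(bl)) {
      metrics <- dplyr::bind_rows(metrics, met(nm, bl[[nm]]$predictions))
    }
  }
  by_type <- correlation_metrics(pred$predicted_ratio, y_true[sp$test],
                                 by = test_pairs$mutation_type)
  attribution <- NULL
  if (attribution_steps > 0) {
    att <- attribute_pairs(model, test_pairs, steps = attribution_steps)
    attribution <- attribution_profile(test_pairs, att)
  }
  list(model = model, metrics = metrics, by_type = by_type,
       efficiencies = eff, pairs = pairs, test = sp$test,
       predictions = pred, attribution = attribution)
}
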