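# Imbalance-aware evaluation: confusion-matrix metrics with explicit
# handling of degenerate (all-negative) classifiers, seed-stability runs and
# hyperparameter-sensitivity sweeps.

#' Confusion-matrix metrics
#'
#' @param y True 0/1 labels.
#' @param pred Predicted 0/1 labels.
#' @return List with `tp`, `fp`, `tn`, `fn`, `accuracy`, `precision`,
#'   `recall`, `f1` and `degenerate` (`TRUE` when the classifier made no
#'   positive prediction, in which case precision and F1 are reported as 0).
#' @export
classification_metrics <- function(y, pred) {
  stopifnot(length(y) == length(pred))
  tp <- sum(y == 1 & pred == 1)
  fp <- sum(y == 0 & pred == 1)
  tn <- sum(y == 0 & pred == 0)
  fn <- sum(y == 1 & pred == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / length(y), precision = precision,
       recall = recall, f1 = f1, degenerate = (tp + fp) == 0)
}

#' Evaluate a classifier on a labeled table
#'
#' Predicts with a fixed 0.5 probability threshold and reports the confusion
#' matrix plus accuracy, precision, recall and F1 under the named prevalence
#' regime. Undefined ratios (no positive predictions) are reported as 0 with
#' the `degenerate` flag set, so a collapsed all-negative classifier is
#' visible rather than an exception.
#'
#' @param model A trained model with a [predict()] method returning
#'   positive-class probabilities.
#' @param table Labeled data (data frame with `ES`, or an
#'   `augmented_dataset`).
#' @param regime Label for the evaluation regime, e.g. `"curated_test"` or
#'   `"production"`.
#' @param threshold Classification threshold (default 0.5).
#' @return An `eval_report` list.
#' @export
evaluate <- function(model, table, regime = "curated_test", threshold = 0.5) {
  df <- if (inherits(table, "augmented_dataset")) table$records else as.data.frame(table)
  if (nrow(df) == 0L) stopf("validation error: empty evaluation table")
  prob <- predict(model, df)
  m <- classification_metrics(df$ES, as.numeric(prob >= threshold))
  structure(c(list(regime = regime, n = nrow(df)), m), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation (%s, n = %d)\n", x$regime, x$n))
  cat(sprintf("  confusion: TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f%s\n",
              x$accuracy, x$precision, x$recall, x$f1,
              if (x$degenerate) "  [degenerate: no positive predictions]" else ""))
  invisible(x)
}

#' Seed-stability study
#'
#' Repeats classifier training under identical configuration but different
#' random initializations (training seeds) on a fixed prepared dataset, and
#' reports the per-seed metrics with their min/max ranges.
#'
#' @param config Pipeline configuration (see [default_pipeline_config()]);
#'   the data stages are run once with `config$seed`.
#' @param seeds Two or more training seeds.
#' @param data Optional pre-built output of the data stages (from
#'   [pipeline_data()]) to avoid regenerating it.
#' @return A `run_summary`: `reports` (per-seed), `failed` (seeds whose run
#'   errored), `range` (data frame of min/max per metric).
#' @export
stability_runs <- function(config, seeds, data = NULL) {
  if (length(seeds) < 2L) stopf("stability_runs needs at least 2 seeds")
  if (is.null(data)) data <- pipeline_data(config)
  reports <- list()
  failed <- integer(0)
  for (s in seeds) {
    rep <- tryCatch(pipeline_train_eval(data, config, train_seed = s)$test,
                    error = function(e) e)
    if (inherits(rep, "error")) {
      failed <- c(failed, s)
    } else {
      reports[[as.character(s)]] <- rep
    }
  }
  metrics <- c("accuracy", "precision", "recall", "f1")
  vals <- vapply(reports, function(r) unlist(r[metrics]), numeric(4L))
  rng <- data.frame(metric = metrics,
                    min = if (length(reports)) apply(vals, 1L, min) else NA_real_,
                    max = if (length(reports)) apply(vals, 1L, max) else NA_real_)
  structure(list(reports = reports, failed = failed, range = rng),
            class = "run_summary")
}

legal_param_range <- function(param) {
  switch(param,
    learning_rate = c(1e-6, 1),
    n_steps = c(1, 16),
    gamma = c(1e-4, 10),
    lambda_sparse = c(0, 1),
    batch_size = c(1, 4096),
    n_d = c(2, 256),
    n_a = c(2, 256),
    stopf("validation error: unknown parameter '%s'", param)
  )
}

#' Hyperparameter sensitivity sweep
#'
#' Re-trains the classifier once per candidate value of a single
#' hyperparameter, everything else (data, seed, remaining configuration)
#' fixed, and reports each run's test metrics together with the deltas
#' against the base configuration's run. All values are validated against
#' the parameter's legal range before any training starts.
#'
#' @param base_config Pipeline configuration.
#' @param param Name of the swept `tabnet_config` field.
#' @param values Values to sweep.
#' @param data Optional pre-built [pipeline_data()] output.
#' @return Data frame: one row per value with `accuracy`, `precision`,
#'   `recall`, `f1` and `delta_*` columns relative to the base run.
#' @export
sensitivity_sweep <- function(base_config, param, values, data = NULL) {
  rng <- legal_param_range(param)
  if (any(values < rng[1L] | values > rng[2L])) {
    stopf("validation error: %s values outside legal range [%g, %g]",
          param, rng[1L], rng[2L])
  }
  if (is.null(data)) data <- pipeline_data(base_config)
  run_with <- function(val) {
    cfg <- base_config
    cfg$tabnet[[param]] <- val
    cfg$tabnet <- do.call(tabnet_config, unclass(cfg$tabnet))
    pipeline_train_eval(data, cfg, train_seed = base_config$seed)$test
  }
  base_rep <- run_with(base_config$tabnet[[param]])
  metrics <- c("accuracy", "precision", "recall", "f1")
  rows <- lapply(values, function(v) {
    r <- run_with(v)
    out <- data.frame(value = v)
    for (m in metrics) {
      out[[m]] <- r[[m]]
      out[[paste0("delta_", m)]] <- r[[m]] - base_rep[[m]]
    }
    out
  })
  do.call(rbind, rows)
}
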