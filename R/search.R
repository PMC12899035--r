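# Seeded random search over the classifier hyperparameter space. Integer
# parameters are drawn uniformly, rate-like parameters log-uniformly.

#' Hyperparameter search space
#'
#' The searched ranges: decision width 8-64, attention width 8-64, decision
#' steps 3-10, prior relaxation 1e-3 to 1e-1, sparsity weight 1e-5 to 1e-1,
#' learning rate 1e-5 to 1e-1, batch size 16-128.
#'
#' @param n_trials Number of trials (default 50).
#' @return A `search_space` list of `c(lower, upper)` ranges.
#' @export
search_space <- function(n_trials = 50L) {
  sp <- list(n_d = c(8, 64), n_a = c(8, 64), n_steps = c(3, 10),
             gamma = c(1e-3, 1e-1), lambda_sparse = c(1e-5, 1e-1),
             learning_rate = c(1e-5, 1e-1), batch_size = c(16, 128),
             n_trials = as.integer(n_trials))
  for (nm in setdiff(names(sp), "n_trials")) {
    if (sp[[nm]][1L] >= sp[[nm]][2L]) stopf("invalid range for %s", nm)
  }
  structure(sp, class = "search_space")
}

sample_config <- function(space, epochs) {
  ri <- function(r) sample(seq(r[1L], r[2L]), 1L)
  rl <- function(r) exp(stats::runif(1L, log(r[1L]), log(r[2L])))
  tabnet_config(n_d = ri(space$n_d), n_a = ri(space$n_a),
                n_steps = ri(space$n_steps), gamma = rl(space$gamma),
                lambda_sparse = rl(space$lambda_sparse),
                learning_rate = rl(space$learning_rate),
                batch_size = ri(space$batch_size), epochs = epochs)
}

#' Random hyperparameter search
#'
#' Draws `space$n_trials` configurations from the search space and scores
#' each with `objective` (higher is better; by convention validation F1). A
#' failing trial is marked failed and the search continues. The full trial
#' log is returned and optionally persisted as CSV.
#'
#' @param objective Function taking a `tabnet_config` and returning a single
#'   numeric score.
#' @param space A [search_space()].
#' @param seed Integer seed.
#' @param epochs Epoch budget passed into each sampled config.
#' @param log_file Optional CSV path for the trial log.
#' @return List with `best_config`, `best_score`, `trials` (data frame with
#'   one row per trial: parameters, `score`, `failed`).
#' @export
hyperparameter_search <- function(objective, space = search_space(), seed = 1L,
                                  epochs = 20L, log_file = NULL) {
  if (!is_count(space$n_trials)) stopf("validation error: n_trials must be >= 1")
  with_seed(seed, {
    trials <- NULL
    best <- list(score = -Inf, config = NULL)
    for (k in seq_len(space$n_trials)) {
      cfg <- sample_config(space, epochs)
      score <- tryCatch(objective(cfg), error = function(e) NA_real_)
      failed <- is.na(score)
      trials <- rbind(trials, data.frame(
        trial = k, n_d = cfg$n_d, n_a = cfg$n_a, n_steps = cfg$n_steps,
        gamma = cfg$gamma, lambda_sparse = cfg$lambda_sparse,
        learning_rate = cfg$learning_rate, batch_size = cfg$batch_size,
        score = score, failed = failed))
      if (!failed && score > best$score) best <- list(score = score, config = cfg)
    }
    if (is.null(best$config)) stopf("all %d trials failed", space$n_trials)
    if (!is.null(log_file)) utils::write.csv(trials, log_file, row.names = FALSE)
    list(best_config = best$config, best_score = best$score, trials = trials)
  })
}
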