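# End-to-end orchestration: generate -> clean -> select -> augment -> train
# -> evaluate, with every intermediate artifact written to disk and a JSON
# run manifest recording seeds and stage timings.

#' Default pipeline configuration
#'
#' The calibrated study conditions at desk scale: a 12,800-record cohort at
#' cleaned-regime imbalance (200 planted positives, 1:63), light raw-export
#' messiness, relevance-based selection of the eight informative indicators
#' (autoencoder fixed at the selected latent dimensionality 3), diffusion
#' augmentation with the 1-duplicate / 4x-generated / 3x-negatives recipe,
#' and the tuned attentive-classifier configuration. The stratified
#' train/valid/test split is 64/16/20.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param outdir Artifact directory for [run_pipeline()] (default: a
#'   session-specific temporary directory).
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L, outdir = NULL) {
  list(
    seed = as.integer(seed),
    outdir = outdir %||% file.path(tempdir(), paste0("stabsense-run-", seed)),
    cohort = list(n_records = 12800L, prevalence = 200 / 12800),
    messiness = list(null_rate = 0.005, junk_rate = 0.002, label_as_text = TRUE),
    select = list(latent_dims = 3L, rank_threshold = 8, min_stats = 3,
                  ae = list(epochs = 30L)),
    diffusion = list(T = 1000L, schedule = "linear",
                     denoiser = list(epochs = 1000L, batch = 256L, lr = 1e-3),
                     mass_balance_tol = 0.5, min_records = 100L),
    recipe = list(duplicate = TRUE, gen_per_real = 4, neg_per_pos = 3),
    tabnet = tabnet_config(),
    split = c(train = 0.64, valid = 0.16, test = 0.20),
    eval = list(production = TRUE, production_n = 50000L,
                reuse_training = FALSE)
  )
}

validate_pipeline_config <- function(config) {
  need <- c("seed", "cohort", "select", "diffusion", "recipe", "tabnet",
            "split", "eval")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    stopf("pre-flight validation error: missing stage config: %s",
          paste(miss, collapse = ", "))
  }
  invisible(config)
}

# Data stages shared by run_pipeline, stability_runs and sensitivity_sweep.
# Returns the cohort, the cleaned table, the selected features, the
# augmented dataset and the stratified splits.
#' @rdname run_pipeline
#' @export
pipeline_data <- function(config) {
  validate_pipeline_config(config)
  seed <- config$seed
  spec <- do.call(cohort_spec, c(config$cohort, list(seed = child_seed(seed, 1L))))
  cohort <- generate_cohort(spec)
  raw <- if (!is.null(config$messiness)) {
    inject_messiness(cohort, do.call(messiness_spec, config$messiness),
                     seed = child_seed(seed, 2L))
  } else cohort
  clean <- clean_table(raw)

  sel_cfg <- config$select
  report <- explicit_relevance(clean, seed = child_seed(seed, 3L))
  ae <- fit_autoencoder(clean, latent_dims = sel_cfg$latent_dims,
                        train_config = sel_cfg$ae %||% list(),
                        seed = child_seed(seed, 4L))
  lat <- latent_report(ae, clean)
  features <- select_features(report, lat,
                              policy = list(rank_threshold = sel_cfg$rank_threshold %||% 8,
                                            min_stats = sel_cfg$min_stats %||% 3))

  dcfg <- config$diffusion
  schedule <- make_schedule(dcfg$T %||% 1000L, dcfg$schedule %||% "linear")
  pos <- clean[clean$ES == 1, , drop = FALSE]
  neg <- clean[clean$ES == 0, , drop = FALSE]
  den_args <- utils::modifyList(list(hidden = c(128, 128)), dcfg$denoiser %||% list())
  denoiser <- train_denoiser(pos, features = features,
                             cfg = do.call(denoiser_config, den_args),
                             schedule = schedule, seed = child_seed(seed, 5L),
                             min_records = dcfg$min_records %||% 100L)
  cset <- constraint_set(positive_features = features,
                         mass_balance_tol = dcfg$mass_balance_tol %||% 0.5)
  n_gen <- round((config$recipe$gen_per_real %||% 4) * nrow(pos))
  gen <- rejection_sample(denoiser, n_gen, cset, seed = child_seed(seed, 6L))
  aug <- compose_augmented(pos, gen$records, neg, recipe = config$recipe,
                           seed = child_seed(seed, 7L))

  idx <- stratified_split(aug$records$ES, config$split, seed = child_seed(seed, 8L))
  list(spec = spec, cohort = cohort, raw = raw, clean = clean,
       relevance = report, autoencoder = ae, latent = lat,
       features = features, schedule = schedule, denoiser = denoiser,
       generated = gen, augmented = aug,
       splits = lapply(idx, function(i) aug$records[i, , drop = FALSE]))
}

# Train on the prepared splits and evaluate the held-out test portion (plus,
# optionally, a freshly generated production-prevalence cohort).
#' @rdname run_pipeline
#' @export
pipeline_train_eval <- function(data, config, train_seed = config$seed) {
  model <- train_tabnet(data$splits$train, data$splits$valid,
                        cfg = config$tabnet, seed = train_seed,
                        features = data$features)
  out <- list(model = model,
              test = evaluate(model, data$splits$test, regime = "curated_test"))
  ev <- config$eval %||% list()
  if (isTRUE(ev$production)) {
    prod_spec <- cohort_spec(
      n_records = ev$production_n %||% 50000L,
      prevalence = prevalence_regimes()[["production"]],
      profiles = config$cohort$profiles %||% default_profiles(),
      seed = child_seed(train_seed, 9L))
    out$production <- evaluate(model, generate_cohort(prod_spec),
                               regime = "production")
  }
  if (isTRUE(ev$reuse_training)) {
    out$production_reuse <- evaluate(model, data$augmented$records,
                                     regime = "production_reuse")
  }
  out
}

#' Run the full soft-sensing pipeline
#'
#' Executes generate -> clean -> select -> augment -> train -> evaluate,
#' writing every intermediate artifact (raw and cleaned CSVs, relevance
#' report, selected features, augmented dataset, classifier checkpoint,
#' evaluation reports) plus a JSON manifest with seeds, stage durations and
#' package version into `config$outdir`. Re-running with the same
#' configuration reproduces all reports. A stage failure aborts with the
#' stage name; artifacts written so far are left in place.
#'
#' @param config Configuration list, see [default_pipeline_config()].
#' @return Invisibly, a `pipeline_result` with the reports, selected
#'   features, model and artifact paths.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  validate_pipeline_config(config)
  outdir <- config$outdir %||% file.path(tempdir(), "stabsense-run")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, package_version = as.character(
    utils::packageVersion("stabsense")), stages = list())
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tic <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(seconds = as.numeric(Sys.time() - tic, units = "secs"))
    res
  }

  data <- stage("data", pipeline_data(config))
  utils::write.csv(data$raw, file.path(outdir, "cohort_raw.csv"), row.names = FALSE)
  write_clean_csv(data$clean, file.path(outdir, "clean.csv"))
  utils::write.csv(as.data.frame(data$relevance),
                   file.path(outdir, "relevance.csv"), row.names = FALSE)
  jsonlite::write_json(data$features, file.path(outdir, "features.json"))
  utils::write.csv(data$augmented$records, file.path(outdir, "augmented.csv"),
                   row.names = FALSE)

  fit <- stage("train_eval", pipeline_train_eval(data, config))
  save_tabnet_json(fit$model, file.path(outdir, "tabnet_checkpoint.json"))
  reports <- fit[setdiff(names(fit), "model")]
  jsonlite::write_json(lapply(reports, unclass),
                       file.path(outdir, "eval_reports.json"), auto_unbox = TRUE,
                       digits = NA)

  manifest$total_seconds <- as.numeric(Sys.time() - t0, units = "secs")
  manifest$features <- data$features
  manifest$counts <- data$augmented[c("n_real_pos", "n_dup_pos", "n_gen_pos",
                                      "n_pos_total", "n_neg")]
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(structure(list(outdir = outdir, features = data$features,
                           model = fit$model, reports = reports,
                           counts = manifest$counts),
                      class = "pipeline_result"))
}

#' Save / load an attentive-classifier checkpoint as JSON
#'
#' Self-describing text checkpoint: configuration, feature scalers and all
#' parameter arrays.
#'
#' @param model A `tabnet_model`.
#' @param path File path.
#' @return `save_tabnet_json` returns `path` invisibly; `load_tabnet_json`
#'   the restored `tabnet_model`.
#' @export
save_tabnet_json <- function(model, path) {
  x <- model[c("params", "cfg", "features", "center", "scale", "best_epoch")]
  x$cfg <- unclass(x$cfg)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_tabnet_json
#' @export
load_tabnet_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  cfg <- do.call(tabnet_config, x$cfg)
  remat <- function(m) if (is.matrix(m)) m else matrix(m, nrow = 1L)
  walk <- function(prm) {
    if (is.list(prm) && all(c("W", "b") %in% names(prm))) {
      list(W = remat(prm$W), b = as.numeric(prm$b))
    } else lapply(prm, walk)
  }
  params <- walk(x$params)
  structure(list(params = params, cfg = cfg, features = x$features,
                 center = stats::setNames(as.numeric(x$center), x$features),
                 scale = stats::setNames(as.numeric(x$scale), x$features),
                 best_epoch = x$best_epoch, history = NULL),
            class = "tabnet_model")
}
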