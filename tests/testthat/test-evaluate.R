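# A model-free classifier stub for metric tests.
const_model <- structure(list(prob = 0), class = "const_model")
predict.const_model <- function(object, newdata, ...) rep(object$prob, nrow(newdata))
registerS3method("predict", "const_model", predict.const_model)

# Prepared data + config for stability/sensitivity runs without re-running
# the generative stages: a curated-prevalence cohort split 64/16/20.
prepared_eval_data <- function(n = 2500, seed = 19) {
  co <- small_cohort(n = n, prevalence = 0.2, seed = seed)
  idx <- stabsense:::stratified_split(co$ES, seed = seed + 1)
  list(features = informative_indicators(),
       splits = lapply(idx, function(i) as.data.frame(co)[i, , drop = FALSE]),
       augmented = list(records = as.data.frame(co)))
}

eval_config <- function(epochs = 12L, seed = 1L) {
  cfg <- default_pipeline_config(seed = seed)
  cfg$tabnet <- tiny_tabnet_cfg(n_d = 16, epochs = epochs, batch_size = 58,
                                learning_rate = 0.012, n_steps = 3)
  cfg$eval$production <- FALSE
  cfg
}

test_that("metrics match the confusion arithmetic, including degenerate cases", {
  y <- c(rep(1, 10), rep(0, 90))
  pred <- c(rep(1, 9), 0, rep(1, 7), rep(0, 83))
  m <- classification_metrics(y, pred)
  expect_equal(m$tp, 9); expect_equal(m$fn, 1)
  expect_equal(m$fp, 7); expect_equal(m$tn, 83)
  expect_equal(m$recall, 0.9)
  expect_equal(m$precision, 0.5625)
  expect_equal(m$accuracy, 0.92)

  perfect <- classification_metrics(y, y)
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  # all-negative predictor on a 0.0928%-prevalence cohort
  co <- generate_cohort(cohort_spec(n_records = 10000,
                                    prevalence = prevalence_regimes()[["production"]],
                                    seed = 23))
  rep <- evaluate(const_model, co, regime = "production")
  expect_gt(rep$accuracy, 0.99)
  expect_equal(rep$recall, 0)
  expect_true(rep$degenerate)
  expect_error(evaluate(const_model, co[0, ], "production"), "empty")
})

test_that("metric formulas agree with a brute-force recount", {
  set.seed(25)
  for (k in 1:50) {
    n <- sample(5:200, 1)
    y <- rbinom(n, 1, runif(1, 0.05, 0.95))
    pred <- rbinom(n, 1, runif(1))
    m <- classification_metrics(y, pred)
    o <- recount_metrics(y, pred)
    for (f in names(o)) expect_equal(m[[f]], o[[f]])
    expect_equal(m$tp + m$fp + m$tn + m$fn, n)
  }
})

test_that("precision degrades with prevalence at fixed classifier quality", {
  # fixed sensitivity/specificity, prevalence drops curated -> production
  set.seed(26)
  sens <- 0.9; spec <- 0.99
  prec_at <- function(prev, n = 200000) {
    y <- rbinom(n, 1, prev)
    pred <- ifelse(y == 1, rbinom(n, 1, sens), rbinom(n, 1, 1 - spec))
    classification_metrics(y, pred)$precision
  }
  p_cur <- prec_at(prevalence_regimes()[["curated"]])
  p_prod <- prec_at(prevalence_regimes()[["production"]])
  expect_gt(p_cur, 0.9)
  expect_lt(p_prod, 0.1)
})

test_that("stability runs: determinism, range bookkeeping, and failure marking", {
  data <- prepared_eval_data()
  cfg <- eval_config()
  rs <- stability_runs(cfg, seeds = c(31, 32, 33), data = data)
  expect_length(rs$reports, 3)
  recalls <- vapply(rs$reports, function(r) r$recall, numeric(1))
  rng <- rs$range
  expect_equal(rng$min[rng$metric == "recall"], min(recalls))
  expect_equal(rng$max[rng$metric == "recall"], max(recalls))
  expect_true(all(rng$min <= rng$max))
  # recall spread across seeds stays narrow on the calibrated cohort
  expect_lt(diff(range(recalls)), 0.05)

  # identical seeds give zero-width ranges
  rs2 <- stability_runs(cfg, seeds = c(31, 31), data = data)
  expect_equal(rs2$range$min, rs2$range$max)

  # runs that cannot train are marked failed without aborting the study
  bad <- data
  bad$splits$train <- bad$splits$train[bad$splits$train$ES == 0, ]
  rs3 <- stability_runs(cfg, seeds = c(1, 2), data = bad)
  expect_equal(rs3$failed, c(1, 2))
  expect_length(rs3$reports, 0)
})

test_that("sensitivity sweeps validate inputs first and report small deltas", {
  data <- prepared_eval_data()
  cfg <- eval_config()
  # illegal value rejected before any training
  expect_error(sensitivity_sweep(cfg, "learning_rate", c(0.01, 10), data = data),
               "legal range")
  expect_error(sensitivity_sweep(cfg, "nonsense", 1, data = data), "unknown parameter")

  # degenerate single-value sweep: one row, zero delta
  sw0 <- sensitivity_sweep(cfg, "learning_rate", cfg$tabnet$learning_rate, data = data)
  expect_equal(nrow(sw0), 1)
  expect_equal(sw0$delta_accuracy, 0)
  expect_equal(sw0$delta_f1, 0)

  # learning rate 0.008-0.016: accuracy moves by < 1.5 points
  sw <- sensitivity_sweep(cfg, "learning_rate", c(0.008, 0.012, 0.016), data = data)
  expect_lt(max(abs(sw$delta_accuracy)), 0.015)

  # decision steps 2-5: accuracy moves by < 2 points
  sw2 <- sensitivity_sweep(cfg, "n_steps", 2:5, data = data)
  expect_lt(max(abs(sw2$delta_accuracy)), 0.02)
})

test_that("the end-to-end pipeline writes all artifacts and reproduces itself", {
  cfg <- default_pipeline_config(seed = 77, outdir = withr::local_tempdir())
  cfg$cohort <- list(n_records = 2000L, prevalence = 0.05)
  cfg$messiness <- list(null_rate = 0.002, junk_rate = 0.001, label_as_text = TRUE)
  cfg$select <- list(latent_dims = 3L, rank_threshold = 8, min_stats = 3,
                     ae = list(epochs = 10L))
  cfg$diffusion <- list(T = 100L, denoiser = list(epochs = 150L, hidden = c(64, 64)),
                        min_records = 50L)
  cfg$tabnet <- tiny_tabnet_cfg(epochs = 10L)
  cfg$eval <- list(production = TRUE, production_n = 4000L)
  res <- run_pipeline(cfg)
  for (f in c("cohort_raw.csv", "clean.csv", "relevance.csv", "features.json",
              "augmented.csv", "tabnet_checkpoint.json", "eval_reports.json",
              "manifest.json")) {
    expect_true(file.exists(file.path(cfg$outdir, f)), label = f)
  }
  expect_equal(res$counts$n_pos_total,
               res$counts$n_real_pos + res$counts$n_dup_pos + res$counts$n_gen_pos)
  # production regime: precision collapses relative to the curated test set
  expect_lte(res$reports$production$precision, res$reports$test$precision)

  cfg2 <- cfg
  cfg2$outdir <- withr::local_tempdir()
  res2 <- run_pipeline(cfg2)
  expect_equal(res2$reports$test[c("accuracy", "precision", "recall", "f1")],
               res$reports$test[c("accuracy", "precision", "recall", "f1")])

  # pre-flight validation
  broken <- cfg
  broken$diffusion <- NULL
  expect_error(run_pipeline(broken), "pre-flight")
})
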