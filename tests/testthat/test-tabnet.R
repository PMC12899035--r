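test_that("analytic gradients match central finite differences", {
  set.seed(42)
  p <- 3; n <- 6
  cfg <- tabnet_config(n_d = 4, n_a = 3, n_steps = 3, gamma = 1.3,
                       lambda_sparse = 0.02, learning_rate = 0.01,
                       batch_size = 4, epochs = 1)
  params <- stabsense:::tabnet_init(p, cfg)
  X <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, 0.5)
  lossfn <- function(prm) {
    stabsense:::tabnet_loss(stabsense:::tabnet_fwd(prm, X, cfg), y, cfg)
  }
  fw <- stabsense:::tabnet_fwd(params, X, cfg, keep_cache = TRUE)
  dl <- (stabsense:::sigmoid(fw$logits) - y) / n
  g <- stabsense:::tabnet_bwd(params, cfg, fw, dl)

  assign_arr <- function(l, pth, v) {
    if (length(pth) == 1) { l[[pth[[1]]]] <- v; l }
    else { l[[pth[[1]]]] <- assign_arr(l[[pth[[1]]]], pth[-1], v); l }
  }
  get_arr <- function(l, pth) Reduce(function(a, i) a[[i]], pth, l)
  paths <- list(list("out", "W"), list("shared", "s1", "W"),
                list("shared", "s2", "W"), list("steps", 1L, "t1", "W"),
                list("steps", 2L, "t2", "W"), list("steps", 4L, "t1", "W"),
                list("att", 1L, "W"), list("att", 2L, "b"), list("att", 3L, "W"))
  for (path in paths) {
    arr <- get_arr(params, path)
    garr <- get_arr(g, path)
    for (i in sample(length(arr), min(4, length(arr)))) {
      h <- 1e-5
      a1 <- arr; a1[i] <- a1[i] + h
      a2 <- arr; a2[i] <- a2[i] - h
      num <- (lossfn(assign_arr(params, path, a1)) -
                lossfn(assign_arr(params, path, a2))) / (2 * h)
      expect_lt(abs(num - garr[i]) / max(1e-6, abs(num) + abs(garr[i])), 1e-4)
    }
  }
})

test_that("forward-pass invariants: masks, importance, instance independence", {
  set.seed(15)
  df <- data.frame(ES = rbinom(40, 1, 0.4), a = rnorm(40), b = rnorm(40), c = rnorm(40))
  cfg <- tiny_tabnet_cfg(n_steps = 3, epochs = 2)
  m <- train_tabnet(df, NULL, cfg, seed = 1, features = c("a", "b", "c"))
  fw <- tabnet_forward(df, m)
  for (M in fw$masks) {
    expect_true(all(M >= 0))
    expect_equal(rowSums(M), rep(1, nrow(df)), tolerance = 1e-6)
  }
  expect_equal(sum(fw$aggregate_importance), 1, tolerance = 1e-6)
  expect_gte(fw$sparsity, 0)

  # single decision step: aggregate importance is that step's mean mask
  m1 <- train_tabnet(df, NULL, tiny_tabnet_cfg(n_steps = 1, epochs = 2),
                     seed = 1, features = c("a", "b", "c"))
  fw1 <- tabnet_forward(df, m1)
  mm <- colMeans(fw1$masks[[1]])
  expect_equal(unname(fw1$aggregate_importance), unname(mm / sum(mm)), tolerance = 1e-12)

  # duplicating a sample cannot change its logit
  df2 <- df[c(1, 1:nrow(df)), ]
  fw2 <- tabnet_forward(df2, m)
  expect_equal(fw2$logits[1], fw2$logits[2], tolerance = 1e-12)
  expect_equal(fw2$logits[1], fw$logits[1], tolerance = 1e-12)
})

test_that("training separates a separable toy and is seed-deterministic", {
  toy <- separable_toy(300)
  cfg <- tiny_tabnet_cfg(epochs = 30)
  m <- train_tabnet(toy, NULL, cfg, seed = 2, features = c("a", "b"))
  acc <- mean((predict(m, toy) >= 0.5) == toy$ES)
  expect_gte(acc, 0.99)

  val <- separable_toy(100, seed = 8)
  ma <- train_tabnet(toy, val, cfg, seed = 5, features = c("a", "b"))
  mb <- train_tabnet(toy, val, cfg, seed = 5, features = c("a", "b"))
  expect_identical(ma$history$valid_f1, mb$history$valid_f1)
  expect_identical(predict(ma, val), predict(mb, val))

  # informative feature dominates the aggregate importance, and its one-hot
  # masks drive the sparsity penalty to ~0
  fw <- tabnet_forward(toy, m)
  expect_equal(names(which.max(fw$aggregate_importance)), "a")
  expect_gt(fw$aggregate_importance[["a"]], 0.5)

  expect_error(train_tabnet(toy[toy$ES == 0, ], NULL, cfg, features = c("a", "b")),
               "single class")
})

test_that("checkpoints round-trip through JSON", {
  toy <- separable_toy(120)
  m <- train_tabnet(toy, NULL, tiny_tabnet_cfg(epochs = 5), seed = 3,
                    features = c("a", "b"))
  f <- withr::local_tempfile(fileext = ".json")
  save_tabnet_json(m, f)
  m2 <- load_tabnet_json(f)
  expect_equal(predict(m2, toy), predict(m, toy), tolerance = 1e-12)
})

test_that("random search respects bounds, bookkeeping, and trial failures", {
  sp <- search_space(n_trials = 30)
  # deterministic cheap objective: prefer learning rates near 1e-3
  obj <- function(cfg) -abs(log10(cfg$learning_rate) + 3)
  res <- hyperparameter_search(obj, sp, seed = 4)
  tr <- res$trials
  expect_equal(nrow(tr), 30)
  expect_true(all(tr$learning_rate >= 1e-5 & tr$learning_rate <= 1e-1))
  expect_true(all(tr$n_d >= 8 & tr$n_d <= 64))
  expect_true(all(tr$n_steps >= 3 & tr$n_steps <= 10))
  expect_true(all(tr$batch_size >= 16 & tr$batch_size <= 128))
  expect_equal(res$best_score, max(tr$score, na.rm = TRUE))
  expect_equal(res$best_config$learning_rate,
               tr$learning_rate[which.max(tr$score)])

  # singleton search returns that trial's config
  res1 <- hyperparameter_search(obj, search_space(n_trials = 1), seed = 4)
  expect_equal(nrow(res1$trials), 1)
  expect_equal(res1$best_score, res1$trials$score[1])

  # failing trials are marked and skipped, the search continues
  obj_flaky <- function(cfg) if (cfg$n_steps %% 2 == 0) stop("boom") else 1
  resf <- hyperparameter_search(obj_flaky, search_space(n_trials = 10), seed = 4)
  expect_true(any(resf$trials$failed))
  expect_equal(resf$best_score, 1)
})

test_that("baselines: GBDT separates, MLP collapses under extreme imbalance", {
  toy <- separable_toy(300)
  gb <- train_baselines(toy, kind = "gbdt", seed = 1, features = c("a", "b"),
                        config = list(nrounds = 50))
  expect_gte(mean((predict(gb, toy) >= 0.5) == toy$ES), 0.99)

  # 0.0928%-prevalence cohort with substantial class overlap (0.5 sd planted
  # shifts), no augmentation: the unweighted cross-entropy optimum is the
  # all-negative strategy, so the MLP collapses to it
  co <- generate_cohort(cohort_spec(n_records = 6000,
                                    prevalence = prevalence_regimes()[["production"]],
                                    profiles = default_profiles(effect_size = 0.5),
                                    seed = 17))
  ml <- train_baselines(co, kind = "mlp", seed = 1,
                        config = list(epochs = 30))
  rep <- evaluate(ml, co, regime = "production")
  expect_equal(rep$recall, 0)
  expect_true(rep$degenerate)
  expect_gt(rep$accuracy, 0.99)

  ml2 <- train_baselines(co, kind = "mlp", seed = 1, config = list(epochs = 30))
  expect_identical(predict(ml2, co), predict(ml, co))
})
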