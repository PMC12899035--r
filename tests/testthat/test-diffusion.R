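test_that("noise schedules satisfy their algebraic contracts", {
  s <- make_schedule(1, beta_end = 0.5)
  expect_equal(s$alpha_bar, 0.5) # single-step product
  expect_equal(s$alpha, 1 - s$beta)

  s <- make_schedule(1000)
  expect_true(all(diff(s$alpha_bar) < 0)) # strictly decreasing
  expect_lt(s$alpha_bar[1000], 1e-3)
  expect_equal(s$alpha_bar, cumprod(1 - s$beta))

  sc <- make_schedule(200, kind = "cosine")
  expect_true(all(sc$beta > 0 & sc$beta < 1))
  expect_true(all(diff(sc$alpha_bar) < 0))

  expect_error(make_schedule(0), "T")
  expect_error(make_schedule(-3), "T")
})

test_that("closed-form forward noising matches the hand example and its moments", {
  # two steps of beta = 0.5 give alpha_bar = 0.25
  s <- make_schedule(2, beta_start = 0.5, beta_end = 0.5)
  expect_equal(s$alpha_bar[2], 0.25)
  xt <- forward_noise(c(2, -2), 2, c(1, 1), s)
  expect_equal(xt, c(1 + sqrt(0.75), -1 + sqrt(0.75)))

  # degenerate limit: alpha_bar ~ 1 returns x0
  s1 <- make_schedule(1, beta_end = 1e-12)
  expect_equal(forward_noise(c(3, 4), 1, c(5, -5), s1), c(3, 4), tolerance = 1e-5)

  expect_error(forward_noise(1, 3, 0, s), "t must lie")

  # moments over many draws: mean -> sqrt(ab) x0, var -> 1 - ab
  s <- make_schedule(50)
  set.seed(4)
  draws <- replicate(10000, forward_noise(2, 25, rnorm(1), s))
  ab <- s$alpha_bar[25]
  expect_equal(mean(draws), sqrt(ab) * 2, tolerance = 4 * sqrt(1 - ab) / sqrt(10000) / (sqrt(ab) * 2))
  expect_equal(var(draws), 1 - ab, tolerance = 0.05)
})

test_that("the closed form equals iterated one-step noising", {
  # symbolic oracle: iterate x_t = sqrt(a_t) x_{t-1} + sqrt(1-a_t) eps_t and
  # track the coefficient on x0 and the accumulated noise variance
  set.seed(9)
  for (k in 1:5) {
    T <- sample(5:50, 1)
    s <- make_schedule(T, beta_start = runif(1, 1e-4, 0.01),
                       beta_end = runif(1, 0.02, 0.2))
    coef_x0 <- 1
    var_noise <- 0
    for (t in seq_len(T)) {
      coef_x0 <- sqrt(s$alpha[t]) * coef_x0
      var_noise <- s$alpha[t] * var_noise + (1 - s$alpha[t])
    }
    expect_equal(coef_x0, sqrt(s$alpha_bar[T]), tolerance = 1e-12)
    expect_equal(var_noise, 1 - s$alpha_bar[T], tolerance = 1e-12)

    # pathwise: the iterated path's effective noise plugged into the closed
    # form reproduces the path exactly
    x0 <- rnorm(3)
    x <- x0
    for (t in seq_len(T)) x <- sqrt(s$alpha[t]) * x + sqrt(1 - s$alpha[t]) * rnorm(3)
    eps_eff <- (x - sqrt(s$alpha_bar[T]) * x0) / sqrt(1 - s$alpha_bar[T])
    expect_equal(forward_noise(x0, T, eps_eff, s), x, tolerance = 1e-12)
  }
})

test_that("multinomial forward flattens one-hot distributions toward uniform", {
  s <- make_schedule(10, beta_start = 0.3, beta_end = 0.3)
  # K = 2 worked example: 0.5 * 1 + 0.5 * 0.5
  s5 <- make_schedule(1, beta_end = 0.5)
  expect_equal(multinomial_forward(c(1, 0), 1, s5), c(0.75, 0.25))

  # beta -> 0 leaves the distribution unchanged; beta -> 1 gives uniform
  s0 <- make_schedule(1, beta_end = 1e-12)
  expect_equal(multinomial_forward(c(0.2, 0.8), 1, s0), c(0.2, 0.8), tolerance = 1e-10)
  s1 <- make_schedule(1, beta_end = 1 - 1e-12)
  expect_equal(multinomial_forward(c(1, 0, 0), 1, s1), rep(1 / 3, 3), tolerance = 1e-10)

  # repeated composition converges to uniform
  p <- c(1, 0, 0, 0)
  for (i in 1:200) p <- multinomial_forward(p, 1, s)
  expect_lt(max(abs(p - 0.25)), 1e-6)
  expect_equal(sum(p), 1)
  expect_true(all(p >= 0))

  expect_error(multinomial_forward(c(1), 1, s), "K")
  expect_error(multinomial_forward(c(0.5, 0.2), 1, s), "probability")
})

test_that("the denoiser recovers a toy joint distribution and trains deterministically", {
  sch <- make_schedule(50)
  cfg <- denoiser_config(hidden = c(64, 64), epochs = 300, batch = 128)
  set.seed(2)
  df <- data.frame(u = rnorm(400, 5, 2), v = rnorm(400, -3, 0.5))
  stats <- sapply(1:3, function(s) {
    m <- train_denoiser(df, features = c("u", "v"), cfg = cfg, schedule = sch, seed = s)
    g <- with_seed(100 + s, stabsense:::reverse_sample(m, 800))
    c(mean(g$u), sd(g$u), mean(g$v), sd(g$v))
  })
  med <- apply(stats, 1, median)
  expect_lt(abs(med[1] - 5) / 5, 0.1)
  expect_lt(abs(med[2] - 2) / 2, 0.1)
  expect_lt(abs(med[3] - (-3)) / 3, 0.1)
  expect_lt(abs(med[4] - 0.5) / 0.5, 0.1)

  # optimization sanity and seeded determinism
  cfg_s <- denoiser_config(hidden = c(32, 32), epochs = 60, batch = 128)
  m1 <- train_denoiser(df, features = c("u", "v"), cfg = cfg_s, schedule = sch, seed = 7)
  m2 <- train_denoiser(df, features = c("u", "v"), cfg = cfg_s, schedule = sch, seed = 7)
  expect_identical(m1$net$W, m2$net$W)
  ma <- stats::filter(m1$losses, rep(1 / 5, 5), sides = 1)
  expect_lt(ma[50], ma[5])
  expect_error(train_denoiser(df[1:20, ], features = c("u", "v"), cfg = cfg_s,
                              schedule = sch, min_records = 100), "at least 100")
})

test_that("the categorical path generates valid one-hot-decoded levels", {
  # multinomial diffusion needs a noise-complete schedule (beta large near
  # T) for the chain to mix; the cosine schedule provides that
  sch <- make_schedule(50, kind = "cosine")
  set.seed(3)
  df <- data.frame(u = rnorm(300, 2, 1), AD1 = rbinom(300, 1, 0.8))
  m <- train_denoiser(df, features = "u", cat_features = "AD1",
                      cfg = denoiser_config(hidden = c(32, 32), epochs = 200, batch = 128),
                      schedule = sch, seed = 5)
  g <- with_seed(9, stabsense:::reverse_sample(m, 300))
  expect_true(all(g$AD1 %in% c(0, 1)))
  # the learned marginal should be closer to 0.8 than to the uniform 0.5
  expect_gt(mean(g$AD1), 0.65)
})

test_that("constraint checks accept compositionally valid records only", {
  expect_true(check_constraints(
    data.frame(Protein = 3.2, TS = 12.6, SNF = 8.7, Fat = 4.0, Acidity = 13,
               Lactose = 4.7, RD = 1.03, MTemp = 6)))
  expect_false(check_constraints(
    data.frame(Protein = 3.2, TS = 13.5, SNF = 8.7, Fat = 4.0, Acidity = 13,
               Lactose = 4.7, RD = 1.03, MTemp = 6))) # residual 0.8 > 0.5
  expect_false(check_constraints(
    data.frame(Protein = -0.01, TS = 12.6, SNF = 8.7, Fat = 4.0, Acidity = 13,
               Lactose = 4.7, RD = 1.03, MTemp = 6))) # strict positivity
  expect_error(check_constraints(data.frame(TS = 1, Fat = 1)), "schema error")
  expect_error(constraint_set(mass_balance_tol = -1), "mass_balance_tol")
})

test_that("rejection sampling returns exactly the quota, all records feasible", {
  co <- small_cohort(n = 1200, prevalence = 0.15, seed = 21)
  pos <- co[co$ES == 1, ]
  sch <- make_schedule(100)
  m <- train_denoiser(pos, cfg = denoiser_config(hidden = c(64, 64), epochs = 200),
                      schedule = sch, seed = 2, min_records = 50)
  g <- rejection_sample(m, 60, seed = 4)
  expect_equal(nrow(g$records), 60)
  expect_true(all(check_constraints(g$records)))
  expect_true(g$acceptance_rate > 0 && g$acceptance_rate <= 1)
  g2 <- rejection_sample(m, 60, seed = 4)
  expect_identical(g$records, g2$records)

  # infeasible tolerance fails with violation frequencies reported
  tight <- constraint_set(mass_balance_tol = 1e-9)
  expect_error(rejection_sample(m, 50, tight, seed = 1, max_attempts = 200),
               "mass-balance violations")
  expect_error(rejection_sample(m, 0), "n_target")
})

test_that("marginal fidelity is 1/0 for identical samples and ~0 for disjoint ones", {
  set.seed(6)
  a <- data.frame(x = rnorm(300))
  mf <- marginal_fidelity(a, a)
  expect_equal(mf$overlap, 1, tolerance = 1e-6)
  expect_equal(mf$ks, 0)
  b <- data.frame(x = rnorm(300) + 100)
  mf2 <- marginal_fidelity(a, b)
  expect_lt(mf2$overlap, 0.01)
  expect_equal(mf2$ks, 1)
  expect_error(marginal_fidelity(a[0, , drop = FALSE], b), "empty")
})

test_that("augmented composition follows the recipe arithmetic and conserves rows", {
  pos <- small_cohort(n = 60, prevalence = 0.5, seed = 31)
  pos <- pos[pos$ES == 1, ][1:10, ]
  neg <- small_cohort(n = 400, prevalence = 0.01, seed = 32)
  neg <- neg[neg$ES == 0, ]
  gen <- pos[rep(1:10, 4), ]

  aug <- compose_augmented(pos, gen, neg, seed = 5)
  expect_equal(aug$n_pos_total, 60) # 10 real + 10 dup + 40 generated
  expect_equal(aug$n_neg, 180)
  expect_equal(aug$n_pos_total + aug$n_neg, nrow(aug$records))
  expect_equal(sum(aug$records$ES), aug$n_pos_total)
  expect_identical(aug$records, compose_augmented(pos, gen, neg, seed = 5)$records)

  # identity composition: no duplicates, no generated records
  aug0 <- compose_augmented(pos, NULL, neg,
                            recipe = list(duplicate = FALSE, gen_per_real = 0))
  expect_equal(aug0$n_pos_total, nrow(pos))

  expect_error(compose_augmented(pos, gen, neg[1:50, ]), "composition error")
  expect_error(compose_augmented(pos, gen[1:13, ], neg), "composition error")
})
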