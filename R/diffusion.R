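# Constraint-aware tabular denoising diffusion. Continuous features follow
# the Gaussian forward process x_t = sqrt(alpha_t) x_{t-1} + sqrt(1-alpha_t) eps
# with the closed form x_t = sqrt(abar_t) x0 + sqrt(1-abar_t) eps; categorical
# features follow the multinomial process that flattens a one-hot vector
# toward the uniform distribution at rate beta_t. A small MLP predicts the
# injected noise (and categorical x0 logits) at each timestep; reverse
# ancestral sampling plus rejection of candidates violating positivity or the
# mass-balance tolerance yields physically plausible minority-class records.

#' Build a diffusion noise schedule
#'
#' @param T Number of timesteps (>= 1).
#' @param kind `"linear"` (beta linearly spaced between `beta_start` and
#'   `beta_end`) or `"cosine"` (squared-cosine cumulative schedule).
#' @param beta_start,beta_end Endpoints for the linear schedule.
#' @return A `diffusion_schedule` with `T`, `beta`, `alpha = 1 - beta` and
#'   `alpha_bar = cumprod(alpha)` (strictly decreasing, near 0 at `T` for the
#'   default `T = 1000`).
#' @export
make_schedule <- function(T = 1000, kind = c("linear", "cosine"),
                          beta_start = 1e-4, beta_end = 0.02) {
  kind <- match.arg(kind)
  if (!is_count(T)) stopf("validation error: T must be a positive integer")
  T <- as.integer(T)
  if (kind == "linear") {
    beta <- if (T == 1L) beta_end else seq(beta_start, beta_end, length.out = T)
  } else {
    s <- 0.008
    f <- function(t) cos((t / T + s) / (1 + s) * pi / 2)^2
    abar <- f(seq_len(T)) / f(0)
    beta <- pmin(1 - abar / c(1, abar[-T]), 0.999)
  }
  if (any(beta <= 0 | beta >= 1)) stopf("validation error: schedule produced beta outside (0, 1)")
  alpha <- 1 - beta
  structure(list(T = T, beta = beta, alpha = alpha, alpha_bar = cumprod(alpha)),
            class = "diffusion_schedule")
}

#' Closed-form forward noising of continuous features
#'
#' `x_t = sqrt(alpha_bar_t) * x0 + sqrt(1 - alpha_bar_t) * eps`, elementwise.
#'
#' @param x0 Numeric vector or matrix of (standardized) feature values.
#' @param t Timestep in `1:T`.
#' @param eps Standard-normal draw with the shape of `x0`.
#' @param schedule A [make_schedule()] object.
#' @return The noised values, same shape as `x0`.
#' @export
forward_noise <- function(x0, t, eps, schedule) {
  if (!is_count(t) || t > schedule$T) {
    stopf("index error: t must lie in 1..%d", schedule$T)
  }
  ab <- schedule$alpha_bar[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' One multinomial forward transition
#'
#' Categorical analogue of the Gaussian corruption: the distribution over the
#' `K` categories is mixed toward uniform,
#' `q(x_t | x_{t-1}) = Cat((1 - beta_t) x_{t-1} + beta_t / K)`.
#'
#' @param p Probability vector of length `K` (e.g. one-hot).
#' @param t Timestep in `1:T`.
#' @param schedule A [make_schedule()] object.
#' @return The transitioned probability vector (nonnegative, sums to 1).
#' @export
multinomial_forward <- function(p, t, schedule) {
  K <- length(p)
  if (K < 2L) stopf("validation error: K must be >= 2")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stopf("validation error: p must be a probability vector")
  }
  if (!is_count(t) || t > schedule$T) stopf("index error: t must lie in 1..%d", schedule$T)
  b <- schedule$beta[t]
  (1 - b) * p + b / K
}

# Cumulative multinomial marginal q(x_t | x0) = abar_t x0 + (1 - abar_t)/K,
# and the posterior q(x_{t-1} | x_t, x0) used during reverse sampling.
multinomial_marginal <- function(p, t, schedule) {
  ab <- schedule$alpha_bar[t]
  ab * p + (1 - ab) / length(p)
}

multinomial_posterior <- function(xt_onehot, x0_prob, t, schedule) {
  K <- length(x0_prob)
  b <- schedule$beta[t]
  ab_prev <- if (t > 1L) schedule$alpha_bar[t - 1L] else 1
  lik <- (1 - b) * xt_onehot + b / K
  pri <- ab_prev * x0_prob + (1 - ab_prev) / K
  w <- lik * pri
  w / sum(w)
}

#' Constraint set for generated records
#'
#' @param positive_features Features that must be strictly positive
#'   (defaults to the eight selected indicators).
#' @param mass_balance_tol Tolerance tau for `|TS - (Fat + SNF)| <= tau` in
#'   g/100 g units; must be positive (default 0.5).
#' @return A `constraint_set`.
#' @export
constraint_set <- function(positive_features = informative_indicators(),
                           mass_balance_tol = 0.5) {
  if (!is.numeric(mass_balance_tol) || mass_balance_tol <= 0) {
    stopf("validation error: mass_balance_tol must be > 0")
  }
  structure(list(positive_features = positive_features,
                 mass_balance_tol = mass_balance_tol),
            class = "constraint_set")
}

#' Check generated records against the physical-plausibility constraints
#'
#' A record passes when all selected feature values are strictly positive and
#' the compositional identity holds within tolerance,
#' `|TS - (Fat + SNF)| <= tau`.
#'
#' @param records Data frame (or single-row list) holding at least TS, Fat,
#'   SNF and the constrained features, in native units.
#' @param cset A [constraint_set()].
#' @return Logical vector, one entry per record.
#' @export
check_constraints <- function(records, cset = constraint_set()) {
  df <- as.data.frame(records)
  need <- unique(c(cset$positive_features, "TS", "Fat", "SNF"))
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("schema error: missing field(s): %s", paste(miss, collapse = ", "))
  pos_ok <- rep(TRUE, nrow(df))
  for (cl in cset$positive_features) pos_ok <- pos_ok & df[[cl]] > 0
  mb_ok <- abs(df$TS - (df$Fat + df$SNF)) <= cset$mass_balance_tol
  pos_ok & mb_ok
}

#' Denoiser training configuration
#'
#' @param hidden MLP hidden-layer widths.
#' @param temb_dim Sinusoidal timestep-embedding size.
#' @param epochs Training epochs (default 1000).
#' @param batch Batch size (default 256).
#' @param lr Initial AdamW learning rate (default 0.001), cosine-annealed.
#' @param weight_decay AdamW decoupled weight decay.
#' @return A `denoiser_config` list.
#' @export
denoiser_config <- function(hidden = c(128, 128), temb_dim = 16L,
                            epochs = 1000L, batch = 256L, lr = 1e-3,
                            weight_decay = 1e-4) {
  if (!is_count(epochs) || !is_count(batch)) {
    stopf("validation error: epochs and batch must be positive integers")
  }
  structure(list(hidden = hidden, temb_dim = as.integer(temb_dim),
                 epochs = as.integer(epochs), batch = as.integer(batch),
                 lr = lr, weight_decay = weight_decay),
            class = "denoiser_config")
}

# Sinusoidal timestep embedding, rows = timesteps in `t` (vector), scaled to
# [0, 1] by T.
timestep_embedding <- function(t, T, dim) {
  half <- dim %/% 2L
  freq <- exp(-log(1000) * (seq_len(half) - 1L) / max(1L, half - 1L))
  ang <- outer(t / T, freq * 1000)
  cbind(sin(ang), cos(ang))
}

#' Train the tabular diffusion denoiser
#'
#' Standardizes the continuous features (scalers stored for the inverse
#' transform), then trains an MLP that receives the noised features at a
#' uniformly drawn timestep plus a sinusoidal timestep embedding and predicts
#' the injected Gaussian noise (mean squared error). Binary/categorical
#' columns, when requested, are one-hot diffused with the multinomial process
#' and the network additionally predicts their original category
#' (cross-entropy head). Training uses AdamW with cosine-annealed learning
#' rate and is deterministic given the seed.
#'
#' @param positives Table of minority-class records (a `clean_table` or data
#'   frame).
#' @param features Continuous feature columns to model (default: the eight
#'   selected indicators).
#' @param cat_features Optional categorical/binary columns to model with the
#'   multinomial process (default none).
#' @param cfg A [denoiser_config()].
#' @param schedule A [make_schedule()] object.
#' @param seed Integer seed.
#' @param min_records Soft floor on the number of training records
#'   (default 100).
#' @return A `tabdiff_model`.
#' @export
train_denoiser <- function(positives, features = informative_indicators(),
                           cat_features = character(0),
                           cfg = denoiser_config(), schedule = make_schedule(),
                           seed = 1L, min_records = 100L) {
  df <- as.data.frame(positives)
  miss <- setdiff(c(features, cat_features), names(df))
  if (length(miss)) stopf("schema error: missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(df) < min_records) {
    stopf("need at least %d minority records to train the denoiser, got %d",
          min_records, nrow(df))
  }
  X <- as.matrix(df[, features, drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Z <- scale(X, center = ctr, scale = scl)
  p <- ncol(Z)

  cats <- lapply(cat_features, function(cl) sort(unique(df[[cl]])))
  names(cats) <- cat_features
  K_tot <- sum(vapply(cats, length, 1L))
  onehot <- NULL
  if (K_tot > 0) {
    onehot <- do.call(cbind, lapply(cat_features, function(cl) {
      stats::model.matrix(~ f - 1, data.frame(f = factor(df[[cl]], levels = cats[[cl]])))
    }))
  }

  in_dim <- p + K_tot + cfg$temb_dim
  out_dim <- p + K_tot
  with_seed(seed, {
    net <- nn_init(c(in_dim, cfg$hidden, out_dim))
    opt <- adam_new(list(W = net$W, b = net$b))
    n <- nrow(Z)
    losses <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      lr_ep <- cfg$lr * 0.5 * (1 + cos(pi * (ep - 1) / cfg$epochs))
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = cfg$batch)) {
        rows <- ord[start:min(start + cfg$batch - 1L, n)]
        m <- length(rows)
        t <- sample.int(schedule$T, m, replace = TRUE)
        ab <- schedule$alpha_bar[t]
        eps <- matrix(stats::rnorm(m * p), m, p)
        xt <- sqrt(ab) * Z[rows, , drop = FALSE] + sqrt(1 - ab) * eps
        inp <- cbind(xt, timestep_embedding(t, schedule$T, cfg$temb_dim))
        target_cat <- NULL
        if (K_tot > 0) {
          oh <- onehot[rows, , drop = FALSE]
          # per-block cumulative marginal, then a sampled noised one-hot
          noised <- matrix(0, m, K_tot)
          off <- 0L
          for (cl in cat_features) {
            K <- length(cats[[cl]])
            blk <- off + seq_len(K)
            qblk <- sweep(oh[, blk, drop = FALSE], 1L, ab, `*`) + (1 - ab) / K
            pick <- apply(qblk, 1L, function(pr) sample.int(K, 1L, prob = pr))
            noised[cbind(seq_len(m), off + pick)] <- 1
            off <- off + K
          }
          inp <- cbind(xt, noised, timestep_embedding(t, schedule$T, cfg$temb_dim))
          target_cat <- oh
        }
        fw <- nn_forward(net, inp, keep_cache = TRUE)
        pred_eps <- fw$out[, seq_len(p), drop = FALSE]
        err <- pred_eps - eps
        loss <- mean(err^2)
        dOut <- matrix(0, m, out_dim)
        dOut[, seq_len(p)] <- 2 * err / length(err)
        if (K_tot > 0) {
          off <- 0L
          for (cl in cat_features) {
            K <- length(cats[[cl]])
            blk <- p + off + seq_len(K)
            logits <- fw$out[, blk, drop = FALSE]
            logits <- logits - apply(logits, 1L, max)
            sm <- exp(logits); sm <- sm / rowSums(sm)
            tg <- target_cat[, off + seq_len(K), drop = FALSE]
            loss <- loss + mean(-rowSums(tg * log(sm + 1e-12)))
            dOut[, blk] <- (sm - tg) / m
            off <- off + K
          }
        }
        if (!is.finite(loss)) stopf("training error: non-finite loss at epoch %d", ep)
        bw <- nn_backward(net, fw$cache, dOut)
        prm <- adam_step(opt, list(W = net$W, b = net$b), list(W = bw$W, b = bw$b),
                         lr = lr_ep, weight_decay = cfg$weight_decay)
        net$W <- prm$W; net$b <- prm$b
        ep_loss <- ep_loss + loss; nb <- nb + 1L
      }
      losses[ep] <- ep_loss / nb
    }
    structure(list(net = net, schedule = schedule, features = features,
                   cat_features = cat_features, cats = cats,
                   center = ctr, scale = scl, cfg = cfg, losses = losses),
              class = "tabdiff_model")
  })
}

# Reverse ancestral sampling: draw n candidate records in native units.
reverse_sample <- function(model, n) {
  s <- model$schedule
  p <- length(model$features)
  K_tot <- sum(vapply(model$cats, length, 1L))
  x <- matrix(stats::rnorm(n * p), n, p)
  cat_oh <- NULL
  if (K_tot > 0) { # start categorical chains at uniform draws
    cat_oh <- matrix(0, n, K_tot)
    off <- 0L
    for (cl in model$cat_features) {
      K <- length(model$cats[[cl]])
      pick <- sample.int(K, n, replace = TRUE)
      cat_oh[cbind(seq_len(n), off + pick)] <- 1
      off <- off + K
    }
  }
  for (t in seq(s$T, 1L)) {
    temb <- timestep_embedding(rep(t, n), s$T, model$cfg$temb_dim)
    inp <- if (is.null(cat_oh)) cbind(x, temb) else cbind(x, cat_oh, temb)
    out <- nn_forward(model$net, inp)$out
    eps_hat <- out[, seq_len(p), drop = FALSE]
    a_t <- s$alpha[t]; b_t <- s$beta[t]; ab_t <- s$alpha_bar[t]
    mu <- (x - b_t / sqrt(1 - ab_t) * eps_hat) / sqrt(a_t)
    if (t > 1L) {
      ab_prev <- s$alpha_bar[t - 1L]
      sigma <- sqrt(b_t * (1 - ab_prev) / (1 - ab_t))
      x <- mu + sigma * matrix(stats::rnorm(n * p), n, p)
    } else {
      x <- mu
    }
    if (!is.null(cat_oh)) {
      off <- 0L
      new_oh <- cat_oh * 0
      for (cl in model$cat_features) {
        K <- length(model$cats[[cl]])
        blk <- p + off + seq_len(K)
        logits <- out[, blk, drop = FALSE]
        logits <- logits - apply(logits, 1L, max)
        x0p <- exp(logits); x0p <- x0p / rowSums(x0p)
        for (i in seq_len(n)) {
          post <- multinomial_posterior(cat_oh[i, off + seq_len(K)], x0p[i, ], t, s)
          pick <- if (t > 1L) sample.int(K, 1L, prob = post) else which.max(post)
          new_oh[i, off + pick] <- 1
        }
        off <- off + K
      }
      cat_oh <- new_oh
    }
  }
  rec <- sweep(sweep(x, 2L, model$scale, `*`), 2L, model$center, `+`)
  colnames(rec) <- model$features
  rec <- as.data.frame(rec)
  if (!is.null(cat_oh)) {
    off <- 0L
    for (cl in model$cat_features) {
      K <- length(model$cats[[cl]])
      idx <- max.col(cat_oh[, off + seq_len(K), drop = FALSE])
      rec[[cl]] <- model$cats[[cl]][idx]
      off <- off + K
    }
  }
  rec
}

#' Generate minority-class records under rejection sampling
#'
#' Runs reverse diffusion in batches and keeps only candidates that satisfy
#' the full [constraint_set()]; candidates violating either constraint are
#' discarded and regenerated until exactly `n_target` records pass.
#'
#' @param model A trained `tabdiff_model`.
#' @param n_target Number of records required (>= 1).
#' @param cset A [constraint_set()].
#' @param seed Integer seed.
#' @param max_attempts Cap on total candidates drawn (default
#'   `100 * n_target`); exceeding it raises a generation error reporting the
#'   violation frequencies per constraint.
#' @return A `generated_batch`: `records` (data frame in native units, all
#'   passing the constraints), `acceptance_rate`, `n_attempted`.
#' @export
rejection_sample <- function(model, n_target, cset = constraint_set(),
                             seed = 1L, max_attempts = 100 * n_target) {
  if (!is_count(n_target)) stopf("validation error: n_target must be >= 1")
  with_seed(seed, {
    kept <- NULL
    attempted <- 0L
    n_pos_fail <- 0L; n_mb_fail <- 0L
    while (is.null(kept) || nrow(kept) < n_target) {
      deficit <- n_target - if (is.null(kept)) 0L else nrow(kept)
      draw <- min(max(deficit + 16L, ceiling(deficit * 1.25)),
                  max(1L, max_attempts - attempted))
      cand <- reverse_sample(model, draw)
      attempted <- attempted + draw
      ok <- check_constraints(cand, cset)
      pos_ok <- rep(TRUE, nrow(cand))
      for (cl in intersect(cset$positive_features, names(cand))) {
        pos_ok <- pos_ok & cand[[cl]] > 0
      }
      n_pos_fail <- n_pos_fail + sum(!pos_ok)
      n_mb_fail <- n_mb_fail + sum(pos_ok & !ok)
      kept <- rbind(kept, cand[ok, , drop = FALSE])
      if (attempted >= max_attempts && nrow(kept) < n_target) {
        stopf(paste0("generation error: only %d/%d records accepted after %d attempts ",
                     "(positivity violations: %d, mass-balance violations: %d)"),
              nrow(kept), n_target, attempted, n_pos_fail, n_mb_fail)
      }
    }
    kept <- kept[seq_len(n_target), , drop = FALSE]
    rownames(kept) <- NULL
    structure(list(records = kept, acceptance_rate = n_target / attempted,
                   n_attempted = attempted), class = "generated_batch")
  })
}

#' Marginal fidelity of generated data
#'
#' Per-feature density-overlap coefficient (integral of the pointwise minimum
#' of the two kernel density estimates on a shared grid) and
#' Kolmogorov-Smirnov distance between generated and real samples. Both lie
#' in [0, 1]; identical samples give overlap 1 and KS 0.
#'
#' @param generated,real Data frames sharing the modelled feature columns.
#' @param features Columns to compare (default: intersection of names).
#' @return Data frame with `feature`, `overlap`, `ks`.
#' @export
marginal_fidelity <- function(generated, real, features = NULL) {
  g <- as.data.frame(generated); r <- as.data.frame(real)
  if (nrow(g) == 0L || nrow(r) == 0L) stopf("validation error: empty input")
  if (is.null(features)) features <- intersect(names(g), names(r))
  if (!length(features)) stopf("validation error: no shared feature columns")
  out <- data.frame(feature = features, overlap = NA_real_, ks = NA_real_)
  for (i in seq_along(features)) {
    x <- g[[features[i]]]; y <- r[[features[i]]]
    rng <- range(c(x, y))
    if (diff(rng) == 0) { # degenerate constant feature
      out$overlap[i] <- 1; out$ks[i] <- 0; next
    }
    grid <- seq(rng[1L] - 0.1 * diff(rng), rng[2L] + 0.1 * diff(rng), length.out = 512)
    dx <- stats::density(x, from = grid[1L], to = grid[512], n = 512)$y
    dy <- stats::density(y, from = grid[1L], to = grid[512], n = 512)$y
    step <- grid[2L] - grid[1L]
    out$overlap[i] <- min(1, sum(pmin(dx, dy)) * step)
    out$ks[i] <- unname(suppressWarnings(stats::ks.test(x, y)$statistic))
  }
  out
}

#' Compose the augmented training dataset
#'
#' Applies the augmentation recipe: every real positive appears twice (the
#' duplicate reinforces the true distribution against the synthetic mass),
#' generated positives number `gen_per_real` times the real positives, and
#' negatives are subsampled to `neg_per_pos` times the total positives. With
#' the study's counts (842 real positives) this yields
#' 842 + 842 + 3368 = 5052 positives and 15,156 negatives.
#'
#' @param real_pos Data frame of real positive records.
#' @param generated_pos Data frame of generated positive records (may have
#'   fewer columns; missing ones are filled with `NA`). Must number
#'   `gen_per_real * nrow(real_pos)` unless `check_recipe = FALSE`.
#' @param negatives Data frame of real negative records.
#' @param recipe List: `duplicate` (logical, default `TRUE`), `gen_per_real`
#'   (default 4), `neg_per_pos` (default 3).
#' @param seed Integer seed for negative subsampling and the final shuffle.
#' @param check_recipe Verify the generated count against the recipe.
#' @return An `augmented_dataset`: `records` (shuffled, with an `ES` column
#'   and a `source` column in `real_pos`/`dup_pos`/`gen_pos`/`neg`), plus the
#'   counts `n_real_pos`, `n_dup_pos`, `n_gen_pos`, `n_pos_total`, `n_neg`.
#' @export
compose_augmented <- function(real_pos, generated_pos, negatives,
                              recipe = list(), seed = 1L, check_recipe = TRUE) {
  rc <- utils::modifyList(list(duplicate = TRUE, gen_per_real = 4, neg_per_pos = 3),
                          recipe)
  real_pos <- as.data.frame(real_pos)
  generated_pos <- if (is.null(generated_pos)) real_pos[0, , drop = FALSE] else as.data.frame(generated_pos)
  negatives <- as.data.frame(negatives)
  n_real <- nrow(real_pos)
  n_gen <- nrow(generated_pos)
  if (check_recipe && n_gen != rc$gen_per_real * n_real) {
    stopf("composition error: recipe expects %d generated positives (%g x %d real), got %d",
          rc$gen_per_real * n_real, rc$gen_per_real, n_real, n_gen)
  }
  n_dup <- if (isTRUE(rc$duplicate)) n_real else 0L
  n_pos_total <- n_real + n_dup + n_gen
  n_neg <- round(rc$neg_per_pos * n_pos_total)
  if (nrow(negatives) < n_neg) {
    stopf("composition error: need %d negatives, only %d available", n_neg, nrow(negatives))
  }
  cols <- names(real_pos)
  pad <- function(df, src) {
    for (cl in setdiff(cols, names(df))) df[[cl]] <- NA
    df <- df[, cols, drop = FALSE]
    df$ES <- if (src == "neg") 0 else 1
    df$source <- src
    df
  }
  with_seed(seed, {
    neg <- negatives[sample.int(nrow(negatives), n_neg), , drop = FALSE]
    rec <- rbind(pad(real_pos, "real_pos"),
                 if (n_dup) pad(real_pos, "dup_pos"),
                 if (n_gen) pad(generated_pos, "gen_pos"),
                 pad(neg, "neg"))
    rec <- rec[sample.int(nrow(rec)), , drop = FALSE]
    rownames(rec) <- NULL
    structure(list(records = rec, n_real_pos = n_real, n_dup_pos = n_dup,
                   n_gen_pos = n_gen, n_pos_total = n_pos_total, n_neg = n_neg),
              class = "augmented_dataset")
  })
}
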