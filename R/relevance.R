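# Feature-relevance analyses: four explicit per-feature statistics (ANOVA F,
# point-biserial correlation, random-forest impurity importance, standardized
# logistic coefficient), the pairwise correlation heatmap matrix, an
# unsupervised autoencoder whose latent space is summarised per coordinate,
# and the selection policy that combines both views into the final feature
# set.

#' Explicit feature-relevance statistics
#'
#' For every indicator, computes the one-way ANOVA F statistic of the feature
#' against the binary label, the point-biserial correlation (group-mean
#' formula, numerically identical to Pearson correlation with the 0/1 coded
#' label), the normalized random-forest impurity importance, and the
#' absolute standardized logistic-regression coefficient from a joint fit on
#' z-scored features. Features with zero variance are flagged and receive
#' `NA` statistics rather than raising an error.
#'
#' @param clean A `clean_table` with both classes present (>= 2 records per
#'   class).
#' @param seed Integer seed; governs the random forest.
#' @param num_trees Number of forest trees (default 500).
#' @return A `relevance_report`: data frame with columns `feature`,
#'   `anova_f`, `pb_r`, `rf_importance`, `logit_coef`, `zero_variance`, plus
#'   the correlation matrix as attribute `corr_matrix`.
#' @export
explicit_relevance <- function(clean, seed = 1L, num_trees = 500) {
  df <- as.data.frame(clean)
  y <- df$ES
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    stopf("explicit_relevance needs at least 2 records in each class")
  }
  feats <- setdiff(names(df), "ES")
  X <- as.matrix(df[, feats, drop = FALSE])
  zero_var <- apply(X, 2L, stats::sd) == 0

  anova_f <- pb_r <- rep(NA_real_, length(feats))
  for (j in seq_along(feats)) {
    if (zero_var[j]) next
    x <- X[, j]
    anova_f[j] <- stats::anova(stats::lm(x ~ factor(y)))[["F value"]][1L]
    pb_r[j] <- point_biserial(x, y)
  }

  rf_importance <- rep(NA_real_, length(feats))
  rf_df <- data.frame(y = factor(y), X[, !zero_var, drop = FALSE])
  fit <- ranger::ranger(y ~ ., data = rf_df, num.trees = num_trees,
                        importance = "impurity", seed = as.integer(seed),
                        num.threads = 1L)
  imp <- fit$variable.importance
  rf_importance[!zero_var] <- imp[feats[!zero_var]] / sum(imp)

  logit_coef <- rep(NA_real_, length(feats))
  Z <- scale(X[, !zero_var, drop = FALSE])
  gfit <- suppressWarnings(
    stats::glm(y ~ ., data = data.frame(y = y, Z), family = stats::binomial())
  )
  co <- stats::coef(gfit)[-1L]
  logit_coef[!zero_var] <- unname(co[paste0(feats[!zero_var])])

  rep_df <- data.frame(feature = feats, anova_f = anova_f, pb_r = pb_r,
                       rf_importance = rf_importance, logit_coef = logit_coef,
                       zero_variance = zero_var, row.names = NULL)
  attr(rep_df, "corr_matrix") <- pairwise_correlations(clean)
  class(rep_df) <- c("relevance_report", "data.frame")
  rep_df
}

# Point-biserial correlation via the group-mean formula
# r = (m1 - m0)/s_n * sqrt(n1*n0/n^2), with the population (1/n) standard
# deviation. Equals Pearson correlation against the 0/1 label.
point_biserial <- function(x, y) {
  n <- length(x)
  n1 <- sum(y == 1)
  n0 <- n - n1
  s_n <- sqrt(sum((x - mean(x))^2) / n)
  if (s_n == 0) return(NA_real_)
  (mean(x[y == 1]) - mean(x[y == 0])) / s_n * sqrt(n1 * n0 / n^2)
}

#' Pairwise Pearson correlations between continuous indicators
#'
#' Symmetric with a unit diagonal; rows/columns of constant features are set
#' to `NA` (diagonal kept at 1) instead of raising.
#'
#' @param clean A `clean_table` (or numeric data frame) with >= 3 records.
#' @return Correlation matrix over the continuous indicator columns.
#' @export
pairwise_correlations <- function(clean) {
  df <- as.data.frame(clean)
  feats <- setdiff(names(df), c("ES", "AD1", "AD2"))
  X <- as.matrix(df[, feats, drop = FALSE])
  if (nrow(X) < 3L) stopf("pairwise_correlations needs at least 3 records")
  cc <- suppressWarnings(stats::cor(X))
  diag(cc) <- 1
  cc
}

# ---- Autoencoder ----------------------------------------------------------

#' Fit an autoencoder and select the latent dimensionality
#'
#' Trains a symmetric multilayer-perceptron autoencoder
#' (15-32-latent-32-15, tanh hidden layers, linear latent and output, mean
#' squared error, Adam) on z-scored indicator features for each candidate
#' latent dimension, and selects the dimension by held-out reconstruction
#' error with a parsimony rule: the smallest dimension whose held-out error
#' is within one standard error of the best, or within 50% relative excess
#' of it. (Beyond the true intrinsic dimensionality, held-out errors differ
#' only by optimization jitter, which the sampling standard error
#' underestimates; an extra latent dimension must therefore cut the error
#' substantially — by more than a third — to be preferred.)
#'
#' @param clean A `clean_table`.
#' @param latent_dims Candidate latent dimensions, a subset of 2:5.
#' @param train_config List with `epochs`, `batch`, `lr`, `holdout`,
#'   `hidden` (width of the symmetric hidden layers).
#' @param seed Integer seed (initialisation, batching and the holdout split).
#' @return An `autoencoder_model`: the selected network, feature scalers,
#'   `latent_dim`, `recon_error` (held-out MSE of the selected model) and the
#'   per-dimension error table `selection`.
#' @export
fit_autoencoder <- function(clean, latent_dims = 2:5,
                            train_config = list(), seed = 1L) {
  if (!all(latent_dims %in% 2:5)) stopf("latent_dims must be a subset of 2:5")
  cfg <- utils::modifyList(
    list(epochs = 40L, batch = 64L, lr = 1e-3, holdout = 0.2, hidden = 32L),
    train_config)
  df <- as.data.frame(clean)
  feats <- setdiff(names(df), "ES")
  X <- as.matrix(df[, feats, drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Z <- scale(X, center = ctr, scale = scl)

  with_seed(seed, {
    n <- nrow(Z)
    hold <- sample.int(n, max(1L, round(n * cfg$holdout)))
    Ztr <- Z[-hold, , drop = FALSE]
    Zho <- Z[hold, , drop = FALSE]
    fits <- list()
    err_mean <- err_se <- numeric(length(latent_dims))
    for (i in seq_along(latent_dims)) {
      d <- latent_dims[i]
      net <- nn_init(c(ncol(Z), cfg$hidden, d, cfg$hidden, ncol(Z)),
                     acts = c("tanh", "linear", "tanh", "linear"))
      tr <- nn_train_mse(net, Ztr, Ztr, epochs = cfg$epochs, batch = cfg$batch,
                         lr = cfg$lr)
      ma <- stats::filter(tr$losses, rep(1 / 5, 5), sides = 1)
      ma <- ma[!is.na(ma)]
      if (length(ma) > 1 && ma[length(ma)] > ma[1L] * 1.5) {
        warning("autoencoder training loss not decreasing in moving average")
      }
      per_row <- rowMeans((nn_forward(tr$net, Zho)$out - Zho)^2)
      err_mean[i] <- mean(per_row)
      err_se[i] <- stats::sd(per_row) / sqrt(length(per_row))
      fits[[i]] <- tr$net
    }
    best <- which.min(err_mean)
    ok <- err_mean <= pmax(err_mean[best] + err_se[best], 1.5 * err_mean[best])
    pick <- which(ok)[1L] # latent_dims assumed sorted ascending
    structure(list(net = fits[[pick]], latent_dim = latent_dims[pick],
                   latent_layer = 2L, center = ctr, scale = scl,
                   features = feats, recon_error = err_mean[pick],
                   selection = data.frame(latent_dim = latent_dims,
                                          holdout_mse = err_mean, se = err_se)),
              class = "autoencoder_model")
  })
}

#' Latent coordinates for a table
#'
#' @param model An `autoencoder_model`.
#' @param clean A `clean_table` (or data frame with the model's features).
#' @return Matrix of latent activations (n x latent_dim).
#' @export
encode_latent <- function(model, clean) {
  df <- as.data.frame(clean)
  X <- as.matrix(df[, model$features, drop = FALSE])
  Z <- scale(X, center = model$center, scale = model$scale)
  L <- nn_forward_to(model$net, Z, model$latent_layer)
  colnames(L) <- paste0("Latent", seq_len(ncol(L)))
  L
}

#' Summarise the latent space
#'
#' Per latent coordinate: distribution summary (mean, sd, skewness), the
#' top-5 features by absolute Pearson correlation with the coordinate
#' ("composition"), and — when the table carries labels — the two-sample t
#' statistic between classes, identifying the most class-separating latent.
#' Degenerate (zero-variance) latents are flagged and get an empty
#' composition.
#'
#' @param model An `autoencoder_model`.
#' @param clean A `clean_table`.
#' @return A `latent_report` list: `summary` data frame and `composition`
#'   (list of character vectors, one per latent).
#' @export
latent_report <- function(model, clean) {
  df <- as.data.frame(clean)
  L <- encode_latent(model, df)
  X <- as.matrix(df[, model$features, drop = FALSE])
  y <- df$ES
  k <- ncol(L)
  comp <- vector("list", k)
  names(comp) <- colnames(L)
  summ <- data.frame(latent = colnames(L), mean = NA_real_, sd = NA_real_,
                     skewness = NA_real_, class_t = NA_real_,
                     degenerate = FALSE)
  for (j in seq_len(k)) {
    lj <- L[, j]
    summ$mean[j] <- mean(lj)
    summ$sd[j] <- stats::sd(lj)
    if (summ$sd[j] == 0) {
      summ$degenerate[j] <- TRUE
      comp[[j]] <- character(0)
      next
    }
    summ$skewness[j] <- e1071::skewness(lj)
    r <- abs(suppressWarnings(stats::cor(X, lj)))[, 1L]
    r[is.na(r)] <- 0
    comp[[j]] <- names(sort(r, decreasing = TRUE))[seq_len(min(5L, length(r)))]
    if (!is.null(y) && length(unique(y)) == 2L) {
      summ$class_t[j] <- unname(stats::t.test(lj[y == 1], lj[y == 0])$statistic)
    }
  }
  structure(list(summary = summ, composition = comp), class = "latent_report")
}

#' Combine explicit and latent relevance into the selected feature set
#'
#' A feature is kept when it ranks within `rank_threshold` (by relevance
#' magnitude) in at least `min_stats` of the four explicit statistics, or —
#' with `use_latent = TRUE` — when it appears in the composition of the most
#' class-separating latent coordinate *and* is corroborated by at least one
#' explicit statistic (rare binary outlier features can dominate latent
#' activations without carrying class signal, so the latent route alone is
#' not trusted). Features with `NA` statistics never pass the explicit
#' route.
#'
#' @param report A `relevance_report` from [explicit_relevance()].
#' @param latent A `latent_report` from [latent_report()], or `NULL`.
#' @param policy List: `rank_threshold` (default 8), `min_stats` (default 3),
#'   `use_latent` (default `TRUE`).
#' @return Character vector of selected features (in indicator order).
#' @export
select_features <- function(report, latent = NULL, policy = list()) {
  pol <- utils::modifyList(list(rank_threshold = 8, min_stats = 3, use_latent = TRUE),
                           policy)
  stats_mat <- cbind(abs(report$anova_f), abs(report$pb_r),
                     abs(report$rf_importance), abs(report$logit_coef))
  votes <- integer(nrow(report))
  for (k in seq_len(ncol(stats_mat))) {
    v <- stats_mat[, k]
    rk <- rank(-v, ties.method = "min", na.last = "keep")
    votes <- votes + (!is.na(rk) & rk <= pol$rank_threshold)
  }
  keep <- votes >= pol$min_stats
  if (isTRUE(pol$use_latent) && !is.null(latent)) {
    ts <- latent$summary$class_t
    if (any(!is.na(ts))) {
      sep <- which.max(abs(ts))
      keep <- keep | (report$feature %in% latent$composition[[sep]] & votes >= 1)
    }
  }
  sel <- report$feature[keep]
  if (!length(sel)) {
    stopf("configuration error: selection policy kept no features")
  }
  sel
}
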