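# Reference classifiers the attentive model is compared against: a two-
# hidden-layer MLP with early stopping and a gradient-boosted decision tree
# ensemble (xgboost). Both expose the same predict() interface.

#' Train a baseline classifier
#'
#' @param train,valid Data (an `augmented_dataset` or data frame with `ES`);
#'   `valid` drives MLP early stopping and may be `NULL`.
#' @param kind `"mlp"` (layers p-32-16-1, ReLU, Adam, early stopping on
#'   validation loss) or `"gbdt"` (500 trees, depth 6, learning rate 0.1).
#' @param seed Integer seed.
#' @param features Feature columns (default: the eight selected indicators).
#' @param config Optional overrides: for `"mlp"` `hidden`, `epochs`, `lr`,
#'   `patience`; for `"gbdt"` `nrounds`, `max_depth`, `eta`.
#' @return An `mlp_model` or `gbdt_model` supporting [predict()].
#' @export
train_baselines <- function(train, valid = NULL, kind = c("mlp", "gbdt"),
                            seed = 1L, features = informative_indicators(),
                            config = list()) {
  kind <- match.arg(kind)
  tr <- extract_xy(train, features)
  if (length(unique(tr$y)) < 2L) {
    stopf("training error: training data contain a single class")
  }
  if (kind == "gbdt") {
    cfg <- utils::modifyList(list(nrounds = 500L, max_depth = 6L, eta = 0.1), config)
    dtrain <- xgboost::xgb.DMatrix(tr$X, label = tr$y)
    bst <- with_seed(seed, xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = cfg$max_depth,
                    eta = cfg$eta, nthread = 1L),
      data = dtrain, nrounds = cfg$nrounds, verbose = 0
    ))
    return(structure(list(booster = bst, features = features), class = "gbdt_model"))
  }
  cfg <- utils::modifyList(list(hidden = c(32L, 16L), epochs = 100L, lr = 1e-3,
                                batch = 64L, patience = 10L), config)
  ctr <- colMeans(tr$X)
  scl <- apply(tr$X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Z <- scale(tr$X, center = ctr, scale = scl)
  va <- NULL
  if (!is.null(valid)) {
    v <- extract_xy(valid, features)
    va <- list(Z = scale(v$X, center = ctr, scale = scl), y = v$y)
  }
  with_seed(seed, {
    net <- nn_init(c(ncol(Z), cfg$hidden, 1L))
    opt <- adam_new(list(W = net$W, b = net$b))
    n <- nrow(Z)
    best <- list(loss = Inf, net = net, since = 0L)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = cfg$batch)) {
        rows <- ord[start:min(start + cfg$batch - 1L, n)]
        fw <- nn_forward(net, Z[rows, , drop = FALSE], keep_cache = TRUE)
        pr <- sigmoid(drop(fw$out))
        dOut <- matrix((pr - tr$y[rows]) / length(rows), ncol = 1L)
        bw <- nn_backward(net, fw$cache, dOut)
        prm <- adam_step(opt, list(W = net$W, b = net$b), list(W = bw$W, b = bw$b),
                         lr = cfg$lr)
        net$W <- prm$W; net$b <- prm$b
      }
      if (!is.null(va)) {
        pv <- sigmoid(drop(nn_forward(net, va$Z)$out))
        vl <- mean(-(va$y * log(pv + 1e-12) + (1 - va$y) * log(1 - pv + 1e-12)))
        if (vl < best$loss) {
          best <- list(loss = vl, net = net, since = 0L)
        } else {
          best$since <- best$since + 1L
          if (best$since >= cfg$patience) break
        }
      }
    }
    final <- if (!is.null(va)) best$net else net
    structure(list(net = final, features = features, center = ctr, scale = scl),
              class = "mlp_model")
  })
}

#' @export
predict.mlp_model <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  Z <- scale(as.matrix(df[, object$features, drop = FALSE]),
             center = object$center, scale = object$scale)
  sigmoid(drop(nn_forward(object$net, Z)$out))
}

#' @export
predict.gbdt_model <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  stats::predict(object$booster,
                 xgboost::xgb.DMatrix(as.matrix(df[, object$features, drop = FALSE])))
}
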