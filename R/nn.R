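# Minimal dense multilayer-perceptron engine with hand-derived gradients and
# Adam/AdamW optimisation. Backs the autoencoder (feature_relevance), the
# diffusion denoiser, and the MLP baseline; the attentive classifier has its
# own architecture-specific backward pass (see tabnet.R) but reuses the
# optimiser defined here. Matrices are row-major samples (n x features).

# `acts`: one activation per layer, in {"relu", "tanh", "linear"}.
nn_init <- function(sizes, acts = NULL) {
  n_layers <- length(sizes) - 1L
  if (is.null(acts)) acts <- c(rep("relu", n_layers - 1L), "linear")
  stopifnot(length(acts) == n_layers)
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- sizes[l]
    fan_out <- sizes[l + 1L]
    sd <- sqrt(2 / (fan_in + fan_out))
    W[[l]] <- matrix(stats::rnorm(fan_in * fan_out, 0, sd), fan_in, fan_out)
    b[[l]] <- numeric(fan_out)
  }
  structure(list(sizes = sizes, acts = acts, W = W, b = b), class = "stabsense_nn")
}

nn_act <- function(pre, kind) {
  switch(kind,
    relu = pmax(pre, 0),
    tanh = tanh(pre),
    linear = pre,
    stopf("unknown activation '%s'", kind)
  )
}

nn_act_grad <- function(pre, post, kind) {
  switch(kind,
    relu = (pre > 0) * 1,
    tanh = 1 - post^2,
    linear = array(1, dim(pre)),
    stopf("unknown activation '%s'", kind)
  )
}

# Forward pass; returns the output and (optionally) the per-layer caches
# needed by nn_backward.
nn_forward <- function(net, X, keep_cache = FALSE) {
  h <- X
  cache <- if (keep_cache) vector("list", length(net$W)) else NULL
  for (l in seq_along(net$W)) {
    pre <- sweep(h %*% net$W[[l]], 2, net$b[[l]], `+`)
    post <- nn_act(pre, net$acts[l])
    if (keep_cache) cache[[l]] <- list(input = h, pre = pre, post = post)
    h <- post
  }
  list(out = h, cache = cache)
}

# Output of an intermediate layer (used to read autoencoder latent codes).
nn_forward_to <- function(net, X, layer) {
  h <- X
  for (l in seq_len(layer)) {
    pre <- sweep(h %*% net$W[[l]], 2, net$b[[l]], `+`)
    h <- nn_act(pre, net$acts[l])
  }
  h
}

# Backward pass from dOut (gradient of the loss w.r.t. the network output).
# Returns parameter gradients and the gradient w.r.t. the input.
nn_backward <- function(net, cache, dOut) {
  gW <- vector("list", length(net$W))
  gb <- vector("list", length(net$W))
  d <- dOut
  for (l in rev(seq_along(net$W))) {
    cc <- cache[[l]]
    dpre <- d * nn_act_grad(cc$pre, cc$post, net$acts[l])
    gW[[l]] <- crossprod(cc$input, dpre)
    gb[[l]] <- colSums(dpre)
    d <- dpre %*% t(net$W[[l]])
  }
  list(W = gW, b = gb, dX = d)
}

# ---- Adam / AdamW over an arbitrary (nested) list of numeric arrays --------

adam_new <- function(params) {
  zero <- function(p) if (is.list(p)) lapply(p, zero) else p * 0
  st <- new.env(parent = emptyenv())
  st$m <- zero(params)
  st$v <- zero(params)
  st$t <- 0L
  st
}

# Decoupled weight decay (AdamW) when weight_decay > 0; plain Adam otherwise.
adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- vector("list", length(p))
      out_m <- vector("list", length(p))
      out_v <- vector("list", length(p))
      names(out_p) <- names(p)
      for (i in seq_along(p)) {
        r <- upd(p[[i]], g[[i]], m[[i]], v[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    step <- mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0) step <- step + weight_decay * p
    list(p = p - lr * step, m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  state$m <- r$m
  state$v <- r$v
  r$p
}

# Train a plain MLP on (X, Y) under squared-error loss. Used by the
# autoencoder; returns the net plus the per-epoch loss trace.
nn_train_mse <- function(net, X, Y, epochs, batch, lr, weight_decay = 0,
                         lr_schedule = c("constant", "cosine")) {
  lr_schedule <- match.arg(lr_schedule)
  n <- nrow(X)
  opt <- adam_new(list(W = net$W, b = net$b))
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    lr_ep <- if (lr_schedule == "cosine") lr * 0.5 * (1 + cos(pi * (ep - 1) / epochs)) else lr
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = batch)) {
      rows <- ord[start:min(start + batch - 1L, n)]
      fw <- nn_forward(net, X[rows, , drop = FALSE], keep_cache = TRUE)
      err <- fw$out - Y[rows, , drop = FALSE]
      loss <- mean(err^2)
      if (!is.finite(loss)) {
        stopf("training diverged (non-finite loss) at epoch %d", ep)
      }
      dOut <- 2 * err / length(err)
      bw <- nn_backward(net, fw$cache, dOut)
      params <- adam_step(opt, list(W = net$W, b = net$b),
                          list(W = bw$W, b = bw$b),
                          lr = lr_ep, weight_decay = weight_decay)
      net$W <- params$W
      net$b <- params$b
      ep_loss <- ep_loss + loss
      nb <- nb + 1L
    }
    losses[ep] <- ep_loss / nb
  }
  list(net = net, losses = losses)
}
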