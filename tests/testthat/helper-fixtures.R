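# Shared fixtures, built in code at test time.

small_cohort <- function(n = 2000, prevalence = 0.2, seed = 1L, ...) {
  generate_cohort(cohort_spec(n_records = n, prevalence = prevalence,
                              seed = seed, ...))
}

# Ten-row raw intake fixture: rows 3 and 8 contain a null, row 5 has an
# unparseable "n/a" in Fat; the rest are valid (some with unit suffixes and
# text labels), so cleaning must retain exactly 7 rows.
toy_raw_table <- function() {
  base <- as.data.frame(small_cohort(n = 10, prevalence = 0.3, seed = 42))
  for (cl in names(base)) base[[cl]] <- as.character(base[[cl]])
  base$ES <- ifelse(base$ES == "1", "Positive", "negative")
  base$Protein[1] <- paste0(base$Protein[1], " g/100g")
  base$MTemp[2] <- paste0(base$MTemp[2], " °C")
  base$SNF[3] <- NA
  base$Fat[5] <- "n/a"
  base$Acidity[8] <- NA
  base
}

# Linearly separable two-feature toy classification table.
separable_toy <- function(n = 300, seed = 3L, margin = 0.5) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x1 <- ifelse(y == 1, 1, -1) * (margin + abs(rnorm(n)))
  data.frame(ES = y, a = x1, b = rnorm(n))
}

tiny_tabnet_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_d = 8L, n_a = 8L, n_steps = 2L, gamma = 1.3, lambda_sparse = 1e-3,
         learning_rate = 0.02, batch_size = 64L, epochs = 25L),
    list(...))
  do.call(tabnet_config, args)
}

# Independent sparsemax oracle: solve sum(max(z - tau, 0)) = 1 for tau by
# bisection, independent of the sorted-threshold algorithm under test.
sparsemax_bisect <- function(z, tol = 1e-12) {
  f <- function(tau) sum(pmax(z - tau, 0)) - 1
  lo <- min(z) - 1
  hi <- max(z)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  pmax(z - (lo + hi) / 2, 0)
}

# Brute-force confusion recount with explicit loops (independent oracle).
recount_metrics <- function(y, pred) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(y)) {
    if (y[i] == 1 && pred[i] == 1) tp <- tp + 1L
    if (y[i] == 0 && pred[i] == 1) fp <- fp + 1L
    if (y[i] == 0 && pred[i] == 0) tn <- tn + 1L
    if (y[i] == 1 && pred[i] == 0) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / length(y),
       precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = if (tp + fn > 0) tp / (tp + fn) else 0)
}
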