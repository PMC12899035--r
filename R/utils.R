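# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library users never lose reproducibility.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed; kept within 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483587)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stopf("`%s` must be a single value in [0, 1]", name)
  }
  invisible(x)
}

# Stratified index split into train/valid/test fractions (must sum to 1).
stratified_split <- function(y, fractions = c(train = 0.64, valid = 0.16, test = 0.20),
                             seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  with_seed(seed, {
    idx <- list(train = integer(0), valid = integer(0), test = integer(0))
    for (cls in unique(y)) {
      rows <- which(y == cls)
      rows <- sample(rows)
      n <- length(rows)
      n_tr <- round(n * fractions[[1L]])
      n_va <- round(n * fractions[[2L]])
      idx$train <- c(idx$train, rows[seq_len(n_tr)])
      idx$valid <- c(idx$valid, rows[n_tr + seq_len(n_va)])
      idx$test <- c(idx$test, rows[setdiff(seq_len(n), seq_len(n_tr + n_va))])
    }
    lapply(idx, sort)
  })
}
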