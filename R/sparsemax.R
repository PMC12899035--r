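# Sparsemax: Euclidean projection of a score vector onto the probability
# simplex. Unlike softmax it assigns exact zeros outside the active support,
# which is what makes the attention masks sparse and interpretable.

#' Sparsemax transformation
#'
#' Projects `z` onto the probability simplex: the solution of
#' `min_p ||p - z||^2` subject to `p >= 0`, `sum(p) = 1`, computed by the
#' sorted-threshold algorithm. Invariant under constant shifts of `z`.
#'
#' @param z Finite numeric vector of scores.
#' @return Probability vector of the same length (nonnegative, sums to 1,
#'   typically sparse).
#' @export
sparsemax <- function(z) {
  if (length(z) == 0L) stopf("validation error: empty score vector")
  if (any(!is.finite(z))) stopf("validation error: scores must be finite")
  u <- sort(z, decreasing = TRUE)
  css <- cumsum(u)
  k <- max(which(1 + seq_along(u) * u > css))
  tau <- (css[k] - 1) / k
  pmax(z - tau, 0)
}

# Row-wise sparsemax for a matrix of scores, vectorized: rows are sorted
# descending in one order() call; the support size is the count of k with
# 1 + k * u_k > cumsum(u)_k (true for exactly 1..k* by the thresholding
# property of the projection).
sparsemax_rows <- function(Z) {
  n <- nrow(Z)
  p <- ncol(Z)
  if (n == 1L) return(matrix(sparsemax(drop(Z)), 1L, p))
  U <- matrix(Z[order(row(Z), -Z)], n, p, byrow = TRUE)
  css <- U
  for (j in seq_len(p)[-1L]) css[, j] <- css[, j - 1L] + U[, j]
  k <- rowSums(1 + rep(seq_len(p), each = n) * U > css)
  tau <- (css[cbind(seq_len(n), k)] - 1) / k
  pmax(Z - tau, 0)
}

# Row-wise Jacobian-vector product: for each row with support S = {p > 0},
# dz[S] = dp[S] - mean(dp[S]), zero off-support.
sparsemax_backward <- function(P, dP) {
  S <- P > 0
  masked <- dP * S
  mean_s <- rowSums(masked) / pmax(rowSums(S), 1L)
  (masked - mean_s * S)
}
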