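# Independent brute-force oracles, written as plain scalar loops so they
# share no code path with the package implementations.

# Passing-Bablok slope/intercept by exhaustive enumeration: double loop over
# pairs, drop identical points and slopes equal to -1, sort with signed
# infinities at the extremes, take the K-shifted median, intercept as the
# median of y - b*x.
oracle_pb <- function(x, y) {
  n <- length(x)
  slopes <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) next
      s <- if (dx == 0) { if (dy > 0) Inf else -Inf } else dy / dx
      if (s == -1) next
      slopes <- c(slopes, s)
    }
  }
  slopes <- sort(slopes)
  N <- length(slopes)
  if (N == 0) return(NULL)
  K <- 0
  for (s in slopes) if (s < -1) K <- K + 1
  clamp <- function(i) min(max(i, 1), N)
  b <- if (N %% 2 == 1) slopes[clamp((N + 1) / 2 + K)]
       else (slopes[clamp(N / 2 + K)] + slopes[clamp(N / 2 + 1 + K)]) / 2
  a <- median(y - b * x)
  list(slope = b, intercept = a, N = N, K = K)
}

# AUC by concordant-pair counting over all (positive, negative) pairs,
# ties worth one half.
oracle_auc <- function(labels, predictor) {
  pos <- predictor[labels == 1]
  neg <- predictor[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      if (p > q) total <- total + 1
      else if (p == q) total <- total + 0.5
    }
  }
  total / (length(pos) * length(neg))
}

# random method-comparison instance; with prob 1/2 x is rounded so ties
# (the discrete reporting pattern) are exercised
random_pb_instance <- function(n) {
  x <- runif(n, 1, 100)
  if (runif(1) < 0.5) x <- round(x)
  y <- runif(1, 0.5, 2) * x + rnorm(n, 0, 5)
  if (runif(1) < 0.3) y <- round(y)
  list(x = x, y = y)
}
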