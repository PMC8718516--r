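# Independent oracles, written against the definitions (not the package
# implementations) and kept deliberately naive.

# Exhaustive DTW: minimum total local cost over all monotone contiguous
# warping paths with steps (1,0), (0,1), (1,1), endpoints matched.
dtw_brute <- function(x, y) {
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  ym <- if (is.matrix(y)) y else matrix(y, ncol = 1)
  lc <- function(i, j) sqrt(sum((xm[i, ] - ym[j, ])^2))
  n <- nrow(xm); m <- nrow(ym)
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(lc(1, 1))
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    lc(i, j) + best
  }
  rec(n, m)
}

# O(n^2) enumeration of max over all contiguous intervals of min(value) * length.
best_interval_brute <- function(v) {
  n <- length(v)
  best <- -Inf; best_start <- 0L; best_end <- 0L
  for (s in seq_len(n)) {
    mn <- Inf
    for (e in s:n) {
      mn <- min(mn, v[e])
      sc <- mn * (e - s + 1L)
      if (sc > best) {
        best <- sc; best_start <- s - 1L; best_end <- e
      }
    }
  }
  list(score = best, start = best_start, end = best_end)
}

# Step-by-step transcription of the published fusion pseudocode:
#   P_k' = (p_prev + Z)^(1/2); K_k = (P_k'^2 / (P_k'^2 + A))^(1/2);
#   x = a + K_k (a - b); P_K = ((1 - K_k) P_k'^2)^(1/2); iterate with p_prev = P_K.
kalman_literal_oracle <- function(a, b, A, Z, p0) {
  x <- numeric(length(a))
  p_prev <- p0
  for (k in seq_along(a)) {
    Pk_prime <- sqrt(p_prev + Z)
    Kk <- sqrt(Pk_prime^2 / (Pk_prime^2 + A))
    x[k] <- a[k] + Kk * (a[k] - b[k])
    PK <- sqrt((1 - Kk) * Pk_prime^2)
    p_prev <- PK
  }
  x
}

# Naive double-loop windowed mean of absolute value (centered, edge-truncated).
iemg_naive <- function(x, window) {
  n <- length(x)
  left <- (window - 1L) %/% 2L
  right <- window - 1L - left
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - left)
    hi <- min(n, i + right)
    acc <- 0
    for (j in lo:hi) acc <- acc + abs(x[j])
    out[i] <- acc / (hi - lo + 1L)
  }
  out
}

# Shared small fixtures -------------------------------------------------------

make_sine_trajectory <- function(rate_hz, t_start = 0, t_end = 5,
                                 sensor_id = "s") {
  ts <- seq(t_start, t_end, by = 1 / rate_hz)
  joint_trajectory(ts, cbind(sin(ts), cos(ts), 0.5 * ts), sensor_id)
}

# A small healthy reference library shared across completion/pipeline tests.
test_reference_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_reference_library(n_refs = 2, seed = 900)
    }
    cache
  }
})
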