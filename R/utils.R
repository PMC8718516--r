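# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed; result stays below 2^31 (R integers are 32-bit).
child_seed <- function(seed, offset) {
  as.integer((abs(as.numeric(seed)) %% 100000) * 20000 +
               (abs(as.numeric(offset)) %% 20000))
}

stop_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
          sprintf("`%s` must be a single finite number", name))
  stop_if(x < lower || x > upper,
          sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  invisible(x)
}

#' Centered moving mean with edge truncation (shorter windows at the ends).
#' @noRd
moving_mean <- function(x, window) {
  n <- length(x)
  window <- max(1L, as.integer(window))
  left <- (window - 1L) %/% 2L
  right <- window - 1L - left
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Linear resampling of a vector to `n_out` points spanning its full support.
#' @noRd
resample_linear <- function(x, n_out) {
  n <- length(x)
  if (n == 1L) return(rep(x, n_out))
  stats::approx(seq_len(n), x, xout = seq(1, n, length.out = n_out))$y
}
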