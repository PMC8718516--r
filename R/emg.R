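# sEMG processing: zero-phase band-pass filtering, the integrated-EMG
# (iEMG) activity envelope, and automatic burst segmentation via the
# recursive maximum (minimum value x length) interval search.

.emg_channel_names <- c("forelimb", "biceps", "deltoid")

#' Three-channel surface-EMG recording
#'
#' @param rate_hz Sampling rate (Hz), > 0.
#' @param channels n x 3 numeric matrix of amplitudes (mV); columns are the
#'   forelimb, biceps brachii and deltoid electrodes.
#' @param channel_names Channel labels.
#' @return Object of class `emg_recording`.
#' @export
emg_recording <- function(rate_hz, channels,
                          channel_names = .emg_channel_names) {
  assert_scalar_num(rate_hz, "rate_hz")
  stop_if(rate_hz <= 0, "`rate_hz` must be > 0")
  channels <- as.matrix(channels)
  stop_if(ncol(channels) != 3, "`channels` must have 3 columns")
  stop_if(any(!is.finite(channels)), "sEMG contains non-finite values")
  structure(list(rate_hz = rate_hz, channels = unname(channels),
                 channel_names = channel_names),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d samples x 3 channels @ %g Hz (%.1f s)\n",
              nrow(x$channels), x$rate_hz, nrow(x$channels) / x$rate_hz))
  invisible(x)
}

#' Zero-phase frequency-domain filter with Butterworth magnitude response
#'
#' Multiplies the FFT of the signal by the real, even magnitude response of a
#' Butterworth band-pass of the given order (optionally with a Gaussian mains
#' notch) and inverts. The response is real and symmetric, so the filter is
#' exactly zero-phase and length-preserving.
#'
#' @param x Numeric vector.
#' @param rate_hz Sampling rate.
#' @param low_hz,high_hz Band edges; either may be `NULL` to skip that edge.
#' @param notch_hz Optional notch center (e.g. 50).
#' @param order Butterworth order.
#' @param notch_bw_hz Notch Gaussian width (Hz).
#' @return Filtered vector, same length.
#' @export
fft_filter <- function(x, rate_hz, low_hz = NULL, high_hz = NULL,
                       notch_hz = NULL, order = 4, notch_bw_hz = 1) {
  n <- length(x)
  if (n < 4) return(x)
  f <- seq(0, n - 1) / n * rate_hz
  f <- pmin(f, rate_hz - f)  # two-sided frequency magnitude
  H <- rep(1, n)
  if (!is.null(low_hz) && low_hz > 0) {
    H <- H * ifelse(f > 0, 1 / sqrt(1 + (low_hz / pmax(f, 1e-12))^(2 * order)), 0)
  }
  if (!is.null(high_hz)) {
    H <- H * 1 / sqrt(1 + (f / high_hz)^(2 * order))
  }
  if (!is.null(notch_hz)) {
    H <- H * (1 - exp(-0.5 * ((f - notch_hz) / notch_bw_hz)^2))
  }
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n
}

#' Band-pass filter an sEMG recording
#'
#' Zero-phase band-pass (default 20--450 Hz, Butterworth magnitude of order 4)
#' applied per channel, with an optional mains notch.
#'
#' @param rec An [emg_recording()].
#' @param low_hz,high_hz Pass band (must satisfy `0 < low < high < rate/2`).
#' @param notch_hz Mains notch center or `NULL` to disable.
#' @param order Butterworth order.
#' @return Filtered [emg_recording()], same length.
#' @export
bandpass_filter <- function(rec, low_hz = 20, high_hz = 450, notch_hz = 50,
                            order = 4) {
  stopifnot(inherits(rec, "emg_recording"))
  stop_if(low_hz <= 0 || high_hz <= low_hz,
          "need 0 < low_hz < high_hz")
  stop_if(high_hz >= rec$rate_hz / 2,
          sprintf("high_hz (%g) must be below Nyquist (%g)", high_hz,
                  rec$rate_hz / 2))
  out <- vapply(1:3, function(ch) {
    fft_filter(rec$channels[, ch], rec$rate_hz, low_hz, high_hz, notch_hz,
               order)
  }, numeric(nrow(rec$channels)))
  emg_recording(rec$rate_hz, out, rec$channel_names)
}

#' Integrated-EMG activity envelope
#'
#' The iEMG is the time-windowed mean of the absolute signal: a centered
#' moving average of `|x|` with the window truncated at the edges, computed
#' per channel. It converts the oscillatory sEMG into a non-negative activity
#' envelope used for burst segmentation.
#'
#' @param rec An [emg_recording()].
#' @param window_s Window length (s); default 0.1.
#' @return Object of class `iemg_envelope`: `list(rate_hz, values,
#'   window_samples)` where `values` is an n x 3 matrix.
#' @export
compute_iemg <- function(rec, window_s = 0.1) {
  stopifnot(inherits(rec, "emg_recording"))
  w <- as.integer(round(window_s * rec$rate_hz))
  stop_if(w < 1, "`window_s` times the sampling rate must be >= 1")
  vals <- vapply(1:3, function(ch) moving_mean(abs(rec$channels[, ch]), w),
                 numeric(nrow(rec$channels)))
  structure(list(rate_hz = rec$rate_hz, values = vals, window_samples = w),
            class = "iemg_envelope")
}

#' Half-open activity interval with its min-by-length score
#'
#' @param start 0-based inclusive start sample.
#' @param end 0-based exclusive end sample.
#' @param score Interval score (minimum envelope value times length).
#' @return Object of class `activity_interval`.
#' @export
activity_interval <- function(start, end, score) {
  stop_if(start < 0 || end <= start, "need 0 <= start < end")
  stop_if(score < 0, "score must be non-negative")
  structure(list(start = as.integer(start), end = as.integer(end),
                 score = score), class = "activity_interval")
}

#' Maximum (minimum value x length) contiguous interval
#'
#' The recursive interval search that drives automatic burst detection: at
#' each level, find the minimum value `a` (at index `ID`) of the current
#' window of length `L`; the whole window is a candidate with score `a * L`;
#' recurse on the sub-windows left and right of `ID` (the minimum's own index
#' is excluded from the children, the only terminating reading of the
#' published recursion, which is the classic largest-rectangle-in-histogram
#' search). Returns the global maximum-score interval; ties break to the
#' leftmost, then shortest, interval. Implemented with an explicit stack so
#' long envelopes cannot overflow the call stack.
#'
#' @param values Non-empty, non-negative numeric vector.
#' @return `list(interval, candidates)`: the best [activity_interval()]
#'   (0-based, half-open) and a data frame of every candidate window examined
#'   with its score.
#' @examples
#' best_interval(c(1, 3, 2))$interval  # [1, 3), score 4
#' @export
best_interval <- function(values) {
  stop_if(length(values) == 0, "`values` must be non-empty")
  stop_if(any(!is.finite(values)), "`values` must be finite")
  stop_if(any(values < 0), "`values` must be non-negative")
  n <- length(values)
  # explicit stack of 1-based closed windows [lo, hi]
  stack_lo <- integer(n + 1L); stack_hi <- integer(n + 1L)
  top <- 1L; stack_lo[1L] <- 1L; stack_hi[1L] <- n
  cand_lo <- integer(0); cand_hi <- integer(0); cand_sc <- numeric(0)
  best_lo <- 1L; best_hi <- n; best_sc <- -1
  while (top > 0L) {
    lo <- stack_lo[top]; hi <- stack_hi[top]; top <- top - 1L
    w <- values[lo:hi]
    id <- lo - 1L + which.min(w)
    a <- values[id]
    L <- hi - lo + 1L
    sc <- a * L
    cand_lo <- c(cand_lo, lo); cand_hi <- c(cand_hi, hi)
    cand_sc <- c(cand_sc, sc)
    better <- sc > best_sc ||
      (sc == best_sc && (lo < best_lo ||
                           (lo == best_lo && L < best_hi - best_lo + 1L)))
    if (better) { best_lo <- lo; best_hi <- hi; best_sc <- sc }
    if (id > lo) {
      top <- top + 1L
      if (top > length(stack_lo)) {
        stack_lo <- c(stack_lo, integer(n)); stack_hi <- c(stack_hi, integer(n))
      }
      stack_lo[top] <- lo; stack_hi[top] <- id - 1L
    }
    if (id < hi) {
      top <- top + 1L
      if (top > length(stack_lo)) {
        stack_lo <- c(stack_lo, integer(n)); stack_hi <- c(stack_hi, integer(n))
      }
      stack_lo[top] <- id + 1L; stack_hi[top] <- hi
    }
  }
  list(
    interval = activity_interval(best_lo - 1L, best_hi, best_sc),
    candidates = data.frame(start = cand_lo - 1L, end = cand_hi,
                            score = cand_sc)
  )
}

#' Automatically segment movement bursts from an iEMG envelope
#'
#' Sums the per-channel envelopes (default; set `per_channel_values` to pass a
#' single channel), suppresses samples below `threshold_frac` of the envelope
#' maximum, then repeatedly applies [best_interval()] to the remaining
#' activity: each selected interval is expanded to its full contiguous
#' supra-threshold island, accepted if it lasts at least `min_duration_s`,
#' zeroed out, and the search repeats until no activity remains. For long
#' recordings the envelope is decimated to about `work_rate_hz` before the
#' search and interval bounds are mapped back to original samples.
#'
#' @param env An [iemg_envelope()] (or a non-negative numeric vector with
#'   attribute-free samples at `rate_hz`).
#' @param threshold_frac Acceptance threshold as a fraction of the global
#'   envelope maximum.
#' @param min_duration_s Minimum accepted burst duration (s).
#' @param rate_hz Required if `env` is a bare vector.
#' @param channel Optional single channel index (1--3) to segment instead of
#'   the channel-summed envelope.
#' @param work_rate_hz Target decimation rate for the interval search.
#' @return List of [activity_interval()]s (0-based, half-open, original
#'   sample indices), pairwise disjoint and sorted by start; possibly empty.
#' @export
segment_bursts <- function(env, threshold_frac = 0.2, min_duration_s = 0.3,
                           rate_hz = NULL, channel = NULL,
                           work_rate_hz = 50) {
  if (inherits(env, "iemg_envelope")) {
    rate_hz <- env$rate_hz
    v <- if (is.null(channel)) rowSums(env$values)
         else env$values[, channel]
  } else {
    stop_if(is.null(rate_hz), "`rate_hz` required for a bare envelope vector")
    v <- as.numeric(env)
  }
  stop_if(length(v) == 0, "envelope is empty")
  stop_if(any(v < 0), "envelope must be non-negative")
  dec <- max(1L, as.integer(floor(rate_hz / work_rate_hz)))
  w <- v[seq(1L, length(v), by = dec)]
  vmax <- max(w)
  if (vmax <= 0) return(list())
  thr <- threshold_frac * vmax
  w[w < thr] <- 0
  min_len <- max(1L, as.integer(round(min_duration_s * rate_hz / dec)))
  out <- list()
  guard <- 0L
  while (any(w > 0) && guard < 10000L) {
    guard <- guard + 1L
    bi <- best_interval(w)$interval
    if (bi$score <= 0) break
    # expand the seed interval to its contiguous supra-threshold island
    lo <- bi$start + 1L; hi <- bi$end  # 1-based closed
    while (lo > 1L && w[lo - 1L] > 0) lo <- lo - 1L
    while (hi < length(w) && w[hi + 1L] > 0) hi <- hi + 1L
    if (hi - lo + 1L >= min_len) {
      s0 <- (lo - 1L) * dec          # 0-based original-rate start
      e0 <- min(hi * dec, length(v)) # exclusive end
      seg <- v[(s0 + 1L):e0]
      out[[length(out) + 1L]] <- activity_interval(s0, e0,
                                                   min(seg) * length(seg))
    }
    w[lo:hi] <- 0
  }
  if (length(out) == 0) return(list())
  out[order(vapply(out, `[[`, integer(1), "start"))]
}

#' Extract a fixed-length classifier input from a recording
#'
#' Linearly resamples the interval's samples to exactly `target_len` per
#' channel and (by default) z-normalizes each channel, producing the
#' `target_len x 3` matrix the action classifier consumes.
#'
#' @param rec An [emg_recording()].
#' @param iv An [activity_interval()] (0-based, half-open) within `rec`.
#' @param target_len Output length (samples); default 200.
#' @param normalize Per-channel z-normalization.
#' @return `target_len x 3` numeric matrix.
#' @export
extract_segment <- function(rec, iv, target_len = 200, normalize = TRUE) {
  stopifnot(inherits(rec, "emg_recording"))
  n <- nrow(rec$channels)
  start <- if (inherits(iv, "activity_interval")) iv$start else iv[[1]]
  end <- if (inherits(iv, "activity_interval")) iv$end else iv[[2]]
  stop_if(start < 0 || end > n || end - start < 2,
          sprintf("degenerate interval [%s, %s) for %d-sample recording",
                  start, end, n))
  seg <- rec$channels[(start + 1L):end, , drop = FALSE]
  out <- vapply(1:3, function(ch) resample_linear(seg[, ch], target_len),
                numeric(target_len))
  if (normalize) {
    out <- apply(out, 2, function(x) {
      s <- stats::sd(x)
      if (s > 0) (x - mean(x)) / s else x - mean(x)
    })
  }
  out
}
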