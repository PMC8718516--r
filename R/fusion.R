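# Kinematic fusion: timestamp synchronization of the two sensor streams onto
# a shared uniform grid, noise-variance estimation, and per-axis scalar
# Kalman fusion.

#' Timestamped 3-D joint trajectory from one sensor
#'
#' @param timestamps Strictly increasing times (s).
#' @param coords n x 3 matrix of positions (m).
#' @param sensor_id Sensor label.
#' @return Object of class `joint_trajectory`.
#' @export
joint_trajectory <- function(timestamps, coords, sensor_id = "sensor") {
  coords <- as.matrix(coords)
  stop_if(ncol(coords) != 3, "`coords` must have 3 columns (x, y, z)")
  stop_if(length(timestamps) != nrow(coords),
          "`timestamps` length must equal `coords` row count")
  stop_if(any(!is.finite(timestamps)) || any(!is.finite(coords)),
          "trajectory contains non-finite values")
  d <- diff(timestamps)
  if (any(d <= 0)) {
    stop("timestamps not strictly increasing at index ",
         which(d <= 0)[1] + 1L, call. = FALSE)
  }
  structure(list(sensor_id = sensor_id, timestamps = as.numeric(timestamps),
                 coords = unname(coords)),
            class = "joint_trajectory")
}

#' @export
print.joint_trajectory <- function(x, ...) {
  cat(sprintf("<joint_trajectory> sensor=%s n=%d span=[%.3f, %.3f] s\n",
              x$sensor_id, length(x$timestamps), x$timestamps[1],
              x$timestamps[length(x$timestamps)]))
  invisible(x)
}

#' Synchronize two trajectories onto a shared uniform grid
#'
#' Linearly interpolates both streams onto the identical uniform grid at
#' `target_rate_hz` covering the overlap of their time supports; samples
#' outside the overlap are discarded (recordings carry rest padding so no
#' movement is lost). An optional constant offset can be added to the second
#' stream's clock before alignment.
#'
#' @param s1,s2 [joint_trajectory()]s with overlapping support (>= 1 s by
#'   default).
#' @param target_rate_hz Grid rate (Hz); convention: the slower sensor's rate.
#' @param offset_s Constant time offset added to `s2`'s timestamps.
#' @param min_overlap_s Minimum required overlap (s).
#' @return `list(s1, s2)` on the identical grid.
#' @export
synchronize_streams <- function(s1, s2, target_rate_hz = 30, offset_s = 0,
                                min_overlap_s = 1) {
  stopifnot(inherits(s1, "joint_trajectory"), inherits(s2, "joint_trajectory"))
  assert_scalar_num(target_rate_hz, "target_rate_hz")
  stop_if(target_rate_hz <= 0, "`target_rate_hz` must be > 0")
  t2 <- s2$timestamps + offset_s
  lo <- max(s1$timestamps[1], t2[1])
  hi <- min(s1$timestamps[length(s1$timestamps)], t2[length(t2)])
  stop_if(hi - lo < min_overlap_s,
          sprintf("temporal overlap of streams is %.3f s, need >= %.3f s",
                  hi - lo, min_overlap_s))
  grid <- seq(lo, lo + floor((hi - lo) * target_rate_hz) / target_rate_hz,
              by = 1 / target_rate_hz)
  interp <- function(ts, coords) {
    vapply(1:3, function(ax) stats::approx(ts, coords[, ax], xout = grid)$y,
           numeric(length(grid)))
  }
  list(s1 = joint_trajectory(grid, interp(s1$timestamps, s1$coords),
                             sensor_id = s1$sensor_id),
       s2 = joint_trajectory(grid, interp(t2, s2$coords),
                             sensor_id = s2$sensor_id))
}

#' Estimate per-axis sensor noise variance
#'
#' Raw variance of a moving limb would conflate motion with noise, so the
#' stream is detrended with a centered moving average (default 0.5 s) and the
#' variance of the residual is returned, corrected for the variance removed
#' by subtracting the window mean (a factor `w / (w - 1)` for white noise).
#'
#' @param s A [joint_trajectory()].
#' @param detrend_window Moving-average window length in samples.
#' @return Length-3 numeric vector of non-negative variances (m^2).
#' @export
estimate_variance <- function(s, detrend_window = NULL) {
  stopifnot(inherits(s, "joint_trajectory"))
  n <- length(s$timestamps)
  if (is.null(detrend_window)) {
    rate <- 1 / stats::median(diff(s$timestamps))
    detrend_window <- max(3L, as.integer(round(0.5 * rate)))
  }
  detrend_window <- as.integer(detrend_window)
  stop_if(detrend_window < 2, "`detrend_window` must be >= 2 samples")
  stop_if(n < 2L * detrend_window,
          sprintf("input too short: %d samples, need >= %d", n,
                  2L * detrend_window))
  # drop half a window at each end: truncated edge windows leave a trend bias
  trim <- detrend_window %/% 2L
  keep <- (trim + 1L):(n - trim)
  vapply(1:3, function(ax) {
    res <- s$coords[, ax] - moving_mean(s$coords[, ax], detrend_window)
    stats::var(res[keep]) * detrend_window / (detrend_window - 1)
  }, numeric(1))
}

#' Per-axis scalar Kalman fusion of two synchronized streams
#'
#' Fuses two equal-length synchronized coordinate streams with a scalar
#' recursion per axis. Two modes are available:
#'
#' * `"standard"` (default): at each step the IMU sample `b` is the
#'   prediction (variance `Z`, plus `p0` extra uncertainty on the first step)
#'   and the depth-camera sample `a` is the measurement (variance `A`):
#'   `K = P'/(P' + A)`, `x = b + K (a - b)`, `P = (1 - K) P'`. The gain lies
#'   in `[0, 1]`, every fused sample lies between `a` and `b`, and with `A`,
#'   `Z` set to the true noise variances the steady-state fused error variance
#'   is `A Z / (A + Z) <= min(A, Z)`.
#' * `"literal"`: transcribes the published pseudocode arithmetic exactly:
#'   `P_k' = sqrt(p_prev + Z)`; `K_k = sqrt(P_k'^2 / (P_k'^2 + A))`;
#'   `x = a + K_k (a - b)`; `P_K = sqrt((1 - K_k) P_k'^2)`; `p_prev <- P_K`.
#'   Kept for auditability; its innovation sign moves the estimate away from
#'   `b`, so it is not the default.
#'
#' @param a,b Equal-length synchronized inputs: [joint_trajectory()]s or
#'   numeric vectors/matrices. `a` is the depth-camera stream, `b` the IMU
#'   stream.
#' @param A Measurement variance of `a` (scalar or per-axis).
#' @param Z Variance of `b` (scalar or per-axis).
#' @param p0 Initial prediction variance.
#' @param mode `"standard"` or `"literal"`.
#' @return For trajectory input, a `fused_trajectory` (fields `timestamps`,
#'   `coords`, `gain_trace`); for vector input, `list(x, gain, variance)`.
#' @export
kalman_fuse <- function(a, b, A = NULL, Z = NULL, p0 = 1e-4,
                        mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  if (inherits(a, "joint_trajectory")) {
    stopifnot(inherits(b, "joint_trajectory"))
    stop_if(length(a$timestamps) != length(b$timestamps),
            "length mismatch between streams; synchronize first")
    if (is.null(A)) A <- estimate_variance(a)
    if (is.null(Z)) Z <- estimate_variance(b)
    A <- rep_len(A, 3); Z <- rep_len(Z, 3)
    coords <- matrix(0, length(a$timestamps), 3)
    gains <- matrix(0, length(a$timestamps), 3)
    for (ax in 1:3) {
      f <- kalman_scalar(a$coords[, ax], b$coords[, ax], A[ax], Z[ax], p0,
                         mode)
      coords[, ax] <- f$x
      gains[, ax] <- f$gain
    }
    return(structure(list(timestamps = a$timestamps, coords = coords,
                          gain_trace = gains, mode = mode),
                     class = c("fused_trajectory", "joint_trajectory")))
  }
  if (is.matrix(a)) {
    stop_if(!is.matrix(b) || any(dim(a) != dim(b)), "length mismatch")
    out <- lapply(seq_len(ncol(a)), function(j)
      kalman_scalar(a[, j], b[, j], rep_len(A, ncol(a))[j],
                    rep_len(Z, ncol(a))[j], p0, mode))
    return(list(x = vapply(out, `[[`, numeric(nrow(a)), "x"),
                gain = vapply(out, `[[`, numeric(nrow(a)), "gain")))
  }
  stop_if(length(a) != length(b), "length mismatch")
  kalman_scalar(a, b, A, Z, p0, mode)
}

kalman_scalar <- function(a, b, A, Z, p0, mode) {
  stop_if(is.null(A) || is.null(Z), "scalar fusion needs explicit A and Z")
  assert_scalar_num(A, "A", lower = 0)
  assert_scalar_num(Z, "Z", lower = 0)
  assert_scalar_num(p0, "p0", lower = 0)
  n <- length(a)
  x <- numeric(n); gain <- numeric(n); pvar <- numeric(n)
  if (mode == "standard") {
    for (k in seq_len(n)) {
      Pp <- Z + if (k == 1L) p0 else 0
      K <- if (Pp + A > 0) Pp / (Pp + A) else 0.5
      x[k] <- b[k] + K * (a[k] - b[k])
      gain[k] <- K
      pvar[k] <- (1 - K) * Pp
    }
  } else {
    p_prev <- p0
    for (k in seq_len(n)) {
      Pk <- sqrt(p_prev + Z)
      K <- sqrt(Pk^2 / (Pk^2 + A))
      x[k] <- a[k] + K * (a[k] - b[k])
      PK <- sqrt((1 - K) * Pk^2)
      gain[k] <- K
      pvar[k] <- PK
      p_prev <- PK
    }
  }
  list(x = x, gain = gain, variance = pvar)
}

#' @export
print.fused_trajectory <- function(x, ...) {
  cat(sprintf("<fused_trajectory> n=%d mode=%s mean gain=%.3f\n",
              length(x$timestamps), x$mode, mean(x$gain_trace)))
  invisible(x)
}

#' Synchronize and fuse a sensor pair in one step
#'
#' @param pair `list(a, b)` of [joint_trajectory()]s (e.g. from
#'   [generate_action_trajectory()]).
#' @param target_rate_hz Resampling rate.
#' @inheritParams kalman_fuse
#' @return A `fused_trajectory`.
#' @export
fuse_pair <- function(pair, target_rate_hz = 30, A = NULL, Z = NULL,
                      p0 = 1e-4, mode = "standard") {
  sync <- synchronize_streams(pair$a, pair$b, target_rate_hz)
  kalman_fuse(sync$s1, sync$s2, A = A, Z = Z, p0 = p0, mode = mode)
}
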