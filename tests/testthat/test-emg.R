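# sEMG filtering, the iEMG envelope, the min-by-length interval recursion,
# burst segmentation and segment extraction.

test_that("band-pass preserves in-band and attenuates out-of-band sinusoids", {
  rate <- 1000
  ts <- seq(0, 2 - 1 / rate, by = 1 / rate)  # integer cycles: no leakage
  in_band <- sin(2 * pi * 100 * ts)
  drift <- sin(2 * pi * 5 * ts)
  rec_in <- emg_recording(rate, cbind(in_band, in_band, in_band))
  rec_dr <- emg_recording(rate, cbind(drift, drift, drift))
  f_in <- bandpass_filter(rec_in, 20, 450, notch_hz = NULL)
  f_dr <- bandpass_filter(rec_dr, 20, 450, notch_hz = NULL)
  expect_equal(sd(f_in$channels[, 1]) / sd(in_band), 1, tolerance = 0.05)
  expect_lt(sd(f_dr$channels[, 1]) / sd(drift), 0.1)
  # zero in, zero out; length preserved
  zero <- emg_recording(rate, matrix(0, 500, 3))
  fz <- bandpass_filter(zero)
  expect_equal(fz$channels, matrix(0, 500, 3), tolerance = 1e-12)
  expect_equal(nrow(f_in$channels), length(ts))
  # band above Nyquist rejected
  expect_error(bandpass_filter(rec_in, 20, 600), "Nyquist")
})

test_that("the 50 Hz notch removes mains interference", {
  rate <- 1000
  ts <- seq(0, 2 - 1 / rate, by = 1 / rate)
  mains <- sin(2 * pi * 50 * ts)
  rec <- emg_recording(rate, cbind(mains, mains, mains))
  f <- bandpass_filter(rec, 20, 450, notch_hz = 50)
  expect_lt(sd(f$channels[, 1]) / sd(mains), 0.15)
})

test_that("iEMG is the windowed mean absolute value", {
  rate <- 100
  # constant signal c -> envelope |c|
  rec_c <- emg_recording(rate, matrix(-2, 50, 3))
  env_c <- compute_iemg(rec_c, 0.1)
  expect_equal(env_c$values, matrix(2, 50, 3), tolerance = 1e-12)
  # alternating +/-1 with window >= 2 -> envelope 1
  alt <- rep(c(1, -1), 25)
  env_a <- compute_iemg(emg_recording(rate, cbind(alt, alt, alt)), 0.05)
  expect_equal(env_a$values[, 1], rep(1, 50), tolerance = 1e-12)
  # random 50-sample signal matches the naive double loop
  set.seed(21)
  x <- rnorm(50)
  env_r <- compute_iemg(emg_recording(rate, cbind(x, x, x)), 0.07)
  expect_equal(env_r$values[, 2], iemg_naive(x, env_r$window_samples),
               tolerance = 1e-12)
  expect_true(all(env_r$values >= 0))
})

test_that("iEMG is translation-equivariant away from the edges", {
  set.seed(22)
  x <- rnorm(200)
  shift <- 30L
  xs <- c(numeric(shift), x)
  e1 <- compute_iemg(emg_recording(100, cbind(x, x, x)), 0.1)$values[, 1]
  e2 <- compute_iemg(emg_recording(100, cbind(xs, xs, xs)), 0.1)$values[, 1]
  w <- e1 > 0  # interior comparison: skip window half-width at both ends
  h <- 6L
  idx <- (h + 1):(length(x) - h)
  expect_equal(e2[idx + shift], e1[idx], tolerance = 1e-12)
})

test_that("best_interval matches its worked examples and rejects bad input", {
  bi <- best_interval(c(1, 3, 2))
  expect_equal(bi$interval$start, 1L)
  expect_equal(bi$interval$end, 3L)
  expect_equal(bi$interval$score, 4)
  # constant array: full interval, score c * L
  bc <- best_interval(rep(2.5, 8))$interval
  expect_equal(c(bc$start, bc$end, bc$score), c(0, 8, 20))
  # single element
  b1 <- best_interval(5)$interval
  expect_equal(c(b1$start, b1$end, b1$score), c(0, 1, 5))
  expect_error(best_interval(numeric(0)), "non-empty")
  expect_error(best_interval(c(1, -2)), "non-negative")
})

test_that("best_interval equals O(n^2) brute force on 500 random arrays", {
  set.seed(23)
  for (i in 1:500) {
    v <- round(runif(sample(1:12, 1), 0, 4), 2)
    got <- best_interval(v)$interval
    want <- best_interval_brute(v)
    expect_equal(got$score, want$score, tolerance = 1e-10)
  }
})

test_that("best_interval ties break to the leftmost, then shortest interval", {
  # two disjoint equal-score plateaus: [0,2) and [4,6), both score 2
  v <- c(1, 1, 0, 0, 1, 1)
  bi <- best_interval(v)$interval
  expect_equal(c(bi$start, bi$end), c(0, 2))
  # full window ties a sub-window: prefer the shorter at the same start
  b2 <- best_interval(c(2, 1, 0.5))$interval  # [0,1) score 2 vs [0,2) score 2
  expect_equal(c(b2$start, b2$end, b2$score), c(0, 1, 2))
})

test_that("segment_bursts recovers a rectangular burst exactly and handles zeros", {
  env <- c(numeric(40), rep(2, 30), numeric(40))
  out <- segment_bursts(env, threshold_frac = 0.2, min_duration_s = 0.1,
                        rate_hz = 100)
  expect_length(out, 1)
  expect_equal(out[[1]]$start, 40L)
  expect_equal(out[[1]]$end, 70L)
  expect_length(segment_bursts(numeric(100), rate_hz = 100), 0)
})

test_that("segment_bursts output is disjoint, sorted and in bounds", {
  set.seed(24)
  for (i in 1:10) {
    env <- abs(rnorm(600)) * rbinom(600, 1, 0.6)
    out <- segment_bursts(env, rate_hz = 100, min_duration_s = 0.05)
    if (length(out) < 2) next
    starts <- vapply(out, `[[`, integer(1), "start")
    ends <- vapply(out, `[[`, integer(1), "end")
    expect_true(all(diff(starts) > 0))
    expect_true(all(starts[-1] >= ends[-length(ends)]))
    expect_true(all(starts >= 0 & ends <= 600))
  }
})

test_that("planted bursts are recovered from generated sEMG (5 reps)", {
  rec <- generate_semg(1, severity_profile(4), 1000, seed = 77, reps = 5)
  env <- compute_iemg(bandpass_filter(rec), 0.1)
  out <- segment_bursts(env)
  gt <- attr(rec, "ground_truth")$intervals
  iou <- function(a1, a2, b1, b2) {
    inter <- max(0, min(a2, b2) - max(a1, b1))
    inter / (max(a2, b2) - min(a1, b1))
  }
  hits <- 0L
  for (g in seq_len(nrow(gt))) {
    best <- max(vapply(out, function(iv)
      iou(gt$start_s[g], gt$end_s[g], iv$start / 1000, iv$end / 1000),
      numeric(1)))
    if (best >= 0.8) hits <- hits + 1L
  }
  expect_gte(hits, nrow(gt) - 1L)
})

test_that("extract_segment resamples and normalizes to the classifier shape", {
  set.seed(25)
  x <- matrix(rnorm(600), 200, 3)
  rec <- emg_recording(1000, x)
  # 200-sample interval: passthrough up to normalization
  seg <- extract_segment(rec, activity_interval(0, 200, 1), normalize = FALSE)
  expect_equal(seg, x, tolerance = 1e-12)
  segn <- extract_segment(rec, activity_interval(0, 200, 1))
  expect_equal(colMeans(segn), numeric(3), tolerance = 1e-12)
  expect_equal(apply(segn, 2, sd), rep(1, 3), tolerance = 1e-12)
  # 400-sample interval: equals direct interpolation at the output positions
  y <- matrix(rnorm(1200), 400, 3)
  rec2 <- emg_recording(1000, y)
  seg2 <- extract_segment(rec2, activity_interval(0, 400, 1),
                          normalize = FALSE)
  pos <- seq(1, 400, length.out = 200)
  for (ch in 1:3) {
    lo <- floor(pos); hi <- ceiling(pos); fr <- pos - lo
    manual <- y[lo, ch] * (1 - fr) + y[hi, ch] * fr
    expect_equal(seg2[, ch], manual, tolerance = 1e-10)
  }
  expect_equal(dim(seg2), c(200L, 3L))
  expect_error(extract_segment(rec, activity_interval(0, 1, 1)), "degenerate")
})
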