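# Synthetic-data generator: templates, severity, sensor noise, sEMG, cohorts.

test_that("zero-noise healthy streams equal the template sampled at each rate", {
  tp <- generate_action_trajectory(1, severity_profile(5),
                                   zero_noise_model(30), zero_noise_model(60),
                                   seed = 7, pad_s = 0.5)
  tpl <- action_template(1)
  for (s in list(tp$a, tp$b)) {
    t_rel <- pmin(1, pmax(0, (s$timestamps - 0.5) / tpl$duration_s))
    expect_equal(s$coords, unname(tpl$waypoint_fn(t_rel)), tolerance = 1e-12)
  }
  # rates respected
  expect_equal(1 / median(diff(tp$a$timestamps)), 30, tolerance = 1e-9)
  expect_equal(1 / median(diff(tp$b$timestamps)), 60, tolerance = 1e-9)
})

test_that("action 2 template has >= 2 interior vertical maxima before the final raise", {
  tp <- generate_action_trajectory(2, severity_profile(5),
                                   zero_noise_model(100), zero_noise_model(100),
                                   seed = 1, pad_s = 0)
  z <- tp$a$coords[, 3]
  peak <- which.max(z)
  before <- z[1:peak]
  n <- length(before)
  is_max <- which(before[2:(n - 1)] > before[1:(n - 2)] &
                    before[2:(n - 1)] > before[3:n]) + 1L
  expect_gte(length(is_max), 2)
})

test_that("action 4 has dominant horizontal displacement in its middle third", {
  tpl <- action_template(4)
  u <- seq(1 / 3, 2 / 3, length.out = 100)
  pos <- tpl$waypoint_fn(u)
  horiz <- max(pos[, 1]) - min(pos[, 1])
  vert <- max(pos[, 3]) - min(pos[, 3])
  expect_gt(horiz, vert)
  expect_gt(horiz, 0.2)
})

test_that("lower grade attenuates peak vertical displacement (same seed)", {
  z_peak <- function(grade) {
    tp <- generate_action_trajectory(1, severity_profile(grade),
                                     zero_noise_model(30), zero_noise_model(60),
                                     seed = 7)
    max(tp$a$coords[, 3]) - tp$a$coords[1, 3]
  }
  expect_lt(z_peak(3), z_peak(5))
  expect_lt(z_peak(4), z_peak(5))
  expect_lt(z_peak(3), z_peak(4))
})

test_that("severity profile invariants hold across the grade scale", {
  profs <- lapply(0:5, severity_profile)
  amp <- vapply(profs, `[[`, numeric(1), "amplitude_scale")
  trem <- vapply(profs, `[[`, numeric(1), "tremor_amp")
  lag <- vapply(profs, `[[`, numeric(1), "lag_scale")
  expect_equal(amp[6], 1)
  expect_equal(trem[6], 0)
  expect_equal(lag[6], 1)
  expect_true(all(diff(amp) > 0))    # amplitude increases with grade
  expect_true(all(diff(trem) < 0))   # tremor decreases with grade
  expect_true(all(lag >= 1))
  expect_error(severity_profile(6), "0..5")
})

test_that("unknown action id is rejected with an explicit message", {
  expect_error(generate_action_trajectory(5, severity_profile(5),
                                          zero_noise_model(), zero_noise_model(),
                                          seed = 1), "1..4")
  expect_error(action_template(0), "1..4")
})

test_that("generators are deterministic under a fixed seed", {
  a1 <- generate_action_trajectory(3, severity_profile(4), seed = 99)
  a2 <- generate_action_trajectory(3, severity_profile(4), seed = 99)
  expect_identical(a1$a$coords, a2$a$coords)
  expect_identical(a1$b$timestamps, a2$b$timestamps)
  r1 <- generate_semg(1, severity_profile(5), 1000, seed = 5)
  r2 <- generate_semg(1, severity_profile(5), 1000, seed = 5)
  expect_identical(r1$channels, r2$channels)
})

test_that("sEMG ground-truth intervals are non-empty and inside the recording", {
  for (a in 1:4) {
    rec <- generate_semg(a, severity_profile(4), 1000, seed = 40 + a, reps = 3)
    gt <- attr(rec, "ground_truth")$intervals
    expect_equal(nrow(gt), 3)
    expect_true(all(gt$end_s > gt$start_s))
    expect_true(all(gt$start_s >= 0))
    expect_true(all(gt$end_s <= nrow(rec$channels) / rec$rate_hz))
  }
})

test_that("burst-window mean absolute amplitude exceeds rest on 20 recordings", {
  for (i in 1:20) {
    action <- (i - 1) %% 4 + 1
    rec <- generate_semg(action, severity_profile(3 + i %% 3), 1000,
                         seed = 200 + i)
    gt <- attr(rec, "ground_truth")$intervals
    ts <- (seq_len(nrow(rec$channels)) - 1) / rec$rate_hz
    inside <- ts >= gt$start_s[1] & ts <= gt$end_s[1]
    for (ch in 1:3) {
      mav_in <- mean(abs(rec$channels[inside, ch]))
      mav_out <- mean(abs(rec$channels[!inside, ch]))
      expect_gt(mav_in, mav_out)
    }
  }
})

test_that("cohort sizes and label balance follow the protocol arithmetic", {
  coh <- generate_cohort(1, grades = 5, reps_per_action = 1, seed = 1,
                         include = "semg")
  expect_equal(nrow(coh$manifest), 4)
  coh2 <- generate_cohort(2, grades = c(5, 4), reps_per_action = 2, seed = 1,
                          include = "semg")
  expect_equal(nrow(coh2$manifest), 2 * 4 * 2)
  expect_true(all(table(coh2$manifest$action_id) == 4))  # uniform by construction
  expect_error(generate_cohort(2, grades = 5, seed = 1), "one entry per")
})

test_that("cohort round-trips through the CSV/JSON directory layout", {
  dir <- file.path(tempdir(), "coh_rt")
  coh <- generate_cohort(1, grades = 4, reps_per_action = 1, seed = 3,
                         noise_b = xsens_noise_model(rate_hz = 60))
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- load_cohort(dir)
  expect_equal(nrow(back$manifest), 4)
  r0 <- coh$records[[1]]; r1 <- back$records[[1]]
  expect_equal(r1$trajectories$a$coords, r0$trajectories$a$coords,
               tolerance = 1e-8)
  expect_equal(r1$emg$channels, r0$emg$channels, tolerance = 1e-8)
  gt0 <- attr(r0$emg, "ground_truth")$intervals
  gt1 <- attr(r1$emg, "ground_truth")$intervals
  expect_equal(gt1$start_s, gt0$start_s, tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})
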