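# Synthetic data generator: kinematic stream pairs (depth camera + IMU) and
# three-channel sEMG recordings with the statistical structure the assessment
# pipeline assumes, so every downstream stage is testable without recordings.

#' Latent (noise-free) severity-transformed trajectory function
#'
#' @param template An [action_template()].
#' @param severity A [severity_profile()].
#' @param tremor_phase Length-3 phase offsets (radians) for the tremor
#'   oscillation on each axis.
#' @return `list(fn, duration_s)` where `fn(t)` maps absolute time (s, motion
#'   starting at 0) to an n x 3 position matrix; outside `[0, duration_s]` the
#'   joint rests at the start position.
#' @noRd
latent_trajectory <- function(template, severity, tremor_phase = c(0, 0, 0)) {
  dur <- template$duration_s * severity$lag_scale
  amp <- severity$amplitude_scale
  rest <- template$waypoint_fn(0)
  fn <- function(t) {
    u <- pmin(1, pmax(0, t / dur))
    pos <- template$waypoint_fn(u)
    pos <- matrix(rest, nrow = length(u), ncol = 3, byrow = TRUE) +
      amp * sweep(pos, 2, rest)
    if (severity$tremor_amp > 0) {
      w <- sin(pi * u)  # tremor only during the movement, vanishing at rest
      for (ax in 1:3) {
        pos[, ax] <- pos[, ax] + severity$tremor_amp * w *
          sin(2 * pi * severity$tremor_hz * t + tremor_phase[ax])
      }
    }
    pos
  }
  list(fn = fn, duration_s = dur)
}

sample_sensor_stream <- function(latent, noise, pad_s, sensor_id) {
  total <- latent$duration_s + 2 * pad_s
  ts <- seq(0, total, by = 1 / noise$rate_hz)
  if (noise$ts_jitter_s > 0) {
    ts <- ts + stats::runif(length(ts), -noise$ts_jitter_s, noise$ts_jitter_s)
    ts[1] <- max(ts[1], 0)
  }
  pos <- latent$fn(ts - pad_s)
  n <- length(ts)
  if (noise$jitter_sd > 0) {
    pos <- pos + matrix(stats::rnorm(3 * n, sd = noise$jitter_sd), n, 3)
  }
  if (noise$spike_prob > 0 && noise$spike_sd > 0) {
    hit <- stats::runif(n) < noise$spike_prob
    if (any(hit)) {
      pos[hit, ] <- pos[hit, ] +
        matrix(stats::rnorm(3 * sum(hit), sd = noise$spike_sd), sum(hit), 3)
    }
  }
  if (noise$drift_sd > 0) {
    step_sd <- noise$drift_sd / sqrt(noise$rate_hz)
    pos <- pos + apply(matrix(stats::rnorm(3 * n, sd = step_sd), n, 3), 2, cumsum)
  }
  joint_trajectory(ts, pos, sensor_id = sensor_id)
}

#' Generate a two-sensor kinematic trajectory pair for one OT repetition
#'
#' Samples the same latent severity-transformed action template through two
#' independent sensor noise models (by default a 30 Hz depth camera with
#' jitter and glitch spikes, and an 800 Hz IMU with drift). Both streams share
#' a common clock origin; rest padding is added before and after the movement
#' so that synchronization never clips motion.
#'
#' @param action_id Integer 1--4, see [action_template()].
#' @param severity A [severity_profile()].
#' @param noise_a,noise_b [sensor_noise_model()]s for the two sensors.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param pad_s Rest padding before/after the movement (s).
#' @return `list(a, b, latent_fn, duration_s)`: two [joint_trajectory()]
#'   streams plus the noise-free latent trajectory function (ground truth).
#' @examples
#' tp <- generate_action_trajectory(1, severity_profile(5),
#'   zero_noise_model(30), zero_noise_model(60), seed = 7)
#' @export
generate_action_trajectory <- function(action_id, severity,
                                       noise_a = kinect_noise_model(),
                                       noise_b = xsens_noise_model(),
                                       seed, pad_s = 0.5) {
  action_id <- validate_action_id(action_id)
  stopifnot(inherits(severity, "severity_profile"),
            inherits(noise_a, "sensor_noise_model"),
            inherits(noise_b, "sensor_noise_model"))
  assert_scalar_num(pad_s, "pad_s", lower = 0)
  tpl <- action_template(action_id)
  with_seed(seed, {
    phase <- stats::runif(3, 0, 2 * pi)
    lat <- latent_trajectory(tpl, severity, tremor_phase = phase)
    a <- sample_sensor_stream(lat, noise_a, pad_s, sensor_id = "kinect")
    b <- sample_sensor_stream(lat, noise_b, pad_s, sensor_id = "xsens")
    list(a = a, b = b,
         latent_fn = function(t) lat$fn(t - pad_s),
         duration_s = lat$duration_s, pad_s = pad_s,
         action_id = action_id)
  })
}

# Per-action, per-channel sEMG burst envelope over normalized burst time
# u in [0,1]. Channels: 1 forelimb, 2 biceps, 3 deltoid. Each action has a
# distinct temporal bump pattern (preserved under per-channel normalization)
# on top of a trapezoid pedestal that keeps the within-burst envelope well
# above baseline.
.gauss_bump <- function(u, center, width) exp(-0.5 * ((u - center) / width)^2)

emg_envelope <- function(action_id, channel, u, ramp_frac) {
  ped <- 0.35 * pmax(0, pmin(1, u / ramp_frac, (1 - u) / ramp_frac))
  b <- .gauss_bump
  bump <- switch(action_id,
    # action 1: single sustained dome, deltoid leads
    {
      ctr <- c(0.55, 0.50, 0.45)[channel]
      w <- c(0.5, 0.8, 1.0)[channel]
      w * b(u, ctr, 0.18)
    },
    # action 2: three effort cycles, biceps-dominant
    {
      off <- 0.02 * (channel - 2)
      w <- c(0.6, 1.0, 0.7)[channel]
      w * (b(u, 0.18 + off, 0.08) + b(u, 0.42 + off, 0.08) +
             b(u, 0.70 + off, 0.10))
    },
    # action 3: concentric/eccentric double hump, forelimb-dominant
    {
      w <- c(1.0, 0.6, 0.5)[channel]
      w * (b(u, 0.30, 0.12) + b(u, 0.70, 0.12))
    },
    # action 4: lift / horizontal carry / lower, channel-specific phases
    {
      switch(channel,
             0.9 * b(u, 0.55, 0.16),                       # forelimb: carry
             0.7 * (b(u, 0.25, 0.12) + b(u, 0.55, 0.12) +
                      b(u, 0.85, 0.12)),                   # biceps: throughout
             1.0 * (b(u, 0.22, 0.10) + b(u, 0.85, 0.10)))  # deltoid: lift/lower
    }
  )
  ped + 0.65 * bump
}

#' Band-limited Gaussian noise carrier (unit standard deviation)
#' @noRd
bandlimited_noise <- function(n, rate_hz, low_hz = 20, high_hz = 450) {
  x <- stats::rnorm(n)
  y <- fft_filter(x, rate_hz, low_hz = low_hz, high_hz = high_hz)
  y / stats::sd(y)
}

#' Generate a synthetic three-channel sEMG recording
#'
#' Produces zero-mean band-limited (20--450 Hz) Gaussian noise amplitude-
#' modulated by an action-specific burst envelope on each of the three
#' channels (forelimb, biceps brachii, deltoid), one burst per repetition,
#' with the protocol's inter-repetition rest. Baseline (inter-burst) noise
#' amplitude is 4% of the burst amplitude. The true burst intervals are
#' attached as ground truth.
#'
#' @param action_id Integer 1--4.
#' @param severity A [severity_profile()]; lower grades attenuate amplitude
#'   and add 5 Hz tremor modulation, and dilate burst duration.
#' @param rate_hz Sampling rate (Hz), >= 1000 recommended.
#' @param seed Integer seed.
#' @param reps Number of movement repetitions (bursts) in the recording.
#' @param lead_s Rest before the first and after the last burst (s).
#' @param rest_s Rest between repetitions (s); the protocol uses 2 s.
#' @return An [emg_recording()] with attribute `ground_truth`:
#'   `list(action_id, grade, intervals)` where `intervals` is a data frame
#'   `(rep, start_s, end_s)`.
#' @examples
#' rec <- generate_semg(1, severity_profile(5), rate_hz = 1000, seed = 1)
#' attr(rec, "ground_truth")$intervals
#' @export
generate_semg <- function(action_id, severity, rate_hz = 1000, seed,
                          reps = 1, lead_s = 1, rest_s = 2) {
  action_id <- validate_action_id(action_id)
  stopifnot(inherits(severity, "severity_profile"))
  assert_scalar_num(rate_hz, "rate_hz")
  stop_if(rate_hz < 200, "`rate_hz` must be >= 200 (>= 1000 recommended)")
  stop_if(!is.numeric(reps) || reps < 1 || reps != round(reps),
          "`reps` must be a positive integer")
  with_seed(seed, {
    base_dur <- unname(.action_durations[as.character(action_id)]) *
      severity$lag_scale
    amp <- 1.0 * (0.4 + 0.6 * severity$amplitude_scale)  # mV scale
    tremor_depth <- min(0.5, severity$tremor_amp / 0.006 * 0.25)

    starts <- numeric(reps)
    t0 <- lead_s
    for (r in seq_len(reps)) {
      starts[r] <- t0 + stats::runif(1, -0.1, 0.1)
      t0 <- t0 + base_dur + rest_s
    }
    starts[1] <- max(starts[1], 0.2)
    total_s <- starts[reps] + base_dur + lead_s
    n <- ceiling(total_s * rate_hz)
    ts <- (seq_len(n) - 1) / rate_hz
    ramp_frac <- 0.15 / base_dur

    channels <- matrix(0, n, 3)
    env_all <- matrix(0, n, 3)
    rep_amp <- stats::runif(reps, 0.9, 1.1)
    for (ch in 1:3) {
      env <- numeric(n)
      for (r in seq_len(reps)) {
        idx <- which(ts >= starts[r] & ts <= starts[r] + base_dur)
        u <- (ts[idx] - starts[r]) / base_dur
        env[idx] <- env[idx] +
          rep_amp[r] * emg_envelope(action_id, ch, u, ramp_frac)
      }
      if (tremor_depth > 0) {
        env <- env * (1 + tremor_depth * sin(2 * pi * severity$tremor_hz * ts))
      }
      env_all[, ch] <- env
      carrier <- bandlimited_noise(n, rate_hz)
      channels[, ch] <- carrier * (amp * env + 0.04 * amp)
    }
    rec <- emg_recording(rate_hz, channels)
    attr(rec, "ground_truth") <- list(
      action_id = action_id,
      grade = severity$lovett_grade,
      intervals = data.frame(rep = seq_len(reps), start_s = starts,
                             end_s = starts + base_dur),
      envelope = env_all
    )
    rec
  })
}

#' Generate a labeled synthetic cohort
#'
#' Emulates the acquisition protocol: each participant performs
#' `reps_per_action` repetitions of each of the four OT actions, yielding
#' `reps_per_action * 4` records per participant with balanced action labels.
#'
#' @param n_participants Number of participants.
#' @param grades Integer vector of Lovett grades, one per participant.
#' @param reps_per_action Repetitions of each action (protocol: 15).
#' @param seed Integer seed.
#' @param include Which modalities to generate: any of `"kinematics"`,
#'   `"semg"`. Dropping a modality speeds up large cohorts.
#' @param noise_a,noise_b Sensor noise models for the kinematic pair.
#' @param emg_rate_hz sEMG sampling rate.
#' @return Object of class `ot_cohort`: `list(records, manifest)`. Each record
#'   holds `participant_id`, `action_id`, `rep`, `grade`, and (per `include`)
#'   `trajectories` (from [generate_action_trajectory()]) and `emg` (from
#'   [generate_semg()]).
#' @examples
#' coh <- generate_cohort(1, grades = 5, reps_per_action = 1, seed = 1,
#'                        include = "semg")
#' nrow(coh$manifest)  # 4
#' @export
generate_cohort <- function(n_participants, grades, reps_per_action = 15,
                            seed, include = c("kinematics", "semg"),
                            noise_a = kinect_noise_model(),
                            noise_b = xsens_noise_model(),
                            emg_rate_hz = 1000) {
  stop_if(length(grades) != n_participants,
          "`grades` must have one entry per participant")
  include <- match.arg(include, c("kinematics", "semg"), several.ok = TRUE)
  records <- vector("list", n_participants * 4L * reps_per_action)
  man <- vector("list", length(records))
  k <- 0L
  for (p in seq_len(n_participants)) {
    sev <- severity_profile(grades[p])
    for (a in 1:4) {
      for (r in seq_len(reps_per_action)) {
        k <- k + 1L
        rec_seed <- child_seed(seed, k)
        rec <- list(participant_id = p, action_id = a, rep = r,
                    grade = grades[p])
        if ("kinematics" %in% include) {
          rec$trajectories <- generate_action_trajectory(
            a, sev, noise_a, noise_b, seed = rec_seed)
        }
        if ("semg" %in% include) {
          rec$emg <- generate_semg(a, sev, rate_hz = emg_rate_hz,
                                   seed = rec_seed + 1L)
        }
        records[[k]] <- rec
        man[[k]] <- data.frame(record = k, participant_id = p, action_id = a,
                               rep = r, grade = grades[p])
      }
    }
  }
  structure(list(records = records, manifest = do.call(rbind, man)),
            class = "ot_cohort")
}

#' Write / read a cohort as a directory of delimited-text files
#'
#' Trajectories are written as `(timestamp_s, x_m, y_m, z_m)` CSVs, sEMG as
#' `(timestamp_s, ch1, ch2, ch3)` CSVs, together with `manifest.csv`
#' (participant, action, rep, grade, file paths) and `ground_truth.json`
#' holding the true burst intervals.
#'
#' @param cohort An `ot_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `write_cohort()` returns `dir` invisibly; `load_cohort()` returns
#'   an `ot_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ot_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$kinect_file <- NA_character_
  man$imu_file <- NA_character_
  man$emg_file <- NA_character_
  gt <- list()
  for (i in seq_len(nrow(man))) {
    rec <- cohort$records[[man$record[i]]]
    stem <- sprintf("p%02d_a%d_r%02d", rec$participant_id, rec$action_id,
                    rec$rep)
    if (!is.null(rec$trajectories)) {
      for (s in c("a", "b")) {
        tr <- rec$trajectories[[s]]
        f <- file.path(dir, sprintf("%s_%s.csv", stem, tr$sensor_id))
        utils::write.csv(data.frame(timestamp_s = tr$timestamps,
                                    x_m = tr$coords[, 1],
                                    y_m = tr$coords[, 2],
                                    z_m = tr$coords[, 3]),
                         f, row.names = FALSE)
        if (s == "a") man$kinect_file[i] <- basename(f)
        else man$imu_file[i] <- basename(f)
      }
    }
    if (!is.null(rec$emg)) {
      f <- file.path(dir, sprintf("%s_emg.csv", stem))
      n <- nrow(rec$emg$channels)
      utils::write.csv(data.frame(
        timestamp_s = (seq_len(n) - 1) / rec$emg$rate_hz,
        ch1 = rec$emg$channels[, 1], ch2 = rec$emg$channels[, 2],
        ch3 = rec$emg$channels[, 3]), f, row.names = FALSE)
      man$emg_file[i] <- basename(f)
      g <- attr(rec$emg, "ground_truth")
      gt[[stem]] <- list(action_id = g$action_id, grade = g$grade,
                         intervals = g$intervals)
    }
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
load_cohort <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  records <- vector("list", nrow(man))
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path) else list()
  for (i in seq_len(nrow(man))) {
    rec <- list(participant_id = man$participant_id[i],
                action_id = man$action_id[i], rep = man$rep[i],
                grade = man$grade[i])
    if (!is.na(man$kinect_file[i])) {
      rec$trajectories <- list(
        a = read_trajectory_csv(file.path(dir, man$kinect_file[i]), "kinect"),
        b = read_trajectory_csv(file.path(dir, man$imu_file[i]), "xsens"))
    }
    if (!is.na(man$emg_file[i])) {
      rec$emg <- read_emg_csv(file.path(dir, man$emg_file[i]))
      stem <- sprintf("p%02d_a%d_r%02d", rec$participant_id, rec$action_id,
                      rec$rep)
      if (!is.null(gt[[stem]])) {
        g <- gt[[stem]]
        attr(rec$emg, "ground_truth") <- list(
          action_id = g$action_id, grade = g$grade,
          intervals = do.call(rbind, lapply(g$intervals, as.data.frame)))
      }
    }
    records[[i]] <- rec
  }
  structure(list(records = records, manifest = man), class = "ot_cohort")
}

#' Read a trajectory / sEMG CSV
#' @param path File path.
#' @param sensor_id Sensor label for the trajectory.
#' @return A [joint_trajectory()] or [emg_recording()].
#' @export
read_trajectory_csv <- function(path, sensor_id = "sensor") {
  d <- utils::read.csv(path)
  stop_if(ncol(d) < 4, paste0("trajectory CSV needs 4 columns: ", path))
  joint_trajectory(d[[1]], as.matrix(d[, 2:4]), sensor_id = sensor_id)
}

#' @rdname read_trajectory_csv
#' @export
read_emg_csv <- function(path) {
  d <- utils::read.csv(path)
  stop_if(ncol(d) < 4, paste0("sEMG CSV needs 4 columns: ", path))
  ts <- d[[1]]
  rate <- 1 / stats::median(diff(ts))
  emg_recording(rate, as.matrix(d[, 2:4]))
}
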