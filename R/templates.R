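# Parametric templates for the four standardized OT actions, impairment
# severity profiles, and sensor noise models. These types define the "world"
# that the synthetic-data generator draws from.

# Rest position of the tracked distal joint (m): x lateral, y anterior,
# z vertical.
.rest_pos <- c(x = 0.30, y = 0.35, z = 0.90)

# Waypoints per action (columns u, x, y, z). Templates are natural cubic
# splines through these, continuous on [0, 1], starting and ending at rest.
.action_waypoints <- list(
  # Action 1: lift an object above head level (> 45 degrees), lower it.
  `1` = cbind(
    u = c(0, 0.2, 0.5, 0.8, 1),
    x = c(0.30, 0.32, 0.34, 0.32, 0.30),
    y = c(0.35, 0.40, 0.45, 0.40, 0.35),
    z = c(0.90, 1.15, 1.65, 1.15, 0.90)
  ),
  # Action 2: trembling lift -- two raise/lower cycles, then a full raise
  # above 45 degrees and put down ("window cleaning").
  `2` = cbind(
    u = c(0, 0.12, 0.24, 0.36, 0.48, 0.60, 0.75, 0.88, 1),
    x = c(0.30, 0.33, 0.30, 0.33, 0.30, 0.33, 0.32, 0.31, 0.30),
    y = c(0.35, 0.40, 0.37, 0.41, 0.38, 0.42, 0.44, 0.40, 0.35),
    z = c(0.90, 1.20, 1.05, 1.28, 1.10, 1.33, 1.55, 1.20, 0.90)
  ),
  # Action 3: straight-arm low lift (> 20 degrees), low load.
  `3` = cbind(
    u = c(0, 0.3, 0.5, 0.7, 1),
    x = c(0.30, 0.33, 0.35, 0.33, 0.30),
    y = c(0.35, 0.55, 0.62, 0.55, 0.35),
    z = c(0.90, 1.08, 1.18, 1.08, 0.90)
  ),
  # Action 4: lift, translate horizontally to the right, put down.
  `4` = cbind(
    u = c(0, 0.18, 0.33, 0.5, 0.67, 0.82, 1),
    x = c(0.30, 0.31, 0.32, 0.55, 0.78, 0.80, 0.80),
    y = c(0.35, 0.42, 0.45, 0.45, 0.45, 0.42, 0.38),
    z = c(0.90, 1.22, 1.25, 1.25, 1.25, 1.22, 0.90)
  )
)

.action_durations <- c(`1` = 4, `2` = 6, `3` = 3.5, `4` = 5)

#' Parametric template for one OT action
#'
#' Returns the idealized (healthy, noise-free) trajectory of the tracked
#' distal joint for one of the four standardized occupational-therapy
#' actions, as a smooth parametric curve over normalized time.
#'
#' @param action_id Integer 1--4. 1: lift an object above head level;
#'   2: trembling lift with two intermediate lower--raise cycles before the
#'   final raise; 3: straight-arm low lift; 4: lift then horizontal
#'   translation.
#' @return An object of class `action_template`: a list with `action_id`,
#'   `duration_s`, and `waypoint_fn(u)` mapping normalized time in `[0, 1]`
#'   to a length-`u` x 3 matrix of positions in meters.
#' @examples
#' tpl <- action_template(1)
#' pos <- tpl$waypoint_fn(seq(0, 1, length.out = 50))
#' @export
action_template <- function(action_id) {
  action_id <- validate_action_id(action_id)
  wp <- .action_waypoints[[as.character(action_id)]]
  fx <- stats::splinefun(wp[, "u"], wp[, "x"], method = "natural")
  fy <- stats::splinefun(wp[, "u"], wp[, "y"], method = "natural")
  fz <- stats::splinefun(wp[, "u"], wp[, "z"], method = "natural")
  structure(
    list(
      action_id = action_id,
      duration_s = unname(.action_durations[as.character(action_id)]),
      waypoint_fn = function(u) {
        stopifnot(all(u >= 0 & u <= 1))
        cbind(x = fx(u), y = fy(u), z = fz(u))
      }
    ),
    class = "action_template"
  )
}

validate_action_id <- function(action_id) {
  if (!is.numeric(action_id) || length(action_id) != 1L ||
      !is.finite(action_id) || action_id != round(action_id) ||
      action_id < 1 || action_id > 4) {
    stop("`action_id` must be an integer in 1..4, got: ",
         deparse(substitute(action_id)), " = ", paste(action_id, collapse = ","),
         call. = FALSE)
  }
  as.integer(action_id)
}

# Severity mapping, Lovett grades 0..5. Grade 5 is the healthy identity;
# amplitude is non-increasing and tremor non-decreasing as the grade drops.
.severity_table <- data.frame(
  lovett_grade = 0:5,
  amplitude_scale = c(0.15, 0.30, 0.45, 0.60, 0.80, 1.00),
  tremor_amp = c(0.015, 0.012, 0.009, 0.006, 0.003, 0.000),
  tremor_hz = c(5, 5, 5, 5, 5, 5),
  lag_scale = c(1.80, 1.60, 1.40, 1.25, 1.10, 1.00)
)

#' Impairment severity profile from a Lovett muscle-strength grade
#'
#' Maps a clinical Lovett grade (0 = no movement, 5 = normal strength) to the
#' kinematic transformation the generator applies to the healthy template:
#' amplitude attenuation, additive tremor (4--6 Hz band, 5 Hz here), and time
#' dilation (slower execution).
#'
#' @param lovett_grade Integer 0--5.
#' @return Object of class `severity_profile` with fields `lovett_grade`,
#'   `amplitude_scale` (fraction in (0, 1]), `tremor_amp` (m), `tremor_hz`
#'   (Hz), `lag_scale` (>= 1).
#' @examples
#' severity_profile(5)  # healthy: identity transform
#' severity_profile(3)
#' @export
severity_profile <- function(lovett_grade) {
  stop_if(!is.numeric(lovett_grade) || length(lovett_grade) != 1L ||
            !lovett_grade %in% 0:5,
          "`lovett_grade` must be an integer in 0..5")
  row <- .severity_table[.severity_table$lovett_grade == lovett_grade, ]
  structure(as.list(row), class = "severity_profile")
}

#' Sensor noise model
#'
#' Describes one kinematic sensor's error process: per-axis white jitter,
#' sporadic large spikes (skeletal-tracking glitches), low-frequency random
#' walk drift (inertial integration error), sampling rate, and timestamp
#' jitter. The two presets contrast a depth camera (unstable but drift-free)
#' with a wearable IMU (precise but drifting).
#'
#' @param jitter_sd White-noise standard deviation per axis (m).
#' @param spike_prob Per-sample probability of a glitch spike.
#' @param spike_sd Spike magnitude standard deviation (m).
#' @param drift_sd Random-walk drift scale (m per sqrt(s)).
#' @param rate_hz Sampling rate (Hz).
#' @param ts_jitter_s Half-width of uniform timestamp jitter (s); capped
#'   internally at `0.4 / rate_hz` so timestamps stay strictly increasing.
#' @return Object of class `sensor_noise_model`.
#' @examples
#' kinect_noise_model()
#' xsens_noise_model()
#' @export
sensor_noise_model <- function(jitter_sd = 0, spike_prob = 0, spike_sd = 0,
                               drift_sd = 0, rate_hz = 30,
                               ts_jitter_s = 0.002) {
  assert_scalar_num(jitter_sd, "jitter_sd", lower = 0)
  assert_scalar_num(spike_prob, "spike_prob", lower = 0, upper = 1)
  assert_scalar_num(spike_sd, "spike_sd", lower = 0)
  assert_scalar_num(drift_sd, "drift_sd", lower = 0)
  assert_scalar_num(rate_hz, "rate_hz")
  stop_if(rate_hz <= 0, "`rate_hz` must be > 0")
  assert_scalar_num(ts_jitter_s, "ts_jitter_s", lower = 0)
  structure(
    list(jitter_sd = jitter_sd, spike_prob = spike_prob, spike_sd = spike_sd,
         drift_sd = drift_sd, rate_hz = rate_hz,
         ts_jitter_s = min(ts_jitter_s, 0.4 / rate_hz)),
    class = "sensor_noise_model"
  )
}

#' @rdname sensor_noise_model
#' @export
kinect_noise_model <- function(rate_hz = 30) {
  sensor_noise_model(jitter_sd = 0.005, spike_prob = 0.01, spike_sd = 0.03,
                     drift_sd = 0, rate_hz = rate_hz)
}

#' @rdname sensor_noise_model
#' @export
xsens_noise_model <- function(rate_hz = 800) {
  sensor_noise_model(jitter_sd = 0.001, spike_prob = 0, spike_sd = 0,
                     drift_sd = 0.002, rate_hz = rate_hz)
}

#' @rdname sensor_noise_model
#' @export
zero_noise_model <- function(rate_hz = 30) {
  sensor_noise_model(rate_hz = rate_hz, ts_jitter_s = 0)
}
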