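# End-to-end orchestration: session configuration, the per-patient report
# combining the kinematic completion path with the sEMG classification path,
# and cohort-level batch reporting.

#' Session configuration
#'
#' Collects every tunable of the pipeline with validated defaults matching
#' the module-level defaults.
#'
#' @param target_rate_hz Fusion grid rate (Hz).
#' @param kf_mode Kalman mode, `"standard"` or `"literal"`.
#' @param kf_p0 Initial prediction variance.
#' @param kf_A,kf_Z Fixed sensor variances, or `NULL` to estimate from the
#'   streams.
#' @param sync_offset_s Constant clock offset added to the IMU stream.
#' @param use_abs_cc Score the completion rubric on `|r|`.
#' @param iemg_window_s iEMG window (s).
#' @param burst_threshold_frac,burst_min_duration_s Segmentation thresholds.
#' @param filter_low_hz,filter_high_hz,filter_notch_hz sEMG filter band.
#' @param segment_len Classifier input length.
#' @param epochs,lr,batch_size Classifier training hyper-parameters.
#' @param seed Master seed.
#' @return Object of class `session_config`.
#' @export
session_config <- function(target_rate_hz = 30,
                           kf_mode = c("standard", "literal"),
                           kf_p0 = 1e-4, kf_A = NULL, kf_Z = NULL,
                           sync_offset_s = 0, use_abs_cc = FALSE,
                           iemg_window_s = 0.1, burst_threshold_frac = 0.2,
                           burst_min_duration_s = 0.3, filter_low_hz = 20,
                           filter_high_hz = 450, filter_notch_hz = 50,
                           segment_len = 200, epochs = 100, lr = 1e-3,
                           batch_size = 32, seed = 1) {
  kf_mode <- match.arg(kf_mode)
  assert_scalar_num(target_rate_hz, "target_rate_hz")
  stop_if(target_rate_hz <= 0, "`target_rate_hz` must be > 0")
  assert_scalar_num(kf_p0, "kf_p0", lower = 0)
  assert_scalar_num(iemg_window_s, "iemg_window_s")
  stop_if(iemg_window_s <= 0, "`iemg_window_s` must be > 0")
  assert_scalar_num(burst_threshold_frac, "burst_threshold_frac",
                    lower = 0, upper = 1)
  assert_scalar_num(burst_min_duration_s, "burst_min_duration_s", lower = 0)
  stop_if(filter_low_hz <= 0 || filter_high_hz <= filter_low_hz,
          "need 0 < filter_low_hz < filter_high_hz")
  structure(as.list(environment()), class = "session_config")
}

process_emg_recording <- function(rec, config) {
  filt <- bandpass_filter(rec, config$filter_low_hz,
                          min(config$filter_high_hz, rec$rate_hz / 2 - 1),
                          config$filter_notch_hz)
  env <- compute_iemg(filt, config$iemg_window_s)
  ivs <- segment_bursts(env, config$burst_threshold_frac,
                        config$burst_min_duration_s)
  segs <- lapply(ivs, function(iv)
    extract_segment(filt, iv, config$segment_len))
  list(filtered = filt, envelope = env, intervals = ivs, segments = segs)
}

#' Run the full assessment for one recording session
#'
#' Mirrors the two-module assessment workflow: the kinematic path
#' (synchronize, Kalman-fuse, split into repetitions, score completion
#' against healthy references) and the sEMG path (filter, iEMG envelope,
#' automatic burst segmentation, fixed-length extraction and — when a trained
#' model is supplied — action classification). Repetition boundaries for the
#' kinematic path are taken from the sEMG segmentation when an sEMG recording
#' is available (the two modalities share one clock); otherwise the fused
#' trajectory is assessed as a single repetition. Stage errors are surfaced
#' with the stage name; a missing sEMG stream degrades to a kinematic-only
#' report rather than failing.
#'
#' @param config A [session_config()].
#' @param kinect,imu [joint_trajectory()]s (or CSV paths).
#' @param emg An [emg_recording()], CSV path, or `NULL`.
#' @param refs A [reference_library()].
#' @param action_id Protocol action label for the session.
#' @param model Optional trained `textcnn_model` for action classification.
#' @return Object of class `patient_report`: per-repetition assessments, mean
#'   CC / DTW / score for the action, predicted labels and agreement rate (if
#'   classified), plus stage counters.
#' @export
run_session <- function(config, kinect, imu, emg = NULL, refs, action_id,
                        model = NULL) {
  stopifnot(inherits(config, "session_config"),
            inherits(refs, "reference_library"))
  action_id <- validate_action_id(action_id)
  if (is.character(kinect)) kinect <- read_trajectory_csv(kinect, "kinect")
  if (is.character(imu)) imu <- read_trajectory_csv(imu, "xsens")
  if (is.character(emg)) {
    emg <- tryCatch(read_emg_csv(emg), error = function(e) NULL)
  }
  log_counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  sync <- stage("synchronize", synchronize_streams(
    kinect, imu, config$target_rate_hz, config$sync_offset_s))
  fused <- stage("fuse", kalman_fuse(sync$s1, sync$s2, A = config$kf_A,
                                     Z = config$kf_Z, p0 = config$kf_p0,
                                     mode = config$kf_mode))
  log_counts$fused_samples <- length(fused$timestamps)

  emg_out <- NULL
  rep_windows <- NULL
  if (!is.null(emg) && nrow(emg$channels) > 0 &&
      any(abs(emg$channels) > 0)) {
    emg_out <- stage("segment", process_emg_recording(emg, config))
    log_counts$bursts <- length(emg_out$intervals)
    if (length(emg_out$intervals) > 0) {
      rep_windows <- lapply(emg_out$intervals, function(iv) {
        c(iv$start / emg$rate_hz - 0.5, iv$end / emg$rate_hz + 0.5)
      })
    }
  }

  slice_fused <- function(win) {
    keep <- fused$timestamps >= win[1] & fused$timestamps <= win[2]
    if (sum(keep) < 5) return(NULL)
    fused$coords[keep, , drop = FALSE]
  }
  reps <- if (is.null(rep_windows)) list(fused$coords) else {
    Filter(Negate(is.null), lapply(rep_windows, slice_fused))
  }
  if (length(reps) == 0) reps <- list(fused$coords)
  assessments <- stage("assess", lapply(reps, function(coords)
    assess_action(coords, refs, action_id, use_abs = config$use_abs_cc)))
  log_counts$repetitions <- length(assessments)

  ccs <- vapply(assessments, `[[`, numeric(1), "cc")
  dtws <- vapply(assessments, `[[`, numeric(1), "dtw_distance")
  classification <- NULL
  if (!is.null(emg_out) && !is.null(model) && length(emg_out$segments) > 0) {
    pred <- stage("classify",
                  predict(model, emg_out$segments))
    classification <- list(predicted = pred,
                           agreement = mean(pred == action_id))
  }
  structure(list(
    action_id = action_id,
    mean_cc = mean(ccs),
    mean_dtw = mean(dtws),
    score = completion_score(mean(ccs), use_abs = config$use_abs_cc),
    per_rep = data.frame(rep = seq_along(ccs), cc = ccs, dtw = dtws,
                         score = completion_score(ccs,
                                                  use_abs = config$use_abs_cc)),
    classification = classification,
    emg_available = !is.null(emg_out),
    counts = log_counts
  ), class = "patient_report")
}

#' @export
print.patient_report <- function(x, ...) {
  cat(sprintf("<patient_report> action=%d mean CC=%.3f DTW=%.2f score=%d%s\n",
              x$action_id, x$mean_cc, x$mean_dtw, x$score,
              if (x$emg_available) "" else " [sEMG absent]"))
  invisible(x)
}

#' Cohort-level completion report
#'
#' Processes every record of a cohort: fuses each repetition's sensor pair,
#' scores it against the healthy references, and aggregates one row per
#' patient with the four per-action mean correlations, DTW distances and
#' completion scores, plus the per-action correlation between patient mean CC
#' and Lovett grade (defined only when grades vary).
#'
#' @param cohort An `ot_cohort` with kinematics (see [generate_cohort()]).
#' @param refs A [reference_library()].
#' @param config A [session_config()].
#' @return `list(table, strength_correlation, failures)`; `table` has columns
#'   `patient`, `grade`, `cc_action1..4`, `dtw_action1..4`, `score_action1..4`.
#' @export
batch_report <- function(cohort, refs, config = session_config()) {
  stopifnot(inherits(cohort, "ot_cohort"))
  man <- cohort$manifest
  patients <- sort(unique(man$participant_id))
  rows <- list()
  failures <- list()
  for (p in patients) {
    cc <- rep(NA_real_, 4); dtw <- rep(NA_real_, 4)
    for (a in 1:4) {
      recs <- which(man$participant_id == p & man$action_id == a)
      ccs <- c(); dts <- c()
      for (ri in recs) {
        rec <- cohort$records[[man$record[ri]]]
        if (is.null(rec$trajectories)) next
        res <- tryCatch({
          fused <- fuse_pair(rec$trajectories, config$target_rate_hz,
                             A = config$kf_A, Z = config$kf_Z,
                             p0 = config$kf_p0, mode = config$kf_mode)
          assess_action(fused, refs, a, use_abs = config$use_abs_cc)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1L]] <-
            sprintf("patient %d action %d rep %d: %s", p, a, man$rep[ri],
                    conditionMessage(res))
          next
        }
        ccs <- c(ccs, res$cc); dts <- c(dts, res$dtw_distance)
      }
      cc[a] <- mean(ccs); dtw[a] <- mean(dts)
    }
    grade <- man$grade[man$participant_id == p][1]
    row <- data.frame(patient = p, grade = grade)
    for (a in 1:4) row[[paste0("cc_action", a)]] <- cc[a]
    for (a in 1:4) row[[paste0("dtw_action", a)]] <- dtw[a]
    for (a in 1:4) {
      row[[paste0("score_action", a)]] <-
        if (is.na(cc[a])) NA_integer_
        else completion_score(cc[a], use_abs = config$use_abs_cc)
    }
    rows[[length(rows) + 1L]] <- row
  }
  tab <- do.call(rbind, rows)
  strength <- rep(NA_real_, 4)
  if (length(unique(tab$grade)) > 1 && nrow(tab) >= 3) {
    for (a in 1:4) {
      strength[a] <- strength_correlation(tab[[paste0("cc_action", a)]],
                                          tab$grade)
    }
  }
  names(strength) <- paste0("action", 1:4)
  list(table = tab, strength_correlation = strength, failures = failures)
}

#' Write a patient report to CSV + JSON
#'
#' @param report A `patient_report` from [run_session()].
#' @param path_prefix Output path prefix (writes `<prefix>.csv` and
#'   `<prefix>.json`).
#' @export
write_report <- function(report, path_prefix) {
  stopifnot(inherits(report, "patient_report"))
  utils::write.csv(report$per_rep, paste0(path_prefix, ".csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(action_id = report$action_id, mean_cc = report$mean_cc,
         mean_dtw = report$mean_dtw, score = report$score,
         emg_available = report$emg_available,
         classification = report$classification,
         counts = report$counts),
    paste0(path_prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path_prefix)
}
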