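# Movement-completion scoring: Pearson correlation between a patient's fused
# trajectory and healthy reference motion, dynamic time warping to absorb
# uneven segmentation, the 0--3 completion rubric, and the correlation of
# completion with clinical muscle strength.

#' Pearson correlation coefficient between two movement series
#'
#' `cov(x1, x2) / sqrt(var(x1) var(x2))`. For 3-axis trajectories (matrices),
#' the coefficient is computed per axis and averaged (unweighted).
#'
#' @param x1 Healthy-reference series (vector or n x k matrix).
#' @param x2 Patient series, same shape.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_cc <- function(x1, x2) {
  if (is.matrix(x1) || is.matrix(x2)) {
    x1 <- as.matrix(x1); x2 <- as.matrix(x2)
    stop_if(any(dim(x1) != dim(x2)), "inputs must have equal dimensions")
    return(mean(vapply(seq_len(ncol(x1)),
                       function(j) pearson_cc(x1[, j], x2[, j]), numeric(1))))
  }
  stop_if(length(x1) != length(x2), "inputs must have equal length")
  stop_if(length(x1) < 3, "need at least 3 samples")
  v1 <- stats::var(x1); v2 <- stats::var(x2)
  stop_if(v1 == 0 || v2 == 0,
          "correlation undefined: an input has zero variance")
  stats::cov(x1, x2) / sqrt(v1 * v2)
}

#' Dynamic time warping distance and optimal path
#'
#' Classic dynamic program with symmetric steps (1,0), (0,1), (1,1), local
#' cost = absolute difference (1-D) or Euclidean distance (multivariate rows),
#' endpoints matched, monotone contiguous path, total cost returned
#' un-normalized (set `normalize = TRUE` to divide by the path length).
#'
#' @param x,y Non-empty numeric vectors or matrices (rows = time).
#' @param normalize Divide the cost by the path length.
#' @return `list(distance, path)`; `path` is an L x 2 matrix of (i, j) index
#'   pairs from (1, 1) to (n, m).
#' @export
dtw_distance <- function(x, y, normalize = FALSE) {
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  ym <- if (is.matrix(y)) y else matrix(y, ncol = 1)
  n <- nrow(xm); m <- nrow(ym)
  stop_if(n == 0 || m == 0, "inputs must be non-empty")
  stop_if(ncol(xm) != ncol(ym), "inputs must have equal dimensionality")
  # local cost matrix (Euclidean across columns)
  cost <- matrix(0, n, m)
  for (j in seq_len(ncol(xm))) {
    cost <- cost + (matrix(xm[, j], n, m) -
                      matrix(ym[, j], n, m, byrow = TRUE))^2
  }
  cost <- sqrt(cost)
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) {
    # vectorized over j is hard because of the row-wise recurrence; the
    # row loop keeps it O(n m) with cheap scalar ops
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- cost[i, j] +
        min(D[i, j], D[i, j + 1L], D[i + 1L, j])
    }
  }
  # backtrack
  path <- matrix(0L, n + m, 2L)
  i <- n; j <- m; k <- 0L
  while (i >= 1L && j >= 1L) {
    k <- k + 1L
    path[k, ] <- c(i, j)
    if (i == 1L && j == 1L) break
    opts <- c(D[i, j], D[i, j + 1L], D[i + 1L, j])  # diag, up, left
    mv <- which.min(opts)
    if (mv == 1L) { i <- i - 1L; j <- j - 1L }
    else if (mv == 2L) i <- i - 1L
    else j <- j - 1L
  }
  path <- path[k:1, , drop = FALSE]
  dist <- D[n + 1L, m + 1L]
  list(distance = if (normalize) dist / nrow(path) else dist, path = path)
}

#' Expand two series along their optimal warping path
#'
#' @inheritParams dtw_distance
#' @return `list(x, y)` of equal length `>= max(len(x), len(y))`, plus the
#'   path.
#' @export
align_by_dtw <- function(x, y) {
  d <- dtw_distance(x, y)
  p <- d$path
  take <- function(s, idx) if (is.matrix(s)) s[idx, , drop = FALSE] else s[idx]
  list(x = take(x, p[, 1]), y = take(y, p[, 2]), path = p,
       distance = d$distance)
}

#' Map a Pearson correlation to the 0--3 completion score
#'
#' Rubric: `r >= 0.8` scores 3 (excellent), `0.5 <= r < 0.8` scores 2
#' (moderate), `0.3 <= r < 0.5` scores 1 (poor), `r < 0.3` scores 0
#' (incomplete). With `use_abs = TRUE` the magnitude `|r|` is used instead of
#' the signed value (the rubric's bottom band is described in terms of
#' insignificant correlation magnitude).
#'
#' @param r Finite correlation value(s).
#' @param use_abs Score on `|r|` instead of signed `r`.
#' @return Integer score(s) in 0..3.
#' @examples
#' completion_score(c(0.96, 0.39, 0.80, 0.29))  # 3 1 3 0
#' @export
completion_score <- function(r, use_abs = FALSE) {
  stop_if(any(!is.finite(r)), "`r` must be finite")
  if (use_abs) r <- abs(r)
  ifelse(r >= 0.8, 3L, ifelse(r >= 0.5, 2L, ifelse(r >= 0.3, 1L, 0L)))
}

#' Healthy reference library
#'
#' @param refs Named list: for each action id (`"1"`..`"4"`), a non-empty list
#'   of reference trajectories (`fused_trajectory` or coordinate matrices).
#' @return Object of class `reference_library`.
#' @export
reference_library <- function(refs) {
  stop_if(!all(as.character(1:4) %in% names(refs)),
          "references must cover every action id 1..4")
  stop_if(any(!vapply(refs, function(r) length(r) > 0, logical(1))),
          "reference list for an action is empty")
  structure(refs, class = "reference_library")
}

#' Build a reference library from healthy synthetic trajectories
#'
#' Generates `n_refs` healthy (grade-5) repetitions of each action, fuses each
#' sensor pair, and packages them as a [reference_library()].
#'
#' @param n_refs References per action.
#' @param seed Integer seed.
#' @param target_rate_hz Fusion grid rate.
#' @param noise_a,noise_b Sensor noise models.
#' @export
make_reference_library <- function(n_refs = 2, seed = 100,
                                   target_rate_hz = 30,
                                   noise_a = kinect_noise_model(),
                                   noise_b = xsens_noise_model()) {
  healthy <- severity_profile(5)
  refs <- lapply(1:4, function(a) {
    lapply(seq_len(n_refs), function(i) {
      pair <- generate_action_trajectory(a, healthy, noise_a, noise_b,
                                         seed = child_seed(seed, a * 100 + i))
      fuse_pair(pair, target_rate_hz)
    })
  })
  names(refs) <- as.character(1:4)
  reference_library(refs)
}

traj_coords <- function(x) {
  if (inherits(x, "joint_trajectory")) x$coords else as.matrix(x)
}

#' Assess one movement repetition against the healthy references
#'
#' DTW-aligns the patient trajectory to each reference for the action, takes
#' the mean Pearson correlation across references, attaches the DTW distance
#' to the nearest reference, and maps the mean correlation to the 0--3
#' completion score.
#'
#' @param patient A `fused_trajectory` (or coordinate matrix).
#' @param refs A [reference_library()].
#' @param action_id Integer 1--4.
#' @param use_abs Passed to [completion_score()].
#' @return Object of class `assessment_record`: `list(action_id, cc,
#'   dtw_distance, score, per_reference)`.
#' @export
assess_action <- function(patient, refs, action_id, use_abs = FALSE) {
  action_id <- validate_action_id(action_id)
  stopifnot(inherits(refs, "reference_library"))
  rlist <- refs[[as.character(action_id)]]
  stop_if(is.null(rlist) || length(rlist) == 0,
          paste0("no reference for action ", action_id))
  pm <- traj_coords(patient)
  ccs <- numeric(length(rlist))
  dists <- numeric(length(rlist))
  for (i in seq_along(rlist)) {
    rm_ <- traj_coords(rlist[[i]])
    al <- align_by_dtw(rm_, pm)
    ccs[i] <- pearson_cc(al$x, al$y)
    dists[i] <- al$distance
  }
  cc <- mean(ccs)
  structure(list(action_id = action_id, cc = cc,
                 dtw_distance = min(dists),
                 score = completion_score(cc, use_abs = use_abs),
                 per_reference = data.frame(reference = seq_along(rlist),
                                            cc = ccs, dtw = dists)),
            class = "assessment_record")
}

#' @export
print.assessment_record <- function(x, ...) {
  cat(sprintf("<assessment_record> action=%d cc=%.3f dtw=%.3f score=%d\n",
              x$action_id, x$cc, x$dtw_distance, x$score))
  invisible(x)
}

#' Correlation between completion and muscle strength
#'
#' Pearson correlation between per-patient mean completion correlations for
#' one action and the patients' Lovett grades.
#'
#' @param assessments Numeric vector of per-patient mean correlations.
#' @param grades Lovett grades, same length.
#' @return Pearson correlation.
#' @export
strength_correlation <- function(assessments, grades) {
  stop_if(length(assessments) != length(grades), "length mismatch")
  stop_if(length(grades) < 3, "need at least 3 patients")
  stop_if(stats::var(grades) == 0, "grades are all equal: correlation undefined")
  pearson_cc(as.numeric(assessments), as.numeric(grades))
}
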