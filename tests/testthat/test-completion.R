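# Pearson correlation, DTW, the completion rubric and strength correlation.

test_that("pearson_cc matches the covariance/variance formula and edge cases", {
  x <- c(1, 2, 4, 3, 5, 7, 6, 8)
  expect_equal(pearson_cc(x, x), 1.0, tolerance = 1e-12)
  expect_equal(pearson_cc(x, -x), -1.0, tolerance = 1e-12)
  # fixed 8-sample pair against direct evaluation of the formula
  y <- c(2, 1, 3, 5, 4, 8, 6, 9)
  n <- length(x)
  cov_xy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  var_x <- sum((x - mean(x))^2) / (n - 1)
  var_y <- sum((y - mean(y))^2) / (n - 1)
  expect_equal(pearson_cc(x, y), cov_xy / sqrt(var_x * var_y),
               tolerance = 1e-12)
  expect_error(pearson_cc(x, rep(1, 8)), "zero variance")
  expect_error(pearson_cc(x, y[1:7]), "equal length")
  # multivariate: unweighted mean of per-axis coefficients
  m1 <- cbind(x, y); m2 <- cbind(y, x)
  expect_equal(pearson_cc(m1, m2),
               mean(c(pearson_cc(x, y), pearson_cc(y, x))), tolerance = 1e-12)
})

test_that("dtw_distance: identity, symmetry, and exhaustive-path equivalence", {
  x <- c(0, 1, 2, 1.5, 3)
  expect_equal(dtw_distance(x, x)$distance, 0)
  # battery: >= 200 random pairs of length <= 6 against brute-force enumeration
  set.seed(11)
  for (i in 1:200) {
    a <- round(runif(sample(2:6, 1), 0, 5), 2)
    b <- round(runif(sample(2:6, 1), 0, 5), 2)
    expect_equal(dtw_distance(a, b)$distance, dtw_brute(a, b),
                 tolerance = 1e-10)
  }
  # symmetry on 50 random short pairs
  set.seed(12)
  for (i in 1:50) {
    a <- runif(sample(3:8, 1)); b <- runif(sample(3:8, 1))
    expect_equal(dtw_distance(a, b)$distance, dtw_distance(b, a)$distance,
                 tolerance = 1e-12)
  }
  # multivariate rows use Euclidean local cost
  am <- cbind(c(0, 1, 2), c(0, 0, 0))
  bm <- cbind(c(0, 1, 1, 2), c(0, 0, 0, 0))
  expect_equal(dtw_distance(am, bm)$distance, dtw_brute(am, bm),
               tolerance = 1e-12)
  expect_error(dtw_distance(numeric(0), 1:3), "non-empty")
})

test_that("dtw path is monotone, contiguous, endpoint-matched", {
  set.seed(13)
  for (i in 1:20) {
    a <- runif(sample(3:10, 1)); b <- runif(sample(3:10, 1))
    p <- dtw_distance(a, b)$path
    expect_equal(p[1, ], c(1, 1))
    expect_equal(p[nrow(p), ], c(length(a), length(b)))
    steps <- diff(p)
    expect_true(all(steps >= 0 & steps <= 1))
    expect_true(all(rowSums(steps) >= 1))
  }
})

test_that("align_by_dtw expands both series along the optimal path", {
  x <- c(0, 1, 2, 3)
  al <- align_by_dtw(x, x)
  expect_equal(al$x, x)
  expect_equal(al$y, x)
  y <- c(0, 1, 1, 2, 3)
  al2 <- align_by_dtw(x, y)
  expect_equal(length(al2$x), length(al2$y))
  expect_gte(length(al2$x), max(length(x), length(y)))
})

test_that("DTW alignment improves CC over plain resampling for time-shifted pairs", {
  set.seed(14)
  wins <- 0L
  for (i in 1:100) {
    f <- function(t) sin(2 * pi * t) + 0.5 * sin(4 * pi * t + runif(1))
    shift <- runif(1, 0.05, 0.2)
    tx <- seq(0, 1, length.out = 60)
    ty <- seq(0, 1, length.out = sample(40:80, 1))
    x <- f(tx)
    y <- f(pmin(1, pmax(0, ty - shift))) + rnorm(length(ty), sd = 0.02)
    al <- align_by_dtw(x, y)
    cc_dtw <- pearson_cc(al$x, al$y)
    n_common <- max(length(x), length(y))
    cc_plain <- pearson_cc(approx(seq_along(x), x, n = n_common)$y,
                           approx(seq_along(y), y, n = n_common)$y)
    if (cc_dtw >= cc_plain) wins <- wins + 1L
  }
  expect_gt(wins, 50)  # majority vote
})

test_that("completion rubric reproduces its banded mapping exactly", {
  expect_identical(completion_score(0.80), 3L)
  expect_identical(completion_score(0.50), 2L)
  expect_identical(completion_score(0.30), 1L)
  expect_identical(completion_score(0.29), 0L)
  expect_identical(completion_score(0.96), 3L)  # patient 4, action 4
  expect_identical(completion_score(0.39), 1L)  # patient 1, action 2
  expect_error(completion_score(NaN), "finite")
  # piecewise-constant, monotone non-decreasing over a fine grid
  grid <- seq(0.3, 1, by = 0.001)
  sc <- completion_score(grid)
  expect_true(all(diff(sc) >= 0))
  expect_setequal(unique(sc), c(1L, 2L, 3L))
  expect_true(all(sc[grid >= 0.8] == 3L))
  expect_true(all(sc[grid >= 0.5 & grid < 0.8] == 2L))
  expect_true(all(sc[grid < 0.5] == 1L))
  # |r| option affects only sign handling
  expect_identical(completion_score(-0.9, use_abs = TRUE), 3L)
  expect_identical(completion_score(-0.9, use_abs = FALSE), 0L)
})

test_that("assess_action: identity, degraded patient, reversed time", {
  refs <- test_reference_library()
  ref_traj <- refs[["1"]][[1]]
  # patient identical to a reference: cc 1 (up to the other reference), dtw 0
  rec <- assess_action(ref_traj, refs, 1)
  expect_equal(rec$dtw_distance, 0)
  expect_equal(rec$per_reference$cc[1], 1.0, tolerance = 1e-12)
  expect_identical(completion_score(rec$per_reference$cc[1]), 3L)
  # synthetic grade-3 patient scores below a healthy identity run
  tp <- generate_action_trajectory(1, severity_profile(3), seed = 31)
  patient <- fuse_pair(tp, 30)
  rec3 <- assess_action(patient, refs, 1)
  expect_lt(rec3$cc, 1)
  expect_lte(rec3$score, 3L)
  # reversed-time stream correlates markedly worse than the forward stream
  # (action 4 is time-asymmetric: the object ends up translated to the right)
  tp4 <- generate_action_trajectory(4, severity_profile(3), seed = 31)
  patient4 <- fuse_pair(tp4, 30)
  fwd <- assess_action(patient4$coords, refs, 4)
  rev <- assess_action(patient4$coords[nrow(patient4$coords):1, ], refs, 4)
  expect_lt(rev$cc, fwd$cc - 0.1)
  expect_error(assess_action(patient, refs, 7), "1..4")
})

test_that("mean CC against healthy references is non-decreasing in grade", {
  refs <- test_reference_library()
  mean_cc <- vapply(c(3, 4, 5), function(g) {
    ccs <- vapply(1:5, function(r) {
      tp <- generate_action_trajectory(2, severity_profile(g),
                                       seed = 500 + r)  # fixed seed bank
      assess_action(fuse_pair(tp, 30), refs, 2)$cc
    }, numeric(1))
    mean(ccs)
  }, numeric(1))
  expect_true(all(diff(mean_cc) >= 0))
})

test_that("strength_correlation behaves on monotone and degenerate input", {
  expect_gt(strength_correlation(c(0.5, 0.6, 0.7, 0.9), c(2, 3, 4, 5)), 0)
  expect_error(strength_correlation(c(0.5, 0.6, 0.7), c(4, 4, 4)),
               "all equal")
  expect_error(strength_correlation(c(0.5, 0.6), c(4, 5)), "at least 3")
})
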