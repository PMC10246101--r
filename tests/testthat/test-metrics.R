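test_that("finite-difference velocity: slopes, smoothing, validation", {
  expect_equal(estimate_velocity(0:2, c(0, 1, 2)), c(1, 1))
  expect_equal(estimate_velocity(0:4, rep(7, 5)), rep(0, 4))
  expect_error(estimate_velocity(c(0, 1, 1), c(0, 1, 2)), "increasing")
  # sampled MJT at 60 Hz: velocity maximum within 2% of the analytic peak
  m <- mjt(0, 50, 1)
  tr <- mjt_sample(m, 60)
  v <- estimate_velocity(tr$t_s, tr$x_pct)
  expect_equal(max(v), 1.875 * 50 / 1, tolerance = 0.02)
  # centred moving average preserves a linear ramp exactly
  vs <- estimate_velocity(seq(0, 1, by = 0.1), seq(0, 5, by = 0.5),
                          smooth_window = 3)
  expect_equal(vs, rep(5, 10))
})

test_that("onset: first positive target-ward sample, thresholds, no-movement", {
  # positions whose successive velocities are 0, 0, 0.2, 1.0
  x <- c(0, 0, 0, 0.2, 1.2)
  expect_identical(detect_onset(0:4, x, target = 50), 3L)
  expect_identical(detect_onset(0:4, rep(0, 5), target = 50), NA_integer_)
  # direction-aware: leftward target with decreasing positions
  expect_identical(detect_onset(0:4, c(50, 50, 49, 40, 30), target = 0), 2L)
  # raising the threshold never moves onset earlier
  set.seed(11)
  for (k in 1:20) {
    t <- seq(0, 2, by = 1 / 60)
    x <- oracle_quintic_pos(0, 50, 2, t) + rnorm(length(t), 0, 0.3)
    o0 <- detect_onset(t, x, 50, epsilon = 0)
    o5 <- detect_onset(t, x, 50, epsilon = 0.5)
    if (!is.na(o0) && !is.na(o5)) expect_gte(o5, o0)
  }
})

test_that("trial end: first tolerance-band entry", {
  seg <- detect_end(c(0, 20, 44, 47, 50), target = 50, tolerance = 5,
                    onset = 1L)
  expect_identical(seg$end, 4L)  # 47 is the first sample with |x-50| <= 5
  expect_true(seg$completed)
  seg2 <- detect_end(c(0, 10, 30, 40, 39), target = 50, tolerance = 5,
                     onset = 1L)
  expect_false(seg2$completed)
  expect_identical(seg2$end, 5L)
  # starting inside the band: end == onset (degenerate trial)
  seg3 <- detect_end(c(0, 1, 2), target = 2, tolerance = 5, onset = 1L)
  expect_identical(seg3$end, 1L)
})

test_that("reference MJT uses the mean time to target", {
  ref <- reference_mjt(c(1.0, 1.2, 1.4), 62.5)
  expect_equal(ref$d, 1.2)
  expect_equal(ref$x0, 0)
  expect_equal(ref$xf, 62.5)
  expect_equal(reference_mjt(0.8, 25)$d, 0.8)
  expect_error(reference_mjt(numeric(0), 25), "completed")
})

test_that("position error: exact, constant offset, noise recovery", {
  ref <- mjt(0, 50, 1)
  t <- seq(0, 1.2, by = 1 / 60)
  x <- mjt_position(ref, pmin(t, 1))
  pe <- position_error(t, x, ref, rate = 60)
  expect_lt(pe$rmse, 1e-9)
  pe3 <- position_error(t, x + 3, ref, rate = 60)
  expect_equal(pe3$rmse, 3, tolerance = 1e-9)
  expect_equal(pe3$signed_mean, 3, tolerance = 1e-9)
  # zero-mean noise of sd 2 yields RMSE ~ 2 on a dense grid
  set.seed(3)
  tg <- seq(0, 1, by = 1e-4)
  pen <- position_error(tg, mjt_position(ref, tg) + rnorm(length(tg), 0, 2),
                        ref, rate = 1e4)
  expect_equal(pen$rmse, 2, tolerance = 0.15)
  expect_error(position_error(seq(0, 0.5, by = 0.01),
                              mjt_position(ref, seq(0, 0.5, by = 0.01)),
                              ref), "shorter")
})

test_that("path efficiency: meander, exact, undershoot, 2-D arc length", {
  expect_equal(path_efficiency(c(0, 30, 20, 46), 50), 132)
  expect_equal(path_efficiency(seq(0, 50, by = 5), 50), 100)
  expect_equal(path_efficiency(seq(0, 45, by = 5), 50), 90)  # (1 - 5/50)*100
  expect_error(path_efficiency(c(50, 50), 50), "undefined")
  expect_equal(path_efficiency(c(0, 3, 3), 4, y = c(0, 4, 0)), 100 * 9 / 4)
})

test_that("peak velocity: earliest tie, degenerate window", {
  pk <- peak_velocity(0:5, c(0, 2, 5, 5, 1), onset = 1L, end = 6L)
  expect_equal(pk$peak, 5)
  expect_equal(pk$time_to_peak, 2)
  expect_equal(peak_velocity(0:5, rep(0, 5), onset = 2L, end = 2L),
               list(peak = 0, time_to_peak = 0))
  # noiseless minimum-jerk trial peaks at half the movement duration
  m <- mjt(0, 50, 1)
  tr <- mjt_sample(m, 60)
  v <- estimate_velocity(tr$t_s, tr$x_pct)
  pk2 <- peak_velocity(tr$t_s, v, 1L, nrow(tr))
  # left-aligned differences put the peak within one sample of d/2
  expect_lt(abs(pk2$time_to_peak - 0.5), 1 / 60 + 1e-9)
})

test_that("velocity peak counting distinguishes bells from submovements", {
  tau <- seq(0, 1, length.out = 120)
  bell <- 30 * tau^2 - 60 * tau^3 + 30 * tau^4
  expect_identical(count_velocity_peaks(bell), 1L)
  # monotone rising segment (entry right at the peak) still counts once
  expect_identical(count_velocity_peaks(bell[tau <= 0.5]), 1L)
  # two well-separated bells count twice
  two <- c(bell, 0.6 * bell)
  expect_identical(count_velocity_peaks(two), 2L)
  # small ripple on the flank is not a peak
  ripple <- bell
  ripple[40] <- ripple[40] + 0.05
  expect_identical(count_velocity_peaks(ripple), 1L)
  expect_identical(count_velocity_peaks(rep(0, 10)), 0L)
})

test_that("metric normalisation is a per-modality rescaling", {
  d <- simulate_reaching(reach_design(n_subjects = 2, blocks = 2,
                                      master_seed = 3))
  m <- trial_metrics(d)
  n <- normalize_metrics(m)
  for (mod in unique(m$modality)) {
    sel <- n$modality == mod & n$completed
    base <- n$target_pct == min(n$target_pct[sel]) & sel
    expect_equal(mean(n$norm_peak_velocity[base]), 1, tolerance = 1e-12)
    expect_equal(mean(n$norm_time_to_target[base]), 1, tolerance = 1e-12)
    # scale invariance of the normalised values
    m2 <- m
    m2$peak_velocity <- m2$peak_velocity * 3.7
    n2 <- normalize_metrics(m2)
    expect_equal(n2$norm_peak_velocity[sel], n$norm_peak_velocity[sel],
                 tolerance = 1e-12)
  }
})

test_that("completion curves step, bound and never decrease", {
  m <- data.frame(subject_id = "S01", modality = "manipulandum",
                  block = 1:4, target_pct = 50,
                  time_to_target = 1, completed = TRUE)
  cc <- completion_curve(m, grid = seq(0, 2, by = 0.25))
  one <- cc[cc$target_pct == "50", ]
  expect_equal(one$pct_completed, c(0, 0, 0, 0, 100, 100, 100, 100, 100))
  expect_identical(nrow(completion_curve(m[0, , drop = FALSE])), 0L)
  d <- simulate_reaching(reach_design(n_subjects = 2, blocks = 2,
                                      master_seed = 4))
  cc2 <- completion_curve(trial_metrics(d))
  for (g in split(cc2, interaction(cc2$modality, cc2$target_pct))) {
    expect_true(all(diff(g$pct_completed[order(g$t_s)]) >= 0))
    expect_true(all(g$pct_completed >= 0 & g$pct_completed <= 100))
  }
})

test_that("trial metrics are deterministic and path length superadditive", {
  d <- simulate_reaching(reach_design(n_subjects = 2, blocks = 2,
                                      master_seed = 5))
  m1 <- trial_metrics(d)
  m2 <- trial_metrics(d)
  expect_identical(m1, m2)
  # path length >= |net displacement| per trial
  tr <- split(d, interaction(d$subject_id, d$modality, d$block, d$target_pct,
                             drop = TRUE, lex.order = TRUE))
  for (i in seq_along(tr)) {
    xs <- tr[[i]]$x_pct[m1$onset_index[i]:nrow(tr[[i]])]
    expect_gte(m1$path_length[i] + 1e-9, abs(xs[length(xs)] - xs[1]))
  }
})

test_that("hold periods are trimmed by segmentation, not preprocessing", {
  # a long pre-movement hold must not contaminate time to target
  prof <- degenerate_profiles()$manipulandum
  tr <- simulate_trial(prof, 50, seed = 9, hold = 1.0)
  dat <- one_trial_data(tr$t_s, tr$x_pct, 50)
  m <- trial_metrics(dat, tolerance = 1e-6, smooth_window = 1)
  d_snap <- attr(tr, "params")$d
  expect_equal(m$time_to_target, d_snap, tolerance = 1e-12)
  expect_equal(m$onset_time, 1.0, tolerance = 1 / 60)
})
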