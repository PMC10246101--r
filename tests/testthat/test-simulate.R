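test_that("duration-law calibration hits its anchors in closed form", {
  targets <- seq(12.5, 87.5, by = 12.5)
  for (anchors in list(c(1.08, 4.24), c(1.68, 4.93), c(0.9, 3.0))) {
    law <- calibrate_duration_law(anchors[1], anchors[2])
    pv <- 1.875 * targets / (law[["intercept"]] + law[["slope"]] * targets)
    expect_equal(cov(targets, pv) / var(targets), anchors[1],
                 tolerance = 1e-9)
    expect_equal(pv[7] / pv[1], anchors[2], tolerance = 1e-9)
    expect_true(all(law[["intercept"]] + law[["slope"]] * targets > 0))
  }
  # endpoint offset shifts the effective displacement
  law2 <- calibrate_duration_law(1.68, 4.93, displacement_offset = -3)
  pv2 <- 1.875 * (targets - 3) /
    (law2[["intercept"]] + law2[["slope"]] * targets)
  expect_equal(cov(targets, pv2) / var(targets), 1.68, tolerance = 1e-9)
  expect_error(calibrate_duration_law(1.08, 8), "ratio")
})

test_that("degenerate profile reproduces the sampled minimum-jerk exactly", {
  prof <- modality_profile("manipulandum", 60, 0.8, 0.008)
  tr <- simulate_trial(prof, 50, seed = 1, hold = 0.25, settle = 0.2)
  pa <- attr(tr, "params")
  d <- pa$d
  expect_equal(d, round((0.8 + 0.008 * 50) * 60) / 60)
  move <- tr[tr$t_s >= 0.25 & tr$t_s <= 0.25 + d, ]
  expect_equal(move$x_pct, mjt_position(mjt(0, 50, d), move$t_s - 0.25),
               tolerance = 1e-12)
  expect_true(all(tr$x_pct[tr$t_s < 0.25] == 0))
  expect_true(all(tr$x_pct[tr$t_s > 0.25 + d] == 50))
  expect_true(all(abs(diff(diff(tr$t_s))) < 1e-12))  # uniform grid
})

test_that("simulation is deterministic and keyed by seed", {
  prof <- default_profiles()$sonomyography
  t1 <- simulate_trial(prof, 62.5, seed = 123)
  t2 <- simulate_trial(prof, 62.5, seed = 123)
  expect_identical(t1, t2)
  t3 <- simulate_trial(prof, 62.5, seed = 124)
  expect_false(identical(t1$x_pct, t3$x_pct))
  des <- reach_design(n_subjects = 2, blocks = 2, master_seed = 77)
  d1 <- simulate_reaching(des)
  d2 <- simulate_reaching(des)
  expect_identical(d1, d2)
  d3 <- simulate(des, seed = 78)
  expect_false(identical(d1$x_pct, d3$x_pct))
})

test_that("default design yields 350 trials per modality", {
  d <- simulate_reaching(reach_design(master_seed = 6))
  keys <- unique(d[, c("subject_id", "modality", "block", "target_pct")])
  expect_identical(nrow(keys), 700L)
  expect_identical(as.vector(table(keys$modality)), c(350L, 350L))
  expect_setequal(unique(d$target_pct), seq(12.5, 87.5, by = 12.5))
  prov <- attr(d, "provenance")
  expect_identical(prov$master_seed, 6L)
  expect_named(prov$profiles, c("manipulandum", "sonomyography"))
})

test_that("drawn durations follow the duration law on average", {
  prof <- default_profiles()$manipulandum
  ds <- vapply(1:200, function(k) {
    attr(simulate_trial(prof, 50, seed = 1000 + k), "params")$d
  }, numeric(1))
  law <- prof$duration_intercept + prof$duration_slope * 50
  expect_equal(mean(ds), law, tolerance = 0.05)
})

test_that("sonomyography draws are more variable at matched distances", {
  # variance_scale and duration noise differ by >= 2x in the defaults
  prof <- default_profiles()
  pv <- function(p, n, target) vapply(seq_len(n), function(k) {
    pa <- attr(simulate_trial(p, target, seed = 5000 + k), "params")
    1.875 * pa$endpoint / pa$d
  }, numeric(1))
  for (target in c(25, 75)) {
    expect_gt(var(pv(prof$sonomyography, 60, target)),
              var(pv(prof$manipulandum, 60, target)))
  }
})

test_that("datasets round-trip through the CSV writer and reader", {
  d <- simulate_reaching(reach_design(n_subjects = 2, blocks = 1,
                                      master_seed = 9))
  path <- file.path(tempdir(), "trials.csv")
  ps <- write_dataset(d, path)
  expect_true(all(file.exists(ps)))
  back <- read_trials(path)
  expect_equal(back$x_pct, d$x_pct, tolerance = 1e-9)
  expect_identical(back$subject_id, d$subject_id)
  side <- jsonlite::read_json(ps[2])
  expect_equal(side$master_seed, 9)
  unlink(ps)
})
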