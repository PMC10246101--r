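#' Control-modality simulation profile
#'
#' Bundles the generator parameters for one cursor-control modality: the
#' linear law mapping movement distance to movement duration, the sampling
#' rate, and the noise structure (white measurement noise, a smooth
#' low-frequency drift, duration variability, endpoint undershoot, optional
#' corrective submovements, and a global variance scale). A per-subject
#' log-normal random effect multiplies both the duration and the noise
#' scales.
#'
#' @param name Modality label (e.g. `"manipulandum"`, `"sonomyography"`).
#' @param sampling_rate Sampling rate in Hz.
#' @param duration_intercept,duration_slope Movement-duration law
#'   `d(D) = intercept + slope * D` (seconds; slope in s per % distance).
#' @param duration_noise_sd SD of the additive duration noise (s).
#' @param additive_noise_sd SD of white position noise (% screen width).
#' @param drift_sd SD of the smooth low-frequency drift component (%).
#' @param undershoot_bias Mean endpoint offset from the target (%); negative
#'   values stop short of the target (inside the tolerance band).
#' @param undershoot_sd SD of the endpoint offset (%).
#' @param corrective_prob Probability of one corrective submovement.
#' @param variance_scale Multiplier applied to all noise standard deviations.
#' @param subject_sd SD (log scale) of the per-subject log-normal effect.
#' @return Object of class `"modality_profile"`.
#' @seealso [default_profiles()], [simulate_trial()]
#' @export
modality_profile <- function(name, sampling_rate,
                             duration_intercept, duration_slope,
                             duration_noise_sd = 0,
                             additive_noise_sd = 0, drift_sd = 0,
                             undershoot_bias = 0, undershoot_sd = 0,
                             corrective_prob = 0, variance_scale = 1,
                             subject_sd = 0) {
  stopifnot(sampling_rate > 0, duration_intercept > 0, duration_slope >= 0,
            duration_noise_sd >= 0, additive_noise_sd >= 0, drift_sd >= 0,
            undershoot_sd >= 0, corrective_prob >= 0, corrective_prob <= 1,
            variance_scale > 0, subject_sd >= 0)
  structure(
    list(name = name, sampling_rate = sampling_rate,
         duration_intercept = duration_intercept,
         duration_slope = duration_slope,
         duration_noise_sd = duration_noise_sd,
         additive_noise_sd = additive_noise_sd, drift_sd = drift_sd,
         undershoot_bias = undershoot_bias, undershoot_sd = undershoot_sd,
         corrective_prob = corrective_prob, variance_scale = variance_scale,
         subject_sd = subject_sd),
    class = "modality_profile"
  )
}

#' @export
print.modality_profile <- function(x, ...) {
  cat(sprintf("Modality profile '%s' (%g Hz)\n", x$name, x$sampling_rate))
  cat(sprintf("  duration law: d(D) = %.4f + %.5f * D  (s)\n",
              x$duration_intercept, x$duration_slope))
  cat(sprintf("  noise: duration sd %.3f s, white %.2f %%, drift %.2f %%, variance scale %.2f\n",
              x$duration_noise_sd, x$additive_noise_sd, x$drift_sd,
              x$variance_scale))
  cat(sprintf("  endpoint: undershoot %.2f +/- %.2f %%, corrective prob %.2f, subject sd %.2f\n",
              x$undershoot_bias, x$undershoot_sd, x$corrective_prob,
              x$subject_sd))
  invisible(x)
}

#' Calibrate a linear duration law from peak-velocity scaling
#'
#' For a minimum-jerk movement the peak velocity obeys
#' `v_peak(D) = 1.875 * D / d(D)`. Given the target OLS slope of peak
#' velocity on distance and the ratio of peak velocities at the largest and
#' smallest distances, this solves the linear duration law
#' `d(D) = a + b * D` in closed form: the ratio anchor fixes `a / b`
#' (the peak-velocity ratio of the family `D / (a/b + D)` is scale-free),
#' and the slope anchor then fixes `b`.
#'
#' @param peak_slope Desired OLS slope of peak velocity on distance (1/s).
#' @param peak_ratio Desired ratio of peak velocity at `max(targets)` to
#'   peak velocity at `min(targets)`.
#' @param targets Distances (% screen width) over which the OLS slope is
#'   evaluated; default the seven-target layout at 12.5-87.5%.
#' @param displacement_offset Mean endpoint offset from the target (%); a
#'   modality that systematically settles short of the target travels
#'   `D + offset`, which the calibration accounts for.
#' @return Named numeric vector `c(intercept, slope)` of the duration law.
#' @examples
#' calibrate_duration_law(1.08, 4.24)
#' @export
calibrate_duration_law <- function(peak_slope, peak_ratio,
                                   targets = seq(12.5, 87.5, by = 12.5),
                                   displacement_offset = 0) {
  stopifnot(peak_slope > 0, peak_ratio > 1, length(targets) >= 3L)
  dmin <- min(targets); dmax <- max(targets)
  eff_min <- dmin + displacement_offset
  eff_max <- dmax + displacement_offset
  stopifnot(eff_min > 0)
  if (peak_ratio >= eff_max / eff_min) {
    stop("peak_ratio must be below the effective distance ratio ",
         eff_max / eff_min, call. = FALSE)
  }
  # v(dmax)/v(dmin) = (eff_max/eff_min) * (a + b*dmin) / (a + b*dmax);
  # the ratio anchor fixes k = a/b, the slope anchor then fixes b
  q <- peak_ratio * eff_min / eff_max
  k <- (q * dmax - dmin) / (1 - q)
  g <- stats::cov(targets,
                  1.875 * (targets + displacement_offset) / (k + targets)) /
    stats::var(targets)
  b <- g / peak_slope
  c(intercept = k * b, slope = b)
}

#' Default modality profiles
#'
#' The two study conditions: a manipulandum (tablet) modality sampled at
#' 60 Hz with low trial-to-trial variability, and a sonomyography-like
#' modality (muscle-signal position control) sampled at 30 Hz with higher
#' variance, a negative endpoint bias (settling short of the target) and more
#' frequent corrective submovements. Duration laws are calibrated with
#' [calibrate_duration_law()] so that the peak-velocity-versus-distance
#' regression has slope 1.08 with ratio 4.24 (manipulandum) and slope 1.68
#' with ratio 4.93 (sonomyography); the manipulandum time-to-target
#' regression slope is then approximately 0.01 s per % distance.
#'
#' @return Named list of two [modality_profile()] objects,
#'   `manipulandum` and `sonomyography`.
#' @export
default_profiles <- function() {
  # mean endpoint offset: bias on non-corrective trials, ~0.3*bias after a
  # corrective submovement
  sono_bias <- -4.0; sono_corr <- 0.15
  dm <- calibrate_duration_law(1.08, 4.24)
  ds <- calibrate_duration_law(
    1.68, 4.93, displacement_offset = sono_bias * (1 - 0.7 * sono_corr))
  list(
    manipulandum = modality_profile(
      name = "manipulandum", sampling_rate = 60,
      duration_intercept = dm[["intercept"]], duration_slope = dm[["slope"]],
      duration_noise_sd = 0.06, additive_noise_sd = 0.04, drift_sd = 0.25,
      undershoot_bias = 0, undershoot_sd = 0.8, corrective_prob = 0.05,
      variance_scale = 1, subject_sd = 0.05),
    sonomyography = modality_profile(
      name = "sonomyography", sampling_rate = 30,
      duration_intercept = ds[["intercept"]], duration_slope = ds[["slope"]],
      duration_noise_sd = 0.09, additive_noise_sd = 0.12, drift_sd = 0.5,
      undershoot_bias = sono_bias, undershoot_sd = 1.0,
      corrective_prob = sono_corr, variance_scale = 1.4, subject_sd = 0.08)
  )
}

# deterministic per-trial / per-subject substream seeds; insertion order
# cannot change draws because every stream is keyed, not sequential
trial_seed <- function(master_seed, subject, modality_idx, target_idx, block) {
  ((master_seed %% 100000) * 1009 + subject * 10007 +
     target_idx * 101 + block * 13 + modality_idx * 3) %% 2147483647L
}

subject_seed <- function(master_seed, subject, modality_idx) {
  ((master_seed %% 100000) * 2003 + subject * 30011 +
     modality_idx * 7) %% 2147483647L
}

# smooth low-frequency drift: spline through coarse Gaussian knots, zeroed
# at the movement start
drift_component <- function(t, sd) {
  if (sd == 0 || length(t) < 2L) return(numeric(length(t)))
  span <- max(t) - min(t)
  nk <- max(4L, ceiling(span * 2) + 2L)
  knots_t <- seq(min(t), max(t), length.out = nk)
  knots_v <- stats::rnorm(nk, 0, sd)
  dr <- stats::spline(knots_t, knots_v, xout = t)$y
  dr - dr[1L]
}

#' Simulate one point-to-point cursor trial
#'
#' Generates a single trial for one modality and target: a zero-velocity hold
#' at the start position, a minimum-jerk transport movement whose duration is
#' drawn from the modality's duration law plus Gaussian noise (snapped to the
#' sampling grid so the final movement sample falls exactly on the movement
#' end), an endpoint drawn with the modality's undershoot bias and clamped
#' inside the tolerance band, optionally one corrective minimum-jerk
#' submovement, a short settle hold, and additive white noise plus a smooth
#' drift component over the movement-and-settle section. Trials are
#' deterministic given the seed.
#'
#' @param profile A [modality_profile()].
#' @param target Target position (% screen width).
#' @param subject_scale Per-subject multiplier on duration and noise scales
#'   (default 1).
#' @param seed Integer seed for this trial's random stream.
#' @param hold Pre-movement hold duration (s), default 0.25.
#' @param settle Post-movement settle duration (s), default 0.2.
#' @param start Start position (%), default 0.
#' @return Data frame with columns `t_s` and `x_pct`, with attribute
#'   `"params"` (list with the drawn movement duration `d`, endpoint offsets
#'   and corrective flag) for provenance.
#' @export
simulate_trial <- function(profile, target, subject_scale = 1, seed = 1L,
                           hold = 0.25, settle = 0.2, start = 0) {
  stopifnot(inherits(profile, "modality_profile"))
  set.seed(as.integer(seed))
  rate <- profile$sampling_rate
  h <- 1 / rate
  vs <- profile$variance_scale * subject_scale

  d_law <- profile$duration_intercept + profile$duration_slope *
    abs(target - start)
  d <- d_law * subject_scale +
    stats::rnorm(1, 0, profile$duration_noise_sd * vs)
  d <- max(d, 0.3)
  d <- max(round(d * rate), 2L) / rate  # snap to the sampling grid

  dirn <- sign(target - start); if (dirn == 0) dirn <- 1
  clamp <- function(u) max(min(u, 4.5), -4.5)
  corrective <- stats::runif(1) < profile$corrective_prob
  if (corrective) {
    # transport overshoots (or misses), then one smaller corrective segment
    u1 <- stats::rnorm(1, 1.5, 1.5 * vs) * dirn
    u2 <- dirn * clamp(stats::rnorm(1, profile$undershoot_bias * 0.3,
                                    0.5 * vs))
    d2 <- max(round(0.4 * d * rate), 2L) / rate
    m1 <- mjt(start, target + u1, d)
    m2 <- mjt(target + u1, target + u2, d2)
    t_move <- seq(0, d + d2, by = h)
    x_move <- ifelse(t_move <= d, predict(m1, pmin(t_move, d)),
                     predict(m2, pmax(pmin(t_move - d, d2), 0)))
    move_end <- d + d2
    endpoint <- target + u2
  } else {
    u <- dirn * clamp(stats::rnorm(1, profile$undershoot_bias,
                                   profile$undershoot_sd * vs))
    m1 <- mjt(start, target + u, d)
    t_move <- seq(0, d, by = h)
    x_move <- predict(m1, t_move)
    move_end <- d
    endpoint <- target + u
  }
  n_settle <- round(settle * rate)
  if (n_settle > 0) {
    t_move <- c(t_move, move_end + seq_len(n_settle) * h)
    x_move <- c(x_move, rep(endpoint, n_settle))
  }
  # drift tapers to zero across the settle: holding the target is visually
  # closed-loop, so slow control wander is suppressed once the cursor dwells
  drift_env <- if (n_settle > 0) {
    pmin(1, pmax(0, (max(t_move) - t_move) / (n_settle * h)))
  } else rep(1, length(t_move))
  x_move <- x_move +
    stats::rnorm(length(x_move), 0, profile$additive_noise_sd * vs) +
    drift_component(t_move, profile$drift_sd * vs) * drift_env
  x_move[1L] <- start  # the movement departs from the held position

  n_hold <- round(hold * rate)
  t_s <- c(seq_len(n_hold) * h - h, t_move + n_hold * h)
  x_pct <- c(rep(start, n_hold), x_move)
  structure(
    data.frame(t_s = t_s, x_pct = x_pct),
    params = list(d = d, d_law = d_law, move_end = move_end,
                  endpoint = endpoint, corrective = corrective,
                  seed = as.integer(seed))
  )
}

#' Experiment design for the simulator
#'
#' Holds the factorial layout of the target-acquisition study: subjects,
#' target positions, blocks (repetitions per target) and the master seed
#' from which all per-trial random streams are derived.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param targets Target positions in % screen width (default the seven
#'   equidistant targets at 12.5, 25, ..., 87.5).
#' @param blocks Repetitions per target (default 5).
#' @param master_seed Integer master seed (default 1).
#' @return Object of class `"reach_design"`.
#' @export
reach_design <- function(n_subjects = 10L,
                         targets = seq(12.5, 87.5, by = 12.5),
                         blocks = 5L, master_seed = 1L) {
  stopifnot(n_subjects >= 1L, blocks >= 1L,
            all(targets > 0), all(targets < 100))
  structure(
    list(n_subjects = as.integer(n_subjects), targets = targets,
         blocks = as.integer(blocks), master_seed = as.integer(master_seed)),
    class = "reach_design"
  )
}

#' @export
print.reach_design <- function(x, ...) {
  cat(sprintf(
    "Reach design: %d subjects x %d targets x %d blocks (seed %d)\n",
    x$n_subjects, length(x$targets), x$blocks, x$master_seed))
  cat("  targets (%):", paste(x$targets, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a full target-acquisition experiment
#'
#' Generates the long-format trajectory dataset for every
#' (subject, modality, target, block) cell of a [reach_design()], using one
#' [modality_profile()] per modality. Per-subject random effects are drawn
#' once per subject and modality; every trial has its own seeded random
#' stream derived from the master seed and the trial key, so datasets are
#' reproducible bit-for-bit and independent of generation order.
#'
#' @param object A [reach_design()].
#' @param nsim Number of datasets (default 1; when larger, a list is
#'   returned and dataset `i` uses `master_seed + i - 1`).
#' @param seed Optional integer overriding the design's master seed.
#' @param profiles Named list of [modality_profile()]s
#'   (default [default_profiles()]).
#' @param ... Unused.
#' @return A long-format data frame with columns `subject_id`, `modality`,
#'   `block`, `target_pct`, `t_s`, `x_pct` (or a list of such data frames
#'   when `nsim > 1`), with attribute `"provenance"` describing the design,
#'   profiles and master seed.
#' @export
simulate.reach_design <- function(object, nsim = 1, seed = NULL,
                                  profiles = default_profiles(), ...) {
  if (nsim > 1) {
    base <- if (is.null(seed)) object$master_seed else as.integer(seed)
    return(lapply(seq_len(nsim) - 1L, function(k) {
      simulate.reach_design(object, nsim = 1, seed = base + k,
                            profiles = profiles)
    }))
  }
  master <- if (is.null(seed)) object$master_seed else as.integer(seed)
  out <- vector("list",
                object$n_subjects * length(profiles) *
                  length(object$targets) * object$blocks)
  k <- 0L
  for (mi in seq_along(profiles)) {
    prof <- profiles[[mi]]
    # all subject effects for one modality come from a single keyed stream
    set.seed(subject_seed(master, 0L, mi))
    scales <- exp(stats::rnorm(object$n_subjects, 0, prof$subject_sd))
    for (s in seq_len(object$n_subjects)) {
      subject_scale <- scales[s]
      for (ti in seq_along(object$targets)) {
        for (b in seq_len(object$blocks)) {
          tr <- simulate_trial(
            prof, object$targets[ti], subject_scale = subject_scale,
            seed = trial_seed(master, s, mi, ti, b))
          k <- k + 1L
          out[[k]] <- data.frame(
            subject_id = sprintf("S%02d", s), modality = prof$name,
            block = b, target_pct = object$targets[ti],
            t_s = tr$t_s, x_pct = tr$x_pct, stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "provenance") <- list(
    design = unclass(object), master_seed = master,
    profiles = lapply(profiles, unclass))
  res
}

#' @rdname simulate.reach_design
#' @param design A [reach_design()].
#' @export
simulate_reaching <- function(design = reach_design(),
                              profiles = default_profiles(), seed = NULL) {
  simulate.reach_design(design, nsim = 1, seed = seed, profiles = profiles)
}

#' Write a simulated dataset with its provenance sidecar
#'
#' Writes the long-format trajectory CSV together with a JSON sidecar
#' recording the design, modality profiles and master seed.
#'
#' @param data A dataset from [simulate_reaching()].
#' @param path Output CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return Invisibly, the two paths written.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  prov <- attr(data, "provenance")
  jsonlite::write_json(prov, side, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(path, side))
}
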