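#' Finite-difference velocity estimate
#'
#' First-order finite difference of position over timestamps, optionally
#' smoothed with a centred moving average. The returned series has one
#' element fewer than the input and is aligned to the left sample of each
#' difference. At the series edges the moving average uses the partial
#' window that fits, so no samples are lost.
#'
#' @param t Strictly increasing numeric vector of timestamps (s).
#' @param x Numeric vector of positions (% screen width), same length as `t`.
#' @param smooth_window Odd integer width of the centred moving average in
#'   samples; 1 (default) means no smoothing.
#' @return Numeric vector of length `length(x) - 1`, units %/s.
#' @export
estimate_velocity <- function(t, x, smooth_window = 1L) {
  stopifnot(is.numeric(t), is.numeric(x), length(t) == length(x))
  if (length(t) < 2L) stop("at least 2 samples are required", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  v <- diff(x) / dt
  w <- as.integer(smooth_window)
  if (w > 1L) {
    half <- w %/% 2L
    n <- length(v)
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    v <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  v
}

#' Movement onset detection
#'
#' Finds the first sample whose target-ward velocity exceeds `epsilon`. The
#' target-ward direction is the sign of (target position minus first
#' position); the default threshold `epsilon = 0` is the first sample with
#' strictly positive target-ward velocity. A larger threshold never moves the
#' detected onset earlier.
#'
#' @param t,x Trajectory timestamps (s) and primary-axis positions (%).
#' @param target Target position (% screen width).
#' @param epsilon Velocity threshold (%/s), default 0.
#' @param velocity Optional pre-computed velocity series aligned to the left
#'   sample (e.g. from [estimate_velocity()] with smoothing); computed
#'   unsmoothed when omitted.
#' @return Integer index of the onset sample, or `NA_integer_` when no sample
#'   qualifies (no-movement flag; the trial is retained but its metrics are
#'   undefined).
#' @export
detect_onset <- function(t, x, target, epsilon = 0, velocity = NULL) {
  if (is.null(velocity)) velocity <- estimate_velocity(t, x)
  dirn <- sign(target - x[1L])
  if (dirn == 0) dirn <- 1
  idx <- which(dirn * velocity > epsilon)
  if (length(idx) == 0L) NA_integer_ else idx[1L]
}

#' Trial end detection
#'
#' The trial end is the first sample at or after onset whose position lies
#' within the tolerance band around the target (`|x - target| <= tolerance`).
#' If the band is never entered the trial is marked uncompleted and the end
#' index is the last sample. A trial already inside the band at onset returns
#' `end == onset` (degenerate, time to target zero).
#'
#' @param x Primary-axis positions (%).
#' @param target Target position (%).
#' @param tolerance Half-width of the acceptance band (% screen width),
#'   default 5 (the +/-5% band used for the seven-target task).
#' @param onset Onset sample index.
#' @return List with `end` (integer index) and `completed` (logical).
#' @export
detect_end <- function(x, target, tolerance = 5, onset = 1L) {
  stopifnot(tolerance > 0, !is.na(onset), onset >= 1L, onset <= length(x))
  inside <- which(abs(x[onset:length(x)] - target) <= tolerance)
  if (length(inside) == 0L) {
    list(end = length(x), completed = FALSE)
  } else {
    list(end = onset + inside[1L] - 1L, completed = TRUE)
  }
}

#' Reference minimum-jerk trajectory for one target
#'
#' Builds the per-target reference MJT the position-error metric compares
#' against: start at 0 (the common start position), end at the target, with
#' duration equal to the mean time to target over the supplied completed
#' trials.
#'
#' @param times Numeric vector of time-to-target values (s) from completed
#'   trials at this target.
#' @param target Target position (% screen width).
#' @return An [mjt()] object.
#' @export
reference_mjt <- function(times, target) {
  times <- times[is.finite(times)]
  if (length(times) == 0L) {
    stop("at least one completed trial is required to build the reference MJT",
         call. = FALSE)
  }
  mjt(0, target, mean(times))
}

#' Position error against the reference minimum-jerk trajectory
#'
#' Root-mean-square and signed mean difference between a position trace and
#' the reference MJT, evaluated on the reference's uniform grid over the
#' movement duration. The trace is given as timestamps (relative to onset)
#' and positions and is linearly interpolated onto the grid.
#'
#' @param t Trace timestamps in seconds from onset; must cover `[0, ref$d]`.
#' @param x Trace positions (%).
#' @param ref Reference [mjt()] object (see [reference_mjt()]).
#' @param rate Evaluation grid rate in Hz (default 60).
#' @return List with `rmse` and `signed_mean`, both in % screen width.
#' @export
position_error <- function(t, x, ref, rate = 60) {
  stopifnot(inherits(ref, "mjt"), length(t) == length(x))
  if (max(t) < ref$d - 1e-9) {
    stop("trace is shorter than the reference MJT duration", call. = FALSE)
  }
  grid <- seq(0, ref$d, by = 1 / rate)
  if (grid[length(grid)] < ref$d - 1e-12) grid <- c(grid, ref$d)
  tr <- stats::approx(t, x, xout = grid, rule = 2)$y
  dev <- tr - predict(ref, grid)
  list(rmse = sqrt(mean(dev^2)), signed_mean = mean(dev))
}

#' Path efficiency of a trajectory segment
#'
#' Ratio (in percent) of the straight-line distance from the segment's start
#' position to the target, to the actual path length traversed. Path length
#' is the sum of successive Euclidean sample-to-sample distances: full 2-D
#' arc length when a lateral axis is supplied, 1-D otherwise. Values above
#' 100% indicate overshoot or a meandering path; values below 100% arise when
#' the movement settles short of the target position.
#'
#' @param x Primary-axis positions (%) from onset to the end of the segment.
#' @param target Target position (%).
#' @param y Optional lateral-axis positions (%), same length as `x`.
#' @return Efficiency in percent: `100 * actual / ideal` where
#'   `ideal = |target - x[1]|`.
#' @examples
#' path_efficiency(c(0, 30, 20, 46), 50)  # path 66, ideal 50 -> 132
#' @export
path_efficiency <- function(x, target, y = NULL) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  ideal <- abs(target - x[1L])
  if (ideal == 0) {
    stop("ideal path length is zero; efficiency is undefined", call. = FALSE)
  }
  if (is.null(y)) {
    actual <- sum(abs(diff(x)))
  } else {
    stopifnot(length(y) == length(x))
    actual <- sum(sqrt(diff(x)^2 + diff(y)^2))
  }
  100 * actual / ideal
}

#' Peak target-ward velocity of a trial segment
#'
#' Maximum of the target-ward velocity between onset and end, with the time
#' offset of the peak from onset. Ties resolve to the earliest sample. An
#' empty window (degenerate trial) returns a peak of 0 at offset 0.
#'
#' @param t Trajectory timestamps (s).
#' @param velocity Velocity series aligned to the left sample
#'   (see [estimate_velocity()]).
#' @param onset,end Sample indices delimiting the movement.
#' @param direction +1 or -1, target-ward sign (default +1).
#' @return List with `peak` (%/s, >= 0 for any moving trial) and
#'   `time_to_peak` (s from onset).
#' @export
peak_velocity <- function(t, velocity, onset, end, direction = 1) {
  if (end <= onset) return(list(peak = 0, time_to_peak = 0))
  idx <- onset:(end - 1L)
  vdir <- direction * velocity[idx]
  k <- which.max(vdir)  # which.max takes the earliest of tied maxima
  list(peak = vdir[k], time_to_peak = t[idx[k]] - t[onset])
}

#' Count distinct velocity peaks in a movement segment
#'
#' Counts local maxima of the target-ward velocity series that qualify as
#' distinct submovement peaks: height at least `height_frac` of the global
#' peak and topographic prominence (rise above the higher of the two
#' enclosing saddles) at least `prominence_frac` of the global peak. A
#' smooth bell-shaped movement yields exactly one; corrective submovements
#' or decomposed movements yield more. Small noise ripples fail either the
#' height or the prominence cut.
#'
#' @param v Target-ward velocity series over the movement (onset to end).
#' @param height_frac Minimum height as a fraction of the global peak
#'   (default 0.3).
#' @param prominence_frac Minimum prominence as a fraction of the global
#'   peak (default 0.2).
#' @return Integer peak count (0 for an empty or non-positive series).
#' @export
count_velocity_peaks <- function(v, height_frac = 0.3,
                                 prominence_frac = 0.2) {
  n <- length(v)
  if (n < 3L) return(as.integer(n > 0 && max(v) > 0))
  pk <- max(v)
  if (pk <= 0) return(0L)
  d <- diff(v)
  locmax <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  if (v[1L] > v[2L]) locmax <- c(1L, locmax)
  if (v[n] > v[n - 1L]) locmax <- c(locmax, n)
  count <- 0L
  for (i in locmax) {
    if (v[i] < height_frac * pk) next
    # prominence: drop to the lowest saddle between this peak and the
    # nearest higher sample; a side with no higher terrain contributes
    # nothing, so the global maximum always qualifies
    left <- if (i > 1L && any(v[seq_len(i - 1L)] > v[i])) {
      j <- max(which(v[seq_len(i - 1L)] > v[i]))
      min(v[j:i])
    } else -Inf
    right <- if (i < n && any(v[(i + 1L):n] > v[i])) {
      j <- i + min(which(v[(i + 1L):n] > v[i]))
      min(v[i:j])
    } else -Inf
    prom <- v[i] - max(left, right)
    if (prom >= prominence_frac * pk) count <- count + 1L
  }
  count
}

# Split a long-format dataset into trials keyed by
# (subject_id, modality, block, target_pct), preserving a stable order.
split_trials <- function(data) {
  required <- c("subject_id", "modality", "block", "target_pct", "t_s", "x_pct")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0L) {
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(data$subject_id, data$modality, data$block,
                     data$target_pct, drop = TRUE, lex.order = TRUE)
  split(data, key)
}

#' Per-trial segmentation and movement metrics
#'
#' Runs the full metric computation on a long-format trajectory dataset: for
#' every trial, movement onset (first positive target-ward velocity), end
#' (first entry into the tolerance band), time to target, peak velocity and
#' its latency, path length and path efficiency (onset to end of trace), and
#' the per-trial position error against the per-target reference MJT built
#' from the mean time to target of completed trials at that
#' (modality, target).
#'
#' Uncompleted and no-movement trials are retained and flagged; their
#' completion-dependent metrics are `NA` and they are excluded from the
#' reference-MJT averages.
#'
#' @param data Long-format data frame with columns `subject_id`, `modality`,
#'   `block`, `target_pct`, `t_s`, `x_pct` and optionally `y_pct`.
#' @param tolerance Acceptance half-band in % screen width (default 5).
#' @param epsilon Onset velocity threshold in %/s (default 0).
#' @param smooth_window Centred moving-average width (samples) applied to the
#'   velocity series used for onset and peak detection (default 5; use 1 for
#'   noise-free data).
#' @return Data frame with one row per trial. Columns include the trial key,
#'   `onset_index`, `onset_time`, `end_index`, `end_time`, `completed`,
#'   `degenerate`, `no_movement`, `time_to_target`, `peak_velocity`,
#'   `time_to_peak`, `path_length`, `path_efficiency`,
#'   `position_error` (per-trial RMSE vs the reference MJT) and
#'   `signed_error`.
#' @export
trial_metrics <- function(data, tolerance = 5, epsilon = 0,
                          smooth_window = 5L) {
  trials <- split_trials(data)
  rows <- lapply(trials, function(tr) {
    tr <- tr[order(tr$t_s), , drop = FALSE]
    t <- tr$t_s
    x <- tr$x_pct
    target <- tr$target_pct[1L]
    if (any(diff(t) <= 0)) {
      stop(sprintf(
        "non-increasing timestamps in trial (subject %s, %s, block %s, target %s)",
        tr$subject_id[1L], tr$modality[1L], tr$block[1L], target),
        call. = FALSE)
    }
    v <- estimate_velocity(t, x, smooth_window = smooth_window)
    dirn <- sign(target - x[1L]); if (dirn == 0) dirn <- 1
    onset <- detect_onset(t, x, target, epsilon = epsilon, velocity = v)
    out <- data.frame(
      subject_id = tr$subject_id[1L], modality = tr$modality[1L],
      block = tr$block[1L], target_pct = target,
      n_samples = length(t),
      onset_index = NA_integer_, onset_time = NA_real_,
      end_index = NA_integer_, end_time = NA_real_,
      completed = FALSE, degenerate = FALSE, no_movement = is.na(onset),
      time_to_target = NA_real_, peak_velocity = NA_real_,
      time_to_peak = NA_real_, n_velocity_peaks = NA_integer_,
      path_length = NA_real_, path_efficiency = NA_real_,
      position_error = NA_real_, signed_error = NA_real_,
      stringsAsFactors = FALSE
    )
    if (is.na(onset)) return(out)
    seg <- detect_end(x, target, tolerance = tolerance, onset = onset)
    out$onset_index <- onset
    out$onset_time <- t[onset]
    out$end_index <- seg$end
    out$end_time <- t[seg$end]
    out$completed <- seg$completed
    out$degenerate <- seg$completed && seg$end == onset
    if (seg$completed) {
      out$time_to_target <- t[seg$end] - t[onset]
      pk <- peak_velocity(t, v, onset, seg$end, direction = dirn)
      out$peak_velocity <- pk$peak
      out$time_to_peak <- pk$time_to_peak
      if (seg$end > onset) {
        out$n_velocity_peaks <-
          count_velocity_peaks(dirn * v[onset:(seg$end - 1L)])
      }
    }
    # path length over onset -> settle (end of trace); 2-D when lateral given
    xs <- x[onset:length(x)]
    ys <- if ("y_pct" %in% names(tr)) tr$y_pct[onset:length(x)] else NULL
    out$path_length <- if (is.null(ys)) sum(abs(diff(xs)))
                       else sum(sqrt(diff(xs)^2 + diff(ys)^2))
    if (abs(target - x[onset]) > 0) {
      out$path_efficiency <- 100 * out$path_length / abs(target - x[onset])
    }
    out
  })
  metrics <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  # per-trial position error against per-(modality, target) reference MJTs
  for (mod in unique(metrics$modality)) {
    for (tg in unique(metrics$target_pct[metrics$modality == mod])) {
      sel <- metrics$modality == mod & metrics$target_pct == tg
      tts <- metrics$time_to_target[sel & metrics$completed]
      if (length(tts) == 0L || mean(tts) <= 0) next
      ref <- reference_mjt(tts, tg)
      rate <- dataset_rate(data, mod)
      for (i in which(sel & metrics$completed)) {
        # metrics rows are in the same order as the split trial list
        tr <- trials[[i]]
        tr <- tr[order(tr$t_s), , drop = FALSE]
        rel_t <- tr$t_s - metrics$onset_time[i]
        keep <- rel_t >= 0
        tt <- rel_t[keep]; xx <- tr$x_pct[keep]
        if (max(tt) < ref$d) {  # extend by the settled position
          tt <- c(tt, ref$d); xx <- c(xx, xx[length(xx)])
        }
        pe <- position_error(tt, xx, ref, rate = rate)
        metrics$position_error[i] <- pe$rmse
        metrics$signed_error[i] <- pe$signed_mean
      }
    }
  }
  metrics
}

# median sampling rate of a modality's trials
dataset_rate <- function(data, modality) {
  sub <- data[data$modality == modality, , drop = FALSE]
  key <- interaction(sub$subject_id, sub$block, sub$target_pct, drop = TRUE)
  dts <- unlist(lapply(split(sub$t_s, key), function(t) diff(sort(t))),
                use.names = FALSE)
  1 / stats::median(dts)
}

#' Normalise metrics to the smallest movement distance
#'
#' Divides each trial's peak velocity (and time to target) by the modality's
#' mean value at the smallest target distance, the convention used to compare
#' velocity scaling across control modalities on a common scale.
#'
#' @param metrics A [trial_metrics()] table.
#' @return The table with `norm_peak_velocity` and `norm_time_to_target`
#'   columns appended.
#' @export
normalize_metrics <- function(metrics) {
  metrics$norm_peak_velocity <- NA_real_
  metrics$norm_time_to_target <- NA_real_
  for (mod in unique(metrics$modality)) {
    sel <- metrics$modality == mod
    dmin <- min(metrics$target_pct[sel])
    base <- sel & metrics$target_pct == dmin & metrics$completed
    if (!any(base)) {
      stop(sprintf(
        "no completed trials at the smallest distance for modality '%s'", mod),
        call. = FALSE)
    }
    ref_pv <- mean(metrics$peak_velocity[base])
    ref_tt <- mean(metrics$time_to_target[base])
    metrics$norm_peak_velocity[sel] <- metrics$peak_velocity[sel] / ref_pv
    metrics$norm_time_to_target[sel] <- metrics$time_to_target[sel] / ref_tt
  }
  metrics
}

#' Completion curves
#'
#' Fraction of trials completed by each time point, per target distance and
#' per modality, plus the across-distance average (`target_pct == "all"`).
#' Curves are nondecreasing in time and lie in `[0, 100]`; uncompleted trials
#' count toward the denominator but never complete.
#'
#' @param metrics A [trial_metrics()] table.
#' @param grid Numeric vector of time points (s); default `seq(0, 3, 0.05)`.
#' @return Long data frame with columns `modality`, `target_pct` (character;
#'   `"all"` for the across-distance average), `t_s`, `pct_completed`.
#' @export
completion_curve <- function(metrics, grid = seq(0, 3, by = 0.05)) {
  if (nrow(metrics) == 0L) {
    return(data.frame(modality = character(), target_pct = character(),
                      t_s = numeric(), pct_completed = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- list()
  for (mod in unique(metrics$modality)) {
    sel <- metrics$modality == mod
    per_dist <- list()
    for (tg in sort(unique(metrics$target_pct[sel]))) {
      sub <- metrics[sel & metrics$target_pct == tg, , drop = FALSE]
      tt <- sub$time_to_target
      frac <- vapply(grid, function(g) {
        100 * sum(!is.na(tt) & tt <= g) / nrow(sub)
      }, numeric(1))
      per_dist[[as.character(tg)]] <- frac
      out[[length(out) + 1L]] <- data.frame(
        modality = mod, target_pct = as.character(tg), t_s = grid,
        pct_completed = frac, stringsAsFactors = FALSE)
    }
    avg <- Reduce(`+`, per_dist) / length(per_dist)
    out[[length(out) + 1L]] <- data.frame(
      modality = mod, target_pct = "all", t_s = grid,
      pct_completed = avg, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
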