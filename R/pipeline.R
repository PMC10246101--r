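#' Read a long-format trajectory dataset
#'
#' Reads and validates the long-format CSV schema: one row per sample with
#' columns `subject_id`, `modality`, `block`, `target_pct`, `t_s`, `x_pct`
#' and optionally `y_pct`; trials are delimited by
#' (subject_id, modality, block, target_pct). Timestamps must be strictly
#' increasing within every trial, and modality labels must be
#' `"manipulandum"` or `"sonomyography"`.
#'
#' @param path Path to a CSV file (UTF-8, header row).
#' @return Validated data frame.
#' @export
read_trials <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(data) == 0L) stop("empty dataset: ", path, call. = FALSE)
  required <- c("subject_id", "modality", "block", "target_pct", "t_s",
                "x_pct")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0L) {
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("target_pct", "t_s", "x_pct")) {
    if (!is.numeric(data[[col]])) {
      stop(sprintf("column '%s' must be numeric", col), call. = FALSE)
    }
  }
  bad_mod <- setdiff(unique(data$modality),
                     c("manipulandum", "sonomyography"))
  if (length(bad_mod) > 0L) {
    stop("unknown modality labels: ", paste(bad_mod, collapse = ", "),
         call. = FALSE)
  }
  if (any(data$x_pct < -10 | data$x_pct > 110)) {
    bad <- which(data$x_pct < -10 | data$x_pct > 110)[1L]
    stop(sprintf("position out of range [-10, 110] at data line %d", bad + 1L),
         call. = FALSE)
  }
  key <- interaction(data$subject_id, data$modality, data$block,
                     data$target_pct, drop = TRUE)
  rows <- split(seq_len(nrow(data)), key)
  for (idx in rows) {
    if (any(diff(data$t_s[idx]) <= 0)) {
      i <- idx[which(diff(data$t_s[idx]) <= 0)[1L] + 1L]
      stop(sprintf(
        "non-increasing timestamps in trial (subject %s, %s, block %s, target %s) at data line %d",
        data$subject_id[i], data$modality[i], data$block[i],
        data$target_pct[i], i + 1L), call. = FALSE)
    }
  }
  data
}

#' Movement-quality analysis of a target-acquisition dataset
#'
#' The central analysis: segments every trial, computes the per-trial
#' kinematic metrics ([trial_metrics()]), builds the per-target reference
#' minimum-jerk trajectories from mean time to target, aggregates per
#' (modality, target), and runs the statistical battery: two-way ANOVAs
#' (modality x distance) on peak velocity, time to target, position error
#' and time to peak; per-distance variance F-tests between modalities for
#' peak velocity, time to target and path efficiency; Brown-Forsythe tests
#' (modality effect on the variance of time to target and peak velocity;
#' distance effect on path-efficiency variance within each modality); and
#' per-modality linear regressions of peak velocity and time to target on
#' distance. Completion curves and normalised metrics are included.
#'
#' @param data Long-format dataset (see [read_trials()]).
#' @param tolerance Acceptance half-band (% screen width), default 5.
#' @param epsilon Onset velocity threshold (%/s), default 0.
#' @param smooth_window Velocity smoothing window (samples), default 5.
#' @param position_error_mode `"mean_trace"` (default) evaluates the RMSE on
#'   the across-trial mean trace per target; `"per_trial"` averages the
#'   per-trial RMSEs. Both variants are always present in the result; the
#'   mode selects which one the aggregate table reports as
#'   `position_error`.
#' @param stats_unit `"trial"` (default) feeds per-trial values to the
#'   statistical tests; `"subject"` aggregates to per-subject means first.
#' @return Object of class `"reach_analysis"` with components `metrics`,
#'   `per_target`, `anova`, `f_tests`, `brown_forsythe`, `regressions`,
#'   `completion`, `mean_traces`, `config`, `provenance`.
#' @export
reach_analysis <- function(data, tolerance = 5, epsilon = 0,
                           smooth_window = 5L,
                           position_error_mode = c("mean_trace", "per_trial"),
                           stats_unit = c("trial", "subject")) {
  position_error_mode <- match.arg(position_error_mode)
  stats_unit <- match.arg(stats_unit)
  metrics <- trial_metrics(data, tolerance = tolerance, epsilon = epsilon,
                           smooth_window = smooth_window)
  metrics <- normalize_metrics(metrics)
  modalities <- unique(metrics$modality)

  # mean traces and mean-trace position error per (modality, target)
  trials <- split_trials(data)
  mean_traces <- list()
  per_target <- list()
  for (mod in modalities) {
    rate <- dataset_rate(data, mod)
    for (tg in sort(unique(metrics$target_pct[metrics$modality == mod]))) {
      sel <- metrics$modality == mod & metrics$target_pct == tg
      comp <- sel & metrics$completed
      tts <- metrics$time_to_target[comp]
      row <- data.frame(
        modality = mod, target_pct = tg,
        n_trials = sum(sel), n_completed = sum(comp),
        time_to_target_mean = mean(tts),
        time_to_target_sd = stats::sd(tts),
        peak_velocity_mean = mean(metrics$peak_velocity[comp]),
        peak_velocity_sd = stats::sd(metrics$peak_velocity[comp]),
        time_to_peak_mean = mean(metrics$time_to_peak[comp]),
        path_efficiency_mean = mean(metrics$path_efficiency[sel],
                                    na.rm = TRUE),
        path_efficiency_sd = stats::sd(metrics$path_efficiency[sel],
                                       na.rm = TRUE),
        position_error_trial_mean = mean(metrics$position_error[comp],
                                         na.rm = TRUE),
        position_error_mean_trace = NA_real_,
        signed_error_mean_trace = NA_real_,
        stringsAsFactors = FALSE)
      if (length(tts) > 0L) {
        ref <- reference_mjt(tts, tg)
        grid <- seq(0, ref$d, by = 1 / rate)
        if (grid[length(grid)] < ref$d - 1e-12) grid <- c(grid, ref$d)
        traces <- vapply(which(comp), function(i) {
          tr <- trials[[i]]
          tr <- tr[order(tr$t_s), , drop = FALSE]
          rel_t <- tr$t_s - metrics$onset_time[i]
          keep <- rel_t >= 0
          stats::approx(rel_t[keep], tr$x_pct[keep], xout = grid,
                        rule = 2)$y
        }, numeric(length(grid)))
        mean_trace <- rowMeans(traces)
        dev <- mean_trace - predict(ref, grid)
        row$position_error_mean_trace <- sqrt(mean(dev^2))
        row$signed_error_mean_trace <- mean(dev)
        mean_traces[[paste(mod, tg, sep = ":")]] <- list(
          modality = mod, target_pct = tg, grid = grid,
          mean_trace = mean_trace, ref = ref,
          sd_trace = apply(traces, 1L, stats::sd))
      }
      per_target[[length(per_target) + 1L]] <- row
    }
  }
  per_target <- do.call(rbind, c(per_target, list(make.row.names = FALSE)))
  per_target$position_error <- if (position_error_mode == "mean_trace") {
    per_target$position_error_mean_trace
  } else {
    per_target$position_error_trial_mean
  }

  # unit of analysis for the statistical battery
  sdat <- metrics[metrics$completed, , drop = FALSE]
  if (stats_unit == "subject") {
    key <- interaction(sdat$subject_id, sdat$modality, sdat$target_pct,
                       drop = TRUE)
    agg <- function(col) tapply(sdat[[col]], key, mean, na.rm = TRUE)
    first <- function(col) tapply(as.character(sdat[[col]]), key,
                                  function(z) z[1L])
    sdat <- data.frame(
      subject_id = first("subject_id"), modality = first("modality"),
      target_pct = as.numeric(tapply(sdat$target_pct, key,
                                     function(z) z[1L])),
      time_to_target = as.numeric(agg("time_to_target")),
      peak_velocity = as.numeric(agg("peak_velocity")),
      time_to_peak = as.numeric(agg("time_to_peak")),
      path_efficiency = as.numeric(agg("path_efficiency")),
      position_error = as.numeric(agg("position_error")),
      stringsAsFactors = FALSE)
  }

  try_stats <- function(expr) {
    tryCatch(expr, error = function(e) {
      data.frame(test = "error", effect = conditionMessage(e),
                 df1 = NA_integer_, df2 = NA_integer_,
                 statistic = NA_real_, p = NA_real_, degenerate = TRUE,
                 stringsAsFactors = FALSE)
    })
  }

  anova_tabs <- list()
  for (metric in c("peak_velocity", "time_to_target", "position_error",
                   "time_to_peak")) {
    tab <- try_stats(two_way_anova(sdat[[metric]], sdat$modality,
                                   sdat$target_pct))
    tab$metric <- metric
    anova_tabs[[metric]] <- tab
  }
  anova_tab <- do.call(rbind, c(anova_tabs, list(make.row.names = FALSE)))

  f_tests <- list()
  if (length(modalities) == 2L) {
    m1 <- modalities[1L]; m2 <- modalities[2L]
    for (metric in c("peak_velocity", "time_to_target", "path_efficiency")) {
      for (tg in sort(unique(sdat$target_pct))) {
        aX <- sdat[[metric]][sdat$modality == m1 & sdat$target_pct == tg]
        bX <- sdat[[metric]][sdat$modality == m2 & sdat$target_pct == tg]
        tab <- try_stats(variance_f_test(aX, bX,
                                         label = sprintf("%s vs %s", m1, m2)))
        tab$metric <- metric
        tab$target_pct <- tg
        f_tests[[length(f_tests) + 1L]] <- tab
      }
    }
  }
  f_tests <- if (length(f_tests) > 0L) {
    do.call(rbind, c(f_tests, list(make.row.names = FALSE)))
  } else NULL

  bf <- list()
  if (length(modalities) == 2L) {
    for (metric in c("time_to_target", "peak_velocity")) {
      tab <- try_stats(brown_forsythe(sdat[[metric]], sdat$modality,
                                      label = "modality"))
      tab$metric <- metric
      bf[[length(bf) + 1L]] <- tab
    }
  }
  for (mod in modalities) {
    sub <- sdat[sdat$modality == mod, , drop = FALSE]
    tab <- try_stats(brown_forsythe(sub$path_efficiency, sub$target_pct,
                                    label = sprintf("distance (%s)", mod)))
    tab$metric <- "path_efficiency"
    bf[[length(bf) + 1L]] <- tab
  }
  bf <- do.call(rbind, c(bf, list(make.row.names = FALSE)))

  regressions <- list()
  for (mod in modalities) {
    sub <- sdat[sdat$modality == mod, , drop = FALSE]
    for (metric in c("peak_velocity", "time_to_target")) {
      fit <- linear_fit(sub$target_pct, sub[[metric]])
      regressions[[length(regressions) + 1L]] <- data.frame(
        modality = mod, metric = metric, slope = fit$slope,
        intercept = fit$intercept, r_squared = fit$r_squared, n = fit$n,
        stringsAsFactors = FALSE)
    }
  }
  regressions <- do.call(rbind, c(regressions, list(make.row.names = FALSE)))

  structure(
    list(metrics = metrics, per_target = per_target, anova = anova_tab,
         f_tests = f_tests, brown_forsythe = bf, regressions = regressions,
         completion = completion_curve(metrics),
         mean_traces = mean_traces,
         config = list(tolerance = tolerance, epsilon = epsilon,
                       smooth_window = smooth_window,
                       position_error_mode = position_error_mode,
                       stats_unit = stats_unit),
         provenance = list(
           n_trials = nrow(metrics),
           n_subjects = length(unique(metrics$subject_id)),
           modalities = modalities,
           input_checksum = round(sum(data$x_pct) + sum(data$t_s), 6))),
    class = "reach_analysis"
  )
}

#' @export
print.reach_analysis <- function(x, ...) {
  cat("Movement-quality analysis\n")
  cat(sprintf("  %d trials, %d subjects, modalities: %s\n",
              x$provenance$n_trials, x$provenance$n_subjects,
              paste(x$provenance$modalities, collapse = ", ")))
  cat(sprintf("  completed: %d (%.1f%%)\n", sum(x$metrics$completed),
              100 * mean(x$metrics$completed)))
  cat("\nDistance-scaling regressions:\n")
  print(x$regressions, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.reach_analysis <- function(object, ...) {
  structure(list(x = object), class = "summary.reach_analysis")
}

#' @export
print.summary.reach_analysis <- function(x, ...) {
  obj <- x$x
  print(obj)
  cat("\nPer-target aggregates:\n")
  cols <- c("modality", "target_pct", "n_completed", "time_to_target_mean",
            "peak_velocity_mean", "path_efficiency_mean", "position_error")
  print(obj$per_target[, cols], row.names = FALSE, digits = 4)
  cat("\nTwo-way ANOVAs (modality x distance):\n")
  print(obj$anova, row.names = FALSE, digits = 4)
  cat("\nBrown-Forsythe tests:\n")
  print(obj$brown_forsythe, row.names = FALSE, digits = 4)
  if (!is.null(obj$f_tests)) {
    cat(sprintf("\nPer-distance variance F-tests: %d of %d with p < 0.05\n",
                sum(obj$f_tests$p < 0.05, na.rm = TRUE), nrow(obj$f_tests)))
  }
  invisible(x)
}

#' @export
coef.reach_analysis <- function(object, ...) {
  object$regressions
}

#' Plot a movement-quality analysis
#'
#' Base-graphics panels mirroring the study's figures: mean position traces
#' with the reference minimum-jerk overlay, peak velocity and time to target
#' versus distance, completion curves, and path efficiency per distance.
#'
#' @param x A [reach_analysis()] object.
#' @param which Character vector among `"traces"`, `"peak_velocity"`,
#'   `"time_to_target"`, `"completion"`, `"path_efficiency"`.
#' @param ... Unused.
#' @export
plot.reach_analysis <- function(x, which = c("traces", "peak_velocity",
                                             "time_to_target", "completion",
                                             "path_efficiency"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  mods <- x$provenance$modalities
  if ("traces" %in% which && length(x$mean_traces) > 0L) {
    tg_show <- stats::median(x$per_target$target_pct)
    tg_show <- x$per_target$target_pct[
      which.min(abs(x$per_target$target_pct - tg_show))][1L]
    op <- graphics::par(mfrow = c(1, length(mods)), mar = c(4, 4, 3, 1))
    for (mod in mods) {
      tr <- x$mean_traces[[paste(mod, tg_show, sep = ":")]]
      if (is.null(tr)) next
      graphics::plot(tr$grid, tr$mean_trace, type = "l", col = "red",
                     lwd = 2, xlab = "time from onset (s)",
                     ylab = "position (% screen width)",
                     main = sprintf("%s, target %g%%", mod, tg_show))
      graphics::polygon(c(tr$grid, rev(tr$grid)),
                        c(tr$mean_trace + tr$sd_trace,
                          rev(tr$mean_trace - tr$sd_trace)),
                        col = grDevices::adjustcolor("gold", 0.4),
                        border = NA)
      graphics::lines(tr$grid, predict(tr$ref, tr$grid), col = "black",
                      lwd = 2, lty = 2)
      graphics::legend("bottomright", c("mean trace", "minimum jerk"),
                       col = c("red", "black"), lty = c(1, 2), bty = "n")
    }
    graphics::par(op)
  }
  panel_by_distance <- function(col, ylab) {
    graphics::plot(range(x$per_target$target_pct),
                   range(x$per_target[[col]], na.rm = TRUE), type = "n",
                   xlab = "target distance (% screen width)", ylab = ylab)
    for (i in seq_along(mods)) {
      sub <- x$per_target[x$per_target$modality == mods[i], ]
      graphics::lines(sub$target_pct, sub[[col]], type = "b", col = i,
                      pch = 19)
    }
    graphics::legend("topleft", mods, col = seq_along(mods), pch = 19,
                     bty = "n")
  }
  if ("peak_velocity" %in% which) {
    panel_by_distance("peak_velocity_mean", "peak velocity (%/s)")
  }
  if ("time_to_target" %in% which) {
    panel_by_distance("time_to_target_mean", "time to target (s)")
  }
  if ("path_efficiency" %in% which) {
    panel_by_distance("path_efficiency_mean", "path efficiency (%)")
  }
  if ("completion" %in% which && nrow(x$completion) > 0L) {
    avg <- x$completion[x$completion$target_pct == "all", ]
    graphics::plot(range(avg$t_s), c(0, 100), type = "n",
                   xlab = "time (s)", ylab = "% trials completed")
    for (i in seq_along(mods)) {
      sub <- avg[avg$modality == mods[i], ]
      graphics::lines(sub$t_s, sub$pct_completed, col = i, lwd = 2)
    }
    graphics::legend("bottomright", mods, col = seq_along(mods), lwd = 2,
                     bty = "n")
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Serialises a [reach_analysis()] to a directory: per-trial metrics,
#' per-target aggregates, the statistical battery (CSV and JSON), the
#' regression fits, completion curves, and figures (PNG) whose backing data
#' are the written CSVs.
#'
#' @param x A [reach_analysis()] object.
#' @param dir Output directory (created if needed).
#' @param figures Write PNG figures (default TRUE).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(x, dir, figures = TRUE) {
  stopifnot(inherits(x, "reach_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(x$metrics, "trial_metrics.csv")
  wr(x$per_target, "per_target.csv")
  stats_tab <- rbind(
    x$anova[, c("test", "effect", "metric", "df1", "df2", "statistic", "p")],
    cbind(x$brown_forsythe[, c("test", "effect", "metric", "df1", "df2",
                               "statistic", "p")]))
  if (!is.null(x$f_tests)) {
    ft <- x$f_tests
    ft$effect <- sprintf("%s @ %g%%", ft$effect, ft$target_pct)
    stats_tab <- rbind(stats_tab,
                       ft[, c("test", "effect", "metric", "df1", "df2",
                              "statistic", "p")])
  }
  wr(stats_tab, "stats.csv")
  wr(x$regressions, "regressions.csv")
  wr(x$completion, "completion_curves.csv")
  pj <- file.path(dir, "stats.json")
  jsonlite::write_json(
    list(config = x$config, provenance = x$provenance,
         anova = x$anova, brown_forsythe = x$brown_forsythe,
         f_tests = x$f_tests, regressions = x$regressions),
    pj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, pj)
  if (figures && nrow(x$metrics) > 0L) {
    for (panel in c("traces", "peak_velocity", "time_to_target",
                    "completion", "path_efficiency")) {
      p <- file.path(dir, paste0("fig_", panel, ".png"))
      grDevices::png(p, width = 900, height = 600)
      tryCatch(plot(x, which = panel), finally = grDevices::dev.off())
      paths <- c(paths, p)
    }
  }
  if (nrow(x$metrics) == 0L) warning("empty report: no figures written")
  invisible(paths)
}
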