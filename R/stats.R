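#' Two-way fixed-effects ANOVA with interaction
#'
#' Classical balanced two-way ANOVA decomposing a per-trial metric into main
#' effects of two crossed factors (typically control modality and movement
#' distance) and their interaction. Distance enters as a categorical factor
#' (7 target levels give 6 degrees of freedom for the distance effect). The
#' design must be balanced with at least two replicates per cell; unbalanced
#' data raise an error rather than silently switching to a Type-II/III
#' decomposition.
#'
#' @param values Numeric response, one element per trial.
#' @param factor_a,factor_b Factors (or vectors coercible to factors) of the
#'   same length as `values`.
#' @param label_a,label_b Effect labels used in the output.
#' @return Data frame with one row per effect (`label_a`, `label_b`,
#'   `interaction`): columns `test`, `effect`, `df1`, `df2`, `statistic`,
#'   `p`, `degenerate`. A zero residual sum of squares is reported as
#'   degenerate (`statistic` and `p` set to `NA`).
#' @export
two_way_anova <- function(values, factor_a, factor_b,
                          label_a = "modality", label_b = "distance") {
  a <- factor(factor_a)
  b <- factor(factor_b)
  stopifnot(length(values) == length(a), length(values) == length(b))
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    stop("both factors need at least 2 levels", call. = FALSE)
  }
  counts <- table(a, b)
  if (any(counts == 0L)) {
    stop("unbalanced design: empty factor cells", call. = FALSE)
  }
  if (length(unique(as.vector(counts))) != 1L || counts[1L] < 2L) {
    stop("unbalanced design: unequal cell counts (>= 2 replicates per cell required)",
         call. = FALSE)
  }
  fit <- stats::aov(values ~ a * b)
  tab <- summary(fit)[[1L]]
  df <- as.integer(tab[["Df"]])
  fs <- tab[["F value"]][1:3]
  ps <- tab[["Pr(>F)"]][1:3]
  ss <- tab[["Sum Sq"]]
  degenerate <- ss[4L] <= 1e-10 * max(sum(ss), .Machine$double.eps) ||
    !all(is.finite(fs))
  if (degenerate) {
    fs <- rep(NA_real_, 3L)
    ps <- rep(NA_real_, 3L)
  }
  data.frame(
    test = "two-way ANOVA",
    effect = c(label_a, label_b, "interaction"),
    df1 = df[1:3], df2 = rep(df[4L], 3L),
    statistic = fs, p = ps, degenerate = degenerate,
    stringsAsFactors = FALSE
  )
}

#' Variance-ratio F-test
#'
#' Two-sample F-test on the ratio of sample variances,
#' `F = var(x) / var(y)` with `n - 1` denominators, and a two-sided p-value
#' from the F distribution with `(n_x - 1, n_y - 1)` degrees of freedom. The
#' direction of the difference is reported alongside the two-sided p.
#'
#' @param x,y Numeric samples, each of size at least 2.
#' @param label Optional effect label stored in the output.
#' @return One-row data frame: `test`, `effect`, `df1`, `df2`, `statistic`
#'   (the variance ratio), `p`, `direction` (`"x>y"`, `"y>x"` or `"equal"`),
#'   `degenerate` (true when the denominator variance is zero).
#' @export
variance_f_test <- function(x, y, label = "variance ratio") {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (vy == 0) {
    return(data.frame(test = "variance F-test", effect = label,
                      df1 = length(x) - 1L, df2 = length(y) - 1L,
                      statistic = NA_real_, p = NA_real_,
                      direction = if (vx > 0) "x>y" else "equal",
                      degenerate = TRUE, stringsAsFactors = FALSE))
  }
  ft <- stats::var.test(x, y)
  data.frame(
    test = "variance F-test", effect = label,
    df1 = unname(ft$parameter[1L]), df2 = unname(ft$parameter[2L]),
    statistic = unname(ft$statistic), p = ft$p.value,
    direction = if (vx > vy) "x>y" else if (vy > vx) "y>x" else "equal",
    degenerate = FALSE, stringsAsFactors = FALSE
  )
}

#' Brown-Forsythe test for homogeneity of variance
#'
#' Transforms every observation to its absolute deviation from the group
#' median and runs a one-way ANOVA F-test on the transformed values. The test
#' is location-invariant: adding a constant to any group leaves the statistic
#' unchanged.
#'
#' @param values Numeric observations.
#' @param groups Grouping factor (or vector coercible to one) of the same
#'   length; at least 2 groups with at least 2 observations each.
#' @param label Optional effect label stored in the output.
#' @return One-row data frame: `test`, `effect`, `df1`, `df2`, `statistic`,
#'   `p`, `degenerate`.
#' @export
brown_forsythe <- function(values, groups, label = "group") {
  g <- factor(groups)
  keep <- is.finite(values) & !is.na(g)
  values <- values[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2L) stop("at least 2 groups are required", call. = FALSE)
  if (any(table(g) < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  med <- tapply(values, g, stats::median)
  dev <- abs(values - med[as.character(g)])
  # classical one-way ANOVA F on the absolute deviations; a zero
  # within-group sum of squares yields a non-finite F, reported degenerate
  wt <- suppressWarnings(stats::oneway.test(dev ~ g, var.equal = TRUE))
  fs <- unname(wt$statistic)
  degenerate <- !is.finite(fs)
  data.frame(
    test = "Brown-Forsythe", effect = label,
    df1 = as.integer(wt$parameter[[1L]]), df2 = as.integer(wt$parameter[[2L]]),
    statistic = if (degenerate) NA_real_ else fs,
    p = if (degenerate) NA_real_ else wt$p.value,
    degenerate = degenerate, stringsAsFactors = FALSE
  )
}

#' Simple linear regression of a metric on movement distance
#'
#' Ordinary least squares fit `y ~ x` returning the slope, intercept and
#' coefficient of determination, used for the distance-scaling regressions
#' (peak velocity and time to target versus target distance).
#'
#' @param x Predictor (target distance, % screen width); not all equal.
#' @param y Response (metric values).
#' @return List of class `"linear_fit"` with `slope`, `intercept`,
#'   `r_squared` and `n`. A constant response yields slope 0 and
#'   `r_squared` 0.
#' @export
linear_fit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("at least 3 points are required", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("singular fit: predictor is constant", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = r2, n = length(x)),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit (n = %d): slope = %.4g, intercept = %.4g, R^2 = %.3f\n",
              x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}
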