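#' Minimum-jerk trajectory model
#'
#' Construct the closed-form minimum-jerk trajectory (MJT) for a
#' point-to-point movement. The MJT is the smooth path that minimises the
#' time integral of squared jerk (the third derivative of position) over the
#' movement, and is the standard reference profile for point-to-point
#' reaching. With normalised time \eqn{\tau = t/d} measured from movement
#' start, the position is the quintic
#' \deqn{x(t) = x_0 + (x_f - x_0)\,(10\tau^3 - 15\tau^4 + 6\tau^5)}
#' and the velocity
#' \deqn{v(t) = \frac{x_f - x_0}{d}\,(30\tau^2 - 60\tau^3 + 30\tau^4),}
#' which is bell-shaped, zero at both endpoints, and peaks at the movement
#' midpoint with value \eqn{1.875\,(x_f - x_0)/d}.
#'
#' Profiles are internally referenced to a start time of zero: `t` passed to
#' [predict.mjt()] is time since movement start. A degenerate movement with
#' `x0 == xf` is allowed and yields a constant trajectory (used to model rest
#' and hold periods).
#'
#' @param x0 Start position (percent of screen width).
#' @param xf Target (final) position (percent of screen width).
#' @param duration Movement duration \eqn{d = t_f - t_s} in seconds; must be
#'   strictly positive.
#' @return An object of class `"mjt"`: a list with elements `x0`, `xf`, `d`,
#'   `ts` (always 0) and `tf` (equal to `d`).
#' @examples
#' m <- mjt(0, 50, 1.2)
#' predict(m, c(0, 0.6, 1.2))
#' predict(m, 0.6, deriv = 1)  # peak velocity = 1.875 * 50 / 1.2
#' @seealso [predict.mjt()], [mjt_sample()], [jerk_cost()]
#' @export
mjt <- function(x0, xf, duration) {
  stopifnot(is.numeric(x0), length(x0) == 1L, is.finite(x0),
            is.numeric(xf), length(xf) == 1L, is.finite(xf),
            is.numeric(duration), length(duration) == 1L, is.finite(duration))
  if (duration <= 0) {
    stop("'duration' must be strictly positive", call. = FALSE)
  }
  structure(
    list(x0 = x0, xf = xf, d = duration, ts = 0, tf = duration),
    class = "mjt"
  )
}

#' @export
print.mjt <- function(x, ...) {
  cat("Minimum-jerk trajectory\n")
  cat(sprintf("  start:    %.4g %% screen width\n", x$x0))
  cat(sprintf("  target:   %.4g %% screen width\n", x$xf))
  cat(sprintf("  duration: %.4g s\n", x$d))
  cat(sprintf("  peak velocity: %.4g %%/s at t = %.4g s\n",
              1.875 * (x$xf - x$x0) / x$d, x$d / 2))
  invisible(x)
}

#' Evaluate a minimum-jerk trajectory
#'
#' Evaluates position or one of its first three time derivatives on the
#' closed-form quintic. Time is measured from movement start and must lie in
#' `[0, d]`.
#'
#' @param object An [mjt()] object.
#' @param t Numeric vector of times in seconds since movement start.
#' @param deriv Integer in `0:3`: 0 = position (% screen width),
#'   1 = velocity (%/s), 2 = acceleration (%/s^2), 3 = jerk (%/s^3).
#' @param ... Unused.
#' @return Numeric vector of the same length as `t`.
#' @export
predict.mjt <- function(object, t, deriv = 0L, ...) {
  stopifnot(is.numeric(t))
  deriv <- as.integer(deriv)
  if (length(deriv) != 1L || is.na(deriv) || deriv < 0L || deriv > 3L) {
    stop("'deriv' must be a single integer in 0:3", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t < object$ts - 1e-12) ||
      any(t > object$tf + 1e-12)) {
    stop(sprintf("time outside the movement domain [0, %g]", object$tf),
         call. = FALSE)
  }
  tau <- pmin(pmax(t / object$d, 0), 1)
  A <- object$xf - object$x0
  d <- object$d
  switch(deriv + 1L,
    object$x0 + A * (10 * tau^3 - 15 * tau^4 + 6 * tau^5),
    (A / d)   * (30 * tau^2 - 60 * tau^3 + 30 * tau^4),
    (A / d^2) * (60 * tau - 180 * tau^2 + 120 * tau^3),
    (A / d^3) * (60 - 360 * tau + 360 * tau^2)
  )
}

#' @rdname predict.mjt
#' @param profile An [mjt()] object.
#' @export
mjt_position <- function(profile, t) predict(profile, t, deriv = 0L)

#' @rdname predict.mjt
#' @export
mjt_velocity <- function(profile, t) predict(profile, t, deriv = 1L)

#' Sample a minimum-jerk trajectory at a uniform rate
#'
#' Positions are evaluated on the uniform grid `0, 1/rate, 2/rate, ...`; the
#' final sample at `tf` is always included (appended when `d` is not an exact
#' multiple of the sampling period).
#'
#' @param profile An [mjt()] object.
#' @param rate Sampling rate in Hz; must be strictly positive.
#' @return A data frame with columns `t_s` (seconds from movement start) and
#'   `x_pct` (percent of screen width).
#' @examples
#' nrow(mjt_sample(mjt(0, 87.5, 1), 60))  # 61 samples
#' @export
mjt_sample <- function(profile, rate) {
  stopifnot(inherits(profile, "mjt"), is.numeric(rate), length(rate) == 1L)
  if (!is.finite(rate) || rate <= 0) {
    stop("'rate' must be strictly positive", call. = FALSE)
  }
  t <- seq(0, profile$tf, by = 1 / rate)
  if (t[length(t)] < profile$tf - 1e-12) t <- c(t, profile$tf)
  data.frame(t_s = t, x_pct = predict(profile, t))
}

#' Jerk cost of a sampled position trace
#'
#' Numerically approximates the movement-smoothness cost
#' \eqn{\int_{t_s}^{t_f} \|\dddot{x}\|^2 \, dt} from a uniformly sampled
#' position trace. Jerk is estimated by third central finite differences at
#' interior samples (third forward/backward differences when fewer than five
#' samples are available); the jerk series is extended to the trace endpoints
#' by linear extrapolation and the squared series integrated with the
#' composite trapezoid rule.
#'
#' For the minimum-jerk quintic over unit displacement and unit duration the
#' exact cost is 720; the sampled estimate converges to it as the sampling
#' rate grows.
#'
#' @param positions Numeric vector of uniformly spaced positions (at least 4).
#' @param rate Sampling rate in Hz.
#' @return Non-negative scalar, units (% screen width)^2 / s^5.
#' @examples
#' tr <- mjt_sample(mjt(0, 1, 1), 1000)
#' jerk_cost(tr$x_pct, 1000)  # ~720
#' @export
jerk_cost <- function(positions, rate) {
  stopifnot(is.numeric(positions), is.numeric(rate), length(rate) == 1L,
            is.finite(rate), rate > 0)
  n <- length(positions)
  if (n < 4L) {
    stop("at least 4 uniformly spaced samples are required", call. = FALSE)
  }
  h <- 1 / rate
  t <- (seq_len(n) - 1L) * h
  if (n == 4L) {
    # single third forward difference: jerk treated as constant on the span
    j <- (positions[4L] - 3 * positions[3L] + 3 * positions[2L] -
            positions[1L]) / h^3
    return(j^2 * (t[4L] - t[1L]))
  }
  i <- 3:(n - 2L)
  j <- (-positions[i - 2L] + 2 * positions[i - 1L] -
          2 * positions[i + 1L] + positions[i + 2L]) / (2 * h^3)
  tj <- t[i]
  # linear extrapolation of the jerk series to the trace endpoints
  m <- length(j)
  j0 <- j[1L] - (j[2L] - j[1L]) / h * (tj[1L] - t[1L])
  j1 <- j[m] + (j[m] - j[m - 1L]) / h * (t[n] - tj[m])
  tt <- c(t[1L], tj, t[n])
  jj <- c(j0, j, j1)^2
  sum(diff(tt) * (jj[-1L] + jj[-length(jj)]) / 2)
}

#' @export
plot.mjt <- function(x, n = 201L, ...) {
  t <- seq(0, x$tf, length.out = n)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(t, predict(x, t), type = "l", lwd = 2,
                 xlab = "time (s)", ylab = "position (% screen width)",
                 main = "Minimum-jerk trajectory", ...)
  graphics::abline(h = x$xf, lty = 3)
  graphics::plot(t, predict(x, t, deriv = 1L), type = "l", lwd = 2,
                 xlab = "time (s)", ylab = "velocity (%/s)", ...)
  invisible(x)
}
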