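# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# quintic position polynomial evaluated term by term
oracle_quintic_pos <- function(x0, xf, d, t) {
  tau <- t / d
  x0 + (xf - x0) * (10 * tau * tau * tau - 15 * tau^4 + 6 * tau^5)
}

# analytic jerk of the minimum-jerk quintic, squared and integrated by
# adaptive quadrature
oracle_jerk_cost <- function(D, d) {
  stats::integrate(function(t) {
    tau <- t / d
    ((D / d^3) * (60 - 360 * tau + 360 * tau^2))^2
  }, 0, d, rel.tol = 1e-12)$value
}

# explicit sum-of-squares decomposition for a balanced two-way layout
oracle_two_way_ss <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  gm <- mean(y)
  na <- table(a); nb <- table(b); nab <- table(a, b)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, list(a, b), mean)
  ss_a <- sum(na * (ma - gm)^2)
  ss_b <- sum(nb * (mb - gm)^2)
  ss_ab <- sum(nab * (sweep(sweep(mab, 1, ma), 2, mb) + gm)^2)
  ss_e <- sum((y - mab[cbind(a, b)])^2)
  ss_t <- sum((y - gm)^2)
  df_a <- nlevels(a) - 1L
  df_b <- nlevels(b) - 1L
  df_ab <- df_a * df_b
  df_e <- length(y) - nlevels(a) * nlevels(b)
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab, ss_e = ss_e, ss_t = ss_t,
       f_a = (ss_a / df_a) / (ss_e / df_e),
       f_b = (ss_b / df_b) / (ss_e / df_e),
       f_ab = (ss_ab / df_ab) / (ss_e / df_e),
       df = c(df_a, df_b, df_ab, df_e))
}

# rest-to-rest perturbation: zero position, velocity and acceleration at
# both endpoints, so the perturbed curve shares the MJT's boundary
# conditions
oracle_perturbed_quintic <- function(x0, xf, d, coefs) {
  function(t) {
    tau <- t / d
    bump <- tau^3 * (1 - tau)^3 *
      (coefs[1] + coefs[2] * tau + coefs[3] * tau^2)
    oracle_quintic_pos(x0, xf, d, t) + bump
  }
}

# noise-free profiles for round-trip tests
degenerate_profiles <- function() {
  lapply(default_profiles(), function(p) {
    modality_profile(p$name, p$sampling_rate,
                     p$duration_intercept, p$duration_slope)
  })
}

# small long-format dataset wrapper for a single hand-built trial
one_trial_data <- function(t, x, target, modality = "manipulandum",
                           subject = "S01", block = 1L, y = NULL) {
  df <- data.frame(subject_id = subject, modality = modality, block = block,
                   target_pct = target, t_s = t, x_pct = x,
                   stringsAsFactors = FALSE)
  if (!is.null(y)) df$y_pct <- y
  df
}
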