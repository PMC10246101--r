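test_that("two-way ANOVA matches the explicit sum-of-squares oracle", {
  set.seed(21)
  for (k in 1:5) {
    a <- rep(c("m1", "m2"), each = 14)
    b <- rep(rep(seq(12.5, 87.5, by = 12.5), each = 2), times = 2)
    y <- 2 * (a == "m2") + 0.05 * b +
      0.01 * (a == "m2") * b + rnorm(length(a))
    out <- two_way_anova(y, a, b)
    or <- oracle_two_way_ss(y, a, b)
    expect_equal(out$statistic, c(or$f_a, or$f_b, or$f_ab),
                 tolerance = 1e-8)
    expect_equal(out$df1, or$df[1:3])
    expect_equal(out$df2, rep(or$df[4], 3))
    # sum-of-squares conservation on the balanced layout
    expect_equal(or$ss_a + or$ss_b + or$ss_ab + or$ss_e, or$ss_t,
                 tolerance = 1e-8 * or$ss_t)
    expect_true(all(out$p >= 0 & out$p <= 1))
  }
  # seven distance levels give 6 degrees of freedom for the distance effect
  a <- rep(c("m1", "m2"), each = 14)
  b <- rep(rep(1:7, each = 2), times = 2)
  out7 <- two_way_anova(rnorm(28), a, b)
  expect_identical(out7$df1[out7$effect == "distance"], 6L)
})

test_that("two-way ANOVA rejects unbalanced designs, flags degenerate data", {
  a <- c("m1", "m1", "m2", "m2", "m2")
  b <- c(1, 2, 1, 2, 2)
  expect_error(two_way_anova(rnorm(5), a, b), "nbalanced")
  a2 <- rep(c("m1", "m2"), each = 4)
  b2 <- rep(c(1, 2), times = 4)
  expect_error(two_way_anova(rnorm(8), a2, rep(1, 8)), "levels")
  out <- two_way_anova(rep(3, 8), a2, b2)
  expect_true(all(out$degenerate))
  expect_true(all(is.na(out$statistic)))
})

test_that("variance F-test: ratio statistic, reciprocity, direction", {
  x <- c(1.2, 3.1, 2.2, 4.7, 0.5, 2.9)
  out <- variance_f_test(x, x)
  expect_equal(out$statistic, 1)
  expect_equal(out$df1, 5)
  expect_equal(out$df2, 5)
  # scaling a sample by 2 about its mean quadruples its variance
  y <- mean(x) + 2 * (x - mean(x)) + 10
  out2 <- variance_f_test(x, y)
  expect_equal(out2$statistic, 0.25, tolerance = 1e-12)
  expect_identical(out2$direction, "y>x")
  # F(A,B) = 1 / F(B,A)
  set.seed(8)
  for (k in 1:10) {
    a <- rnorm(12); b <- rnorm(15, sd = 2)
    f1 <- variance_f_test(a, b); f2 <- variance_f_test(b, a)
    expect_equal(f1$statistic, 1 / f2$statistic, tolerance = 1e-12)
    expect_equal(f1$p, f2$p, tolerance = 1e-12)
    # two-sided p from the F distribution, computed directly
    fr <- var(a) / var(b)
    pref <- 2 * min(pf(fr, 11, 14), 1 - pf(fr, 11, 14))
    expect_equal(f1$p, pref, tolerance = 1e-12)
  }
  expect_true(variance_f_test(rnorm(5), rep(1, 5))$degenerate)
  expect_error(variance_f_test(rnorm(5), 1), "at least 2")
})

test_that("Brown-Forsythe: zero for identical spreads, location-invariant", {
  g1 <- c(1, 2, 3, 4, 5)
  out <- brown_forsythe(c(g1, g1), rep(c("a", "b"), each = 5))
  expect_equal(out$statistic, 0)
  # equal spread, different means: deviation sets identical, F = 0
  out2 <- brown_forsythe(c(g1, g1 + 100), rep(c("a", "b"), each = 5))
  expect_equal(out2$statistic, 0, tolerance = 1e-12)
  set.seed(13)
  v <- c(rnorm(20), rnorm(20, sd = 3))
  g <- rep(c("a", "b"), each = 20)
  f0 <- brown_forsythe(v, g)
  vshift <- v + (g == "b") * 57.3
  f1 <- brown_forsythe(vshift, g)
  expect_equal(f1$statistic, f0$statistic, tolerance = 1e-9)
  expect_equal(f1$df1, 1L)
  expect_equal(f1$df2, 38L)
  expect_error(brown_forsythe(rnorm(3), c("a", "a", "b")), "at least 2")
})

test_that("Brown-Forsythe agrees with the car implementation", {
  skip_if_not_installed("car")
  set.seed(31)
  for (k in 1:5) {
    v <- c(rnorm(15), rnorm(20, sd = 2), rnorm(12, sd = 0.5))
    g <- factor(rep(c("a", "b", "c"), c(15, 20, 12)))
    ours <- brown_forsythe(v, g)
    ref <- car::leveneTest(v, g, center = stats::median)
    expect_equal(ours$statistic, ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(ours$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("linear fit: exact line, constant response, closed-form slope", {
  x <- seq(12.5, 87.5, by = 12.5)
  f <- linear_fit(x, 1.08 * x)
  expect_equal(f$slope, 1.08, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-10)
  expect_equal(f$r_squared, 1)
  fc <- linear_fit(x, rep(4, 7))
  expect_equal(fc$slope, 0)
  expect_equal(fc$r_squared, 0)
  set.seed(17)
  y <- 2 + 0.7 * x + rnorm(7)
  fn <- linear_fit(x, y)
  expect_equal(fn$slope, sum((x - mean(x)) * (y - mean(y))) /
                 sum((x - mean(x))^2), tolerance = 1e-12)
  expect_true(fn$r_squared >= 0 && fn$r_squared <= 1)
  expect_error(linear_fit(rep(1, 5), rnorm(5)), "ingular")
  expect_error(linear_fit(1:2, 1:2), "at least 3")
})
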