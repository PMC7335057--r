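test_that("baseline correction subtracts the anchor's final-window mean", {
  t <- (0:35999) / 120
  anchor <- pupil_trace(t, rep(5, length(t)))
  stim <- pupil_trace(t, rep(5, length(t)))
  corr <- baseline_correct(stim, anchor)
  expect_true(all(corr$diameter_mm == 0))
  stim4 <- pupil_trace(t, rep(4, length(t)))
  corr4 <- baseline_correct(stim4, anchor)
  expect_true(all(corr4$diameter_mm == -1))
  expect_equal(corr4$meta$baseline_mm, 5)
  short <- pupil_trace((0:599) / 120, rep(5, 600))
  expect_error(baseline_correct(stim, short, window_s = 10), "shorter")
})

test_that("baseline correction recovers designed per-subject shifts", {
  set.seed(21)
  t <- (0:35999) / 120
  for (shift in c(-0.6, 0.2, 1.1)) {
    base <- 5 + runif(1, -0.5, 0.5)
    anchor <- pupil_trace(t, base + rnorm(length(t), 0, 0.05))
    stim <- pupil_trace(t, base + shift + rnorm(length(t), 0, 0.05))
    corr <- baseline_correct(stim, anchor)
    expect_equal(mean(corr$diameter_mm), shift, tolerance = 0.02)
  }
})

test_that("diameter extraction averages the right window", {
  t <- (0:35999) / 120
  const <- pupil_trace(t, rep(3, length(t)))
  expect_equal(extract_diameter(const, 1), 3)
  expect_equal(extract_diameter(const, 299.99), 3)
  # mean of a linear ramp is its midpoint value
  ramp <- pupil_trace(t, 2 + 0.01 * t)
  expect_equal(extract_diameter(ramp, 60, window_s = 1), 2.6,
               tolerance = 1e-4)
  # extraction at the trace end right-aligns the window: mean over [299,300]
  expect_equal(extract_diameter(ramp, 35999 / 120, window_s = 1),
               2 + 0.01 * 299.5, tolerance = 1e-3)
  expect_error(extract_diameter(const, 400), "outside")
  # windowed mean equals its direct recomputation
  set.seed(3)
  wig <- pupil_trace(t, 4 + 0.5 * sin(t / 7) + rnorm(length(t), 0, 0.01))
  sel <- t >= 59.5 & t <= 60.5
  expect_equal(extract_diameter(wig, 60), mean(wig$diameter_mm[sel]),
               tolerance = 1e-9)
})

test_that("prediction errors summarize predicted minus measured", {
  e <- prediction_error(3.0, c(3.0, 3.0))
  expect_equal(e$mean_error_mm, 0)
  expect_equal(e$sd_error_mm, 0)
  e2 <- prediction_error(3.0, c(2.0, 4.0))
  expect_equal(e2$mean_error_mm, 0)
  expect_equal(e2$sd_error_mm, sqrt(2))
  expect_error(prediction_error(3.0, numeric(0)), "empty")
  # subject order cannot matter
  set.seed(8)
  meas <- rnorm(20, 2.5, 0.3)
  expect_equal(prediction_error(3, meas)[, 4:6],
               prediction_error(3, rev(meas))[, 4:6])
  # sampling distribution: cohort built as prediction + N(0.5, 0.1^2)
  meas <- 3 - (0.5 + rnorm(20, 0, 0.1))
  e3 <- prediction_error(3, meas)
  se <- e3$sd_error_mm / sqrt(e3$n)
  expect_lt(abs(e3$mean_error_mm - 0.5), 3 * se)
})

test_that("offset correction centers condition means", {
  oc <- offset_correct(c(chromatic = 0.94, polychromatic = 0.71))
  expect_equal(oc$offset_mm, 0.825)
  expect_equal(unname(oc$corrected_mm), c(0.115, -0.115))
  expect_lt(abs(unname(oc$corrected_mm)[1] - 0.12), 0.005 + 1e-9)
  expect_equal(unname(offset_correct(c(0.3, 0.3))$corrected_mm), c(0, 0))
  set.seed(4)
  m <- rnorm(3)
  expect_equal(sum(offset_correct(m)$corrected_mm), 0)
  expect_error(offset_correct(0.5), "at least two")
})

test_that("rm_anova matches the definitional oracle and stats::mlm", {
  mats <- list(
    matrix(c(5, 4, 3, 6, 5, 5, 7, 5, 4, 6, 6, 5, 5, 3, 3), 5, 3,
           byrow = TRUE),
    matrix(c(2, 9, 4, 3, 8, 6, 1, 7, 5, 4, 9, 6, 2, 8, 3), 5, 3,
           byrow = TRUE),
    { set.seed(13); matrix(rnorm(24, 5), 8, 3) },
    { set.seed(14); matrix(rnorm(28, 4), 7, 4) })
  for (y in mats) {
    a <- rm_anova(y)
    o <- rm_anova_oracle(y)
    expect_equal(a$f_value, o$f, tolerance = 1e-8)
    expect_equal(a$mauchly_w, o$w, tolerance = 1e-8)
    expect_equal(a$gg_epsilon, o$eps, tolerance = 1e-8)
    expect_equal(a$mauchly_chi2, o$chi2, tolerance = 1e-8)
    expect_equal(a$mauchly_p, o$p, tolerance = 1e-8)
    # independent route: R's multivariate linear model machinery (whose
    # p-value adds Box's higher-order term, so only W is compared exactly)
    fit <- lm(y ~ 1)
    mt <- stats::mauchly.test(fit, X = ~1)
    expect_equal(a$mauchly_w, unname(mt$statistic), tolerance = 1e-10)
  }
})

test_that("rm_anova respects its algebraic identities", {
  set.seed(31)
  # k = 2: F is the squared paired t statistic, sphericity trivial
  y2 <- matrix(rnorm(20, 5, 0.8), 10, 2)
  a2 <- rm_anova(y2)
  tt <- t.test(y2[, 1], y2[, 2], paired = TRUE)
  expect_equal(a2$f_value, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a2$gg_epsilon, 1)
  expect_equal(a2$mauchly_p, 1)
  expect_false(a2$gg_applied)
  # adding a constant to one subject's row leaves F unchanged
  y <- matrix(rnorm(18, 4, 0.5), 6, 3)
  y_shift <- y; y_shift[2, ] <- y_shift[2, ] + 5
  expect_equal(rm_anova(y)$f_value, rm_anova(y_shift)$f_value,
               tolerance = 1e-10)
  # epsilon = 1 leaves the degrees of freedom uncorrected
  a <- rm_anova(y)
  if (!a$gg_applied) {
    expect_equal(a$df1, ncol(y) - 1)
    expect_equal(a$df2, (nrow(y) - 1) * (ncol(y) - 1))
  }
  # Bonferroni p-values are capped multiples of the raw ones
  expect_true(all(a$pairwise$p_bonferroni <=
                    pmin(1, a$pairwise$p * nrow(a$pairwise)) + 1e-12))
  expect_error(rm_anova(matrix(c(1, NA, 3, 4, 5, 6), 2, 3)), "missing")
  expect_error(rm_anova(matrix(1:4, 2, 2)), "at least 3")
})
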