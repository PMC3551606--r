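test_that("initial_rate recovers exact and noisy slopes", {
  exact <- gen_progress(rate = 2.0, duration_s = 300, n_points = 60)
  expect_equal(initial_rate(exact), 2.0, tolerance = 1e-12)
  flat <- gen_progress(rate = 0, duration_s = 300, n_points = 60)
  expect_equal(initial_rate(flat), 0)

  # regression oracle: noisy slope within +/- 3 OLS standard errors
  noisy <- gen_progress(rate = 1.5, duration_s = 60, n_points = 60,
                        noise_sd = 0.01, seed = 7)
  k <- ceiling(0.25 * 60)
  ols <- summary(stats::lm(noisy$fluorescence[1:k] ~ noisy$time_s[1:k]))
  se <- ols$coefficients[2, 2]
  expect_equal(initial_rate(noisy), 1.5, tolerance = 3 * se / 1.5)

  # a drifting-down trace clips to zero with a warning
  down <- progress_curve(seq(0, 50, length.out = 20), seq(10, 1, length.out = 20))
  expect_warning(r <- initial_rate(down), "clipped")
  expect_identical(r, 0)
  expect_error(initial_rate(exact, window = 0.01), "fewer than 4")
})

test_that("residual activity percentages behave and are scale-invariant", {
  expect_equal(residual_activity(5, 5)$residual_pct, 100)
  expect_equal(residual_activity(0, 5)$residual_pct, 0)
  expect_equal(residual_activity(0, 5)$reduction_pct, 100)

  # the reported inhibition: a rate ratio of 0.147 leaves 14.7% residual,
  # an 85.3% reduction
  r <- residual_activity(0.147 * 8, 8)
  expect_equal(r$residual_pct, 14.7, tolerance = 1e-9)
  expect_equal(r$reduction_pct, 85.3, tolerance = 1e-9)
  expect_equal(r$residual_pct + r$reduction_pct, 100)

  # multiplying both rates by any c > 0 changes nothing
  for (c in c(0.2, 3, 117)) {
    rc <- residual_activity(0.147 * 8 * c, 8 * c)
    expect_equal(rc$residual_pct, r$residual_pct, tolerance = 1e-9)
  }
  expect_error(residual_activity(1, 0), "positive")
})

test_that("full synthetic pipeline reproduces the generated residual fraction", {
  pair <- gen_progress_pair(control_rate = 10, residual_frac = 0.147,
                            noise_sd = 0.01 * 10 * 300, seed = 3)
  r <- residual_activity(initial_rate(pair$inhibited),
                         initial_rate(pair$control))
  expect_lt(abs(r$residual_pct - 14.7), 0.5)
})

test_that("dose series sorts, averages duplicates, and interpolates IC50", {
  mk <- function(res, conc) residual_activity(res, 100, conc)
  # 80% at 1 uM, 20% at 10 uM: the 50% crossing interpolates to 10^0.5 uM
  ds <- dose_series(list(mk(20, 10), mk(80, 1)))
  expect_equal(ds$table$concentration_uM, c(1, 10))
  expect_equal(ds$ic50_uM, 3.16227766017, tolerance = 1e-9)

  # a series that never crosses 50% has no IC50
  ds2 <- dose_series(list(mk(90, 1), mk(70, 3), mk(60, 10)))
  expect_true(is.na(ds2$ic50_uM))
  # single point: table only
  ds3 <- dose_series(list(mk(40, 3)))
  expect_equal(nrow(ds3$table), 1)
  expect_true(is.na(ds3$ic50_uM))
  # duplicates averaged with a note
  expect_message(ds4 <- dose_series(list(mk(60, 3), mk(40, 3))), "averaged")
  expect_equal(ds4$table$residual_pct, 50)
})

test_that("E-64 titration is exact on collinear points and scale-invariant", {
  t1 <- e64_titration(c(0, 25, 50), c(10, 5, 0))
  expect_equal(t1$active_concentration_nM, 50, tolerance = 1e-9)
  expect_true(t1$valid)
  # scaling all rates leaves the x-intercept unchanged
  t3 <- e64_titration(c(0, 25, 50), 3 * c(10, 5, 0))
  expect_equal(t3$active_concentration_nM, 50, tolerance = 1e-9)

  # regression oracle on noisy data: recovered intercept within its 95% CI
  set.seed(21)
  conc <- seq(0, 60, by = 10)
  rate <- pmax(7.5 * (1 - conc / 75), 0) + rnorm(length(conc), sd = 0.1)
  tt <- e64_titration(conc, rate)
  fit <- stats::lm(rate ~ conc)
  # delta-method CI for -a/b
  v <- stats::vcov(fit); a <- coef(fit)[1]; b <- coef(fit)[2]
  se <- sqrt(v[1, 1] / b^2 + a^2 * v[2, 2] / b^4 - 2 * a * v[1, 2] / b^3)
  expect_lt(abs(tt$active_concentration_nM - 75), 2.5 * se)

  expect_error(e64_titration(c(0, 25, 50), c(1, 2, 3)), "regime")
  expect_error(e64_titration(c(0, 25), c(2, 1)), "at least 3")
})
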