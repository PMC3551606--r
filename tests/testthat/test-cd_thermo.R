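test_that("mean residue ellipticity conversion is correct and homogeneous", {
  # 100 mdeg, 30 uM, 79 residues, 1 mm path: 100 / (10 * 0.1 * 3e-5 * 79)
  expect_equal(mdeg_to_mre(100, 30e-6, 79, 0.1), 42194.092827, tolerance = 1e-9)
  expect_identical(mdeg_to_mre(0, 1e-5, 50, 0.1), 0)

  # degree-1 homogeneity in the signal, degree -1 in the other factors
  s <- c(-30, -5, 12)
  base <- mdeg_to_mre(s, 30e-6, 79, 0.1)
  expect_equal(mdeg_to_mre(2 * s, 30e-6, 79, 0.1), 2 * base)
  expect_equal(mdeg_to_mre(s, 2 * 30e-6, 79, 0.1), base / 2)
  expect_equal(mdeg_to_mre(s, 30e-6, 2 * 79, 0.1), base / 2)
  expect_equal(mdeg_to_mre(s, 30e-6, 79, 0.2), base / 2)

  expect_error(mdeg_to_mre(10, -1e-5, 79, 0.1), "concentration")
  expect_error(mdeg_to_mre(10, 3e-5, 0, 0.1), "n_residues")
  expect_error(mdeg_to_mre(10, 3e-5, 79, 0), "path_length")
})

test_that("two-state signal has the right midpoint, limits and closed-form value", {
  Yn <- -10; Yd <- -2; dH <- 50; Tm <- 331.15
  # at Tm the equilibrium constant is 1: signal is the baseline midpoint
  expect_equal(two_state_signal(Tm, Yn, 0, Yd, 0, dH, Tm), (Yn + Yd) / 2)
  # far below Tm the native baseline dominates
  expect_equal(two_state_signal(200, Yn, 0, Yd, 0, dH, Tm), Yn, tolerance = 1e-9)
  # direct evaluation of the closed form at 293.15 K (frozen)
  expect_equal(two_state_signal(293.15, Yn, 0, Yd, 0, dH, Tm),
               -9.99957766426, tolerance = 1e-9)
  # sloped baselines at Tm: mean of the two baseline values there
  expect_equal(two_state_signal(Tm, Yn, 0.02, Yd, 0.008, dH, Tm),
               ((Yn + 0.02 * Tm) + (Yd + 0.008 * Tm)) / 2)
  expect_error(two_state_signal(-5, Yn, 0, Yd, 0, dH, Tm), "positive")
})

test_that("noiseless fit recovers the generating parameters", {
  curve <- gen_melt(dH = 40, Tm_c = 58, Yn = -28, Mn = 0.02, Yd = -4, Md = 0.008)
  fit <- fit_two_state(curve)
  expect_true(fit$converged)
  expect_equal(fit$Tm_c, 58, tolerance = 1e-3)
  expect_equal(fit$dH, 40, tolerance = 1e-3)
  expect_equal(fit$Yn, -28, tolerance = 1e-2)
  expect_equal(fit$Yd, -4, tolerance = 1e-2)
  expect_equal(fit$dS, fit$dH / fit$Tm, tolerance = 1e-9)
  expect_identical(fit$cooperative, "cooperative")
})

test_that("an exactly linear trace is labelled non-cooperative", {
  tc <- seq(4, 96, 2)
  curve <- melt_curve(tc, -20 + 0.05 * tc, unit = "mdeg")
  fit <- suppressWarnings(fit_two_state(curve))
  expect_identical(fit$cooperative, "non-cooperative")
})

test_that("fit residual matches a brute-force grid search oracle", {
  # small curves; grid search solves baselines by OLS at each (dH, Tm)
  for (seed in c(11, 12)) {
    curve <- gen_melt(dH = 45, Tm_c = 52, noise_frac = 0.03, seed = seed)
    fit <- fit_two_state(curve)
    oracle_rmse <- grid_two_state_rmse(curve$temperature_c, curve$signal)
    expect_lte(fit$rmse, oracle_rmse * 1.05)
  }
})

test_that("Tm and dH are recovered from noisy melts", {
  # 100 melts of a sharply cooperative transition, noise sd 3% of amplitude
  tm_err <- numeric(100); dh_rel <- numeric(100)
  for (s in 1:100) {
    fit <- fit_two_state(gen_melt(dH = 50, Tm_c = 58, noise_frac = 0.03, seed = s))
    tm_err[s] <- abs(fit$Tm_c - 58)
    dh_rel[s] <- abs(fit$dH - 50) / 50
  }
  expect_lt(median(tm_err), 0.5)
  expect_lt(median(dh_rel), 0.10)
})

test_that("free energy and fraction unfolded obey the two-state identities", {
  fit <- fit_two_state(gen_melt(dH = 50, Tm_c = 58, Yn = -10, Mn = 0,
                                Yd = -2, Md = 0))
  Tm <- fit$Tm
  expect_equal(gibbs_free_energy(fit, Tm), 0, tolerance = 1e-8)
  expect_equal(fraction_unfolded(fit, Tm), 0.5, tolerance = 1e-8)

  # frozen hand arithmetic at 293.15 K for dH = 50, Tm = 331.15 K
  fit50 <- structure(list(Yn = -10, Mn = 0, Yd = -2, Md = 0, dH = 50,
                          Tm = 331.15, dS = 50 / 331.15, converged = TRUE),
                     class = "two_state_fit")
  expect_equal(gibbs_free_energy(fit50, 293.15), 5.73758115658, tolerance = 1e-9)
  expect_equal(fraction_unfolded(fit50, 293.15), 5.27919674691e-05,
               tolerance = 1e-8)
  expect_gt(gibbs_free_energy(fit50, 293.15), 0)   # stable below Tm
  expect_gt(fraction_unfolded(fit50, 400), 0.99)   # unfolded far above Tm

  # fraction unfolded strictly increasing in T for positive enthalpy
  Ts <- seq(280, 360, by = 1)
  fr <- vapply(Ts, function(T) fraction_unfolded(fit50, T), numeric(1))
  expect_true(all(diff(fr) > 0))
  expect_true(all(fr >= 0 & fr <= 1))

  expect_error(gibbs_free_energy(fit50, -3), "Kelvin")
})

test_that("ddG_u has the right sign logic and arithmetic", {
  mk <- function(dH, Tm_c, converged = TRUE)
    structure(list(dH = dH, Tm = Tm_c + 273.15, dS = dH / (Tm_c + 273.15),
                   converged = converged),
              class = "two_state_fit")
  a <- mk(50, 58)
  expect_equal(delta_delta_G(a, a, 293.15), 0)
  # lower Tm, equal dH, below both Tm: destabilising, so negative
  expect_lt(delta_delta_G(a, mk(50, 40), 293.15), 0)
  # matches the hand-computed dG difference
  b <- mk(30, 45)
  expected <- 30 * (1 - 293.15 / 318.15) - 50 * (1 - 293.15 / 331.15)
  expect_equal(delta_delta_G(a, b, 293.15), expected, tolerance = 1e-12)
  expect_error(delta_delta_G(a, mk(30, 45, converged = FALSE)), "converged")
  expect_equal(delta_delta_G(a, mk(30, 45, converged = FALSE), force = TRUE),
               expected, tolerance = 1e-12)
})

test_that("melt curve validation rejects malformed input", {
  expect_error(melt_curve(1:5, 1:5), "at least 10")
  expect_error(melt_curve(c(4, 6, 8, 10, 12, 14, 16, 18, 20, 20),
                          rnorm(10)), "strictly increasing")
  expect_error(melt_curve(seq(100, 145, 5), rnorm(10)), "plausible")
  expect_error(fit_two_state(gen_melt(40, 15, grid_c = seq(4, 24, 2))),
               "span")
})
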