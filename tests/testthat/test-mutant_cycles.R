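mk_fit <- function(dH, Tm_c, converged = TRUE)
  structure(list(dH = dH, Tm = Tm_c + 273.15, dS = dH / (Tm_c + 273.15),
                 converged = converged),
            class = "two_state_fit")

test_that("coupling energy: additivity gives zero, exchange symmetry holds", {
  # additive double mutant: g_dm = g_m1 + g_m2 - g_wt
  expect_identical(coupling_energy(5, 3, 2.5, 3 + 2.5 - 5), 0)
  # hand arithmetic
  expect_equal(coupling_energy(5.0, 3.0, 2.5, 1.5), 1.0)
  # swapping the single mutants leaves the coupling unchanged
  expect_equal(coupling_energy(5, 3, 2.5, 1.5), coupling_energy(5, 2.5, 3, 1.5))
  # traversing the cycle from the double mutant (wt<->dm with m1<->m2
  # relabelled) also leaves it unchanged ...
  expect_equal(coupling_energy(1.5, 2.5, 3, 5), coupling_energy(5, 3, 2.5, 1.5))
  # ... while exchanging along one mutation edge (wt<->m1, m2<->dm) negates it
  expect_equal(coupling_energy(3, 5, 1.5, 2.5), -coupling_energy(5, 3, 2.5, 1.5))
  expect_error(coupling_energy(NaN, 1, 1, 1), "finite")
})

test_that("run_cycle composes gibbs_free_energy and coupling_energy", {
  fits <- list(C72S = mk_fit(50, 58), m1 = mk_fit(40, 50),
               m2 = mk_fit(38, 48), dm = mk_fit(30, 41))
  spec <- cycle_spec("cyc1", "C72S", "m1", "m2", "dm", pair = "A-B")
  res <- run_cycle(spec, fits, T_ref = 293.15)
  g <- vapply(fits, gibbs_free_energy, numeric(1), T_ref = 293.15)
  expect_equal(unname(res$ddG_int),
               coupling_energy(g[["C72S"]], g[["m1"]], g[["m2"]], g[["dm"]]))
  # recomputable from its own components to 1e-9
  cmp <- res$components
  expect_equal(unname(res$ddG_int),
               unname(cmp["wt"] - cmp["m1"] - cmp["m2"] + cmp["dm"]),
               tolerance = 1e-9)

  # a different reference temperature changes components but the identity holds
  res2 <- run_cycle(spec, fits, T_ref = 277)
  expect_false(isTRUE(all.equal(res2$components, res$components)))
  cmp2 <- res2$components
  expect_equal(unname(res2$ddG_int),
               unname(cmp2["wt"] - cmp2["m1"] - cmp2["m2"] + cmp2["dm"]),
               tolerance = 1e-9)
})

test_that("engineered additive cycle gives exactly zero coupling", {
  # pick dm so that dG_dm = dG_m1 + dG_m2 - dG_wt at T_ref by construction:
  # with dG = dH (1 - T/Tm), choose dH_dm and solve Tm_dm
  T_ref <- 293.15
  g <- function(f) gibbs_free_energy(f, T_ref)
  wt <- mk_fit(50, 58); m1 <- mk_fit(40, 50); m2 <- mk_fit(38, 48)
  target <- g(m1) + g(m2) - g(wt)
  dH_dm <- 30
  Tm_dm <- T_ref / (1 - target / dH_dm)
  dm <- structure(list(dH = dH_dm, Tm = Tm_dm, dS = dH_dm / Tm_dm,
                       converged = TRUE), class = "two_state_fit")
  res <- run_cycle(cycle_spec("add", "wt", "m1", "m2", "dm"),
                   list(wt = wt, m1 = m1, m2 = m2, dm = dm), T_ref)
  expect_equal(unname(res$ddG_int), 0, tolerance = 1e-12)
})

test_that("cycle coupling equals the cross-module ddG_u difference", {
  # ddG_int = ddG_u(m2 -> dm) - ddG_u(wt -> m1), both from delta_delta_G
  fits <- list(wt = mk_fit(52, 56), m1 = mk_fit(44, 49),
               m2 = mk_fit(41, 47), dm = mk_fit(33, 40))
  T_ref <- 293.15
  res <- run_cycle(cycle_spec("x", "wt", "m1", "m2", "dm"), fits, T_ref)
  expect_equal(unname(res$ddG_int),
               delta_delta_G(fits$m2, fits$dm, T_ref) -
                 delta_delta_G(fits$wt, fits$m1, T_ref),
               tolerance = 1e-12)
})

test_that("run_cycle validates its inputs", {
  fits <- list(wt = mk_fit(50, 58), m1 = mk_fit(40, 50), m2 = mk_fit(38, 48))
  spec <- cycle_spec("c", "wt", "m1", "m2", "dm")
  expect_error(run_cycle(spec, fits), "dm")
  fits$dm <- mk_fit(30, 41, converged = FALSE)
  expect_error(run_cycle(spec, fits), "converge")
  expect_s3_class(run_cycle(spec, fits, force = TRUE), "cycle_result")
  expect_error(cycle_spec("c", "wt", "m1", "m1", "dm"), "distinct")
})
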