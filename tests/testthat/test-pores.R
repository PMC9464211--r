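test_that("pore system enforces its invariants", {
  ps <- pore_system()
  expect_equal(sum(ps$alpha), 1)
  expect_equal(unname(ps$radii), c(250, 45, 2))
  expect_error(pore_system(alpha = c(0.1, 0.8, 0.2)), "sum to 1")
  expect_error(pore_system(LpS = -1))
})

test_that("hindered-transport reflection coefficients behave physically", {
  expect_equal(reflection_sigma(0, 45), 0)
  expect_equal(reflection_sigma(52, 45), 1)     # solute larger than pore
  expect_equal(reflection_sigma(c(10, 300), 100, water_only = TRUE), c(1, 1))
  sig <- reflection_sigma(seq(1, 45, 2), 45)
  expect_true(all(diff(sig) > 0))               # monotone in solute size
  expect_true(all(sig >= 0 & sig <= 1))
  # albumin is strongly reflected by small pores, weakly by large pores
  expect_gt(reflection_sigma(35.5, 45), 0.9)
  expect_lt(reflection_sigma(35.5, 250), 0.1)
})

test_that("per-pore fluid flux reproduces direct evaluations of the extended
           Starling formula", {
  ps <- pore_system(LpS = 6)
  # all gradients zero: equilibrium in every pore
  for (pore in c("large", "small", "ultrasmall"))
    expect_equal(pore_fluid_flux(pore, 10, 10, c(20, 6), c(20, 6),
                                 sigma_p = c(1, 1), pores = ps), 0)
  # small pores, full protein reflection, slight oncotic excess: absorption
  expect_equal(
    pore_fluid_flux("small", P_c = 13.8, P_is = 0, pi_pl = 25.8, pi_is = 11.8,
                    sigma_p = 1, pores = ps),
    0.85 * 6 * (13.8 - 14.0), tolerance = 1e-12)
  # aquaporins see small-solute gradients at full strength
  expect_equal(
    pore_fluid_flux("ultrasmall", P_c = 0, P_is = 0, pi_pl = 0, pi_is = 0,
                    sigma_p = 0, c_pl = 1, c_is = 0, phi = 1, sigma_s = 1,
                    pores = ps),
    -0.10 * 6 * 19.3)
  expect_error(pore_fluid_flux("medium", 10, 0, 0, 0, 0), "unknown pore")
})

test_that("classic aggregate Starling flux matches its closed form", {
  expect_equal(classic_starling_flux(14, 0, 14, 0, 1, 6), 0)
  expect_equal(classic_starling_flux(14, 0, 14.2, 0, 1, 6), -1.2)
  expect_equal(classic_starling_flux(2, 0, 30, 0, 0, 6), 12)
  expect_error(classic_starling_flux(1, 0, 1, 0, 1.5, 6))
})

test_that("summed pore fluxes aggregate to the classic single-membrane flux
           when all pores share one reflection coefficient", {
  ps <- pore_system(LpS = 6)
  set.seed(42)
  for (i in 1:25) {
    P_c <- runif(1, 5, 30); P_is <- runif(1, -3, 3)
    pi_pl <- runif(2, 5, 20); pi_is <- runif(2, 1, 10)
    sigma <- runif(1)
    per_pore <- vapply(1:3, function(k)
      pore_fluid_flux(k, P_c, P_is, pi_pl, pi_is, sigma_p = c(sigma, sigma),
                      pores = ps), numeric(1))
    expect_equal(sum(per_pore),
                 classic_starling_flux(P_c, P_is, sum(pi_pl), sum(pi_is),
                                       sigma, 6),
                 tolerance = 1e-10)
  }
})
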