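test_that("refilling rate: derivative form and flux form agree after the
           priming transient", {
  tr <- get_scenario("lps6")
  rr <- refilling_rate(tr)
  # R = dVp/dt + UF equals -J_v + Q_L once the first minutes have passed
  late <- rr$time >= 5
  expect_lt(max(abs(rr$R[late] - rr$R_flux[late])), 0.05)
  # the arithmetic of the definition
  expect_equal(rr$R, rr$dVp_dt + tr$derived$UF)
})

test_that("Kr curve implements R over the oncotic pressure change with masking
           and the 5-min start", {
  tr <- get_scenario("lps6")
  k <- kr_curve(tr)
  expect_s3_class(k, "kr_curve")
  expect_gte(min(k$time), 5)
  rr <- refilling_rate(tr)
  d <- tr$derived
  i <- match(k$time, d$time)
  expect_equal(k$Kr, rr$R[i] / (d$pi_pl[i] - d$pi_pl[1]))
  expect_true(all(is.finite(k$Kr)))
  # an equilibrium run never builds an oncotic signal: fully masked, flagged
  expect_warning(kfl <- kr_curve(get_scenario("flatline300")),
                 "entirely masked")
  expect_true(all(is.na(kfl$Kr)))
})

test_that("Starling decomposition is zero at t = 0, sums to its net, and uses
           the absorption-positive sign convention", {
  tr <- get_scenario("lps6")
  sd <- starling_decomposition(tr)
  expect_equal(unlist(sd[1, -1]), stats::setNames(rep(0, 7), names(sd)[-1]))
  expect_equal(sd$net, sd$capillary + sd$interstitial_hydrostatic +
                 sd$plasma_oncotic + sd$interstitial_oncotic + sd$small_solute)
  n <- nrow(sd)
  expect_gt(sd$plasma_oncotic[n], 0)        # rising pi_pl favours absorption
  expect_lt(sd$interstitial_oncotic[n], 0)  # rising pi_is opposes it
  expect_gt(sd$capillary[n], 0)             # falling P_c favours absorption
  expect_lt(sd$interstitial_hydrostatic[n], 0)
  # net increase far smaller than the plasma oncotic change alone
  expect_lt(abs(sd$net[n]), 0.5 * sd$plasma_oncotic[n])
  # hydrostatic gradient nearly constant: the two deltas almost cancel
  expect_lt(abs(sd$capillary[n] + sd$interstitial_hydrostatic[n]),
            0.3 * abs(sd$plasma_oncotic[n]))
})

test_that("finite-difference log-sensitivity is exact on power laws", {
  expect_equal(hdrefill:::relative_sensitivity_fd(function(x) 3 * x, 2), 1,
               tolerance = 1e-8)
  expect_equal(hdrefill:::relative_sensitivity_fd(function(x) 5, 2), 0)
  expect_equal(hdrefill:::relative_sensitivity_fd(function(x) x^2, 3), 2,
               tolerance = 1e-6)
  expect_error(hdrefill:::relative_sensitivity_fd(function(x) 0, 1))
})

test_that("relative sensitivity of Kr rejects invalid parameters and returns
           one row per evaluation time", {
  pt <- default_patient()
  expect_error(relative_sensitivity(pt, session_protocol(), "no.such.param"),
               "unknown parameter")
  res <- relative_sensitivity(pt, session_protocol(), "interstitium.LS",
                              t_eval = 240)
  expect_s3_class(res, "sensitivity_result")
  expect_equal(nrow(res), 1)
  expect_true(is.finite(res$S))
})

test_that("the sensitivity screen ranks parameters and reports the simulation
           count", {
  pt <- default_patient()
  sc <- sensitivity_screen(pt, session_protocol(),
                           t_eval = 240,
                           params = c("pores.LpS", "interstitium.C_is"),
                           threshold = 0.0)
  expect_equal(sc$n_simulations, 5)
  expect_equal(sort(unique(sc$all$parameter)),
               c("interstitium.C_is", "pores.LpS"))
  expect_true(all(is.finite(sc$all$S)))
  expect_true(all(diff(abs(sc$top$S)) <= 0))
})
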