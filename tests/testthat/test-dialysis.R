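test_that("ultrafiltration profile is constant with the priming correction", {
  p <- session_protocol()
  expect_equal(ultrafiltration_profile(0, p), 12.5)
  expect_equal(ultrafiltration_profile(c(0, 120, 240), p), rep(12.5, 3))
  expect_error(ultrafiltration_profile(241, p), "outside the session")
  expect_error(ultrafiltration_profile(-1, p), "outside the session")
  # infused priming raises the rate so net removal is unchanged
  pi_ <- session_protocol(priming = "infused")
  expect_equal(ultrafiltration_profile(0, pi_), (3000 + 220) / 240)
  # UF-rate variants reach the stated totals
  expect_equal(ultrafiltration_profile(0, session_protocol(uf_total_mL = 2400)) * 240, 2400)
  expect_equal(ultrafiltration_profile(0, session_protocol(uf_total_mL = 3600)) * 240, 3600)
})

test_that("LpS profile is constant or ramps linearly between the endpoints", {
  pt <- virtual_patient()
  expect_equal(hdrefill:::lps_at(c(0, 120, 240), session_protocol(), pt),
               rep(6, 3))
  ramp <- session_protocol(lps_start = 6, lps_end = 4)
  expect_equal(hdrefill:::lps_at(c(0, 120, 240), ramp, pt), c(6, 5, 4))
})

test_that("dialyzer exchange follows the clearance law with Donnan weighting", {
  expect_equal(dialyzer_solute_exchange(200, 20, 20, alphaD = 1), 0)
  expect_equal(dialyzer_solute_exchange(200, 20, 0), 4)
  expect_equal(dialyzer_solute_exchange(100, 22, 32), -1)   # uptake
  expect_equal(dialyzer_solute_exchange(200, 147.4, 140, alphaD = 0.95),
               200 * (0.95 * 147.4 - 140) / 1000)
  expect_error(dialyzer_solute_exchange(-10, 20, 0))
})

test_that("priming procedures move the right volumes and masses", {
  init <- default_init()
  # discarded: in-body blood falls by the circuit volume, composition unchanged
  std <- apply_priming(init, session_protocol())
  expect_equal(sum(std$V), sum(init$V) - 220)
  expect_equal(std$V_circuit, 220)
  expect_equal(std$M_pl, init$M_pl)
  expect_equal(std$N_pl, init$N_pl)
  # infused: saline enters the circulating blood, diluting plasma protein by
  # V_p/(V_p + circuit); total circulating volume grows by the circuit volume
  inf <- apply_priming(init, session_protocol(priming = "infused"))
  expect_equal(sum(inf$V) + inf$V_circuit, sum(init$V) + 220)
  V_p0 <- sum(init$V) - init$V_rbc
  conc0 <- sum(init$M_pl) / V_p0
  conc1 <- sum(inf$M_pl) / (V_p0 + 220)
  expect_equal(conc1 / conc0, V_p0 / (V_p0 + 220))
  expect_equal(inf$N_pl[["Na"]] - init$N_pl[["Na"]], 154 * 0.220)
  expect_equal(inf$N_pl[["Cl"]] - init$N_pl[["Cl"]], 154 * 0.220)
  # no priming: untouched
  none <- apply_priming(init, session_protocol(priming = "none"))
  expect_equal(none$V, init$V)
  expect_equal(none$V_circuit, 0)
})

test_that("cumulative ultrafiltrate equals the protocol total", {
  tr <- get_scenario("lps6")
  expect_equal(unname(tr$states[nrow(tr$states), 41]), 3000, tolerance = 0.01)
  tr15 <- get_scenario("uf15")
  expect_equal(unname(tr15$states[nrow(tr15$states), 41]), 3600, tolerance = 0.01)
})
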