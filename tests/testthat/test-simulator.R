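test_that("overload distribution is proportional to the normal volumes", {
  pt <- virtual_patient()
  ov <- distribute_overload(pt)
  expect_equal(ov$dV_plasma, 500)
  expect_equal(ov$dV_interstitium, 2500)
  expect_equal(distribute_overload(pt, 0)$dV_plasma, 0)
  expect_equal(distribute_overload(pt, 1800)$dV_plasma, 300)
  expect_equal(distribute_overload(pt, 1800)$dV_interstitium, 1500)
})

test_that("the initializer balances filtration against lymph (zero refilling)
           and re-solving after an LpS change moves only P_c0", {
  init <- default_init()
  expect_lt(init$residual_mlmin, 1e-6)
  expect_equal(init$P_is0, interstitial_pressure(init$V_is), tolerance = 1e-12)
  expect_equal(init$Q_L0, lymph_flow(init$P_is0), tolerance = 1e-12)
  pt8 <- set_patient_param(virtual_patient(), "pores.LpS", 8)
  init8 <- solve_initial_steady_state(pt8)
  expect_lt(init8$residual_mlmin, 1e-6)
  expect_false(isTRUE(all.equal(init8$P_c0, default_init()$P_c0)))
  expect_equal(init8$Q_L0, init$Q_L0)       # same volumes, same lymph balance
})

test_that("an undisturbed equilibrium run stays flat", {
  pt <- default_patient()
  tr <- run_session(pt, session_protocol(duration_min = 60, uf_total_mL = 0,
                                         priming = "none"),
                    init = default_init())
  d <- tr$derived
  for (col in c("P_is", "Q_L", "pi_pl", "pi_is", "V_p", "BV", "TP"))
    expect_lt(max(abs(d[[col]] / d[[col]][1] - 1)), 1e-5)
})

test_that("basal session: blood volume declines monotonically after the first
           minutes", {
  d <- get_scenario("lps6")$derived
  late <- d$BV[d$time >= 10]
  expect_true(all(diff(late) < 0))
})

test_that("water and protein ledgers are conserved over a 5-h session", {
  tr <- get_scenario("dur300")
  y <- tr$states
  water <- rowSums(y[, 1:9]) + y[, 10] + y[, 11] + y[, 41]
  expect_lt(max(abs(water - water[1])), 0.1)           # mL
  protein <- rowSums(y[, 12:15])
  expect_lt(max(abs(protein - protein[1])), 1e-6)      # g
  solutes <- rowSums(y[, 16:36]) + rowSums(y[, 42:48])
  expect_lt(max(abs(solutes - solutes[1])), 1e-6)      # mmol, incl. dialysate
})

test_that("halving the ODE tolerances leaves end-of-session plasma volume
           unchanged to 0.01%", {
  pt <- default_patient()
  init <- default_init()
  pr <- session_protocol()
  st0 <- apply_priming(init, pr)
  ctx <- hdrefill:::build_context(pt, pr, init)
  ctx$V_circ <- st0$V_circuit
  y0 <- hdrefill:::state_to_vector(st0)
  times <- seq(0, 240, 0.5)
  run_tol <- function(rtol) {
    s <- deSolve::lsoda(y0, times, hdrefill:::rhs_ode, parms = ctx,
                        rtol = rtol, atol = pmax(abs(y0), 1) * rtol / 10,
                        maxsteps = 100000)
    sum(s[nrow(s), 1 + 1:9]) + 220 - init$V_rbc
  }
  expect_lt(abs(run_tol(1e-8) / run_tol(5e-9) - 1), 1e-4)
})

test_that("the scenario battery enumerates the named study variants", {
  pt <- default_patient()
  sub <- scenario_battery(pt, scenarios = c("lps6", "ramp_6_4"),
                          init = default_init())
  expect_named(sub, c("lps6", "ramp_6_4"))
  expect_error(scenario_battery(pt, scenarios = "lps7"), "unknown scenario")
  # ramps start from the basal LpS
  expect_equal(sub$ramp_6_4$derived$LpS[1], 6)
  expect_equal(sub$ramp_6_4$derived$LpS[nrow(sub$ramp_6_4$derived)], 4)
  # protocol-only variants share the basal pre-dialysis state
  expect_equal(sub$lps6$states[1, ], sub$ramp_6_4$states[1, ])
})
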