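test_that("elastance pressures and link flows follow their linear laws", {
  expect_equal(compartment_pressures(100, 2, 100), 0)
  expect_equal(compartment_pressures(3600, 75, 2700), 12)
  expect_equal(compartment_pressures(5600, 75, 2700) /
                 compartment_pressures(4150, 75, 2700), 2)  # homogeneity
  P <- rep(10, 9)
  q <- vascular_flows(P, rep(0.01, 7), k_pump = c(100, 100))
  expect_equal(unname(q[c(1:5, 7, 8)]), rep(0, 7))            # passive, dP = 0
  expect_equal(unname(vascular_flows(c(100, 10, rep(10, 7)), c(0.018, rep(0.01, 6)),
                                     c(100, 100))[["la_sa"]]), 5000)
  # pumps clip at negative filling pressure
  Pneg <- rep(10, 9); Pneg[6] <- -2; Pneg[9] <- -1
  qn <- vascular_flows(Pneg, rep(0.01, 7), c(100, 100))
  expect_equal(unname(qn[c("rh_pa", "lh_la")]), c(0, 0))
})

test_that("baroreflex controllers are neutral at set point, bounded, and
           monotone under a pressure step", {
  pt <- virtual_patient()
  st <- c(hr = 0, ctr = 0, res = 0, vu = 0)
  setpt <- c(high = 100, low = 4)
  # at set point the outputs stay neutral
  out <- st
  for (i in 1:200)
    out <- baroreflex_update(out, c(high = 100, low = 4), setpt, pt$baro, 0.1)
  expect_equal(unname(out), rep(0, 4), tolerance = 1e-12)
  # arterial pressure step down: resistance scaling rises to a bounded plateau
  out <- st; path <- numeric(300)
  for (i in 1:300) {
    out <- baroreflex_update(out, c(high = 95, low = 4), setpt, pt$baro, 0.1)
    path[i] <- out[["res"]]
  }
  expect_true(all(diff(path) >= -1e-12))
  expect_lte(max(path), pt$baro$amp[["res"]])
  expect_gt(path[300], 0)
  # zero gains: open loop, neutral outputs never respond to any afferent
  pt0 <- pt; pt0$baro$gain[] <- 0
  out2 <- st
  for (i in 1:50)
    out2 <- baroreflex_update(out2, c(high = 60, low = 15), setpt, pt0$baro, 0.1)
  expect_equal(unname(out2), rep(0, 4))
})

test_that("the closed loop conserves blood volume exactly", {
  pt <- default_patient()
  init <- default_init()
  # equilibrium: every state derivative vanishes
  pr0 <- session_protocol(priming = "none", uf_total_mL = 0)
  ctx <- hdrefill:::build_context(pt, pr0, init)
  y0 <- hdrefill:::state_to_vector(apply_priming(init, pr0))
  dy <- hdrefill:::model_fluxes(0, y0, ctx)[[1]]
  expect_lt(max(abs(dy)), 1e-6)
  # with ultrafiltration the blood-volume ledger loses exactly UF
  pr <- session_protocol()
  ctx2 <- hdrefill:::build_context(pt, pr, init)
  st2 <- apply_priming(init, pr)
  ctx2$V_circ <- st2$V_circuit
  dy2 <- hdrefill:::model_fluxes(0, hdrefill:::state_to_vector(st2), ctx2)[[1]]
  jv_ql <- dy2[10] + dy2[11]   # interstitium + cells gain = J_v - Q_L
  expect_equal(sum(dy2[1:9]) + jv_ql, -12.5, tolerance = 1e-9)
})

test_that("ultrafiltration-driven venous pressure drop reaches the capillaries
           with the transmission fraction 0.8", {
  tr <- get_scenario("lps6")
  d <- tr$derived
  dPc <- d$P_c - d$P_c[1]
  dPsv <- d$P_sv - d$P_sv[1]
  expect_equal(dPc, 0.8 * dPsv, tolerance = 1e-9)
})
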