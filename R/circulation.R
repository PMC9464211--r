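#' Elastance pressures of the vascular compartments
#'
#' Lumped relation `P = (V - V_u) / C` per compartment.
#'
#' @param volumes compartment blood volumes (mL).
#' @param compliances compartment compliances (mL/mmHg).
#' @param unstressed unstressed volumes (mL).
#' @return Pressures in mmHg.
#' @export
compartment_pressures <- function(volumes, compliances, unstressed) {
  stopifnot(all(compliances > 0))
  (volumes - unstressed) / compliances
}

#' Flows along the circulation loop
#'
#' Passive links obey `Q = dP / R` (backflow allowed, there are no valves
#' outside the hearts); the two continuous-flow pumps deliver a flow linear in
#' their filling pressure, scaled by the heart-rate and contractility
#' controller outputs and clipped at zero.
#'
#' @param pressures named per-compartment pressures (mmHg), flow order.
#' @param resistances outflow resistances of the seven passive links
#'   (mmHg.min/mL), in flow order skipping the two pump links.
#' @param k_pump pump gains `c(right, left)` in mL/min/mmHg.
#' @param s_hr,s_ctr heart-rate and contractility scalings (1 = neutral).
#' @return Named vector of the nine link flows (mL/min), `from_to` names.
#' @export
vascular_flows <- function(pressures, resistances, k_pump,
                           s_hr = 1, s_ctr = 1) {
  stopifnot(all(resistances > 0), length(pressures) == 9)
  P <- unname(pressures)
  q <- c(
    la_sa  = (P[1] - P[2]) / resistances[1],
    sa_cap = (P[2] - P[3]) / resistances[2],
    cap_sv = (P[3] - P[4]) / resistances[3],
    sv_lv  = (P[4] - P[5]) / resistances[4],
    lv_rh  = (P[5] - P[6]) / resistances[5],
    rh_pa  = k_pump[1] * s_hr * s_ctr * max(P[6], 0),
    pa_pv  = (P[7] - P[8]) / resistances[6],
    pv_lh  = (P[8] - P[9]) / resistances[7],
    lh_la  = k_pump[2] * s_hr * s_ctr * max(P[9], 0)
  )
  q
}

#' Static characteristic of one baroreflex controller
#'
#' Saturating (sigmoidal) response `amp * tanh(gain * err / amp)` of a
#' controller to its afferent pressure error; bounded by `amp`, neutral (zero)
#' at the set point.
#'
#' @param err afferent error, set point minus afferent pressure (mmHg).
#' @param gain controller gain (output units per mmHg).
#' @param amp saturation amplitude (output units).
#' @return Static controller output.
#' @export
baroreflex_static <- function(err, gain, amp) {
  amp * tanh(gain * err / amp)
}

#' First-order update of the baroreflex controller states
#'
#' Each of the four controllers (heart rate, contractility, arteriolar
#' resistance, venous unstressed volume) relaxes with its own time constant
#' toward the sigmoidal static characteristic of its afferent error. With all
#' gains zero the outputs are frozen (open loop).
#'
#' @param state named numeric vector `c(hr, ctr, res, vu)` of controller outputs.
#' @param afferent named afferent pressures `c(high, low)` in mmHg: large
#'   arteries and right heart.
#' @param setpt named set points `c(high, low)` (mmHg).
#' @param baro the `baro` block of a [virtual_patient()].
#' @param dt time step (min).
#' @return Updated state vector.
#' @export
baroreflex_update <- function(state, afferent, setpt, baro, dt) {
  stopifnot(dt > 0)
  d <- baroreflex_derivs(state, afferent, setpt, baro)
  state + dt * d
}

# time-derivatives of the four controller states (used inside the ODE RHS)
baroreflex_derivs <- function(state, afferent, setpt, baro) {
  err_hi <- setpt[["high"]] - afferent[["high"]]
  err_lo <- setpt[["low"]] - afferent[["low"]]
  tgt <- c(
    hr  = baroreflex_static(err_hi, baro$gain[["hr"]],  baro$amp[["hr"]]),
    ctr = baroreflex_static(err_hi, baro$gain[["ctr"]], baro$amp[["ctr"]]),
    res = baroreflex_static(err_hi, baro$gain[["res"]], baro$amp[["res"]]),
    # low-pressure signal: pressure drop -> venoconstriction (negative offset)
    vu  = -baroreflex_static(err_lo, baro$gain[["vu"]], baro$amp[["vu"]])
  )
  (tgt - state) / baro$tau
}

# Derived circulation constants: unstressed volumes, link resistances and pump
# gains chosen so that the normal (healthy) volumes, pressures and cardiac
# output of the registry are a steady state of the loop.
circulation_constants <- function(patient) {
  circ <- patient$circ
  V_n <- circ$BV_n * circ$frac
  Vu <- V_n - circ$C * circ$P_n
  P <- unname(circ$P_n)
  CO <- circ$CO_n
  R <- c(
    la_sa  = (P[1] - P[2]) / CO,
    sa_cap = (P[2] - P[3]) / CO,
    cap_sv = (P[3] - P[4]) / CO,
    sv_lv  = (P[4] - P[5]) / CO,
    lv_rh  = (P[5] - P[6]) / CO,
    pa_pv  = (P[7] - P[8]) / CO,
    pv_lh  = (P[8] - P[9]) / CO
  )
  k_pump <- c(right = CO / P[6], left = CO / P[9])
  list(V_n = V_n, Vu = Vu, R = R, k_pump = k_pump, C = circ$C)
}

# Closed-form steady state of the circulation loop for a given total blood
# volume and a constant transcapillary leak J (mL/min, capillary compartment
# to interstitium) returned as lymph into the large veins. Baroreflex neutral.
# Link flows: CO on arterial/pulmonary links, CO - J between capillaries and
# large veins. Pressures are linear in CO; the total-volume constraint then
# fixes CO.
circulation_steady_state <- function(patient, BV_total, J = 0) {
  cc <- circulation_constants(patient)
  R <- cc$R
  kR <- cc$k_pump[["right"]]
  kL <- cc$k_pump[["left"]]
  # P_i = a_i * CO + b_i
  a <- numeric(9); b <- numeric(9)
  a[6] <- 1 / kR                          # right-heart filling sets pump flow
  a[9] <- 1 / kL
  a[5] <- a[6] + R[["lv_rh"]]
  a[4] <- a[5] + R[["sv_lv"]]; b[4] <- -J * R[["sv_lv"]]
  a[3] <- a[4] + R[["cap_sv"]]; b[3] <- b[4] - J * R[["cap_sv"]]
  a[2] <- a[3] + R[["sa_cap"]]; b[2] <- b[3]
  a[1] <- a[2] + R[["la_sa"]]; b[1] <- b[2]
  a[8] <- a[9] + R[["pv_lh"]]
  a[7] <- a[8] + R[["pa_pv"]]
  Cv <- unname(cc$C)
  CO <- (BV_total - sum(cc$Vu) - sum(Cv * b)) / sum(Cv * a)
  P <- a * CO + b
  V <- cc$Vu + Cv * P
  list(P = stats::setNames(P, names(patient$circ$P_n)),
       V = stats::setNames(V, names(patient$circ$P_n)),
       CO = CO, constants = cc)
}
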