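#' Dialysis session protocol
#'
#' Defines one hemodialysis scenario: duration, total net ultrafiltration,
#' priming-saline handling, extracorporeal circuit volume, and the
#' time-profile of the whole-body filtration coefficient LpS (constant or a
#' linear ramp over the session). Dialyzer clearances and dialysate
#' composition live in the [virtual_patient()] registry so the sensitivity
#' screen can enumerate them.
#'
#' @param duration_min session duration (min).
#' @param uf_total_mL total net ultrafiltration (mL).
#' @param priming `"discarded"` (circuit filled with the patient's blood,
#'   saline drained), `"infused"` (saline given to the patient; the UF rate is
#'   raised by the circuit volume to reach the same net fluid removal) or
#'   `"none"` (no extracorporeal circuit, no dialyzer; equilibrium runs).
#' @param circuit_mL extracorporeal circuit volume (dialyzer + tubing, mL).
#' @param Qb dialyzer blood flow rate (mL/min).
#' @param lps_start,lps_end LpS profile (mL/min/mmHg); `NULL` start uses the
#'   patient's registry value, `NULL` end keeps LpS constant.
#' @param saline_Na,saline_Cl composition of the priming saline (mmol/L).
#' @param dialyzer run the diffusive dialyzer solute exchange (`FALSE` gives
#'   an ultrafiltration-only session, e.g. isolated UF experiments).
#' @return An object of class `session_protocol`.
#' @export
#' @examples
#' session_protocol()                        # basal: 4 h, 3 L, discarded
#' session_protocol(lps_start = 6, lps_end = 4)  # LpS ramp 6 -> 4
session_protocol <- function(duration_min = 240, uf_total_mL = 3000,
                             priming = c("discarded", "infused", "none"),
                             circuit_mL = 220, Qb = 300,
                             lps_start = NULL, lps_end = NULL,
                             saline_Na = 154, saline_Cl = 154,
                             dialyzer = TRUE) {
  priming <- match.arg(priming)
  stopifnot(duration_min > 0, uf_total_mL >= 0, circuit_mL >= 0)
  if (!is.null(lps_start)) stopifnot(lps_start > 0)
  if (!is.null(lps_end)) stopifnot(lps_end > 0)
  structure(list(duration_min = duration_min, uf_total_mL = uf_total_mL,
                 priming = priming, circuit_mL = circuit_mL, Qb = Qb,
                 lps_start = lps_start, lps_end = lps_end,
                 saline_Na = saline_Na, saline_Cl = saline_Cl,
                 dialyzer = dialyzer),
            class = "session_protocol")
}

#' @export
print.session_protocol <- function(x, ...) {
  cat(sprintf("<session_protocol> %g min, UF %g mL (%.2f mL/min), priming %s\n",
              x$duration_min, x$uf_total_mL,
              ultrafiltration_profile(0, x), x$priming))
  if (!is.null(x$lps_start))
    cat(sprintf("  LpS %g -> %g mL/min/mmHg\n", x$lps_start,
                if (is.null(x$lps_end)) x$lps_start else x$lps_end))
  invisible(x)
}

#' Ultrafiltration rate at time t
#'
#' Constant rate `uf_total / duration`; with the priming saline infused the
#' rate is raised to `(uf_total + circuit volume) / duration` so the session
#' achieves the same net fluid removal.
#'
#' @param t time since the start of HD (min); vectorised.
#' @param protocol a [session_protocol()].
#' @return UF rate in mL/min.
#' @export
ultrafiltration_profile <- function(t, protocol) {
  if (any(t < 0 | t > protocol$duration_min))
    stop("time outside the session: [0, ", protocol$duration_min, "] min")
  if (protocol$priming == "none" || protocol$uf_total_mL == 0)
    return(rep(0, length(t)))
  total <- protocol$uf_total_mL +
    if (protocol$priming == "infused") protocol$circuit_mL else 0
  rep(total / protocol$duration_min, length(t))
}

# LpS at time t under the protocol profile (linear ramp)
lps_at <- function(t, protocol, patient) {
  s <- if (is.null(protocol$lps_start)) patient$pores$LpS else protocol$lps_start
  if (is.null(protocol$lps_end)) return(rep(s, length(t)))
  s + (protocol$lps_end - s) * t / protocol$duration_min
}

#' Diffusive dialyzer solute exchange
#'
#' Removal rate `CL * (alphaD * c_plw - c_di) / 1000` of one solute, where
#' `CL` is its clearance/dialysance, `alphaD` the Gibbs-Donnan coefficient
#' across the dialyzer membrane, `c_plw` the plasma-water concentration and
#' `c_di` the dialysate concentration. Negative values mean uptake from the
#' dialysate (e.g. bicarbonate).
#'
#' @param clearance dialyzer clearance/dialysance (mL/min).
#' @param c_plw plasma-water concentration (mmol/L).
#' @param c_di dialysate concentration (mmol/L).
#' @param alphaD Gibbs-Donnan coefficient across the dialyzer membrane.
#' @return Removal rate in mmol/min (positive = removed from the patient).
#' @export
#' @examples
#' dialyzer_solute_exchange(200, 20, 0)        # urea
#' dialyzer_solute_exchange(100, 22, 32)       # bicarbonate uptake
dialyzer_solute_exchange <- function(clearance, c_plw, c_di, alphaD = 1) {
  stopifnot(all(clearance >= 0))
  clearance * (alphaD * c_plw - c_di) / 1000
}

#' Apply the priming procedure to the pre-dialysis state
#'
#' Converts the pre-dialysis steady state (no extracorporeal circuit) into the
#' state at t = 0, after the circuit has been filled:
#' \itemize{
#' \item discarded: the circuit is filled with 220 mL of the patient's whole
#'   blood and the saline is drained; in-body blood volume drops by the
#'   circuit volume, no composition change, total circulating volume unchanged.
#' \item infused: the priming saline is pushed into the patient while the
#'   circuit fills with blood; circulating plasma gains the circuit volume of
#'   isotonic saline, diluting proteins and solutes.
#' \item none: state returned unchanged (no circuit).
#' }
#'
#' @param state0 pre-dialysis state list from [solve_initial_steady_state()].
#' @param protocol a [session_protocol()].
#' @return The state list at t = 0, with `V_circuit` set.
#' @export
apply_priming <- function(state0, protocol) {
  st <- state0
  vc <- protocol$circuit_mL
  if (protocol$priming == "none" || vc == 0) {
    st$V_circuit <- 0
    return(st)
  }
  if (protocol$priming == "infused") {
    # saline enters the plasma of the circulating blood
    st$V[] <- st$V * (1 + vc / sum(st$V))
    st$N_pl[["Na"]] <- st$N_pl[["Na"]] + protocol$saline_Na * vc / 1000
    st$N_pl[["Cl"]] <- st$N_pl[["Cl"]] + protocol$saline_Cl * vc / 1000
  }
  # circuit fills with the patient's blood (in-body volume falls either way)
  st$V[] <- st$V * (1 - vc / sum(st$V))
  st$V_circuit <- vc
  st
}
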