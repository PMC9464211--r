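#' Interstitium and lymph parameters
#'
#' Parameter bundle for the interstitial pressure-volume law and the lymph-flow
#' law. Internal units are mL, min and mmHg throughout the package; the
#' conventional clinical units (L, L/day, mL/mmHg/h) are converted here, once.
#'
#' @param P_is_n normal interstitial pressure (mmHg).
#' @param V_is_n normal interstitial volume (mL).
#' @param C_is_frac interstitial compliance as a fraction of `V_is_n` per mmHg.
#' @param Q_L_n_lday normal afferent lymph flow (L/day).
#' @param LS_mlmmhgh lymph flow sensitivity to interstitial pressure (mL/mmHg/h).
#' @param V_ex_frac protein-excluded interstitial volume as a fraction of `V_is_n`.
#' @return An object of class `interstitium_params` with fields in mL/min/mmHg:
#'   `P_is_n`, `V_is_n`, `C_is` (mL/mmHg), `Q_L_n` (mL/min), `LS` (mL/mmHg/min),
#'   `V_is_ex` (mL) and the cutoff pressure `P_is_ex` (mmHg) at which lymph flow
#'   ceases, obtained by evaluating the pressure-volume law at `V_is_ex`.
#' @export
#' @examples
#' p <- interstitium_params()
#' interstitial_pressure(17500, p)  # fluid-overloaded
#' lymph_flow(-1, p)                # normal pressure -> normal flow
interstitium_params <- function(P_is_n = -1, V_is_n = 15000, C_is_frac = 0.12,
                                Q_L_n_lday = 8, LS_mlmmhgh = 43.1,
                                V_ex_frac = 0.5) {
  stopifnot(C_is_frac > 0, V_ex_frac > 0, V_ex_frac < 1, Q_L_n_lday >= 0)
  C_is <- C_is_frac * V_is_n / 1000          # L/mmHg expressed on V in mL: mL/mmHg
  V_is_ex <- V_ex_frac * V_is_n
  p <- list(
    P_is_n = P_is_n,
    V_is_n = V_is_n,
    C_is = C_is * 1000,                      # mL/mmHg
    Q_L_n = Q_L_n_lday * 1000 / (24 * 60),   # mL/min
    LS = LS_mlmmhgh / 60,                    # mL/mmHg/min
    V_is_ex = V_is_ex
  )
  p$P_is_ex <- P_is_n + (V_is_ex - V_is_n) / p$C_is
  structure(p, class = "interstitium_params")
}

#' Interstitial hydrostatic pressure from interstitial volume
#'
#' Linear pressure-volume relation `P_is = P_is_n + (V_is - V_is_n)/C_is`.
#'
#' @param V_is interstitial fluid volume (mL).
#' @param params an [interstitium_params()] object.
#' @return Pressure in mmHg.
#' @export
interstitial_pressure <- function(V_is, params = interstitium_params()) {
  stopifnot(all(V_is > 0))
  params$P_is_n + (V_is - params$V_is_n) / params$C_is
}

#' Lymph flow from interstitial pressure
#'
#' Piecewise-linear lymph law: above the normal interstitial pressure the flow
#' rises from its normal value with sensitivity `LS`; between the normal
#' pressure and the excluded-volume cutoff it declines linearly to zero; at and
#' below the cutoff it is zero. Continuous at the normal pressure.
#'
#' @param P_is interstitial pressure (mmHg); vectorised.
#' @param params an [interstitium_params()] object.
#' @return Lymph flow in mL/min (never negative).
#' @export
lymph_flow <- function(P_is, params = interstitium_params()) {
  up <- params$Q_L_n + params$LS * (P_is - params$P_is_n)
  dn <- params$Q_L_n * (P_is - params$P_is_ex) / (params$P_is_n - params$P_is_ex)
  q <- ifelse(P_is >= params$P_is_n, up, pmax(dn, 0))
  pmax(q, 0)
}

#' Capillary pressure coupled to venous pressure
#'
#' Mean capillary blood pressure is assumed resistant to arterial pressure
#' changes (capillary-bed autoregulation) while a fraction `w_v` of venous
#' pressure changes is transmitted back: `P_c = P_c0 + w_v (P_sv - P_sv0)`.
#'
#' @param P_sv small-veins pressure (mmHg).
#' @param P_c0 capillary pressure at the reference venous pressure (mmHg).
#' @param w_v transmitted fraction of venous pressure changes.
#' @param P_sv0 reference small-veins pressure (mmHg).
#' @return Capillary pressure in mmHg.
#' @export
capillary_pressure <- function(P_sv, P_c0, w_v = 0.8, P_sv0 = 12) {
  P_c0 + w_v * (P_sv - P_sv0)
}
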