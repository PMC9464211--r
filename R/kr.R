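# Analysis layer: vascular refilling rate, refilling coefficient Kr(t),
# Starling-force decomposition, local relative sensitivities.

#' Vascular refilling rate from a simulated trajectory
#'
#' The refilling rate is `R(t) = dV_p/dt + UF(t)`: the net fluid gain of the
#' circulation (transcapillary absorption plus lymph) that offsets the
#' ultrafiltration. The plasma-volume derivative is taken by second-order
#' central differences on the fixed output grid (one-sided at the edges). The
#' flux form `-J_v + Q_L` of the same quantity is returned alongside as an
#' internal consistency check.
#'
#' @param trajectory an [run_session()] trajectory.
#' @return data.frame with `time`, `R` (derivative form, mL/min), `R_flux`
#'   (flux form) and `dVp_dt`.
#' @export
refilling_rate <- function(trajectory) {
  d <- trajectory$derived
  dt <- diff(d$time[1:2])
  n <- nrow(d)
  dv <- numeric(n)
  dv[2:(n - 1)] <- (d$V_p[3:n] - d$V_p[1:(n - 2)]) / (2 * dt)
  dv[1] <- (-3 * d$V_p[1] + 4 * d$V_p[2] - d$V_p[3]) / (2 * dt)
  dv[n] <- (3 * d$V_p[n] - 4 * d$V_p[n - 1] + d$V_p[n - 2]) / (2 * dt)
  data.frame(time = d$time, R = dv + d$UF, R_flux = d$refill_flux, dVp_dt = dv)
}

#' Vascular refilling coefficient Kr(t)
#'
#' `Kr(t) = R(t) / (pi_pl(t) - pi_pl(0))`: refilling rate per unit change of
#' plasma oncotic pressure since the session start. Kr diverges as t -> 0
#' (infinitesimal denominator), so the curve is reported from `start` minutes
#' onward, and points where `|pi_pl(t) - pi_pl(0)| < mask_tol` are masked
#' (`NA`). Plasma oncotic pressure comes from the simulated albumin/globulin
#' fractions through the oncotic polynomials.
#'
#' @param trajectory a [run_session()] trajectory.
#' @param start first reported time (min).
#' @param mask_tol denominator mask tolerance (mmHg).
#' @return An object of class `kr_curve`: data.frame fields `time`, `Kr`
#'   (mL/min/mmHg), `R`, `UF`, `dpi` plus attributes.
#' @export
kr_curve <- function(trajectory, start = 5, mask_tol = 0.05) {
  d <- trajectory$derived
  rr <- refilling_rate(trajectory)
  dpi <- d$pi_pl - d$pi_pl[1]
  keep <- d$time >= start
  kr <- ifelse(abs(dpi) < mask_tol, NA_real_, rr$R / dpi)
  out <- data.frame(time = d$time[keep], Kr = kr[keep], R = rr$R[keep],
                    UF = d$UF[keep], dpi = dpi[keep])
  if (all(is.na(out$Kr)))
    warning("Kr curve entirely masked: plasma oncotic pressure never moved ",
            "beyond the mask tolerance")
  structure(out, class = c("kr_curve", "data.frame"),
            pi_pl0 = d$pi_pl[1], start = start, mask_tol = mask_tol)
}

#' @export
print.kr_curve <- function(x, ...) {
  ok <- is.finite(x$Kr)
  cat(sprintf("<kr_curve> t in [%g, %g] min, %d points (%d masked)\n",
              min(x$time), max(x$time), nrow(x), sum(!ok)))
  if (any(ok))
    cat(sprintf("  Kr: %.2f (first) -> %.2f (last) mL/min/mmHg\n",
                x$Kr[which(ok)[1]], x$Kr[rev(which(ok))[1]]))
  invisible(x)
}

#' Decomposition of the Starling forces driving vascular refilling
#'
#' Expresses each force as its signed change since t = 0, with the sign
#' convention that positive values favour transcapillary absorption (vascular
#' refilling): falling capillary pressure and rising plasma oncotic pressure
#' plot upward; rising interstitial oncotic pressure and falling interstitial
#' hydrostatic pressure plot downward. The small-solute osmotic force is the
#' small-pore-reflection-weighted gradient (the aquaporin pathway sees the full
#' gradient but carries no solute). The lymph contribution is reported
#' separately in pressure units as `Q_L / LpS`.
#'
#' @param trajectory a [run_session()] trajectory.
#' @return An object of class `starling_decomposition` (data.frame): `time`,
#'   `capillary`, `interstitial_hydrostatic`, `plasma_oncotic`,
#'   `interstitial_oncotic`, `small_solute`, `net` (their sum) and
#'   `lymph_equiv` (mmHg).
#' @export
starling_decomposition <- function(trajectory) {
  d <- trajectory$derived
  delta <- function(x) x - x[1]
  out <- data.frame(
    time = d$time,
    capillary = -delta(d$P_c),
    interstitial_hydrostatic = delta(d$P_is),
    plasma_oncotic = delta(d$pi_pl),
    interstitial_oncotic = -delta(d$pi_is),
    small_solute = -delta(d$osm_small),
    lymph_equiv = delta(d$Q_L / d$LpS)
  )
  out$net <- out$capillary + out$interstitial_hydrostatic +
    out$plasma_oncotic + out$interstitial_oncotic + out$small_solute
  structure(out, class = c("starling_decomposition", "data.frame"))
}

# finite-difference relative (log) sensitivity of a scalar functional:
# S = [f(theta+) - f(theta-)] / (2 delta) * theta / f(theta)
relative_sensitivity_fd <- function(f, theta, rel_step = 1e-4) {
  stopifnot(theta != 0)
  f0 <- f(theta)
  if (!is.finite(f0) || f0 == 0) stop("functional is zero or non-finite at the base point")
  h <- rel_step * theta
  (f(theta + h) - f(theta - h)) / (2 * h) * theta / f0
}

#' Local relative sensitivity of Kr to one model parameter
#'
#' Central-difference log-sensitivity `S_k = dKr/dtheta * theta/Kr` with the
#' parameter perturbed by +/-0.01% of its value. Each evaluation re-solves the
#' pre-dialysis steady state (the initial capillary pressure is re-adjusted)
#' and re-runs the full session, so the sensitivity includes the parameter's
#' effect on the initial conditions, and two full simulations are run per
#' parameter.
#'
#' @param patient a [virtual_patient()].
#' @param protocol a [session_protocol()].
#' @param param flattened registry name (see [flatten_patient()]).
#' @param t_eval evaluation time(s) (min); values snap to the output grid.
#' @param rel_step relative perturbation (default 1e-4, i.e. 0.01%).
#' @param base optional cached baseline [kr_curve()] to avoid re-simulation.
#' @return An object of class `sensitivity_result`: data.frame `parameter`,
#'   `value`, `t_eval`, `Kr`, `S`.
#' @export
relative_sensitivity <- function(patient, protocol, param, t_eval = NULL,
                                 rel_step = 1e-4, base = NULL) {
  if (is.null(t_eval)) t_eval <- c(5, protocol$duration_min)
  flat <- flatten_patient(patient)
  if (!param %in% names(flat)) stop("unknown parameter: ", param)
  theta <- flat[[param]]
  if (theta == 0) stop("relative sensitivity undefined for zero-valued ", param)
  kr_at <- function(value) {
    pt <- set_patient_param(patient, param, value)
    kc <- kr_curve(run_session(pt, protocol))
    vapply(t_eval, function(tt) kc$Kr[which.min(abs(kc$time - tt))], numeric(1))
  }
  if (is.null(base)) base <- kr_at(theta) else {
    base <- vapply(t_eval, function(tt) base$Kr[which.min(abs(base$time - tt))],
                   numeric(1))
  }
  if (any(!is.finite(base)) || any(base == 0))
    stop("Kr is zero, masked or non-finite at an evaluation time")
  h <- rel_step * theta
  up <- kr_at(theta + h)
  dn <- kr_at(theta - h)
  S <- (up - dn) / (2 * h) * theta / base
  structure(data.frame(parameter = param, value = theta, t_eval = t_eval,
                       Kr = base, S = S),
            class = c("sensitivity_result", "data.frame"))
}

#' Screen the relative sensitivity of Kr over the parameter registry
#'
#' Runs [relative_sensitivity()] for every (or a subset of the) scalar
#' parameters of the registry, at the requested evaluation times, and ranks by
#' absolute sensitivity. Two full simulations are run per parameter; the
#' baseline is simulated once and shared.
#'
#' @param patient a [virtual_patient()].
#' @param protocol a [session_protocol()].
#' @param t_eval evaluation times (min).
#' @param params parameter names (default: the full registry).
#' @param threshold reporting threshold on `|S|` for the `top` table.
#' @return List with `all` (every parameter x time), `top` (filtered at
#'   `|S| > threshold`, ranked) and `n_simulations`.
#' @export
sensitivity_screen <- function(patient, protocol = session_protocol(),
                               t_eval = c(5, protocol$duration_min),
                               params = NULL, threshold = 0.5) {
  flat <- flatten_patient(patient)
  if (is.null(params)) params <- names(flat)
  params <- params[flat[params] != 0]
  base <- kr_curve(run_session(patient, protocol))
  rows <- lapply(params, function(pn) {
    tryCatch(relative_sensitivity(patient, protocol, pn, t_eval = t_eval,
                                  base = base),
             error = function(e)
               data.frame(parameter = pn, value = flat[[pn]], t_eval = t_eval,
                          Kr = NA_real_, S = NA_real_))
  })
  all <- do.call(rbind, rows)
  top <- all[is.finite(all$S) & abs(all$S) > threshold, ]
  top <- top[order(-abs(top$S)), ]
  list(all = all, top = top, n_simulations = 2 * length(params) + 1)
}
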