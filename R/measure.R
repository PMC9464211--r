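# Synthetic clinical measurement series and the hematocrit-based Kr estimator,
# emulating how the refilling coefficient is obtained from real monitor data:
# relative blood volume tracked via hematocrit under the constant-erythrocyte-
# volume assumption, plasma oncotic pressure from total plasma protein.

#' Synthesize clinical-style measurement series from a trajectory
#'
#' Samples hematocrit and total plasma protein from a simulated trajectory on
#' clinical schedules and applies multiplicative Gaussian noise per channel.
#' Hematocrit is erythrocyte volume over circulating blood volume (erythrocyte
#' volume constant); relative blood volume follows from it.
#'
#' @param trajectory a [run_session()] trajectory.
#' @param hct_every hematocrit sampling interval (min).
#' @param tp_every total-protein sampling interval (min).
#' @param noise_cv list or vector with `hct` and `tp` coefficients of
#'   variation (0 = noiseless).
#' @param seed integer seed; fixed seed gives a bit-identical series.
#' @return An object of class `measurement_series`: `hct` data.frame (`time`,
#'   `hct`, `rbv_pct`), `tp` data.frame (`time`, `tp`), the noise settings and
#'   seed, plus the true initial plasma volume as attribute `V_p0_true`.
#' @export
synthesize_measurements <- function(trajectory, hct_every = 10, tp_every = 30,
                                    noise_cv = c(hct = 0.01, tp = 0.01),
                                    seed = 1) {
  d <- trajectory$derived
  t_end <- max(d$time)
  t_hct <- seq(0, t_end, by = hct_every)
  t_tp <- seq(0, t_end, by = tp_every)
  if (max(t_hct) > t_end || min(t_hct) < min(d$time))
    stop("sampling schedule outside the trajectory")
  at <- function(x, tt) stats::approx(d$time, x, tt)$y
  set.seed(seed)
  hct <- at(d$Hct, t_hct) * (1 + stats::rnorm(length(t_hct), 0, noise_cv[["hct"]]))
  tp <- at(d$TP, t_tp) * (1 + stats::rnorm(length(t_tp), 0, noise_cv[["tp"]]))
  structure(list(
    hct = data.frame(time = t_hct, hct = hct,
                     rbv_pct = 100 * hct[1] / hct),
    tp = data.frame(time = t_tp, tp = tp),
    noise_cv = noise_cv, seed = seed
  ), class = "measurement_series",
  V_p0_true = d$V_p[1], uf_rate = d$UF[1])
}

#' @export
print.measurement_series <- function(x, ...) {
  cat(sprintf("<measurement_series> %d hematocrit + %d protein samples, CV %g/%g, seed %d\n",
              nrow(x$hct), nrow(x$tp), x$noise_cv[["hct"]], x$noise_cv[["tp"]],
              x$seed))
  invisible(x)
}

#' Plasma volume series from hematocrit measurements
#'
#' Under constant erythrocyte volume,
#' `V_p(t)/V_p(0) = Hct(0)(1 - Hct(t)) / (Hct(t)(1 - Hct(0)))`. An
#' exponential-plus-offset curve `V_p(t) = A + B exp(-t/tau)` is fitted by
#' least squares and its analytic derivative is returned as the instantaneous
#' rate of plasma volume change, as clinical Kr estimation does.
#'
#' @param series a [synthesize_measurements()] object.
#' @param V_p0 absolute initial plasma volume estimate (mL).
#' @return List with `samples` (time, V_p), the fit coefficients, and
#'   functions `V_p(t)` and `dVp_dt(t)`.
#' @export
plasma_volume_from_rbv <- function(series, V_p0) {
  h <- series$hct
  if (nrow(h) < 4) stop("need at least 4 hematocrit samples for the fit")
  ratio <- h$hct[1] * (1 - h$hct) / (h$hct * (1 - h$hct[1]))
  vp <- V_p0 * ratio
  df <- data.frame(t = h$time, vp = vp)
  span <- max(vp) - min(vp)
  if (span < 1e-9) {
    fit <- list(A = mean(vp), B = 0, tau = Inf)
  } else {
    nls <- minpack.lm::nlsLM(
      vp ~ A + B * exp(-t / tau), data = df,
      start = list(A = min(vp), B = vp[1] - min(vp), tau = max(df$t) / 2),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(nls)
    fit <- list(A = cf[["A"]], B = cf[["B"]], tau = cf[["tau"]])
  }
  list(samples = df, fit = fit,
       V_p = function(t) fit$A + fit$B * exp(-t / fit$tau),
       dVp_dt = function(t) {
         if (!is.finite(fit$tau)) rep(0, length(t))
         else -fit$B / fit$tau * exp(-t / fit$tau)
       })
}

#' Measurement-based refilling coefficient (clinical estimator)
#'
#' Applies the Kr definition the way it is used on clinical data: plasma
#' volume rate from the fitted hematocrit-derived curve
#' ([plasma_volume_from_rbv()]), plasma oncotic pressure from measured total
#' protein through the Landis-Pappenheimer polynomial, so
#' `Kr(t) = (dV_p/dt + UF) / (pi_LP(C(t)) - pi_LP(C(0)))`, reported from
#' minute `start` with the same denominator mask as the model-truth curve.
#' Total-protein samples are interpolated onto the hematocrit grid with a
#' monotone spline.
#'
#' @param series a [synthesize_measurements()] object.
#' @param uf_rate ultrafiltration rate (mL/min), constant.
#' @param V_p0 initial plasma volume estimate (mL).
#' @param grid_dt output grid (min).
#' @param start,mask_tol as in [kr_curve()].
#' @return A `kr_curve` object.
#' @export
kr_from_measurements <- function(series, uf_rate, V_p0, grid_dt = 0.5,
                                 start = 5, mask_tol = 0.05) {
  pv <- plasma_volume_from_rbv(series, V_p0)
  t_end <- max(series$hct$time)
  tt <- seq(start, t_end, by = grid_dt)
  tp_fun <- stats::splinefun(series$tp$time, series$tp$tp, method = "monoH.FC")
  dpi <- pi_landis_pappenheimer(pmax(tp_fun(tt), 0)) -
    pi_landis_pappenheimer(max(series$tp$tp[1], 0))
  R <- pv$dVp_dt(tt) + uf_rate
  kr <- ifelse(abs(dpi) < mask_tol, NA_real_, R / dpi)
  structure(data.frame(time = tt, Kr = kr, R = R, UF = uf_rate, dpi = dpi),
            class = c("kr_curve", "data.frame"),
            pi_pl0 = pi_landis_pappenheimer(series$tp$tp[1]),
            start = start, mask_tol = mask_tol)
}
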