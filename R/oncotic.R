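#' Colloid osmotic (oncotic) pressure of the albumin fraction
#'
#' Albumin contribution to plasma or interstitial oncotic pressure as a cubic
#' polynomial in the total protein concentration, split by the albumin mass
#' fraction. The polynomial pair ([pi_albumin()] and [pi_globulin()]) is
#' calibrated so that their sum at the normal albumin-to-globulin ratio of 1.5
#' (a = 0.6) reproduces the classical Landis-Pappenheimer total to within 1%
#' over the physiological range.
#'
#' @param C total protein concentration (g/dL), plasma or interstitial.
#' @param a albumin mass fraction of total protein (dimensionless, in (0,1]).
#' @return Oncotic pressure in mmHg.
#' @seealso [pi_globulin()], [pi_landis_pappenheimer()]
#' @export
#' @examples
#' pi_albumin(7, 0.6)
pi_albumin <- function(C, a) {
  stopifnot(all(C >= 0), all(a > 0), all(a <= 1))
  a * (2.8 * C + 0.18 * C^2 + 0.012 * C^3)
}

#' Colloid osmotic (oncotic) pressure of the globulin fraction
#'
#' Non-albumin ("globulin") contribution to the oncotic pressure; see
#' [pi_albumin()] for the calibration of the polynomial pair.
#'
#' @inheritParams pi_albumin
#' @return Oncotic pressure in mmHg.
#' @export
pi_globulin <- function(C, a) {
  stopifnot(all(C >= 0), all(a > 0), all(a <= 1))
  (1 - a) * (1.1 * C + 0.13 * C^2 + 0.005 * C^3)
}

#' Landis-Pappenheimer oncotic pressure from total protein
#'
#' Classical single-polynomial relation between total protein concentration and
#' colloid osmotic pressure. Used by the measurement-based Kr estimator, which
#' only sees total plasma protein (no albumin/globulin split).
#'
#' @param C total protein concentration (g/dL).
#' @return Oncotic pressure in mmHg.
#' @export
#' @examples
#' pi_landis_pappenheimer(7)
pi_landis_pappenheimer <- function(C) {
  stopifnot(all(C >= 0))
  2.1 * C + 0.16 * C^2 + 0.009 * C^3
}

#' Van't Hoff Gibbs-Donnan ion-excess term (optional)
#'
#' Additive small-ion excess oncotic term `RT * |z_p| * c_p / 2` per protein
#' fraction, with `c_p` the molar protein concentration. The empirical
#' polynomials of [pi_albumin()] and [pi_globulin()] already embed the
#' Gibbs-Donnan ion excess, so this term is off by default in
#' [virtual_patient()] (`include_donnan = FALSE`); it is provided for
#' exploring an explicit charge-based correction.
#'
#' @param C total protein concentration (g/dL).
#' @param a albumin mass fraction.
#' @param z_alb,z_glob net protein charges (valence) at pH 7.4.
#' @param mw_alb,mw_glob molar masses (g/mmol).
#' @param RT gas constant times temperature (mmHg/(mmol/L)).
#' @return Additional oncotic pressure in mmHg.
#' @export
pi_donnan <- function(C, a, z_alb = -17, z_glob = -6,
                      mw_alb = 66.4, mw_glob = 170, RT = 19.3) {
  stopifnot(all(C >= 0))
  c_alb <- 10 * C * a / mw_alb        # g/dL -> g/L -> mmol/L
  c_glob <- 10 * C * (1 - a) / mw_glob
  RT * (abs(z_alb) * c_alb + abs(z_glob) * c_glob) / 2
}
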