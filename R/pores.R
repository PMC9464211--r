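#' Three-pore system of the aggregated capillary wall
#'
#' The whole-body capillary wall is represented by three parallel pathways:
#' large pores (gaps/vesicular transport of macromolecules), small pores
#' (inter-endothelial clefts) and ultrasmall pores (aquaporins, a
#' water-exclusive pathway). Each pore class carries a fraction `alpha` of the
#' whole-body filtration coefficient `LpS` (also written K_f).
#'
#' @param radii pore radii in Angstrom for (large, small, ultrasmall).
#' @param alpha fractions of `LpS` per pore class; must sum to 1.
#' @param LpS whole-body capillary filtration coefficient (mL/min/mmHg).
#' @param RT gas constant times temperature, mmHg per mmol/L.
#' @return An object of class `pore_system`.
#' @export
pore_system <- function(radii = c(large = 250, small = 45, ultrasmall = 2),
                        alpha = c(large = 0.05, small = 0.85, ultrasmall = 0.10),
                        LpS = 6, RT = 19.3) {
  stopifnot(length(radii) == 3, length(alpha) == 3, LpS > 0)
  if (abs(sum(alpha) - 1) > 1e-12)
    stop("pore conductivity fractions alpha must sum to 1")
  structure(list(radii = radii, alpha = alpha, LpS = LpS, RT = RT),
            class = "pore_system")
}

#' Osmotic reflection coefficient from hindered-transport pore theory
#'
#' Hard-sphere-in-cylinder result `sigma = (1 - (1 - lambda)^2)^2` with
#' `lambda = a_s / r_pore`, clamped to \[0, 1\]; solutes larger than the pore are
#' fully reflected. Ultrasmall pores (aquaporins) reflect every solute and
#' protein regardless of size (water-exclusive pathway), which callers encode
#' by `water_only = TRUE`.
#'
#' @param a_solute solute Stokes radius (Angstrom); vectorised.
#' @param r_pore pore radius (Angstrom).
#' @param water_only if `TRUE` return 1 for every solute.
#' @return Reflection coefficient(s) in \[0, 1\].
#' @export
#' @examples
#' reflection_sigma(35.5, 45)   # albumin, small pores
#' reflection_sigma(35.5, 250)  # albumin, large pores
reflection_sigma <- function(a_solute, r_pore, water_only = FALSE) {
  if (water_only) return(rep(1, length(a_solute)))
  lambda <- pmin(a_solute / r_pore, 1)
  pmin(pmax((1 - (1 - lambda)^2)^2, 0), 1)
}

#' Fluid flux through one pore class
#'
#' Extended Starling flux for pore class `i`:
#' `J_v,i = alpha_i * K_f * [(P_c - P_is) - sum_p sigma_p,i (pi_pl,p - pi_is,p)
#'  - sum_s sigma_s,i phi_s (c_pl,s - c_is,s) RT]`,
#' filtration (plasma to interstitium) positive. Concentrations are per litre
#' of water; the Gibbs-Donnan effect for small ions is carried by the oncotic
#' pressure polynomials, not by the concentration term.
#'
#' @param pore index or name of the pore class ("large", "small", "ultrasmall").
#' @param P_c capillary pressure (mmHg).
#' @param P_is interstitial pressure (mmHg).
#' @param pi_pl,pi_is per-protein-fraction oncotic pressures (mmHg), same order.
#' @param sigma_p per-protein reflection coefficients for this pore class.
#' @param c_pl,c_is per-solute water-phase concentrations (mmol/L), same order.
#' @param phi per-solute osmotic activity coefficients.
#' @param sigma_s per-solute reflection coefficients for this pore class.
#' @param pores a [pore_system()].
#' @return Fluid flux in mL/min.
#' @export
pore_fluid_flux <- function(pore, P_c, P_is, pi_pl, pi_is, sigma_p,
                            c_pl = numeric(0), c_is = numeric(0),
                            phi = numeric(0), sigma_s = numeric(0),
                            pores = pore_system()) {
  i <- if (is.character(pore)) match(pore, names(pores$alpha)) else as.integer(pore)
  if (is.na(i) || i < 1 || i > 3) stop("unknown pore index: ", pore)
  osm <- if (length(c_pl)) sum(sigma_s * phi * (c_pl - c_is)) * pores$RT else 0
  pores$alpha[[i]] * pores$LpS *
    ((P_c - P_is) - sum(sigma_p * (pi_pl - pi_is)) - osm)
}

#' Classic aggregate Starling flux
#'
#' Single-membrane form `J_v = K_f [(P_c - P_is) - sigma (pi_pl - pi_is)]`
#' with one aggregate reflection coefficient; used for didactic decompositions
#' and consistency checks of the per-pore formulation.
#'
#' @param P_c,P_is hydraulic/hydrostatic pressures (mmHg).
#' @param pi_pl,pi_is total oncotic pressures (mmHg).
#' @param sigma aggregate protein reflection coefficient in \[0, 1\].
#' @param K_f filtration coefficient (mL/min/mmHg).
#' @return Fluid flux in mL/min, filtration positive.
#' @export
classic_starling_flux <- function(P_c, P_is, pi_pl, pi_is, sigma, K_f) {
  stopifnot(sigma >= 0, sigma <= 1)
  K_f * ((P_c - P_is) - sigma * (pi_pl - pi_is))
}
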