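#' Transcapillary protein flux through one pore class
#'
#' Proteins cross the capillary wall by convection and diffusion through large
#' and small pores only (aquaporins carry no protein). The convective term uses
#' the mean membrane concentration, `(1 - sigma) * J_v * (c_pl + c_is)/2`; the
#' diffusive term is a permeability-surface product times the concentration
#' difference. Positive flux moves protein from plasma to interstitium, so the
#' operation is mass-conservative by construction (plasma loss = interstitial
#' gain).
#'
#' @param sigma reflection coefficient of the protein for this pore class.
#' @param J_v fluid flux through this pore class (mL/min, filtration positive).
#' @param c_pl,c_is protein concentrations (g/mL) in plasma and in the
#'   protein-available interstitial volume.
#' @param PS diffusive permeability-surface product (mL/min).
#' @return Protein flux in g/min.
#' @export
#' @examples
#' protein_flux(0.05, 0.3, 0.05, 0.05, PS = 0)  # pure convection
protein_flux <- function(sigma, J_v, c_pl, c_is, PS = 0) {
  stopifnot(sigma >= 0, sigma <= 1, PS >= 0)
  (1 - sigma) * J_v * (c_pl + c_is) / 2 + PS * (c_pl - c_is)
}

#' Transcapillary small-solute flux through one pore class
#'
#' Convection `(1 - sigma) * J_v * mean concentration` plus diffusion
#' `PS * (c_pl - c_is)`. Concentrations are mmol per litre of water; the
#' returned flux is mmol/min, plasma-to-interstitium positive.
#'
#' @param sigma reflection coefficient for this pore class.
#' @param J_v fluid flux through this pore class (mL/min).
#' @param c_pl,c_is water-phase concentrations (mmol/L).
#' @param PS diffusive permeability-surface product (mL/min).
#' @return Solute flux in mmol/min.
#' @export
small_solute_flux <- function(sigma, J_v, c_pl, c_is, PS = 0) {
  stopifnot(sigma >= 0, sigma <= 1, PS >= 0)
  ((1 - sigma) * J_v * (c_pl + c_is) / 2 + PS * (c_pl - c_is)) / 1000
}

#' Electroneutrality adjustment of transcapillary ion fluxes
#'
#' One collective species ("other anions", average charge -2) is designated as
#' the electroneutrality carrier: its transcapillary flux is set so that the
#' summed charge flux across the capillary wall is exactly zero at every
#' instant, keeping both plasma and interstitial fluid electroneutral.
#' Uncharged solutes are unaffected.
#'
#' @param fluxes named numeric vector of per-solute transcapillary fluxes
#'   (mmol/min, plasma-to-interstitium positive).
#' @param valence named integer charges, same names as `fluxes`.
#' @param carrier name of the carrier species.
#' @return `fluxes` with the carrier entry replaced by the charge-balancing
#'   value.
#' @export
#' @examples
#' f <- c(Na = 0.2, urea = 1, other_anions = 0)
#' electroneutrality_adjustment(f, c(Na = 1, urea = 0, other_anions = -2))
electroneutrality_adjustment <- function(fluxes, valence,
                                         carrier = "other_anions") {
  if (!carrier %in% names(fluxes)) stop("carrier species absent: ", carrier)
  z_c <- valence[[carrier]]
  stopifnot(z_c != 0)
  others <- setdiff(names(fluxes), carrier)
  fluxes[[carrier]] <- -sum(valence[others] * fluxes[others]) / z_c
  fluxes
}
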