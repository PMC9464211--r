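#' Virtual dialysis patient: full parameter registry
#'
#' Builds the complete parameter registry of the whole-body model for a 70-kg
#' reference patient: the nine-compartment circulation with baroreflex, the
#' three-pore capillary wall, protein and small-solute transport, the
#' interstitium/lymph laws, intracellular exchange, and the dialyzer-side
#' solute parameters. Every entry can be perturbed individually, which is what
#' the sensitivity screen enumerates (see [flatten_patient()]).
#'
#' Circulation compartments (in flow order): large arteries, small
#' arteries/arterioles, systemic capillaries, small veins/venules, large veins,
#' right heart, pulmonary arteries, pulmonary veins, left heart. Two
#' continuous-flow pumps (right heart to pulmonary arteries, left heart to
#' large arteries) represent ventricular pumping; passive links are Ohmic.
#' Compliances, normal pressures and volume fractions are standard resting
#' values chosen so the healthy steady state shows a MAP near 93 mmHg, small
#' veins at 12 mmHg and cardiac output near 6.5 L/min.
#'
#' @param overload_mL pre-dialysis fluid overload (mL), split proportionally
#'   between plasma and interstitium by [distribute_overload()].
#' @param LpS whole-body capillary filtration coefficient (mL/min/mmHg).
#' @param TP0 pre-dialysis total plasma protein (g/dL).
#' @param a_pl0 pre-dialysis albumin mass fraction of plasma protein.
#' @param include_donnan add the explicit [pi_donnan()] ion-excess term to the
#'   oncotic pressures (off by default: the empirical polynomials already embed
#'   the small-ion Gibbs-Donnan excess).
#' @return An object of class `virtual_patient` (a nested parameter list).
#' @export
#' @examples
#' pt <- virtual_patient()
#' pt$pores$LpS
virtual_patient <- function(overload_mL = 3000, LpS = 6, TP0 = 7.0,
                            a_pl0 = 0.6, include_donnan = FALSE) {
  comp <- c("large_arteries", "small_arteries", "capillaries", "small_veins",
            "large_veins", "right_heart", "pulm_arteries", "pulm_veins",
            "left_heart")
  circ <- list(
    BV_n = 5000,      # normal total blood volume (mL)
    CO_n = 6500,      # normal cardiac output (mL/min)
    Hct0 = 0.40,      # normal systemic hematocrit (erythrocyte volume constant)
    # normal volume fractions of total blood volume
    frac = stats::setNames(c(0.10, 0.05, 0.05, 0.47, 0.15,
                             0.03, 0.026, 0.09, 0.034), comp),
    # normal compartment pressures (mmHg)
    P_n = stats::setNames(c(93, 75, 18, 12, 5, 4, 15, 8, 5), comp),
    # compartment compliances (mL/mmHg)
    C = stats::setNames(c(1.2, 0.8, 3, 100, 60, 20, 4, 25, 15), comp)
  )
  baro <- list(
    # heart rate, contractility, arteriolar resistance: high-pressure afferent
    # (large arteries); venous unstressed volume: low-pressure afferent
    # (right heart). Saturating first-order controllers, neutral at set point.
    gain = c(hr = 0.02, ctr = 0.015, res = 0.03, vu = 100),
    amp  = c(hr = 0.30, ctr = 0.30,  res = 0.50, vu = 500),
    tau  = c(hr = 0.5,  ctr = 1.0,   res = 1.0,  vu = 2.0)
  )
  sol_names <- c("Na", "K", "Cl", "HCO3", "urea", "creatinine", "other_anions")
  solutes <- list(
    names = sol_names,
    valence = stats::setNames(c(1, 1, -1, -1, 0, 0, -2), sol_names),
    phi = stats::setNames(c(0.93, 0.93, 0.93, 0.93, 1, 1, 1), sol_names),
    radius = stats::setNames(c(2.3, 2.0, 1.8, 2.1, 2.6, 3.0, 2.8), sol_names),
    # whole-wall diffusive permeability-surface products (mL/min); small
    # hydrophilic solutes are near flow-limited across the whole-body capillary
    # bed, so transcapillary disequilibria stay at the few-percent level and
    # the limiting barrier for urea is the cell membrane (two-pool kinetics)
    PS_cap = stats::setNames(c(6000, 6000, 7000, 6000, 8000, 3000, 0),
                             sol_names),
    # dialyzer clearance/dialysance (mL/min): urea value reused for the other
    # small solutes except creatinine (x0.9) and bicarbonate (x0.5); the lumped
    # anion carrier gets a low dialysance (see methods vignette)
    CL = stats::setNames(c(200, 200, 200, 100, 200, 180, 25), sol_names),
    # dialysate composition (mmol/L)
    c_di = stats::setNames(c(140, 2, 111, 32, 0, 0, 0), sol_names),
    # Gibbs-Donnan coefficient across the dialyzer membrane
    alphaD = stats::setNames(c(0.95, 0.95, 1.05, 1.05, 1, 1, 1.05), sol_names),
    # pre-dialysis plasma concentrations (mmol/L plasma); other_anions is
    # derived from electroneutrality at initialisation
    c_pl0 = stats::setNames(c(138, 5, 102, 22, 20, 0.8, NA), sol_names),
    # intracellular reference concentrations (mmol/L cell water)
    c_ic0 = stats::setNames(c(12, 140, 4, 10, NA, NA, 100), sol_names),
    # cell-membrane exchange: plain gradient for urea/creatinine, pump-leak
    # deviation law for Na/K/other anions, none for Cl/HCO3
    cell_mode = stats::setNames(c("deviation", "deviation", "none", "none",
                                  "gradient", "gradient", "deviation"),
                                sol_names),
    PS_cell = stats::setNames(c(100, 800, 0, 0, 700, 500, 50), sol_names),
    # intracellular stiffness of the deviation law: the pump-leak flux is
    # PS * (dev_ecf - stiff * dev_icf); stiff < 1 means the intracellular pool
    # is strongly buffered (clinically, cells supply ~2/3 of the potassium
    # removed while the intracellular concentration barely moves)
    cell_stiff = stats::setNames(c(1, 0.5, 1, 1, 1, 1, 0.5), sol_names),
    # effective-osmole weight at the cell membrane (urea is near-ineffective,
    # creatinine partially effective)
    sigma_cell = stats::setNames(c(1, 1, 1, 1, 0.05, 0.5, 1), sol_names),
    carrier = "other_anions"
  )
  proteins <- list(
    names = c("albumin", "globulin"),
    radius = c(albumin = 35.5, globulin = 52),
    # diffusive PS per pore class (mL/min), rows protein, cols large/small
    PS_large = c(albumin = 2.0, globulin = 1.5),
    PS_small = c(albumin = 0.5, globulin = 0.05),
    TP0 = TP0,
    a_pl0 = a_pl0
  )
  structure(list(
    weight_kg = 70,
    overload_mL = overload_mL,
    V_ic_n = 22000,            # intracellular water excluding erythrocytes (mL)
    k_cellwater = 6.6,         # cell-membrane water conductance, mL/min/(mmol/L)
    fpl_slope = 0.01,          # plasma water fraction = 1 - slope * TP(g/dL)
    w_v = 0.8,                 # venous-to-capillary pressure transmission
    P_sv_n = 12,               # normal small-veins pressure (mmHg)
    include_donnan = include_donnan,
    donnan = list(z_alb = -17, z_glob = -6, mw_alb = 66.4, mw_glob = 170),
    circ = circ,
    baro = baro,
    pores = pore_system(LpS = LpS),
    interstitium = interstitium_params(),
    solutes = solutes,
    proteins = proteins
  ), class = "virtual_patient")
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat("<virtual_patient>\n")
  cat(sprintf("  weight %g kg, overload %g mL, LpS %g mL/min/mmHg\n",
              x$weight_kg, x$overload_mL, x$pores$LpS))
  cat(sprintf("  blood %g mL (Hct %.2f), interstitium %g mL, cells %g mL\n",
              x$circ$BV_n, x$circ$Hct0, x$interstitium$V_is_n, x$V_ic_n))
  cat(sprintf("  plasma protein %g g/dL (albumin fraction %.2f), %d solutes\n",
              x$proteins$TP0, x$proteins$a_pl0, length(x$solutes$names)))
  cat(sprintf("  registry: %d scalar parameters\n", length(flatten_patient(x))))
  invisible(x)
}

#' Flatten the patient registry to a named numeric vector
#'
#' Enumerates every scalar numeric parameter of a [virtual_patient()] under a
#' dotted name (e.g. `circ.C.small_veins`, `solutes.CL.urea`, `pores.LpS`).
#' This is the parameter space walked by [sensitivity_screen()].
#'
#' @param patient a [virtual_patient()].
#' @return Named numeric vector.
#' @export
flatten_patient <- function(patient) {
  skip <- c("names", "cell_mode", "carrier", "include_donnan",
            "P_is_ex")  # derived from the other interstitium entries
  out <- list()
  walk <- function(x, prefix) {
    for (nm in names(x)) {
      if (nm %in% skip) next
      v <- x[[nm]]
      key <- if (prefix == "") nm else paste0(prefix, ".", nm)
      if (is.list(v)) {
        walk(v, key)
      } else if (is.numeric(v)) {
        if (length(v) == 1 && is.null(names(v))) {
          out[[key]] <<- unname(v)
        } else {
          nms <- names(v)
          if (is.null(nms)) nms <- as.character(seq_along(v))
          for (j in seq_along(v)) {
            if (is.na(v[[j]])) next   # derived at initialisation
            out[[paste0(key, ".", nms[j])]] <<- unname(v[[j]])
          }
        }
      }
    }
  }
  walk(unclass(patient), "")
  unlist(out)
}

#' Set one registry parameter by its flattened name
#'
#' @param patient a [virtual_patient()].
#' @param name dotted parameter name as produced by [flatten_patient()].
#' @param value new numeric value.
#' @return The modified `virtual_patient`. Derived quantities (interstitial
#'   cutoff pressure etc.) are rebuilt.
#' @export
set_patient_param <- function(patient, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  x <- unclass(patient)
  # walk down to the owning element
  ref <- list()
  node <- x
  for (k in seq_along(parts)) {
    p <- parts[k]
    if (is.list(node) && !is.null(node[[p]])) {
      ref[[k]] <- p
      node <- node[[p]]
    } else if (is.numeric(node) && p %in% names(node)) {
      ref[[k]] <- p
      node <- node[[p]]
    } else {
      stop("unknown parameter: ", name)
    }
  }
  x <- modify_leaf(x, unlist(ref), value)
  # rebuild derived pieces kept inside sub-objects
  if (parts[1] == "interstitium") {
    ip <- x$interstitium
    ip$P_is_ex <- ip$P_is_n + (ip$V_is_ex - ip$V_is_n) / ip$C_is
    x$interstitium <- ip
  }
  structure(x, class = "virtual_patient")
}

modify_leaf <- function(x, path, value) {
  p <- path[1]
  if (length(path) == 1) {
    if (is.list(x)) x[[p]] <- value else x[p] <- value
    return(x)
  }
  x[[p]] <- modify_leaf(x[[p]], path[-1], value)
  x
}
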