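# Configuration: flat key -> value registry I/O with provenance, validation
# and run manifests.

#' Validate a virtual patient registry
#'
#' Checks the structural invariants of the registry (positive compliances,
#' resistances implied by positive pressure drops, pore fractions summing to
#' one, reflection-coefficient inputs, nonnegative amounts). All violations
#' are reported together.
#'
#' @param patient a [virtual_patient()].
#' @return Invisibly `TRUE`; otherwise an error listing every violation.
#' @export
validate_patient <- function(patient) {
  bad <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  chk(all(patient$circ$C > 0), "circ.C: compliances must be > 0")
  chk(all(patient$circ$frac > 0), "circ.frac: volume fractions must be > 0")
  chk(abs(sum(patient$circ$frac) - 1) < 1e-6, "circ.frac: must sum to 1")
  chk(all(diff(unname(patient$circ$P_n[c(1, 2, 3, 4, 5)])) < 0),
      "circ.P_n: systemic pressures must fall along the flow path")
  chk(patient$pores$LpS > 0, "pores.LpS: must be > 0")
  chk(abs(sum(patient$pores$alpha) - 1) < 1e-12, "pores.alpha: must sum to 1")
  chk(all(patient$pores$radii > 0), "pores.radii: must be > 0")
  chk(patient$interstitium$C_is > 0, "interstitium.C_is: must be > 0")
  chk(patient$interstitium$V_is_ex < patient$interstitium$V_is_n,
      "interstitium.V_is_ex: must be below the normal volume")
  chk(patient$interstitium$Q_L_n >= 0, "interstitium.Q_L_n: must be >= 0")
  chk(sum(patient$solutes$cell_mode == "deviation" |
            patient$solutes$cell_mode == "gradient" |
            patient$solutes$cell_mode == "none") == length(patient$solutes$names),
      "solutes.cell_mode: unknown mode")
  chk(sum(patient$solutes$names == patient$solutes$carrier) == 1,
      "solutes.carrier: exactly one electroneutrality carrier required")
  chk(all(patient$solutes$CL >= 0), "solutes.CL: clearances must be >= 0")
  chk(all(stats::na.omit(patient$solutes$c_pl0) >= 0),
      "solutes.c_pl0: concentrations must be >= 0")
  chk(patient$proteins$TP0 >= 0, "proteins.TP0: must be >= 0")
  chk(patient$proteins$a_pl0 > 0 && patient$proteins$a_pl0 < 1,
      "proteins.a_pl0: must be in (0,1)")
  chk(patient$V_ic_n > 0, "V_ic_n: must be > 0")
  if (length(bad))
    stop("invalid patient configuration:\n  ", paste(bad, collapse = "\n  "))
  invisible(TRUE)
}

protocol_keys <- c("duration_min", "uf_total_mL", "priming", "circuit_mL",
                   "Qb", "lps_start", "lps_end", "saline_Na", "saline_Cl",
                   "dialyzer")

#' Load patient and protocol configuration
#'
#' Builds the default registry and applies the overrides found in a YAML file
#' with two optional blocks: `patient:` (flattened registry keys as produced
#' by [flatten_patient()], e.g. `pores.LpS: 8`) and `protocol:` (the
#' [session_protocol()] arguments). Unknown keys are rejected, and the merged
#' patient is validated.
#'
#' @param path YAML file; `NULL` gives the pure defaults.
#' @return List with `patient`, `protocol` and `overrides` (the applied keys).
#' @export
#' @examples
#' cfg <- load_config()          # full default registry
#' cfg$patient$pores$LpS
load_config <- function(path = NULL) {
  patient <- virtual_patient()
  protocol_args <- list()
  overrides <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    extra <- setdiff(names(raw), c("patient", "protocol"))
    if (length(extra))
      stop("unknown top-level config block(s): ", paste(extra, collapse = ", "))
    flat <- flatten_patient(patient)
    for (key in names(raw$patient)) {
      if (!key %in% names(flat))
        stop("unknown patient parameter in config: ", key)
      val <- raw$patient[[key]]
      if (!is.numeric(val) || length(val) != 1)
        stop("patient parameter ", key, " must be a single number")
      patient <- set_patient_param(patient, key, val)
      overrides[[paste0("patient.", key)]] <- val
    }
    for (key in names(raw$protocol)) {
      if (!key %in% protocol_keys)
        stop("unknown protocol field in config: ", key)
      protocol_args[[key]] <- raw$protocol[[key]]
      overrides[[paste0("protocol.", key)]] <- raw$protocol[[key]]
    }
  }
  validate_patient(patient)
  protocol <- do.call(session_protocol, protocol_args)
  list(patient = patient, protocol = protocol, overrides = overrides)
}

#' Write a deterministic run manifest
#'
#' Records everything needed to reproduce a run bit-identically: the full
#' flattened parameter registry, the protocol, the seed (measurement emulation
#' is the only stochastic stage; the forward model is deterministic), solver
#' statistics and content hashes of the written outputs.
#'
#' @param path output JSON file.
#' @param patient a [virtual_patient()].
#' @param protocol a [session_protocol()].
#' @param scenario scenario identifier string.
#' @param seed seed used for any measurement emulation (or `NA`).
#' @param outputs character vector of output files to hash (md5).
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, patient, protocol, scenario = "basal",
                               seed = NA, outputs = character(0)) {
  mf <- list(
    scenario = scenario,
    package_version = as.character(utils::packageVersion("hdrefill")),
    patient = as.list(flatten_patient(patient)),
    protocol = unclass(protocol),
    seed = seed,
    output_md5 = if (length(outputs)) as.list(tools::md5sum(outputs)) else list()
  )
  jsonlite::write_json(mf, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(mf)
}

#' Rebuild patient and protocol from a run manifest
#'
#' Inverse of [write_run_manifest()]: reproduces the exact parameter registry
#' and protocol recorded in a manifest.
#'
#' @param path manifest JSON file.
#' @return List with `patient` and `protocol`.
#' @export
read_run_manifest <- function(path) {
  mf <- jsonlite::read_json(path, simplifyVector = TRUE)
  patient <- virtual_patient()
  flat <- flatten_patient(patient)
  for (key in names(mf$patient)) {
    if (!key %in% names(flat)) stop("manifest parameter unknown: ", key)
    if (mf$patient[[key]] != flat[[key]])
      patient <- set_patient_param(patient, key, mf$patient[[key]])
  }
  pr <- mf$protocol[!vapply(mf$protocol, is.null, logical(1))]
  protocol <- do.call(session_protocol, pr[names(pr) %in% protocol_keys])
  list(patient = patient, protocol = protocol)
}

#' Export plot-ready data for the standard figure panels
#'
#' Writes one tidy CSV per panel from a [scenario_battery()] result: Kr and
#' refilling rate against time for the constant-LpS sessions (discarded and
#' infused priming), the session-duration and UF-rate comparisons, the
#' Starling-force decomposition of the basal session, the LpS-ramp comparison
#' (including the ramp profiles), and relative blood volume for the UF
#' variants. Units are given in a comment header line.
#'
#' @param battery named trajectory list from [scenario_battery()].
#' @param dir output directory (created if missing).
#' @return Character vector of the files written.
#' @export
export_figure_data <- function(battery, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  put <- function(fname, df, units) {
    p <- file.path(dir, fname)
    con <- file(p, "w")
    writeLines(paste0("# units: ", units), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    written <<- c(written, p)
  }
  kr_cols <- function(names) {
    base <- battery[[names[1]]]
    kt <- kr_curve(base)$time
    df <- data.frame(time = kt)
    for (nm in names) {
      kc <- kr_curve(battery[[nm]])
      df[[paste0("Kr_", nm)]] <- kc$Kr
      df[[paste0("refill_", nm)]] <- kc$R
    }
    df
  }
  if (all(c("lps4", "lps6", "lps8") %in% names(battery)))
    put("fig_kr_constant_lps.csv", kr_cols(c("lps4", "lps6", "lps8")),
        "time min; Kr mL/min/mmHg; refill mL/min")
  if (all(c("dur180", "lps6", "dur300") %in% names(battery)))
    put("fig_kr_duration.csv", kr_cols(c("dur180", "lps6", "dur300")),
        "time min; Kr mL/min/mmHg; refill mL/min")
  if (all(c("infused_lps4", "infused_lps6", "infused_lps8") %in% names(battery)))
    put("fig_kr_infused.csv",
        kr_cols(c("infused_lps4", "infused_lps6", "infused_lps8")),
        "time min; Kr mL/min/mmHg; refill mL/min")
  if ("lps6" %in% names(battery))
    put("fig_starling_forces.csv",
        as.data.frame(starling_decomposition(battery$lps6)),
        "time min; all forces mmHg, change vs t=0, positive favours absorption")
  if (all(c("ramp_6_4", "lps6", "ramp_6_8") %in% names(battery))) {
    df <- kr_cols(c("ramp_6_4", "lps6", "ramp_6_8"))
    for (nm in c("ramp_6_4", "lps6", "ramp_6_8")) {
      d <- battery[[nm]]$derived
      df[[paste0("BV_", nm)]] <- d$BV[d$time %in% df$time]
      df[[paste0("LpS_", nm)]] <- d$LpS[d$time %in% df$time]
    }
    put("fig_kr_lps_ramps.csv", df,
        "time min; Kr mL/min/mmHg; refill mL/min; BV mL; LpS mL/min/mmHg")
  }
  if (all(c("uf10", "lps6", "uf15") %in% names(battery))) {
    d0 <- battery$uf10$derived
    df <- data.frame(time = d0$time,
                     RBV_uf10 = battery$uf10$derived$RBV,
                     RBV_uf125 = battery$lps6$derived$RBV,
                     RBV_uf15 = battery$uf15$derived$RBV)
    put("fig_rbv_uf_variants.csv", df, "time min; RBV % of pre-dialysis")
  }
  written
}
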