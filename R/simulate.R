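# Simulator core: steady-state initialisation, ODE right-hand side, session
# execution. Internal units throughout: mL, min, mmHg, mmol, g.

# state vector layout
.iV   <- 1:9     # compartment blood volumes
.iVis <- 10      # interstitial volume
.iVic <- 11      # intracellular volume
.iMpl <- 12:13   # plasma protein masses (albumin, globulin)
.iMis <- 14:15   # interstitial protein masses
.iNpl <- 16:22   # plasma solute amounts (7 solutes)
.iNis <- 23:29   # interstitial solute amounts
.iNic <- 30:36   # intracellular solute amounts
.iB   <- 37:40   # baroreflex controller states (hr, ctr, res, vu)
.iUF  <- 41      # cumulative ultrafiltrate ledger
.iDL  <- 42:48   # cumulative dialysate-side solute removal ledger
.nstate <- 48

# Damped Newton with forward-difference Jacobian and step halving; used by the
# steady-state initialiser. Reports the residual norm on failure.
damped_newton <- function(fun, x0, tol = 1e-11, maxit = 100, lower = NULL) {
  x <- x0
  r <- fun(x)
  for (it in seq_len(maxit)) {
    nrm <- max(abs(r))
    if (nrm < tol) return(x)
    J <- matrix(0, length(r), length(x))
    for (j in seq_along(x)) {
      h <- 1e-7 * max(abs(x[j]), 1e-3)
      xj <- x; xj[j] <- xj[j] + h
      J[, j] <- (fun(xj) - r) / h
    }
    step <- tryCatch(solve(J, -r), error = function(e)
      stop("steady-state initialiser: singular Jacobian (residual ",
           signif(nrm, 3), ")"))
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      if (!is.null(lower)) xn <- pmax(xn, lower)
      rn <- tryCatch(fun(xn), error = function(e) rep(NA_real_, length(r)))
      if (all(is.finite(rn)) && max(abs(rn)) < nrm) break
      lambda <- lambda / 2
      if (lambda < 1e-8)
        stop("steady-state initialiser: line search failed (residual ",
             signif(nrm, 3), " mL/min-equivalent)")
    }
    x <- xn; r <- rn
  }
  stop("steady-state initialiser did not converge; residual ",
       signif(max(abs(r)), 3))
}

# per-fraction oncotic pressures (albumin, globulin) in mmHg
oncotic_pair <- function(TP, a, patient) {
  p <- c(pi_albumin(TP, a), pi_glob = pi_globulin(TP, a))
  if (isTRUE(patient$include_donnan)) {
    d <- patient$donnan
    p <- p + c(pi_donnan(TP, a, d$z_alb, 0, d$mw_alb, d$mw_glob,
                         patient$pores$RT),
               pi_donnan(TP, a, 0, d$z_glob, d$mw_alb, d$mw_glob,
                         patient$pores$RT))
  }
  unname(p)
}

#' Distribute the pre-dialysis fluid overload
#'
#' The overload volume is divided between the vascular space and the
#' interstitium proportionally to their normal volumes (normal plasma volume
#' over normal plasma + interstitial volume); the intracellular space is
#' unchanged.
#'
#' @param patient a [virtual_patient()].
#' @param overload_mL overload to distribute; defaults to the registry value.
#' @return List with `dV_plasma`, `dV_interstitium` (mL) and the resulting
#'   pre-dialysis `V_p0`, `V_is0`, `BV0` (mL).
#' @export
#' @examples
#' distribute_overload(virtual_patient())  # +500 mL plasma, +2500 mL tissue
distribute_overload <- function(patient, overload_mL = patient$overload_mL) {
  V_p_n <- patient$circ$BV_n * (1 - patient$circ$Hct0)
  V_is_n <- patient$interstitium$V_is_n
  dvp <- overload_mL * V_p_n / (V_p_n + V_is_n)
  list(dV_plasma = dvp,
       dV_interstitium = overload_mL - dvp,
       V_p0 = V_p_n + dvp,
       V_is0 = V_is_n + overload_mL - dvp,
       BV0 = patient$circ$BV_n + dvp)
}

# reflection-coefficient matrices from pore theory (rows species, cols pores)
sigma_tables <- function(patient) {
  radii <- patient$pores$radii
  sp <- cbind(large = reflection_sigma(patient$proteins$radius, radii[[1]]),
              small = reflection_sigma(patient$proteins$radius, radii[[2]]),
              ultrasmall = reflection_sigma(patient$proteins$radius, radii[[3]],
                                            water_only = TRUE))
  ss <- cbind(large = reflection_sigma(patient$solutes$radius, radii[[1]]),
              small = reflection_sigma(patient$solutes$radius, radii[[2]]),
              ultrasmall = reflection_sigma(patient$solutes$radius, radii[[3]],
                                            water_only = TRUE))
  list(sigma_p = sp, sigma_s = ss)
}

#' Pre-dialysis steady state of the fluid-overloaded patient
#'
#' Distributes the overload, solves the closed-loop circulation steady state,
#' and adjusts the initial mean capillary pressure `P_c0` together with the
#' interstitial protein and solute composition so that at t = 0 the total
#' transcapillary filtration exactly balances lymph absorption (zero net
#' vascular refilling) and every protein/solute compartment balance is
#' stationary. Baroreflex set points are taken at this state, so the whole
#' system is an equilibrium of the ODE.
#'
#' @param patient a [virtual_patient()].
#' @return List with the state (`V`, `V_is`, `V_ic`, `M_pl`, `M_is`, `N_pl`,
#'   `N_is`, `N_ic`, `baro`, `V_circuit`), the solved `P_c0`, reference venous
#'   pressure `P_sv0`, baroreflex `setpoints`, intracellular impermeant
#'   osmolyte amount `X_ic`, deviation-law reference concentrations, and
#'   solver diagnostics (`residual_mlmin`).
#' @export
solve_initial_steady_state <- function(patient) {
  ov <- distribute_overload(patient)
  ip <- patient$interstitium
  V_is0 <- ov$V_is0
  P_is0 <- interstitial_pressure(V_is0, ip)
  Q_L0 <- lymph_flow(P_is0, ip)

  css <- circulation_steady_state(patient, ov$BV0, J = Q_L0)
  V_rbc <- patient$circ$Hct0 * patient$circ$BV_n
  V_p0 <- ov$BV0 - V_rbc
  stopifnot(abs(V_p0 - ov$V_p0) < 1e-9)

  # plasma composition
  TP0 <- patient$proteins$TP0
  a0 <- patient$proteins$a_pl0
  M_pl <- TP0 / 100 * V_p0 * c(a0, 1 - a0)          # g
  F_pl <- 1 - patient$fpl_slope * TP0
  V_pw <- F_pl * V_p0
  sol <- patient$solutes
  c_pl <- sol$c_pl0                                  # mmol/L plasma
  c_pl_w <- c_pl / F_pl                              # mmol/L plasma water
  z <- sol$valence
  ic <- match(sol$carrier, sol$names)
  c_pl_w[ic] <- -sum(z[-ic] * c_pl_w[-ic], na.rm = TRUE) / z[ic]
  N_pl <- c_pl_w * V_pw / 1000                       # mmol

  st <- sigma_tables(patient)
  alpha <- patient$pores$alpha
  Kf <- patient$pores$LpS
  RT <- patient$pores$RT
  V_av <- V_is0 - ip$V_is_ex
  c_pl_prot <- M_pl / V_p0                           # g/mL
  pi_pl <- oncotic_pair(TP0, a0, patient)
  PSp <- rbind(large = patient$proteins$PS_large,
               small = patient$proteins$PS_small)    # pores x proteins

  # Interstitial composition consistent with zero net drift, given P_c0.
  # Solved by relaxing the composition sub-system (interstitial protein masses
  # and non-carrier solute amounts at fixed volumes and plasma composition) in
  # pseudo-time: the physical dynamics are stable wherever a steady state
  # exists, unlike a naive fixed-point iteration.
  nonc <- setdiff(seq_along(c_pl_w), ic)
  comp_fluxes <- function(mz, P_c0) {
    c_av <- pmax(mz[1:2], 1e-9) / V_av
    c_is_w <- c_pl_w
    c_is_w[nonc] <- pmax(mz[-(1:2)], 1e-12) / V_is0 * 1000
    c_is_w[ic] <- max(-sum(z[nonc] * c_is_w[nonc]) / z[ic], 1e-9)
    TP_is <- sum(c_av) * 100
    a_is <- c_av[1] / sum(c_av)
    pi_is <- oncotic_pair(TP_is, a_is, patient)
    osm <- RT * as.numeric(crossprod(st$sigma_s, sol$phi * (c_pl_w - c_is_w)))
    Jv <- alpha * Kf * ((P_c0 - P_is0) -
                          as.numeric(crossprod(st$sigma_p, pi_pl - pi_is)) - osm)
    dM <- vapply(1:2, function(p) {
      sum((1 - st$sigma_p[p, 1:2]) * Jv[1:2]) * (c_pl_prot[p] + c_av[p]) / 2 +
        (PSp["large", p] + PSp["small", p]) * (c_pl_prot[p] - c_av[p]) -
        Q_L0 * c_av[p]
    }, numeric(1))
    dN <- vapply(nonc, function(s) {
      (sum((1 - st$sigma_s[s, 1:2]) * Jv[1:2]) * (c_pl_w[s] + c_is_w[s]) / 2 +
         sol$PS_cap[s] * (c_pl_w[s] - c_is_w[s]) - Q_L0 * c_is_w[s]) / 1000
    }, numeric(1))
    list(d = c(dM, dN), Jv = Jv, c_av = c_av, c_is_w = c_is_w)
  }
  resid <- function(x) {
    cf <- comp_fluxes(x[-1], x[1])
    c(sum(cf$Jv) - Q_L0, cf$d)
  }
  x0 <- c(18, 0.4 * c_pl_prot * V_av, c_pl_w[nonc] * V_is0 / 1000)
  x <- damped_newton(resid, x0, tol = 1e-11, maxit = 200,
                     lower = c(1, rep(1e-6, length(x0) - 1)))
  P_c0 <- x[1]
  sol_in <- comp_fluxes(x[-1], P_c0)

  M_is <- sol_in$c_av * V_av
  N_is <- sol_in$c_is_w * V_is0 / 1000

  # intracellular space: urea/creatinine equilibrated, ions at their reference
  # concentrations, impermeant osmolytes X close the effective-osmolality gap
  V_ic <- patient$V_ic_n
  c_ic <- sol$c_ic0
  c_ic[["urea"]] <- sol_in$c_is_w[["urea"]]
  c_ic[["creatinine"]] <- sol_in$c_is_w[["creatinine"]]
  N_ic <- c_ic * V_ic / 1000
  osm_is_eff <- sum(sol$sigma_cell * sol$phi * sol_in$c_is_w)
  osm_ic_part <- sum(sol$sigma_cell * sol$phi * c_ic)
  X_ic <- (osm_is_eff - osm_ic_part) * V_ic / 1000   # mmol

  list(
    V = css$V, V_is = V_is0, V_ic = V_ic,
    M_pl = stats::setNames(M_pl, patient$proteins$names),
    M_is = stats::setNames(M_is, patient$proteins$names),
    N_pl = stats::setNames(N_pl, sol$names),
    N_is = stats::setNames(N_is, sol$names),
    N_ic = stats::setNames(N_ic, sol$names),
    baro = c(hr = 0, ctr = 0, res = 0, vu = 0),
    V_circuit = 0,
    P_c0 = P_c0, P_sv0 = css$P[["small_veins"]],
    setpoints = c(high = css$P[["large_arteries"]],
                  low = css$P[["right_heart"]]),
    X_ic = X_ic,
    c_is_ref = sol_in$c_is_w, c_ic_ref = c_ic,
    V_rbc = V_rbc, CO0 = css$CO,
    P_is0 = P_is0, Q_L0 = Q_L0,
    residual_mlmin = abs(sum(sol_in$Jv) - Q_L0)
  )
}

# Build the constant context passed to the ODE right-hand side
build_context <- function(patient, protocol, init) {
  st <- sigma_tables(patient)
  hd <- protocol$priming != "none"
  uf_rate <- if (hd) ultrafiltration_profile(0, protocol) else 0
  list(
    cc = circulation_constants(patient),
    baro = patient$baro,
    setpt = init$setpoints,
    sigma_p = st$sigma_p, sigma_s = st$sigma_s,
    PS_prot = rbind(large = patient$proteins$PS_large,
                    small = patient$proteins$PS_small),
    phi = unname(patient$solutes$phi),
    zval = unname(patient$solutes$valence),
    PS_cap = unname(patient$solutes$PS_cap),
    CL = unname(patient$solutes$CL),
    c_di = unname(patient$solutes$c_di),
    alphaD = unname(patient$solutes$alphaD),
    carrier = match(patient$solutes$carrier, patient$solutes$names),
    cell_mode = unname(patient$solutes$cell_mode),
    PS_cell = unname(patient$solutes$PS_cell),
    cell_stiff = unname(patient$solutes$cell_stiff),
    sigma_cell = unname(patient$solutes$sigma_cell),
    c_is_ref = unname(init$c_is_ref), c_ic_ref = unname(init$c_ic_ref),
    X_ic = init$X_ic,
    alpha = unname(patient$pores$alpha), RT = patient$pores$RT,
    ip = patient$interstitium,
    k_cw = patient$k_cellwater, fpl_slope = patient$fpl_slope,
    w_v = patient$w_v,
    P_c0 = init$P_c0, P_sv0 = init$P_sv0,
    V_rbc = init$V_rbc,
    V_circ = if (hd) protocol$circuit_mL else 0,
    hd = hd, dialyzer = hd && isTRUE(protocol$dialyzer),
    Qb = protocol$Qb, uf_rate = uf_rate,
    duration = protocol$duration_min,
    lps_fun = local({
      pt <- patient; pr <- protocol
      function(t) lps_at(t, pr, pt)
    }),
    patient = patient
  )
}

# Full model fluxes; returns the state derivative and (optionally) the derived
# diagnostic series used by the analysis layer.
model_fluxes <- function(t, y, ctx, want_diag = FALSE) {
  y <- unname(y)
  V <- y[.iV]; V_is <- y[.iVis]; V_ic <- y[.iVic]
  M_pl <- y[.iMpl]; M_is <- y[.iMis]
  N_pl <- y[.iNpl]; N_is <- y[.iNis]; N_ic <- y[.iNic]
  B <- y[.iB]

  cc <- ctx$cc
  Vu <- unname(cc$Vu)
  Vu[4] <- Vu[4] + B[4]
  P <- (V - Vu) / unname(cc$C)
  R <- unname(cc$R)
  R[2] <- R[2] * (1 + B[3])            # arteriolar resistance control
  s <- (1 + B[1]) * (1 + B[2])         # heart rate x contractility
  q <- c((P[1] - P[2]) / R[1], (P[2] - P[3]) / R[2], (P[3] - P[4]) / R[3],
         (P[4] - P[5]) / R[4], (P[5] - P[6]) / R[5],
         cc$k_pump[[1]] * s * max(P[6], 0),
         (P[7] - P[8]) / R[6], (P[8] - P[9]) / R[7],
         cc$k_pump[[2]] * s * max(P[9], 0))

  ip <- ctx$ip
  P_is <- ip$P_is_n + (V_is - ip$V_is_n) / ip$C_is
  Q_L <- if (P_is >= ip$P_is_n) {
    ip$Q_L_n + ip$LS * (P_is - ip$P_is_n)
  } else {
    max(ip$Q_L_n * (P_is - ip$P_is_ex) / (ip$P_is_n - ip$P_is_ex), 0)
  }
  P_sv <- P[4]
  P_c <- ctx$P_c0 + ctx$w_v * (P_sv - ctx$P_sv0)

  V_p <- sum(V) + ctx$V_circ - ctx$V_rbc
  Mtot <- M_pl[1] + M_pl[2]
  TP <- Mtot / V_p * 100
  a_pl <- M_pl[1] / Mtot
  F_pl <- 1 - ctx$fpl_slope * TP
  V_pw <- F_pl * V_p
  c_pl_w <- N_pl / V_pw * 1000
  c_is_w <- N_is / V_is * 1000
  pi_pl <- oncotic_pair(TP, a_pl, ctx$patient)

  V_av <- V_is - ip$V_is_ex
  c_av <- M_is / V_av
  TP_is <- (M_is[1] + M_is[2]) / V_av * 100
  a_is <- M_is[1] / (M_is[1] + M_is[2])
  pi_is <- oncotic_pair(TP_is, a_is, ctx$patient)

  dc <- c_pl_w - c_is_w
  osm <- ctx$RT * as.numeric(crossprod(ctx$sigma_s, ctx$phi * dc))
  dpi <- pi_pl - pi_is
  Kf <- ctx$lps_fun(min(t, ctx$duration))
  Jv <- ctx$alpha * Kf *
    ((P_c - P_is) - as.numeric(crossprod(ctx$sigma_p, dpi)) - osm)
  Jv_tot <- sum(Jv)

  # protein fluxes through large and small pores (g/min, plasma -> tissue)
  c_pl_prot <- M_pl / V_p
  Jp <- numeric(2)
  for (p in 1:2) {
    Jp[p] <- sum((1 - ctx$sigma_p[p, 1:2]) * Jv[1:2]) * (c_pl_prot[p] + c_av[p]) / 2 +
      (ctx$PS_prot[1, p] + ctx$PS_prot[2, p]) * (c_pl_prot[p] - c_av[p])
  }

  # small-solute fluxes (mmol/min); carrier closes the charge balance
  conv <- as.numeric((1 - ctx$sigma_s[, 1:2]) %*% Jv[1:2])
  Js <- (conv * (c_pl_w + c_is_w) / 2 + ctx$PS_cap * dc) / 1000
  icx <- ctx$carrier
  Js[icx] <- -sum(ctx$zval[-icx] * Js[-icx]) / ctx$zval[icx]

  # dialyzer and ultrafiltration
  in_session <- ctx$hd && t <= ctx$duration
  UF <- if (in_session) ctx$uf_rate else 0
  Jd <- if (in_session && ctx$dialyzer) {
    j <- ctx$CL * (ctx$alphaD * c_pl_w - ctx$c_di) / 1000 +
      UF * ctx$alphaD * c_pl_w / 1000
    # the dialysate effluent is electroneutral: cancel any net charge flux by
    # redistributing it over the charged species, weighted by their ionic
    # conductance across the membrane (clearance x concentration)
    w <- ctx$CL * c_pl_w * (ctx$zval != 0)
    imb <- sum(ctx$zval * j)
    j - ctx$zval * w * imb / sum(ctx$zval^2 * w)
  } else rep(0, length(N_pl))

  # cell membrane: osmotic water shift and solute exchange
  c_ic_w <- N_ic / V_ic * 1000
  osm_is_eff <- sum(ctx$sigma_cell * ctx$phi * c_is_w)
  osm_ic_eff <- sum(ctx$sigma_cell * ctx$phi * c_ic_w) + ctx$X_ic / V_ic * 1000
  J_cw <- ctx$k_cw * (osm_ic_eff - osm_is_eff)
  Jc <- numeric(length(N_pl))
  for (sdx in seq_along(Jc)) {
    m <- ctx$cell_mode[sdx]
    if (m == "gradient") {
      Jc[sdx] <- ctx$PS_cell[sdx] * (c_is_w[sdx] - c_ic_w[sdx]) / 1000
    } else if (m == "deviation") {
      Jc[sdx] <- ctx$PS_cell[sdx] *
        ((c_is_w[sdx] - ctx$c_is_ref[sdx]) -
           ctx$cell_stiff[sdx] * (c_ic_w[sdx] - ctx$c_ic_ref[sdx])) / 1000
    }
  }

  lymph_s <- Q_L * c_is_w / 1000
  lymph_p <- Q_L * c_av

  # The arteriovenous access is flow-neutral apart from the ultrafiltrate:
  # the circuit returns all blood it draws minus UF, so only -UF acts on the
  # access node (venous side).
  dV <- c(q[9] - q[1],
          q[1] - q[2],
          q[2] - q[3] - Jv_tot,
          q[3] - q[4] - if (in_session) UF else 0,
          q[4] - q[5] + Q_L,
          q[5] - q[6],
          q[6] - q[7],
          q[7] - q[8],
          q[8] - q[9])

  err_hi <- ctx$setpt[["high"]] - P[1]
  err_lo <- ctx$setpt[["low"]] - P[6]
  ba <- ctx$baro
  tgt <- c(ba$amp[["hr"]] * tanh(ba$gain[["hr"]] * err_hi / ba$amp[["hr"]]),
           ba$amp[["ctr"]] * tanh(ba$gain[["ctr"]] * err_hi / ba$amp[["ctr"]]),
           ba$amp[["res"]] * tanh(ba$gain[["res"]] * err_hi / ba$amp[["res"]]),
           -ba$amp[["vu"]] * tanh(ba$gain[["vu"]] * err_lo / ba$amp[["vu"]]))
  dB <- (tgt - B) / ba$tau

  dy <- numeric(length(y))
  dy[.iV] <- dV
  dy[.iVis] <- Jv_tot - Q_L - J_cw
  dy[.iVic] <- J_cw
  dy[.iMpl] <- -Jp + lymph_p
  dy[.iMis] <- Jp - lymph_p
  dy[.iNpl] <- -Js - Jd + lymph_s
  dy[.iNis] <- Js - lymph_s - Jc
  dy[.iNic] <- Jc
  dy[.iB] <- dB
  dy[.iUF] <- UF
  dy[.iDL] <- Jd

  if (!want_diag) return(list(dy))
  list(dy, diag = c(
    P_c = P_c, P_is = P_is, P_sv = P_sv, MAP = P[1],
    pi_pl = sum(pi_pl), pi_is = sum(pi_is),
    pi_pl_alb = pi_pl[1], pi_pl_glob = pi_pl[2],
    pi_is_alb = pi_is[1], pi_is_glob = pi_is[2],
    osm_small = osm[2], osm_large = osm[1], osm_ultrasmall = osm[3],
    Jv_large = Jv[1], Jv_small = Jv[2], Jv_ultrasmall = Jv[3],
    Jv_total = Jv_tot, Q_L = Q_L, UF = UF,
    V_p = V_p, V_is = V_is, V_ic = V_ic,
    BV = sum(V) + ctx$V_circ, Hct = ctx$V_rbc / (sum(V) + ctx$V_circ),
    TP = TP, a_pl = a_pl, TP_is = TP_is,
    CO = q[9], LpS = Kf,
    refill_flux = -Jv_tot + Q_L
  ))
}

rhs_ode <- function(t, y, ctx) model_fluxes(t, y, ctx, want_diag = FALSE)

state_to_vector <- function(st) {
  y <- numeric(.nstate)
  y[.iV] <- st$V
  y[.iVis] <- st$V_is
  y[.iVic] <- st$V_ic
  y[.iMpl] <- st$M_pl
  y[.iMis] <- st$M_is
  y[.iNpl] <- st$N_pl
  y[.iNis] <- st$N_is
  y[.iNic] <- st$N_ic
  y[.iB] <- st$baro
  y[.iUF] <- 0
  y
}

#' Run one dialysis session (or equilibrium run)
#'
#' Integrates the full model over the session with a stiff adaptive solver
#' (relative tolerance 1e-8) on a fixed 0.5-min output grid, after applying
#' the priming procedure to the pre-dialysis steady state. The forward model
#' is fully deterministic.
#'
#' @param patient a [virtual_patient()].
#' @param protocol a [session_protocol()].
#' @param init optional cached result of [solve_initial_steady_state()]
#'   (recomputed if missing); re-initialisation is required whenever the
#'   patient registry changes.
#' @param sample_dt output grid spacing (min).
#' @return An object of class `hd_trajectory`: time grid, raw state matrix,
#'   and a data.frame of derived series (pressures, oncotic pressures,
#'   per-pore fluxes, lymph flow, plasma volume, relative blood volume, total
#'   protein, ...), all recomputable from the states.
#' @export
#' @examples
#' \donttest{
#' traj <- run_session(virtual_patient(), session_protocol())
#' head(traj$derived)
#' }
run_session <- function(patient, protocol, init = NULL, sample_dt = 0.5) {
  if (is.null(init)) init <- solve_initial_steady_state(patient)
  st0 <- apply_priming(init, protocol)
  ctx <- build_context(patient, protocol, init)
  ctx$V_circ <- st0$V_circuit
  y0 <- state_to_vector(st0)
  times <- seq(0, protocol$duration_min, by = sample_dt)
  atol <- pmax(abs(y0), 1) * 1e-9
  sol <- deSolve::lsoda(y0, times, rhs_ode, parms = ctx,
                        rtol = 1e-8, atol = atol, maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed at t = ", max(sol[, 1]),
         "; state: ", paste(signif(sol[nrow(sol), -1], 4), collapse = ", "))
  states <- sol[, -1, drop = FALSE]
  diag <- t(vapply(seq_along(times), function(i) {
    model_fluxes(times[i], states[i, ], ctx, want_diag = TRUE)$diag
  }, numeric(30)))
  derived <- data.frame(time = times, diag)
  derived$RBV <- 100 * derived$BV / derived$BV[1]
  structure(list(times = times, states = states, derived = derived,
                 patient = patient, protocol = protocol, init = init,
                 context = ctx),
            class = "hd_trajectory")
}

#' @export
print.hd_trajectory <- function(x, ...) {
  d <- x$derived
  n <- nrow(d)
  cat(sprintf("<hd_trajectory> %g min, %d samples, priming %s\n",
              max(x$times), n, x$protocol$priming))
  cat(sprintf("  blood volume %0.f -> %.0f mL (RBV %+.1f%%)\n",
              round(d$BV[1]), d$BV[n], d$RBV[n] - 100))
  cat(sprintf("  P_is %.2f -> %.2f mmHg, lymph %.2f -> %.2f mL/min\n",
              d$P_is[1], d$P_is[n], d$Q_L[1], d$Q_L[n]))
  cat(sprintf("  pi_pl %.1f -> %.1f mmHg\n", d$pi_pl[1], d$pi_pl[n]))
  invisible(x)
}

#' Named battery of the study scenarios
#'
#' Runs the full scenario set: constant LpS 4/6/8 with priming discarded,
#' LpS ramps 6->4 and 6->8, 3-h and 5-h sessions at the same 3 L total
#' ultrafiltration, UF-rate variants 10 and 15 mL/min, and the three
#' priming-infused counterparts of the constant-LpS sessions. Scenarios that
#' only change the protocol (ramps, durations, UF rates) share the basal
#' pre-dialysis steady state; the constant-LpS variants re-solve their own
#' steady state, since the initial capillary pressure that balances
#' filtration against lymph depends on LpS.
#'
#' @param patient a [virtual_patient()].
#' @param scenarios subset of scenario names to run (default: all 12).
#' @param init optional cached [solve_initial_steady_state()] result for the
#'   patient's own LpS.
#' @return Named list of [run_session()] trajectories.
#' @export
scenario_battery <- function(patient = virtual_patient(), scenarios = NULL,
                             init = NULL) {
  specs <- list(
    lps4 = list(lps = 4, proto = session_protocol()),
    lps6 = list(lps = 6, proto = session_protocol()),
    lps8 = list(lps = 8, proto = session_protocol()),
    ramp_6_4 = list(lps = 6, proto = session_protocol(lps_end = 4)),
    ramp_6_8 = list(lps = 6, proto = session_protocol(lps_end = 8)),
    dur180 = list(lps = 6, proto = session_protocol(duration_min = 180)),
    dur300 = list(lps = 6, proto = session_protocol(duration_min = 300)),
    uf10 = list(lps = 6, proto = session_protocol(uf_total_mL = 2400)),
    uf15 = list(lps = 6, proto = session_protocol(uf_total_mL = 3600)),
    infused_lps4 = list(lps = 4, proto = session_protocol(priming = "infused")),
    infused_lps6 = list(lps = 6, proto = session_protocol(priming = "infused")),
    infused_lps8 = list(lps = 8, proto = session_protocol(priming = "infused"))
  )
  if (!is.null(scenarios)) {
    bad <- setdiff(scenarios, names(specs))
    if (length(bad)) stop("unknown scenarios: ", paste(bad, collapse = ", "))
    specs <- specs[scenarios]
  }
  inits <- list()
  get_init <- function(lps) {
    key <- as.character(lps)
    if (is.null(inits[[key]])) {
      if (lps == patient$pores$LpS && !is.null(init)) {
        inits[[key]] <<- list(patient = patient, init = init)
      } else {
        pt <- set_patient_param(patient, "pores.LpS", lps)
        inits[[key]] <<- list(patient = pt,
                              init = solve_initial_steady_state(pt))
      }
    }
    inits[[key]]
  }
  lapply(specs, function(sc) {
    gi <- get_init(sc$lps)
    run_session(gi$patient, sc$proto, init = gi$init)
  })
}
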