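#' Two-fluid vent environment
#'
#' The external world of the protocell: an acidic fluid on one face and
#' an alkaline fluid on the other, both clamped (their H+, OH- and
#' other ion concentrations never change during a run, being sustained
#' by large-scale flow). Both fluids carry the same ocean-like ionic
#' background; Cl- defaults to the charge-balancing value of each
#' fluid.
#'
#' @param pH_acid,pH_alk pH of the acidic and alkaline fluids, in
#'   `[0, 14]`.
#' @param ocean_Na,ocean_K Na+ and K+ concentrations, mol/L.
#' @param ocean_Cl Cl- concentration, mol/L, or `NULL` to charge-balance
#'   each fluid (`Na + K + H - OH`).
#' @param H2 Dissolved hydrogen available to the pump, mol/L.
#' @param temperature K.
#' @param Kw Water ion product, (mol/L)^2.
#' @return List of class `vent_environment` with per-fluid ion
#'   concentration vectors `acid` and `alk` (mol/L, ions H, OH, Na, K,
#'   Cl).
#' @examples
#' vent_environment(7, 10)
#' @export
vent_environment <- function(pH_acid = 7, pH_alk = 10,
                             ocean_Na = 0.4, ocean_K = 0.01,
                             ocean_Cl = NULL, H2 = 1e-3,
                             temperature = 298, Kw = 1e-14) {
  check_finite(pH_acid, "pH_acid"); check_finite(pH_alk, "pH_alk")
  if (pH_acid < 0 || pH_acid > 14 || pH_alk < 0 || pH_alk > 14)
    stop("pH values must lie in [0, 14]", call. = FALSE)
  if (ocean_Na < 0 || ocean_K < 0 || H2 < 0)
    stop("ocean_Na, ocean_K and H2 must be non-negative", call. = FALSE)
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  fluid <- function(pH) {
    H <- ph_to_concentration(pH)
    OH <- Kw / H
    Cl <- if (is.null(ocean_Cl)) ocean_Na + ocean_K + H - OH else ocean_Cl
    if (Cl < 0) stop("charge-balancing Cl- is negative; supply ocean_Cl",
                     call. = FALSE)
    c(H = H, OH = OH, Na = ocean_Na, K = ocean_K, Cl = Cl)
  }
  structure(list(pH_acid = pH_acid, pH_alk = pH_alk,
                 acid = fluid(pH_acid), alk = fluid(pH_alk),
                 H2 = H2, temperature = temperature, Kw = Kw),
            class = "vent_environment")
}

#' Full simulation configuration for one protocell run
#'
#' Bundles environment, membrane permeabilities, geometry, membrane
#' proteins, initial interior and time-stepping controls, applying the
#' documented defaults for everything not supplied. Defaults follow
#' the reference conditions: a 1 um cell half embedded in each fluid,
#' pH 7 acid against pH 10 alkaline, ocean Na+ 0.4 M and K+ 0.01 M,
#' H+ permeability 1e-3 cm/s with OH- equal to H+ and Na+/K+/Cl- six
#' orders of magnitude lower, interior starting as neutral water with
#' the acid-side ocean ionic composition.
#'
#' @param pH_acid,pH_alk External pH values.
#' @param perm_H_cm_s Lipid H+ permeability, cm/s.
#' @param perm_OH_cm_s OH- permeability, cm/s; defaults to the H+ value
#'   (hydroxide is given the same simple-diffusion treatment as the
#'   proton and no separate measurement is adopted).
#' @param perm_Na_cm_s Na+ permeability, cm/s; defaults to 1e-6 times
#'   the H+ value (lipid membranes are ~6 orders of magnitude less
#'   permeable to Na+ than to H+).
#' @param perm_K_cm_s,perm_Cl_cm_s K+ and Cl- permeabilities; default
#'   to the Na+ value.
#' @param atpase,ech,spap,pump Surface fractions of the four proteins
#'   on the acid face (0 disables).
#' @param pump_ion `"H"` or `"Na"`.
#' @param efficiency_scale Turnover multiplier applied to all proteins.
#' @param protein_overrides Named list (by kind) of argument lists
#'   forwarded to [protein_spec()], e.g.
#'   `list(atpase = list(ions_per_cycle = 6))`.
#' @param ocean_Na,ocean_K,ocean_Cl,H2,temperature See
#'   [vent_environment()].
#' @param radius_um,acid_fraction See [membrane_geometry()].
#' @param init_pH Initial internal pH (default 7: neutral water).
#' @param dt Initial/maximum Euler step, s. The step is halved
#'   adaptively whenever any concentration would go negative or change
#'   by more than 1% in one step, and is additionally capped by the
#'   passive-exchange stability limit.
#' @param t_end Integration horizon, s.
#' @param steady_tol Steady-state slope tolerance on the reported
#'   -deltaG, kJ/mol/s.
#' @param steady_window Window over which the slope must stay below
#'   `steady_tol`, s.
#' @param record_dt Recording interval, s.
#' @param seed Integer seed (used only by fluctuation runs).
#' @return List of class `protocell_config`.
#' @examples
#' cfg <- protocell_config(atpase = 0.01, perm_H_cm_s = 1e-3)
#' @export
protocell_config <- function(pH_acid = 7, pH_alk = 10,
                             perm_H_cm_s = 1e-3,
                             perm_OH_cm_s = perm_H_cm_s,
                             perm_Na_cm_s = 1e-6 * perm_H_cm_s,
                             perm_K_cm_s = perm_Na_cm_s,
                             perm_Cl_cm_s = perm_Na_cm_s,
                             atpase = 0, ech = 0, spap = 0, pump = 0,
                             pump_ion = "H",
                             efficiency_scale = protein_constants()$efficiency_scale,
                             protein_overrides = list(),
                             ocean_Na = 0.4, ocean_K = 0.01, ocean_Cl = NULL,
                             H2 = 1e-3, temperature = 298,
                             radius_um = 1, acid_fraction = 0.5,
                             init_pH = 7,
                             dt = 1e-3, t_end = 600,
                             steady_tol = 1e-4, steady_window = 10,
                             record_dt = 0.5, seed = NULL) {
  env <- vent_environment(pH_acid, pH_alk, ocean_Na, ocean_K, ocean_Cl,
                          H2, temperature)
  geometry <- membrane_geometry(radius_um, acid_fraction)
  perms <- c(H = perm_H_cm_s, OH = perm_OH_cm_s, Na = perm_Na_cm_s,
             K = perm_K_cm_s, Cl = perm_Cl_cm_s)
  check_finite(perms, "permeability")
  if (any(perms < 0)) stop("permeabilities must be non-negative", call. = FALSE)
  if (!is.list(protein_overrides) ||
      (length(protein_overrides) &&
       !all(names(protein_overrides) %in% PROTEIN_KINDS)))
    stop("protein_overrides must be a named list keyed by protein kind",
         call. = FALSE)
  fracs <- c(atpase = atpase, ech = ech, spap = spap, pump = pump)
  proteins <- list()
  for (kind in PROTEIN_KINDS) {
    if (fracs[[kind]] > 0) {
      args <- c(list(kind = kind, surface_fraction = fracs[[kind]],
                     efficiency_scale = efficiency_scale),
                protein_overrides[[kind]] %||% list())
      if (kind == "pump" && is.null(args$pumped_ion)) args$pumped_ion <- pump_ion
      proteins[[kind]] <- do.call(protein_spec, args)
    }
  }
  na_users <- vapply(proteins, function(p)
    p$kind %in% c("atpase", "ech", "spap") ||
      (p$kind == "pump" && identical(p$pumped_ion, "Na")), logical(1))
  if (any(na_users) && (ocean_Na <= 0 || env$acid[["Na"]] <= 0))
    stop("a configured protein exchanges Na+ but the environment has no Na+",
         call. = FALSE)
  if (any(c(dt, t_end, steady_tol, steady_window, record_dt) <= 0))
    stop("dt, t_end, steady_tol, steady_window and record_dt must be positive",
         call. = FALSE)
  init_H <- ph_to_concentration(init_pH)
  init_OH <- env$Kw / init_H
  init <- c(H = init_H, OH = init_OH,
            Na = env$acid[["Na"]], K = env$acid[["K"]],
            Cl = env$acid[["Na"]] + env$acid[["K"]] + init_H - init_OH)
  structure(list(env = env, geometry = geometry, perms_cm_s = perms,
                 proteins = proteins, init = init,
                 sim = list(dt = dt, t_end = t_end, steady_tol = steady_tol,
                            steady_window = steady_window,
                            record_dt = record_dt, seed = seed),
                 constants = physical_constants(
                   water_ion_product = env$Kw,
                   standard_temperature = temperature)),
            class = "protocell_config")
}

# --- internal: SI view of a config ---------------------------------------

as_core_params <- function(config) {
  env <- config$env; geo <- config$geometry
  P <- cm_s_to_m_s(config$perms_cm_s)[ION_NAMES]
  z <- ION_VALENCE[ION_NAMES]
  c_acid <- molar_to_si(env$acid[ION_NAMES])
  c_alk <- molar_to_si(env$alk[ION_NAMES])
  c0 <- molar_to_si(config$init[ION_NAMES])
  prot <- lapply(config$proteins, function(p) {
    list(type = match(p$kind, PROTEIN_KINDS),
         max_flux = unit_count(p, geo) * p$max_turnover *
           p$efficiency_scale * p$ions_per_cycle / AVOGADRO,
         satK = kJ_to_J(protein_constants()$saturation_half_kJ),
         pump_ion = if (p$kind == "pump") match(p$pumped_ion, ION_NAMES) else 1L,
         f_h2 = if (p$kind == "pump") env$H2 / (env$H2 + p$K_H2_molar) else 1,
         K_pump = if (p$kind == "pump") kJ_to_J(p$K_pump_kJ) else 1)
  })
  list(z = unname(z), P = unname(P),
       carrier = unname(ION_CARRIER[ION_NAMES]),
       c_acid = unname(c_acid), c_alk = unname(c_alk), c0 = unname(c0),
       A_acid = geo$area_acid, A_alk = geo$area_alk, V = geo$volume_m3,
       proteins = unname(prot),
       T = env$temperature, F = config$constants$faraday,
       Rgas = config$constants$gas_constant,
       Kw = env$Kw * 1e6)   # (mol/L)^2 -> (mol/m^3)^2
}

# Per-ion, per-pathway fluxes (mol/s, inward positive) at a given
# internal state. Pure-R reference used by step_state(), ion_balance()
# and the tests; mirrors the compiled core exactly. H+ and OH- cross
# the lipid by electroneutral carriers: linear flux per face, excluded
# from the constant-field voltage (see ION_CARRIER).
compute_fluxes <- function(c_in_si, pars) {
  RT <- pars$Rgas * pars$T
  c_eff <- (pars$c_acid * pars$A_acid + pars$c_alk * pars$A_alk) /
    (pars$A_acid + pars$A_alk)
  dpsi <- {
    cat <- pars$z > 0 & !pars$carrier
    an <- pars$z < 0 & !pars$carrier
    num <- sum(pars$P[cat] * c_eff[cat]) + sum(pars$P[an] * c_in_si[an])
    den <- sum(pars$P[cat] * c_in_si[cat]) + sum(pars$P[an] * c_eff[an])
    RT / pars$F * log(num / den)
  }
  ghk1 <- function(i, c_out, A) {
    if (pars$carrier[i]) return(pars$P[i] * A * (c_out - c_in_si[i]))
    u <- pars$z[i] * pars$F * dpsi / RT
    if (abs(u) < 1e-8)
      pars$P[i] * A * ((c_out - c_in_si[i]) - u * (c_out + c_in_si[i]) / 2)
    else
      pars$P[i] * A * u * (c_out - c_in_si[i] * exp(u)) / (exp(u) - 1)
  }
  lipid_acid <- vapply(1:5, function(i) ghk1(i, pars$c_acid[i], pars$A_acid),
                       numeric(1))
  lipid_alk <- vapply(1:5, function(i) ghk1(i, pars$c_alk[i], pars$A_alk),
                      numeric(1))
  dG <- pars$z * pars$F * dpsi + RT * log(c_in_si / pars$c_acid)   # J/mol, inward
  dG_chem <- RT * log(c_in_si / pars$c_acid)
  prot_flux <- matrix(0, nrow = length(pars$proteins), ncol = 5)
  sat <- function(x, K) { a <- abs(x); a / (a + K) }
  for (k in seq_along(pars$proteins)) {
    p <- pars$proteins[[k]]
    if (p$type %in% c(1, 2)) {            # atpase / ech
      wH <- max(-dG[1], 0); wNa <- max(-dG[3], 0); s <- wH + wNa
      if (s > 0) {
        wH <- wH / s; wNa <- wNa / s
        dG_eff <- wH * (-dG[1]) + wNa * (-dG[3])
        tot <- p$max_flux * sat(dG_eff, p$satK)
        prot_flux[k, 1] <- wH * tot; prot_flux[k, 3] <- wNa * tot
      }
    } else if (p$type == 3) {             # spap
      dG_net <- dG_chem[1] - dG_chem[3]
      r <- p$max_flux * sat(dG_net, p$satK)
      dirH <- -sign(dG_net)
      prot_flux[k, 1] <- dirH * r; prot_flux[k, 3] <- -dirH * r
    } else {                              # pump
      i <- p$pump_ion
      dG_opp <- -dG[i]                    # dG of outward transfer
      prot_flux[k, i] <- -p$max_flux * p$f_h2 *
        exp(-max(dG_opp, 0) / p$K_pump)
    }
  }
  list(dpsi = dpsi, dG = dG, dG_chem = dG_chem,
       lipid_acid = lipid_acid, lipid_alk = lipid_alk,
       protein = prot_flux,
       total = lipid_acid + lipid_alk + colSums(prot_flux))
}

# Reported -dG combination: promiscuity-partition-weighted mean of the
# per-ion -dG (kJ/mol); all weight on one ion when only it is
# favourable, and the larger (least negative) component when neither is.
combine_reported <- function(minus_dG_H, minus_dG_Na) {
  wH <- max(minus_dG_H, 0); wNa <- max(minus_dG_Na, 0); s <- wH + wNa
  if (s <= 0) return(max(minus_dG_H, minus_dG_Na))
  (wH * minus_dG_H + wNa * minus_dG_Na) / s
}

#' Electrochemical free energy of the internal state
#'
#' Per-ion free energy of inward transfer across the acid face,
#' `dG = zF dpsi + RT ln(c_in / c_acid)` (reported as -dG, the driving
#' force available to membrane proteins), together with the single
#' reported -dG: the promiscuity-partition-weighted mean of the H+ and
#' Na+ components, using the same weights as the ATPase ion
#' preference.
#'
#' @param internal Named internal concentrations, mol/L (ions `H`,
#'   `OH`, `Na`, `K`, `Cl`; at least `H` and `Na`).
#' @param config A [protocell_config()]; supplies the acid-face
#'   concentrations, temperature and constants.
#' @param dpsi Membrane potential psi_in - psi_out, V. If `NULL`,
#'   computed from the GHK voltage equation with the face-pooled
#'   effective external concentrations.
#' @return List with `minus_dG_H`, `minus_dG_Na`, `minus_dG_reported`
#'   (kJ/mol), `dpsi` (V) and the partition `weights`.
#' @examples
#' cfg <- protocell_config()
#' st <- c(H = 1e-10, OH = 1e-4, Na = 0.4, K = 0.01, Cl = 0.41)
#' free_energy(st, cfg, dpsi = 0)$minus_dG_H   # 17.12 for 3 pH units
#' @export
free_energy <- function(internal, config, dpsi = NULL) {
  stopifnot(inherits(config, "protocell_config"))
  pars <- as_core_params(config)
  need <- intersect(ION_NAMES, names(internal))
  c_in <- molar_to_si(config$init)
  c_in[need] <- molar_to_si(internal[need])
  c_in <- unname(c_in[ION_NAMES])
  if (any(c_in[c(1, 3)] <= 0) || any(pars$c_acid[c(1, 3)] <= 0))
    stop("free_energy: H+ and Na+ concentrations must be strictly ",
         "positive inside and on the acid face", call. = FALSE)
  RT <- pars$Rgas * pars$T
  if (is.null(dpsi)) {
    c_eff <- (pars$c_acid * pars$A_acid + pars$c_alk * pars$A_alk) /
      (pars$A_acid + pars$A_alk)
    bare <- !pars$carrier   # carrier-borne H+/OH- do not set the potential
    dpsi <- ghk_voltage(pars$P[bare], pars$z[bare], c_in[bare],
                        c_eff[bare], pars$T, config$constants)
  }
  dG <- pars$z * pars$F * dpsi + RT * log(c_in / pars$c_acid)
  mH <- J_to_kJ(-dG[1]); mNa <- J_to_kJ(-dG[3])
  w <- promiscuity_weights(mH, mNa)
  list(minus_dG_H = mH, minus_dG_Na = mNa,
       minus_dG_reported = combine_reported(mH, mNa),
       dpsi = dpsi, weights = w)
}

#' Instantaneous ion balance of the protocell
#'
#' Evaluates every term of the per-ion flux balance at a given internal
#' state: the passive (GHK) lipid-phase flux on each face and each
#' configured protein's contribution (acid face only). Inward
#' positive, mol/s.
#'
#' @param internal Named internal concentrations, mol/L.
#' @param config A [protocell_config()].
#' @return List with `dpsi` (V), `minus_dG_kJ` (per-ion, kJ/mol), and
#'   data frame `fluxes`: one row per pathway (`lipid_acid`,
#'   `lipid_alk`, one per protein, `total`), one column per ion.
#' @examples
#' cfg <- protocell_config(atpase = 0.01, perm_H_cm_s = 1e-2)
#' ion_balance(c(H = 1e-10, OH = 1e-4, Na = 0.4, K = 0.01, Cl = 0.41), cfg)
#' @export
ion_balance <- function(internal, config) {
  stopifnot(inherits(config, "protocell_config"))
  pars <- as_core_params(config)
  c_in <- molar_to_si(config$init)
  need <- intersect(ION_NAMES, names(internal))
  c_in[need] <- molar_to_si(internal[need])
  fl <- compute_fluxes(unname(c_in[ION_NAMES]), pars)
  rows <- rbind(lipid_acid = fl$lipid_acid, lipid_alk = fl$lipid_alk)
  if (length(config$proteins))
    rows <- rbind(rows, structure(fl$protein,
                                  dimnames = list(names(config$proteins), NULL)))
  rows <- rbind(rows, total = fl$total)
  colnames(rows) <- ION_NAMES
  list(dpsi = fl$dpsi, minus_dG_kJ = J_to_kJ(-fl$dG),
       fluxes = as.data.frame(rows))
}

#' One explicit-Euler step of the protocell (reference implementation)
#'
#' Advances the internal state by one forward-Euler step of the ion
#' balance, then re-equilibrates H+/OH- to the water ion product and
#' recomputes the membrane potential. This is the pure-R reference for
#' the compiled integrator core and takes a fixed `dt` (no
#' adaptivity).
#'
#' @param internal Named internal concentrations, mol/L.
#' @param dt Step, s.
#' @param config A [protocell_config()].
#' @return List with the updated `internal` (mol/L), `dpsi` (V) and
#'   `t_increment`.
#' @export
step_state <- function(internal, dt, config) {
  stopifnot(inherits(config, "protocell_config"))
  pars <- as_core_params(config)
  c_in <- unname(molar_to_si(internal[ION_NAMES]))
  fl <- compute_fluxes(c_in, pars)
  dc <- fl$total * dt / pars$V
  c_new <- c_in + dc
  d <- c_new[1] - c_new[2]
  H <- (d + sqrt(d * d + 4 * pars$Kw)) / 2
  c_new[1] <- H; c_new[2] <- H - d
  if (any(c_new < 0))
    stop("step_state: a concentration went negative; reduce dt", call. = FALSE)
  fl2 <- compute_fluxes(c_new, pars)
  out <- si_to_molar(c_new); names(out) <- ION_NAMES
  list(internal = out, dpsi = fl2$dpsi, t_increment = dt)
}

#' Run a protocell simulation
#'
#' Integrates the ion balance with the adaptive explicit-Euler core:
#' fluxes are summed per ion (lipid phase on both faces plus every
#' configured protein on the acid face), internal amounts are advanced,
#' H+/OH- are re-equilibrated to the water ion product, and the
#' membrane potential is recomputed, every step. The step is halved
#' whenever a concentration would go negative or move by more than 1%
#' (for the equilibrated H+/OH- pool, 1% of the pool's proton-excess
#' coordinate), and grown back when changes are small. The run stops at
#' `t_end` or as soon as the reported -dG has drifted less than
#' `steady_tol` kJ/mol/s over `steady_window` seconds.
#'
#' @param config A [protocell_config()].
#' @param schedule Optional data frame of external-pH changes with
#'   columns `t`, `pH_acid`, `pH_alk` (piecewise-constant from each
#'   `t` on), used by fluctuation scenarios.
#' @param audit If `TRUE`, track the per-step conservation residual
#'   (bookkeeping audit) and per-pathway fluxes at each record point.
#' @return Object of class `protocell_run`: list with `series` (data
#'   frame: `t`, `minus_dG_H`, `minus_dG_Na`, `minus_dG_reported`
#'   kJ/mol, `dpsi` V, `pH_in`, and internal concentrations in mol/L),
#'   `summary` (steady/final values and stop reason), `config`, and
#'   audit fields when requested.
#' @examples
#' run <- run_protocell(protocell_config(atpase = 0.01, t_end = 5))
#' run$summary$minus_dG_reported
#' @export
run_protocell <- function(config, schedule = NULL, audit = FALSE) {
  stopifnot(inherits(config, "protocell_config"))
  pars <- as_core_params(config)
  sched <- matrix(numeric(0), ncol = 5)
  if (!is.null(schedule)) {
    stopifnot(all(c("t", "pH_acid", "pH_alk") %in% names(schedule)))
    Kw <- config$env$Kw
    sched <- cbind(schedule$t,
                   molar_to_si(ph_to_concentration(schedule$pH_acid)),
                   molar_to_si(Kw / ph_to_concentration(schedule$pH_acid)),
                   molar_to_si(ph_to_concentration(schedule$pH_alk)),
                   molar_to_si(Kw / ph_to_concentration(schedule$pH_alk)))
    sched <- sched[order(sched[, 1]), , drop = FALSE]
  }
  res <- sim_core(pars$z, pars$P, pars$carrier,
                  pars$c_acid, pars$c_alk, pars$c0,
                  pars$A_acid, pars$A_alk, pars$V, pars$proteins,
                  pars$T, pars$F, pars$Rgas, pars$Kw,
                  config$sim$dt, config$sim$t_end,
                  kJ_to_J(config$sim$steady_tol), config$sim$steady_window,
                  config$sim$record_dt, 0.01, 1e-9, sched, audit)
  series <- data.frame(t = res$time,
                       minus_dG_H = res$out[, 1],
                       minus_dG_Na = res$out[, 2],
                       minus_dG_reported = res$out[, 3],
                       dpsi = res$out[, 4],
                       pH_in = res$out[, 5])
  conc <- si_to_molar(res$conc)
  colnames(conc) <- ION_NAMES
  series <- cbind(series, as.data.frame(conc))
  n <- nrow(series)
  summary <- list(t_final = series$t[n],
                  minus_dG_H = series$minus_dG_H[n],
                  minus_dG_Na = series$minus_dG_Na[n],
                  minus_dG_reported = series$minus_dG_reported[n],
                  dpsi = series$dpsi[n], pH_in = series$pH_in[n],
                  internal = conc[n, ],
                  stop_reason = res$stop_reason,
                  n_steps = res$n_steps)
  out <- list(series = series, summary = summary, config = config)
  if (audit) {
    out$max_conservation_residual <- res$max_residual
    pw <- as.data.frame(res$pathway)
    names(pw) <- c("lipid_acid_H", "lipid_alk_H", "protein_H",
                   "lipid_acid_Na", "lipid_alk_Na", "protein_Na")
    out$pathway_fluxes <- cbind(t = series$t, pw)
  }
  class(out) <- "protocell_run"
  out
}

#' @export
print.protocell_run <- function(x, ...) {
  s <- x$summary
  cat("<protocell_run> ", s$stop_reason, " at t = ",
      format(s$t_final, digits = 4), " s (", s$n_steps, " steps)\n",
      "  -dG reported = ", format(s$minus_dG_reported, digits = 4),
      " kJ/mol (H: ", format(s$minus_dG_H, digits = 4),
      ", Na: ", format(s$minus_dG_Na, digits = 4), ")\n",
      "  dpsi = ", format(1e3 * s$dpsi, digits = 3), " mV, internal pH = ",
      format(s$pH_in, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Open-system reference free energy
#'
#' The -dG of an open system: a single membrane carrying the same
#' proteins but separating a continuous flux of acid and alkaline
#' fluids, so the proteins see the full gradient. Implemented by
#' clamping the interior to the alkaline-fluid composition and
#' evaluating [free_energy()] with the membrane potential of that
#' clamped configuration. Used as the denominator of relative-loss
#' comparisons.
#'
#' @param config A [protocell_config()].
#' @return As [free_energy()].
#' @examples
#' open_system_reference(protocell_config(atpase = 0.01))$minus_dG_reported
#' @export
open_system_reference <- function(config) {
  stopifnot(inherits(config, "protocell_config"))
  free_energy(config$env$alk, config)
}
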