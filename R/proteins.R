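PROTEIN_KINDS <- c("atpase", "ech", "spap", "pump")

#' Specification of one membrane protein population
#'
#' A protein population is described by its kind, the fraction of the
#' acid-face surface it occupies, the footprint of one unit, its
#' maximum (modern) turnover, the number of ions moved per catalytic
#' cycle, and the efficiency scale applied to turnover (0.1 by
#' default: primordial enzymes are assumed to run at 10% of modern
#' rates). Kind-specific defaults come from [protein_constants()];
#' any field can be overridden. All proteins operate on the acid face
#' only, where the proton gradient points inward.
#'
#' @param kind One of `"atpase"`, `"ech"`, `"spap"`, `"pump"`.
#' @param surface_fraction Fraction of the acid-face area occupied
#'   (0.01 for "1%").
#' @param max_turnover Cycles per second of one unit at modern rates.
#' @param unit_footprint_nm2 Membrane footprint of one unit, nm^2.
#' @param ions_per_cycle Ions translocated per cycle (3.3 for the
#'   ATPase: protons or sodium ions per ATP synthesized).
#' @param efficiency_scale Multiplier on turnover in (0, 1].
#' @param pumped_ion For `kind = "pump"` only: `"H"` or `"Na"`.
#' @param K_H2_molar Pump half-saturation for dissolved H2, mol/L.
#' @param K_pump_kJ Pump opposing-gradient scale, kJ/mol.
#' @return List of class `protein_spec`.
#' @examples
#' protein_spec("atpase", 0.01)
#' protein_spec("pump", 0.05, pumped_ion = "Na")
#' @export
protein_spec <- function(kind, surface_fraction,
                         max_turnover = NULL, unit_footprint_nm2 = NULL,
                         ions_per_cycle = NULL, efficiency_scale = NULL,
                         pumped_ion = NULL,
                         K_H2_molar = NULL, K_pump_kJ = NULL) {
  kind <- match.arg(tolower(kind), PROTEIN_KINDS)
  defaults <- protein_constants()
  d <- defaults[[kind]]
  max_turnover <- max_turnover %||% d$max_turnover
  unit_footprint_nm2 <- unit_footprint_nm2 %||% d$unit_footprint_nm2
  ions_per_cycle <- ions_per_cycle %||% d$ions_per_cycle
  efficiency_scale <- efficiency_scale %||% defaults$efficiency_scale
  check_finite(surface_fraction, "surface_fraction")
  if (surface_fraction < 0 || surface_fraction > 1)
    stop("surface_fraction must lie in [0, 1]", call. = FALSE)
  if (max_turnover <= 0 || unit_footprint_nm2 <= 0 || ions_per_cycle <= 0)
    stop("max_turnover, unit_footprint_nm2 and ions_per_cycle must be positive",
         call. = FALSE)
  if (efficiency_scale <= 0 || efficiency_scale > 1)
    stop("efficiency_scale must lie in (0, 1]", call. = FALSE)
  spec <- list(kind = kind, surface_fraction = surface_fraction,
               max_turnover = max_turnover,
               unit_footprint_nm2 = unit_footprint_nm2,
               unit_footprint = nm2_to_m2(unit_footprint_nm2),
               ions_per_cycle = ions_per_cycle,
               efficiency_scale = efficiency_scale)
  if (kind == "pump") {
    pumped_ion <- pumped_ion %||% "H"
    if (!pumped_ion %in% c("H", "Na"))
      stop("pumped_ion must be 'H' or 'Na', got '", pumped_ion, "'",
           call. = FALSE)
    spec$pumped_ion <- pumped_ion
    spec$K_H2_molar <- K_H2_molar %||% d$K_H2_molar
    spec$K_pump_kJ <- K_pump_kJ %||% d$K_pump_kJ
    if (spec$K_H2_molar <= 0 || spec$K_pump_kJ <= 0)
      stop("K_H2_molar and K_pump_kJ must be positive", call. = FALSE)
  }
  structure(spec, class = "protein_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of protein units on the acid face
#'
#' Continuum estimate: `surface_fraction * area_acid / unit_footprint`,
#' not rounded.
#'
#' @param spec A [protein_spec()].
#' @param geometry A [membrane_geometry()].
#' @return Real-valued unit count.
#' @examples
#' unit_count(protein_spec("atpase", 0.01), membrane_geometry())  # ~982
#' @export
unit_count <- function(spec, geometry) {
  stopifnot(inherits(spec, "protein_spec"),
            inherits(geometry, "membrane_geometry"))
  spec$surface_fraction * geometry$area_acid / spec$unit_footprint
}

#' Hyperbolic saturation of protein flux with driving force
#'
#' Michaelis-Menten-type dependence of flux on the magnitude of the
#' driving free energy: `|dG| / (|dG| + K)`. Zero at zero drive,
#' strictly increasing, asymptotically approaching (never reaching) 1;
#' with the default half-saturation of 2 kJ/mol the factor exceeds 0.9
#' slightly beyond a 20 kJ/mol drive, the gradient equivalent to a
#' membrane potential of roughly 200 mV.
#'
#' @param dG_drive_kJ Driving free energy, kJ/mol (sign ignored).
#' @param half_saturation_kJ Half-saturation constant, kJ/mol.
#' @return Dimensionless factor in [0, 1).
#' @examples
#' saturation_factor(20)    # 20/22 = 0.909
#' @export
saturation_factor <- function(dG_drive_kJ, half_saturation_kJ = 2) {
  check_finite(dG_drive_kJ, "dG_drive_kJ")
  if (any(half_saturation_kJ <= 0))
    stop("half_saturation_kJ must be positive", call. = FALSE)
  a <- abs(dG_drive_kJ)
  a / (a + half_saturation_kJ)
}

# Partition weights of a promiscuous protein between H+ and Na+:
# proportional to each ion's favourable inward driving force -dG,
# zero for ions with unfavourable gradients. Returns c(H =, Na =)
# summing to 1, or c(0, 0) when neither gradient is favourable.
promiscuity_weights <- function(minus_dG_H_kJ, minus_dG_Na_kJ) {
  w <- c(H = max(minus_dG_H_kJ, 0), Na = max(minus_dG_Na_kJ, 0))
  s <- sum(w)
  if (s <= 0) return(c(H = 0, Na = 0))
  w / s
}

#' Inward H+/Na+ flux through the ATP synthase
#'
#' The ATPase is fully promiscuous for H+ and Na+; preference between
#' the ions depends solely on their respective favourable gradient
#' sizes. Total ion flux is
#' `unit_count * max_turnover * efficiency_scale * ions_per_cycle *
#' saturation_factor(dG_effective)`, where the effective drive is the
#' partition-weighted mean of the per-ion inward driving forces. Flux
#' is inward only (the synthesis direction); ions with unfavourable
#' gradients receive zero flux.
#'
#' @param spec A [protein_spec()] of kind `"atpase"` (or `"ech"`, which
#'   shares the contract).
#' @param geometry A [membrane_geometry()].
#' @param dG_H_kJ,dG_Na_kJ Per-ion free energy of inward transfer
#'   across the acid face, kJ/mol (negative = favourable influx).
#' @param half_saturation_kJ Saturation constant, kJ/mol.
#' @return Named list: `H` and `Na` inward fluxes (mol/s), `total`
#'   (mol/s), and the partition `weights`.
#' @examples
#' atpase_flux(protein_spec("atpase", 0.01), membrane_geometry(),
#'             dG_H_kJ = -17, dG_Na_kJ = 0)
#' @export
atpase_flux <- function(spec, geometry, dG_H_kJ, dG_Na_kJ,
                        half_saturation_kJ = protein_constants()$saturation_half_kJ) {
  stopifnot(inherits(spec, "protein_spec"))
  if (!spec$kind %in% c("atpase", "ech"))
    stop("atpase_flux requires an 'atpase' or 'ech' spec", call. = FALSE)
  check_finite(dG_H_kJ, "dG_H_kJ"); check_finite(dG_Na_kJ, "dG_Na_kJ")
  w <- promiscuity_weights(-dG_H_kJ, -dG_Na_kJ)
  dG_eff <- w[["H"]] * (-dG_H_kJ) + w[["Na"]] * (-dG_Na_kJ)
  n_ions_per_s <- unit_count(spec, geometry) * spec$max_turnover *
    spec$efficiency_scale * spec$ions_per_cycle *
    saturation_factor(dG_eff, half_saturation_kJ)
  total <- n_ions_per_s / AVOGADRO
  list(H = w[["H"]] * total, Na = w[["Na"]] * total,
       total = total, weights = w)
}

AVOGADRO <- 6.02214076e23

#' Inward H+/Na+ flux through the energy-converting hydrogenase
#'
#' Identical contract to [atpase_flux()]; the Ech differs only in its
#' defaults (per-unit ion rate double the ATPase's, slightly smaller
#' footprint).
#'
#' @inheritParams atpase_flux
#' @return As [atpase_flux()].
#' @export
ech_flux <- function(spec, geometry, dG_H_kJ, dG_Na_kJ,
                     half_saturation_kJ = protein_constants()$saturation_half_kJ) {
  if (spec$kind != "ech")
    stop("ech_flux requires an 'ech' spec", call. = FALSE)
  atpase_flux(spec, geometry, dG_H_kJ, dG_Na_kJ, half_saturation_kJ)
}

#' Coupled H+/Na+ exchange through the sodium-proton antiporter
#'
#' Strict electroneutral 1:1 antiport: the H+ and Na+ flows are equal
#' and opposite at every instant, so no net charge crosses. Direction
#' follows the larger of the two chemical gradients: the net exchange
#' driving force is `dG_net = dG_H - dG_Na` (chemical terms only; the
#' electrical terms of two like-charged ions moving in opposite
#' directions cancel exactly). H+ flows inward when its inward drive
#' exceeds the Na+ inward drive (`dG_net < 0`). Magnitude is
#' `unit_count * max_turnover * efficiency_scale *
#' saturation_factor(|dG_net|)`.
#'
#' @param spec A [protein_spec()] of kind `"spap"`.
#' @param geometry A [membrane_geometry()].
#' @param dG_H_chem_kJ,dG_Na_chem_kJ Chemical (concentration-only)
#'   free energies of inward transfer across the acid face, kJ/mol.
#' @param half_saturation_kJ Saturation constant, kJ/mol.
#' @return Named list with inward fluxes `H` and `Na` (mol/s; equal
#'   magnitude, opposite sign) and `dG_net_kJ`.
#' @examples
#' spap_flux(protein_spec("spap", 0.05), membrane_geometry(), -17, 0)
#' @export
spap_flux <- function(spec, geometry, dG_H_chem_kJ, dG_Na_chem_kJ,
                      half_saturation_kJ = protein_constants()$saturation_half_kJ) {
  stopifnot(inherits(spec, "protein_spec"))
  if (spec$kind != "spap")
    stop("spap_flux requires a 'spap' spec", call. = FALSE)
  check_finite(dG_H_chem_kJ, "dG_H_chem_kJ")
  check_finite(dG_Na_chem_kJ, "dG_Na_chem_kJ")
  dG_net <- dG_H_chem_kJ - dG_Na_chem_kJ
  rate <- unit_count(spec, geometry) * spec$max_turnover *
    spec$efficiency_scale * spec$ions_per_cycle *
    saturation_factor(dG_net, half_saturation_kJ) / AVOGADRO
  # dG_net < 0: H+ influx more favourable than Na+ influx -> H in, Na out.
  dirH <- -sign(dG_net)
  list(H = dirH * rate, Na = -dirH * rate, dG_net_kJ = dG_net)
}

#' Outward flux through the generic H2-dependent ion pump
#'
#' A generic system able to extrude H+ or Na+, powered by dissolved
#' hydrogen and throttled by the opposing electrochemical gradient:
#' \deqn{J_{out} = N\,k\,\epsilon \; \frac{[H_2]}{[H_2]+K_{H2}} \;
#'   e^{-\max(\Delta G_{opp},0)/K_{pump}}.}
#' The Boltzmann-like back-pressure factor makes pumping easier
#' against an alkaline fluid and harder against an acidic one, and
#' stalls the pump at a finite opposing gradient. Flux is strictly 0
#' when `[H2] = 0`.
#'
#' @param spec A [protein_spec()] of kind `"pump"`.
#' @param geometry A [membrane_geometry()].
#' @param dG_opp_kJ Opposing electrochemical gradient for outward
#'   transfer of the pumped ion across the acid face, kJ/mol
#'   (positive = opposing).
#' @param H2_molar Dissolved H2, mol/L.
#' @return Outward flux of the pumped ion, mol/s (non-negative).
#' @examples
#' pump_flux(protein_spec("pump", 0.05), membrane_geometry(), 5, 1e-3)
#' @export
pump_flux <- function(spec, geometry, dG_opp_kJ, H2_molar) {
  stopifnot(inherits(spec, "protein_spec"))
  if (spec$kind != "pump")
    stop("pump_flux requires a 'pump' spec", call. = FALSE)
  check_finite(dG_opp_kJ, "dG_opp_kJ"); check_finite(H2_molar, "H2_molar")
  if (H2_molar < 0) stop("H2_molar must be non-negative", call. = FALSE)
  f_h2 <- H2_molar / (H2_molar + spec$K_H2_molar)
  g_opp <- exp(-max(dG_opp_kJ, 0) / spec$K_pump_kJ)
  unit_count(spec, geometry) * spec$max_turnover * spec$efficiency_scale *
    spec$ions_per_cycle * f_h2 * g_opp / AVOGADRO
}

#' Capacity ratio of ATPase versus lipid-phase proton flux
#'
#' Compares the two proton entry routes per unit of membrane area, each
#' at its maximal drive: the ATPase pathway at modern turnover
#' (`turnover * ions_per_cycle / footprint / N_A` mol s^-1 m^-2) against
#' passive lipid-phase diffusion at the full acid-side proton
#' concentration (`P * [H+]_acid`). Returned as log10 of the ratio;
#' with the default constants, a proton permeability of 1e-2 cm/s and
#' an acid side at pH 7 the ATPase route is close to 4 orders of
#' magnitude faster.
#'
#' @param permeability_cm_s Lipid H+ permeability, cm/s.
#' @param pH_acid Acid-side pH.
#' @param spec ATPase [protein_spec()]; only its per-unit kinetic
#'   constants are used (surface fraction and efficiency scale cancel
#'   out of a per-area capacity comparison at modern rates).
#' @return log10 of (ATPase per-area capacity / lipid per-area flux).
#' @examples
#' proton_flux_ratio(1e-2, 7)   # ~3.6: nearly 4 orders of magnitude
#' @export
proton_flux_ratio <- function(permeability_cm_s = 1e-2, pH_acid = 7,
                              spec = protein_spec("atpase", 0.01)) {
  atpase_per_area <- spec$max_turnover * spec$ions_per_cycle /
    spec$unit_footprint / AVOGADRO                      # mol s^-1 m^-2
  lipid_per_area <- cm_s_to_m_s(permeability_cm_s) *
    molar_to_si(ph_to_concentration(pH_acid))           # mol s^-1 m^-2
  log10(atpase_per_area / lipid_per_area)
}
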