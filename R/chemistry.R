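#' @useDynLib protomotive, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Internal unit policy: all computation is SI (m, s, mol, V, J) with
# concentrations in mol/m^3. User-facing quantities are ingested in the
# units customary in the field -- permeability in cm/s, concentration in
# mol/L, protein footprints in nm^2, energies in kJ/mol -- and converted
# exactly once at the boundary by the helpers below.

#' Unit conversions at the ingestion boundary
#'
#' The simulator computes in SI internally (metres, seconds, moles,
#' volts, joules; concentrations in mol/m^3). These helpers convert the
#' customary input units once at the boundary; each pair is an exact
#' inverse.
#'
#' @param x Numeric vector.
#' @return Converted numeric vector.
#' @name unit_policy
#' @examples
#' cm_s_to_m_s(1e-3)       # 1e-5 m/s
#' molar_to_si(0.4)        # 400 mol/m^3
#' nm2_to_m2(64)           # 6.4e-17 m^2
NULL

#' @rdname unit_policy
#' @export
cm_s_to_m_s <- function(x) x * 1e-2
#' @rdname unit_policy
#' @export
m_s_to_cm_s <- function(x) x * 1e2
#' @rdname unit_policy
#' @export
molar_to_si <- function(x) x * 1e3
#' @rdname unit_policy
#' @export
si_to_molar <- function(x) x * 1e-3
#' @rdname unit_policy
#' @export
nm2_to_m2 <- function(x) x * 1e-18
#' @rdname unit_policy
#' @export
kJ_to_J <- function(x) x * 1e3
#' @rdname unit_policy
#' @export
J_to_kJ <- function(x) x * 1e-3

check_finite <- function(x, name) {
  if (length(x) == 0L || any(!is.finite(x)))
    stop("'", name, "' must be finite (got ",
         paste(utils::head(x, 3), collapse = ", "), ")", call. = FALSE)
  invisible(x)
}

#' pH arithmetic
#'
#' Convert between pH and proton concentration in mol/L. The two
#' functions are exact inverses.
#'
#' @param pH Numeric vector of pH values.
#' @param conc Numeric vector of H+ concentrations, mol/L (must be > 0).
#' @return `ph_to_concentration` returns mol/L; `concentration_to_ph`
#'   returns pH units.
#' @examples
#' ph_to_concentration(7)            # 1e-7
#' concentration_to_ph(1e-10)        # 10
#' @export
ph_to_concentration <- function(pH) {
  check_finite(pH, "pH")
  10^(-pH)
}

#' @rdname ph_to_concentration
#' @export
concentration_to_ph <- function(conc) {
  check_finite(conc, "conc")
  if (any(conc <= 0))
    stop("'conc' must be strictly positive to take a pH", call. = FALSE)
  -log10(conc)
}

#' Re-equilibrate protons and hydroxide to the water ion product
#'
#' Given total (pre-neutralization) amounts of H+ and OH- expressed as
#' concentrations, returns the pair after neutralization to water and
#' re-equilibration to the dissociation constant Kw. The difference
#' H - OH is conserved exactly (neutralization removes equal amounts of
#' each), and the returned pair satisfies H*OH = Kw. Solved in closed
#' form via the quadratic root: with d = total_H - total_OH,
#' H = (d + sqrt(d^2 + 4 Kw))/2 and OH = H - d.
#'
#' @param total_H,total_OH Total concentrations before equilibration,
#'   mol/L; must be non-negative.
#' @param Kw Water ion product, (mol/L)^2.
#' @return Named list with elements `H` and `OH` (mol/L).
#' @examples
#' equilibrate_water(1e-4, 1e-4)   # neutral: both 1e-7
#' eq <- equilibrate_water(2e-7, 1e-7)
#' eq$H * eq$OH                    # 1e-14
#' @export
equilibrate_water <- function(total_H, total_OH, Kw = 1e-14) {
  check_finite(total_H, "total_H"); check_finite(total_OH, "total_OH")
  check_finite(Kw, "Kw")
  if (any(total_H < 0) || any(total_OH < 0))
    stop("total_H and total_OH must be non-negative", call. = FALSE)
  if (Kw <= 0) stop("Kw must be positive", call. = FALSE)
  d <- total_H - total_OH
  s <- sqrt(d * d + 4 * Kw)
  # numerically stable root: take the larger species from the quadratic
  # and the smaller from the ion product (avoids cancellation when
  # |d| >> sqrt(Kw))
  H <- ifelse(d >= 0, (d + s) / 2, 2 * Kw / (s - d))
  list(H = H, OH = Kw / H)
}

#' Face-pooled effective external concentration
#'
#' The two external fluids differ, but a single membrane potential is
#' computed for the whole cell; each ion's "external" concentration in
#' the voltage equation is the face-area-weighted mean of its
#' acid-face and alkaline-face values. When the two fluids are
#' identical the rule degenerates to the common value.
#'
#' @param conc_acid,conc_alk External concentrations on the acid and
#'   alkaline faces (any consistent unit).
#' @param area_acid,area_alk Face areas (any consistent unit).
#' @return Pooled concentration in the input unit.
#' @examples
#' effective_external(1e-7, 1e-10)                 # 5.00005e-8
#' effective_external(1e-7, 1e-10, 3, 1)           # acid face 75% of area
#' @export
effective_external <- function(conc_acid, conc_alk,
                               area_acid = 1, area_alk = 1) {
  check_finite(conc_acid, "conc_acid"); check_finite(conc_alk, "conc_alk")
  check_finite(area_acid, "area_acid"); check_finite(area_alk, "area_alk")
  if (any(conc_acid < 0) || any(conc_alk < 0))
    stop("face concentrations must be non-negative", call. = FALSE)
  if (any(area_acid < 0) || any(area_alk < 0) ||
      any(area_acid + area_alk <= 0))
    stop("face areas must be non-negative with positive total", call. = FALSE)
  (conc_acid * area_acid + conc_alk * area_alk) / (area_acid + area_alk)
}
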