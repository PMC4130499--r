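#' Spherical two-faced membrane geometry
#'
#' The protocell is a sphere half embedded in the alkaline fluid, with
#' the other half exposed to the comparatively acidic fluid. The
#' surface is split between the two faces by `acid_fraction`.
#'
#' @param radius_um Cell radius in micrometres (default 1).
#' @param acid_fraction Fraction of the surface exposed to the acidic
#'   fluid (default 0.5, the half-and-half embedding).
#' @return List of class `membrane_geometry` with `radius` (m),
#'   `area_acid`, `area_alk` (m^2), `volume_L` and `volume_m3`.
#' @examples
#' g <- membrane_geometry()
#' g$area_acid / g$area_alk   # 1
#' @export
membrane_geometry <- function(radius_um = 1, acid_fraction = 0.5) {
  check_finite(radius_um, "radius_um"); check_finite(acid_fraction, "acid_fraction")
  if (radius_um <= 0) stop("radius_um must be positive", call. = FALSE)
  if (acid_fraction <= 0 || acid_fraction >= 1)
    stop("acid_fraction must lie strictly between 0 and 1", call. = FALSE)
  r <- radius_um * 1e-6
  area <- 4 * pi * r^2
  vol <- 4 / 3 * pi * r^3
  structure(list(radius = r,
                 area_acid = acid_fraction * area,
                 area_alk = (1 - acid_fraction) * area,
                 volume_m3 = vol,
                 volume_L = vol * 1e3),
            class = "membrane_geometry")
}

#' Specification of one permeant ion
#'
#' Bundles the quantities the flux equations need for one ionic
#' species: valence, lipid-phase permeability, its fixed external
#' concentration on each face, and its initial internal concentration.
#'
#' @param name Ion identifier, one of `"H"`, `"OH"`, `"Na"`, `"K"`, `"Cl"`.
#' @param valence Integer charge, -1 or +1.
#' @param permeability_cm_s Lipid-phase permeability, cm/s.
#' @param conc_acid_face,conc_alk_face External concentrations, mol/L.
#' @param initial_internal Initial internal concentration, mol/L.
#' @return List of class `ion_spec`; permeability is stored both as
#'   given (`permeability_cm_s`) and in SI (`permeability`, m/s).
#' @examples
#' ion_spec("Na", +1, 1e-9, 0.4, 0.4, 0.4)
#' @export
ion_spec <- function(name, valence, permeability_cm_s,
                     conc_acid_face, conc_alk_face,
                     initial_internal = conc_acid_face) {
  if (!name %in% ION_NAMES)
    stop("unknown ion '", name, "'; modelled ions are ",
         paste(ION_NAMES, collapse = ", "), call. = FALSE)
  if (!valence %in% c(-1L, 1L))
    stop("valence of '", name, "' must be -1 or +1", call. = FALSE)
  for (f in c("permeability_cm_s", "conc_acid_face", "conc_alk_face",
              "initial_internal")) {
    v <- get(f)
    check_finite(v, f)
    if (v < 0) stop("'", f, "' of ion '", name, "' must be >= 0", call. = FALSE)
  }
  structure(list(name = name, valence = as.integer(valence),
                 permeability_cm_s = permeability_cm_s,
                 permeability = cm_s_to_m_s(permeability_cm_s),
                 conc_acid_face = conc_acid_face,
                 conc_alk_face = conc_alk_face,
                 initial_internal = initial_internal),
            class = "ion_spec")
}

#' Passive flux of a neutral species
#'
#' Simple diffusion: flux = P * A * (c_ext - c_int), inward positive.
#'
#' @param P Permeability, m/s (>= 0).
#' @param A Membrane area, m^2 (>= 0).
#' @param c_ext,c_int External and internal concentrations (any common
#'   unit; the flux is returned in that unit times m^3/s, i.e. mol/s
#'   when concentrations are mol/m^3).
#' @return Net inward flux.
#' @examples
#' passive_flux_neutral(1e-4, 6.28e-12, 2e-4, 1e-4)
#' @export
passive_flux_neutral <- function(P, A, c_ext, c_int) {
  check_finite(P, "P"); check_finite(A, "A")
  check_finite(c_ext, "c_ext"); check_finite(c_int, "c_int")
  if (any(P < 0)) stop("'P' must be non-negative", call. = FALSE)
  if (any(A < 0)) stop("'A' must be non-negative", call. = FALSE)
  P * A * (c_ext - c_int)
}

#' Goldman-Hodgkin-Katz flux of a charged species
#'
#' Constant-field electrodiffusive flux across one membrane face,
#' inward positive, under the package-wide convention
#' `dpsi = psi_in - psi_out`. With u = zF dpsi / RT,
#' \deqn{J = P A u \frac{c_{out} - c_{in} e^{u}}{e^{u} - 1}.}
#' As `dpsi -> 0` this reduces to simple diffusion
#' `P*A*(c_out - c_in)`, and the flux vanishes exactly at the ion's
#' Nernst potential `(RT/zF) log(c_out/c_in)`. For `|u| < 1e-8` a
#' first-order series is used to avoid the 0/0 singularity.
#'
#' @param P Permeability, m/s.
#' @param z Valence (+1 or -1 here).
#' @param dpsi Membrane potential psi_in - psi_out, V.
#' @param c_in,c_out Internal / external concentrations, mol/m^3.
#' @param A Face area, m^2.
#' @param T_K Temperature, K.
#' @param constants Output of [physical_constants()].
#' @return Net inward flux, mol/s.
#' @examples
#' # zero at the Nernst potential:
#' k <- physical_constants()
#' vN <- k$gas_constant * 298 / k$faraday * log(10)
#' ghk_flux(1e-5, 1, vN, 1e-4, 1e-3, 1e-12, 298)
#' @export
ghk_flux <- function(P, z, dpsi, c_in, c_out, A, T_K = 298,
                     constants = physical_constants()) {
  check_finite(P, "P"); check_finite(dpsi, "dpsi")
  check_finite(c_in, "c_in"); check_finite(c_out, "c_out")
  check_finite(A, "A"); check_finite(T_K, "T_K")
  if (any(P < 0) || any(A < 0))
    stop("'P' and 'A' must be non-negative", call. = FALSE)
  if (any(T_K <= 0)) stop("'T_K' must be positive", call. = FALSE)
  if (any(c_in < 0) || any(c_out < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  u <- z * constants$faraday * dpsi / (constants$gas_constant * T_K)
  small <- abs(u) < 1e-8
  out <- numeric(length(u + P + c_in + c_out + A))
  # recycle explicitly
  n <- length(out)
  P <- rep_len(P, n); u <- rep_len(u, n); c_in <- rep_len(c_in, n)
  c_out <- rep_len(c_out, n); A <- rep_len(A, n); small <- rep_len(small, n)
  if (any(small))
    out[small] <- (P * A * ((c_out - c_in) -
                              u * (c_out + c_in) / 2))[small]
  if (any(!small))
    out[!small] <- (P * A * u * (c_out - c_in * exp(u)) /
                      (exp(u) - 1))[!small]
  out
}

#' Goldman-Hodgkin-Katz membrane potential
#'
#' Multi-ion resting potential under the constant-field assumption,
#' with the convention `dpsi = psi_in - psi_out`: permeant cations in
#' external excess drive `dpsi > 0`. External concentrations are the
#' face-pooled effective values (see [effective_external()]).
#'
#' \deqn{\Delta\psi = \frac{RT}{F}\,\ln\frac{\sum_{cat} P_i c_{i,out} +
#'   \sum_{an} P_j c_{j,in}}{\sum_{cat} P_i c_{i,in} +
#'   \sum_{an} P_j c_{j,out}}}
#'
#' @param P Numeric vector of permeabilities, m/s.
#' @param z Matching valences (+1/-1).
#' @param c_in,c_out Matching internal and effective external
#'   concentrations, mol/m^3.
#' @param T_K Temperature, K.
#' @param constants Output of [physical_constants()].
#' @return Membrane potential, V.
#' @examples
#' # single permeant cation, ten-fold external excess: +59.2 mV
#' ghk_voltage(1e-5, 1, 1e-4, 1e-3)
#' @export
ghk_voltage <- function(P, z, c_in, c_out, T_K = 298,
                        constants = physical_constants()) {
  check_finite(P, "P"); check_finite(c_in, "c_in"); check_finite(c_out, "c_out")
  if (any(P < 0)) stop("'P' must be non-negative", call. = FALSE)
  if (!all(z %in% c(-1, 1))) stop("valences must be -1 or +1", call. = FALSE)
  cat <- z > 0
  num <- sum(P[cat] * c_out[cat]) + sum(P[!cat] * c_in[!cat])
  den <- sum(P[cat] * c_in[cat]) + sum(P[!cat] * c_out[!cat])
  if (num <= 0 || den <= 0) {
    side <- c(if (num <= 0) "numerator (external cations + internal anions)",
              if (den <= 0) "denominator (internal cations + external anions)")
    stop("GHK voltage undefined: zero permeability-weighted ",
         paste(side, collapse = " and "), call. = FALSE)
  }
  constants$gas_constant * T_K / constants$faraday * log(num / den)
}
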