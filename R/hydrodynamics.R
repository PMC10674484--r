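# Steady-state anisotropy -> rotational correlation time -> hydrodynamic
# volume/radius, under the spherical-rotor approximation.

#' Solvent and photophysical conditions for the hydrodynamic chain
#'
#' Bundles the quantities needed to convert a steady-state anisotropy and a
#' fluorescence lifetime into a hydrodynamic size: solvent viscosity,
#' temperature and the limit (fundamental) anisotropy of the fluorophore.
#'
#' @param viscosity_cP Solvent viscosity in centipoise. Default 0.89 cP
#'   (water at 298 K).
#' @param temperature_K Absolute temperature in kelvin. Default 298.
#' @param r0 Limit anisotropy of the fluorophore (dimensionless, in
#'   (0, 0.4]). Default 0.260, the accepted value for tryptophan excited at
#'   295 nm.
#' @return An object of class `hydro_conditions`.
#' @examples
#' hydro_conditions()
#' hydro_conditions(viscosity_cP = 1.0, temperature_K = 293)
#' @export
hydro_conditions <- function(viscosity_cP = 0.89, temperature_K = 298,
                             r0 = 0.260) {
  stopifnot(is.numeric(viscosity_cP), length(viscosity_cP) == 1L,
            is.numeric(temperature_K), length(temperature_K) == 1L,
            is.numeric(r0), length(r0) == 1L)
  if (viscosity_cP <= 0) stop("viscosity_cP must be > 0")
  if (temperature_K <= 0) stop("temperature_K must be > 0")
  if (r0 <= 0 || r0 > 0.4) stop("r0 must lie in (0, 0.4]")
  structure(
    list(viscosity_cP = viscosity_cP,
         temperature_K = temperature_K,
         r0 = r0,
         gas_constant = 8.314,       # J mol^-1 K^-1
         avogadro = 6.022e23),       # mol^-1
    class = "hydro_conditions")
}

#' Steady-state anisotropy from polarized intensities
#'
#' r = (Ivv - g * Ivh) / (Ivv + 2 * g * Ivh), where Ivv and Ivh are the
#' emission intensities with vertical excitation and vertical/horizontal
#' analyzer, and g corrects for the instrument's polarization bias.
#'
#' @param Ivv,Ivh Polarized intensities (counts, >= 0, not both zero).
#' @param g_factor Instrument g-factor (> 0). Default 1 (no correction).
#' @return Anisotropy (dimensionless).
#' @examples
#' anisotropy_from_intensities(370, 300)   # 0.0722
#' @export
anisotropy_from_intensities <- function(Ivv, Ivh, g_factor = 1) {
  stopifnot(is.numeric(Ivv), is.numeric(Ivh), length(Ivv) == length(Ivh))
  if (any(Ivv < 0) || any(Ivh < 0)) stop("intensities must be >= 0")
  if (g_factor <= 0) stop("g_factor must be > 0")
  denom <- Ivv + 2 * g_factor * Ivh
  if (any(denom == 0)) stop("Ivv and Ivh are both zero: anisotropy undefined")
  (Ivv - g_factor * Ivh) / denom
}

#' Rotational correlation time from the Perrin equation
#'
#' For a spherical rotor the Perrin relation r0/r = 1 + tau/sigma links the
#' steady-state anisotropy r to the rotational correlation time sigma via the
#' fluorescence lifetime tau.  Inverted: sigma = tau / (r0/r - 1).
#'
#' @param r Measured steady-state anisotropy, 0 < r < r0.
#' @param tau_ns Fluorescence lifetime in ns (> 0).
#' @param cond A [hydro_conditions()] object supplying r0.
#' @return Rotational correlation time in ns.
#' @examples
#' rotational_correlation_time(0.110, 3.0, hydro_conditions())  # 2.2 ns
#' @export
rotational_correlation_time <- function(r, tau_ns, cond = hydro_conditions()) {
  stopifnot(inherits(cond, "hydro_conditions"))
  if (any(tau_ns <= 0)) stop("tau_ns must be > 0")
  if (any(r <= 0)) stop("anisotropy r must be > 0")
  if (any(r >= cond$r0))
    stop("anisotropy at or above limit value r0: rotational correlation ",
         "time undefined")
  tau_ns / (cond$r0 / r - 1)
}

#' Per-molecule hydrodynamic volume from the Stokes-Einstein-Debye relation
#'
#' sigma = eta * Vh_molar / (R * T) with Vh_molar the molar hydrodynamic
#' volume; the per-molecule volume is Vh = sigma * R * T / (eta * N_A).
#' Units are converted internally (cP -> Pa s, ns -> s, m^3 -> nm^3).
#'
#' @param sigma_ns Rotational correlation time in ns (> 0).
#' @param cond A [hydro_conditions()] object.
#' @return Hydrodynamic volume in nm^3 per molecule.
#' @examples
#' hydrodynamic_volume(2.2, hydro_conditions())  # 10.2 nm^3
#' @export
hydrodynamic_volume <- function(sigma_ns, cond = hydro_conditions()) {
  stopifnot(inherits(cond, "hydro_conditions"))
  if (any(sigma_ns <= 0)) stop("sigma_ns must be > 0")
  eta_Pa_s <- cond$viscosity_cP * 1e-3
  sigma_s <- sigma_ns * 1e-9
  v_m3 <- sigma_s * cond$gas_constant * cond$temperature_K /
    (eta_Pa_s * cond$avogadro)
  v_m3 * 1e27
}

#' Sphere radius from volume
#'
#' Inverts Vh = (4/3) pi Rh^3, returning the radius in angstrom for a volume
#' in nm^3.
#'
#' @param Vh_nm3 Volume in nm^3 (> 0).
#' @return Radius in angstrom.
#' @examples
#' radius_from_volume(10.2)  # 13.4 A
#' @export
radius_from_volume <- function(Vh_nm3) {
  if (any(Vh_nm3 <= 0)) stop("Vh_nm3 must be > 0")
  10 * (3 * Vh_nm3 / (4 * pi))^(1 / 3)
}

#' Sphere volume from radius
#'
#' Vh = (4/3) pi (Rh/10)^3: radius in angstrom in, volume in nm^3 out.
#'
#' @param Rh_A Radius in angstrom (> 0).
#' @return Volume in nm^3.
#' @examples
#' volume_from_radius(13.8)  # 11.0 nm^3
#' @export
volume_from_radius <- function(Rh_A) {
  if (any(Rh_A <= 0)) stop("Rh_A must be > 0")
  (4 / 3) * pi * (Rh_A / 10)^3
}

#' Full anisotropy-to-size chain
#'
#' Composes the Perrin equation, the Stokes-Einstein-Debye relation and the
#' sphere inversion: (r, tau) -> sigma -> Vh -> Rh.  First-order (delta
#' method) uncertainties on sigma, Vh, Rh are propagated from `r_se` when
#' given.
#'
#' @param r Steady-state anisotropy, 0 < r < r0.
#' @param tau_ns Fluorescence lifetime in ns.
#' @param cond A [hydro_conditions()] object.
#' @param r_se Optional standard error on r for uncertainty propagation.
#' @return A `hydro_result` list with fields `r`, `tau_ns`, `sigma_ns`,
#'   `Vh_nm3`, `Rh_A` and, when `r_se` is given, `sigma_se_ns`, `Vh_se_nm3`,
#'   `Rh_se_A`.
#' @examples
#' hydro_chain(0.112, 3.00)  # Vh = 10.5 nm^3, Rh = 13.5 A
#' @export
hydro_chain <- function(r, tau_ns, cond = hydro_conditions(), r_se = NULL) {
  sigma <- rotational_correlation_time(r, tau_ns, cond)
  Vh <- hydrodynamic_volume(sigma, cond)
  Rh <- radius_from_volume(Vh)
  out <- list(r = r, tau_ns = tau_ns, sigma_ns = sigma,
              Vh_nm3 = Vh, Rh_A = Rh)
  if (!is.null(r_se)) {
    # d sigma / d r = tau * r0 / (r0 - r)^2
    dsdr <- tau_ns * cond$r0 / (cond$r0 - r)^2
    out$sigma_se_ns <- abs(dsdr) * r_se
    out$Vh_se_nm3 <- Vh / sigma * out$sigma_se_ns
    out$Rh_se_A <- Rh / (3 * Vh) * out$Vh_se_nm3
  }
  class(out) <- "hydro_result"
  out
}

#' Apply the hydrodynamic chain to a table of (tau, r) measurements
#'
#' Vectorized convenience over [hydro_chain()]: takes a data frame with
#' columns `concentration_uM`, `tau_ns`, `r` (optionally `r_se`) and returns
#' it extended with `sigma_ns`, `Vh_nm3`, `Rh_A`.
#'
#' @param df Data frame with columns `concentration_uM`, `tau_ns`, `r`.
#' @param cond A [hydro_conditions()] object.
#' @return The input data frame with the derived columns appended.
#' @export
hydro_table <- function(df, cond = hydro_conditions()) {
  stopifnot(is.data.frame(df),
            all(c("concentration_uM", "tau_ns", "r") %in% names(df)))
  sigma <- rotational_correlation_time(df$r, df$tau_ns, cond)
  df$sigma_ns <- sigma
  df$Vh_nm3 <- hydrodynamic_volume(sigma, cond)
  df$Rh_A <- radius_from_volume(df$Vh_nm3)
  df
}
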