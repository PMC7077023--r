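#' Reynolds number based on hydraulic diameter
#'
#' \eqn{Re = |Q_{max}| D_H / (\nu A_{cs})}: peak oscillatory flow magnitude
#' times hydraulic diameter over kinematic viscosity times cross-sectional
#' area.
#'
#' @param q_max_abs Peak flow-rate magnitude, m^3/s.
#' @param dh Hydraulic diameter, m.
#' @param area Cross-sectional area, m^2.
#' @param nu Kinematic viscosity, m^2/s.
#' @return Dimensionless Reynolds number (vectorised).
#' @examples
#' reynolds_number(1e-6, 1e-2, 1e-4, 1e-6) # 100
#' @export
reynolds_number <- function(q_max_abs, dh, area, nu) {
  stop_if_not_positive(q_max_abs = q_max_abs, dh = dh, area = area, nu = nu)
  q_max_abs * dh / (nu * area)
}

#' Womersley number
#'
#' \eqn{\alpha = (D_H/2)\sqrt{\omega/\nu}}, the ratio of oscillatory inertia
#' to viscous forces.
#'
#' @param dh Hydraulic diameter, m.
#' @param omega Angular frequency, s^-1.
#' @param nu Kinematic viscosity, m^2/s.
#' @return Dimensionless Womersley number (vectorised).
#' @export
womersley_number <- function(dh, omega, nu) {
  stop_if_not_positive(dh = dh, omega = omega, nu = nu)
  dh / 2 * sqrt(omega / nu)
}

#' Cross-sectional mean velocity
#'
#' Signed ratio \eqn{Q/A_{cs}}. Negative values are caudally directed
#' (systolic), positive cranially directed (diastolic).
#'
#' @param q Flow rate, m^3/s (signed).
#' @param area Cross-sectional area, m^2.
#' @return Mean velocity, m/s.
#' @export
mean_velocity <- function(q, area) {
  stop_if_not_positive(area = area)
  if (!is.numeric(q) || anyNA(q)) rlang::abort("`q` must be numeric.")
  q / area
}

# Local oscillatory flow-amplitude factor. The rigid model carries the full
# caudally-imposed stroke up to the foramen magnum; above it the amplitude
# tapers linearly to `cranial_taper` at the cranial outlet, where velocities
# are minimal.
amplitude_attenuation <- function(z, z_top, cranial_taper = 0.02) {
  att <- rep(1, length(z))
  up <- z > 0
  att[up] <- 1 - (1 - cranial_taper) * z[up] / z_top
  att
}

#' Axial hydrodynamic characterisation
#'
#' Computes, per axial slice, the Reynolds number, Womersley number and the
#' signed peak systolic/diastolic mean velocities, using the local flow
#' amplitude (full spinal stroke, linearly attenuated across the cranium).
#'
#' @param profile A [neuraxis_profile()].
#' @param waveform A [cardiac_waveform()].
#' @param fluid A [csf_fluid()].
#' @param cranial_taper Residual amplitude fraction at the cranial outlet.
#' @return A tibble of class `hydro_profile` with columns `z_m`, `reynolds`,
#'   `womersley`, `v_systole_ms`, `v_diastole_ms`.
#' @export
characterize_hydrodynamics <- function(profile, waveform,
                                       fluid = csf_fluid(),
                                       cranial_taper = 0.02) {
  if (!inherits(profile, "neuraxis_profile")) {
    rlang::abort("`profile` must be a neuraxis_profile.")
  }
  if (!inherits(waveform, "pulsation_waveform")) {
    rlang::abort("`waveform` must be a pulsation_waveform.")
  }
  att <- amplitude_attenuation(
    profile$z_m, max(profile$z_m), cranial_taper
  )
  q_sys <- attr(waveform, "peak_systolic_flow") * att
  q_dia <- attr(waveform, "peak_diastolic_flow") * att
  q_amp <- pmax(abs(q_sys), abs(q_dia))
  out <- tibble::tibble(
    z_m = profile$z_m,
    reynolds = reynolds_number(
      q_amp, profile$dh_m, profile$area_m2, fluid$kinematic_viscosity
    ),
    womersley = womersley_number(
      profile$dh_m, attr(waveform, "angular_frequency"),
      fluid$kinematic_viscosity
    ),
    v_systole_ms = q_sys / profile$area_m2,
    v_diastole_ms = q_dia / profile$area_m2
  )
  structure(out, class = c("hydro_profile", class(out)))
}

#' Summary statistics of a hydrodynamic characterisation
#'
#' Reports the mean hydraulic diameter, the Womersley number under both
#' averaging conventions (mean of the pointwise values, and the value at the
#' mean hydraulic diameter), the peak signed mean velocities over the spinal
#' slices and the maximum Reynolds number.
#'
#' @param hydro A `hydro_profile`.
#' @param profile The matching [neuraxis_profile()].
#' @return A one-row tibble.
#' @export
hydro_summary <- function(hydro, profile) {
  if (!identical(nrow(hydro), nrow(profile))) {
    rlang::abort("`hydro` and `profile` grids do not conform.")
  }
  spinal <- profile$region == "spinal"
  tibble::tibble(
    mean_dh_m = mean(profile$dh_m),
    mean_womersley_pointwise = mean(hydro$womersley),
    womersley_at_mean_dh = mean(profile$dh_m) / 2 *
      mean(hydro$womersley / (profile$dh_m / 2)),
    mean_area_m2 = mean(profile$area_m2),
    mean_perimeter_m = mean(profile$perimeter_m),
    peak_systolic_velocity_ms = min(hydro$v_systole_ms[spinal]),
    peak_diastolic_velocity_ms = max(hydro$v_diastole_ms[spinal]),
    max_reynolds = max(hydro$reynolds)
  )
}
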