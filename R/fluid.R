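#' CSF fluid properties
#'
#' Bundles the physical constants of the working fluid: cerebrospinal fluid is
#' modelled as water-like, with the molecular diffusivities of the fluorescein
#' blood-surrogate tracer and of hemoglobin carried alongside. The kinematic
#' viscosity is derived as \eqn{\nu = \mu / \rho}.
#'
#' @param density Fluid density in kg/m^3.
#' @param dynamic_viscosity Dynamic viscosity in Pa s.
#' @param diffusivity_tracer Molecular diffusivity of the fluorescein tracer,
#'   m^2/s.
#' @param diffusivity_hemoglobin Molecular diffusivity of hemoglobin, m^2/s.
#'
#' @return An object of class `csf_fluid`: a list with fields `density`,
#'   `dynamic_viscosity`, `kinematic_viscosity`, `diffusivity_tracer` and
#'   `diffusivity_hemoglobin`.
#' @examples
#' fl <- csf_fluid()
#' fl$kinematic_viscosity # ~8.92e-7 m^2/s
#' @export
csf_fluid <- function(density = 998.3,
                      dynamic_viscosity = 0.89e-3,
                      diffusivity_tracer = 4.25e-10,
                      diffusivity_hemoglobin = 10.2e-11) {
  stop_if_not_positive(
    density = density, dynamic_viscosity = dynamic_viscosity,
    diffusivity_tracer = diffusivity_tracer,
    diffusivity_hemoglobin = diffusivity_hemoglobin
  )
  structure(
    list(
      density = density,
      dynamic_viscosity = dynamic_viscosity,
      kinematic_viscosity = dynamic_viscosity / density,
      diffusivity_tracer = diffusivity_tracer,
      diffusivity_hemoglobin = diffusivity_hemoglobin
    ),
    class = "csf_fluid"
  )
}

#' @export
print.csf_fluid <- function(x, ...) {
  cat("<csf_fluid>\n")
  cat(sprintf("  density             %.1f kg/m^3\n", x$density))
  cat(sprintf("  dynamic viscosity   %.3g Pa s\n", x$dynamic_viscosity))
  cat(sprintf("  kinematic viscosity %.4g m^2/s\n", x$kinematic_viscosity))
  cat(sprintf("  D (tracer)          %.3g m^2/s\n", x$diffusivity_tracer))
  cat(sprintf("  D (hemoglobin)      %.3g m^2/s\n", x$diffusivity_hemoglobin))
  invisible(x)
}
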