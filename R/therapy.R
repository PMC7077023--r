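#' Therapy configuration
#'
#' Describes the port layout and flow rates of the modelled intervention.
#' Under Neurapheresis therapy, CSF is aspirated at the lumbar spine (L2),
#' filtered, and returned at the upper thoracic spine (T2); under lumbar
#' drain, CSF is withdrawn passively at the lumbar site. Constant CSF
#' production near the ventricles balances the net withdrawal, so the rigid
#' constant-volume domain satisfies
#' `production + return = aspiration + drain`.
#'
#' Rates are given in mL/min (the clinical unit) and stored in m^3/s.
#'
#' @param mode `"neurapheresis"`, `"lumbar_drain"` or `"none"`.
#' @param aspiration_ml_min Aspiration rate at the lumbar catheter port.
#' @param return_ml_min Filtered-CSF return rate at the thoracic port.
#' @param production_ml_min Total CSF production rate at the ventricles.
#' @param drain_ml_min Passive lumbar drainage rate.
#' @param z_aspiration,z_return,z_production Port axial locations, m
#'   (origin at the foramen magnum, negative caudal). The lumbar drain is
#'   co-located with the aspiration site.
#' @param kernel_halfwidth Gaussian half-width over which each port's flow is
#'   distributed along the axis, m (the physical catheter holes span a finite
#'   length).
#' @param return_concentration Tracer volume fraction of the returned fluid
#'   (0 = ideal filtration).
#' @param tilt_deg Patient tilt angle, degrees. Metadata only: tracer and CSF
#'   share the same density, so gravity cannot separate the phases in this
#'   model.
#'
#' @return A `therapy_config` list with rates in m^3/s (`aspiration`,
#'   `return_flow`, `production`, `drain`).
#' @examples
#' therapy_config("neurapheresis")
#' therapy_config("lumbar_drain")
#' @export
therapy_config <- function(mode = c("neurapheresis", "lumbar_drain", "none"),
                           aspiration_ml_min = 2.0,
                           return_ml_min = 1.8,
                           production_ml_min = 0.2,
                           drain_ml_min = 0.2,
                           z_aspiration = -0.44,
                           z_return = -0.15,
                           z_production = 0.10,
                           kernel_halfwidth = 0.01,
                           return_concentration = 0,
                           tilt_deg = 30) {
  mode <- match.arg(mode)
  rates <- switch(mode,
    neurapheresis = list(
      aspiration = aspiration_ml_min, return_flow = return_ml_min,
      production = production_ml_min, drain = 0
    ),
    lumbar_drain = list(
      aspiration = 0, return_flow = 0,
      production = production_ml_min, drain = drain_ml_min
    ),
    none = list(aspiration = 0, return_flow = 0, production = 0, drain = 0)
  )
  for (nm in names(rates)) {
    if (rates[[nm]] < 0) rlang::abort("Port rates must be non-negative.")
  }
  bal <- rates$production + rates$return_flow -
    rates$aspiration - rates$drain
  if (abs(bal) > 1e-12 * max(1e-12, rates$aspiration + rates$drain)) {
    rlang::abort(paste0(
      "Fluid balance violated: production + return must equal ",
      "aspiration + drain in the rigid constant-volume domain (imbalance ",
      format(bal), " mL/min)."
    ))
  }
  if (return_concentration < 0 || return_concentration > 1) {
    rlang::abort("`return_concentration` must lie in [0, 1].")
  }
  stop_if_not_positive(kernel_halfwidth = kernel_halfwidth)
  structure(
    list(
      mode = mode,
      aspiration = ml_min_to_m3s(rates$aspiration),
      return_flow = ml_min_to_m3s(rates$return_flow),
      production = ml_min_to_m3s(rates$production),
      drain = ml_min_to_m3s(rates$drain),
      z_aspiration = z_aspiration,
      z_return = z_return,
      z_production = z_production,
      kernel_halfwidth = kernel_halfwidth,
      return_concentration = return_concentration,
      tilt_deg = tilt_deg
    ),
    class = "therapy_config"
  )
}

#' @export
print.therapy_config <- function(x, ...) {
  cat("<therapy_config>", x$mode, "\n")
  fmt <- function(q) sprintf("%.2f mL/min", q / M3S_PER_ML_MIN)
  cat("  aspiration", fmt(x$aspiration), "at z =", x$z_aspiration, "m\n")
  cat("  return    ", fmt(x$return_flow), "at z =", x$z_return, "m\n")
  cat("  production", fmt(x$production), "at z =", x$z_production, "m\n")
  cat("  drain     ", fmt(x$drain), "at z =", x$z_aspiration, "m\n")
  invisible(x)
}
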