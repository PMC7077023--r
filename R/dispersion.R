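# Shear-augmented (Taylor-type) dispersion: order-of-magnitude similitude
# chain for oscillatory flow in the subarachnoid space,
#
#   Sc      = nu / D                       (Schmidt)
#   beta^2  = (L/2)^2 omega / D            (oscillatory Peclet, squared)
#   alpha^2 = beta^2 / Sc = (L/2)^2 omega / nu   (Womersley, squared)
#   R_max   = P^2 Sc / alpha^2             (max enhancement, optimal mixing)
#   D_eff   = (1 + R_max) D
#   Sh      = h L / D_eff                  (convective / diffusive transport)
#
# Because R_max * D = P^2 nu / alpha^2 does not involve D, the effective
# diffusivity is (for R_max >> 1) independent of the molecular species: the
# fluorescein tracer is a similitude surrogate for hemoglobin.

#' Schmidt number
#' @param nu Kinematic viscosity, m^2/s.
#' @param d_mol Molecular diffusivity, m^2/s.
#' @return Dimensionless `nu / d_mol`.
#' @export
schmidt_number <- function(nu, d_mol) {
  stop_if_not_positive(nu = nu, d_mol = d_mol)
  nu / d_mol
}

#' Oscillatory Peclet number squared
#' @param length_scale Characteristic transverse length L, m.
#' @param omega Angular frequency, s^-1.
#' @param d_mol Molecular diffusivity, m^2/s.
#' @return Dimensionless `(L/2)^2 * omega / d_mol`.
#' @export
oscillatory_peclet_sq <- function(length_scale, omega, d_mol) {
  stop_if_not_positive(
    length_scale = length_scale, omega = omega, d_mol = d_mol
  )
  (length_scale / 2)^2 * omega / d_mol
}

#' Womersley number squared from the Peclet/Schmidt pair
#'
#' `beta_sq / sc`, algebraically `(L/2)^2 omega / nu`; identical for every
#' species in the same region.
#' @param beta_sq Oscillatory Peclet number squared.
#' @param sc Schmidt number.
#' @return Dimensionless squared Womersley number.
#' @export
womersley_sq <- function(beta_sq, sc) {
  stop_if_not_positive(beta_sq = beta_sq, sc = sc)
  beta_sq / sc
}

#' Maximum shear-augmented dispersion enhancement
#'
#' `R_max = P^2 * Sc / alpha^2` with P the non-dimensional pressure-gradient
#' parameter (default adopted value 152.6).
#' @param p Non-dimensional pressure parameter.
#' @param sc Schmidt number.
#' @param alpha_sq Squared Womersley number (> 0).
#' @return Dimensionless maximum enhancement.
#' @export
dispersion_enhancement <- function(p, sc, alpha_sq) {
  stop_if_not_positive(sc = sc, alpha_sq = alpha_sq)
  if (!is.numeric(p) || anyNA(p) || any(p < 0)) {
    rlang::abort("`p` must be non-negative.")
  }
  p^2 * sc / alpha_sq
}

#' Effective (shear-augmented) diffusivity
#' @param r_max Maximum enhancement (>= 0).
#' @param d_mol Molecular diffusivity, m^2/s.
#' @return `(1 + r_max) * d_mol`, m^2/s.
#' @export
effective_diffusivity <- function(r_max, d_mol) {
  stop_if_not_positive(d_mol = d_mol)
  if (!is.numeric(r_max) || anyNA(r_max) || any(r_max < 0)) {
    rlang::abort("`r_max` must be non-negative.")
  }
  (1 + r_max) * d_mol
}

#' Sherwood number
#'
#' Ratio of convective to effective-diffusive mass transport,
#' `Sh = h / (D_eff / L) = h L / D_eff`.
#' @param h Convective mass-transport coefficient (velocity scale), m/s.
#' @param d_eff Effective diffusivity, m^2/s.
#' @param length_scale Characteristic length L, m.
#' @return Dimensionless Sherwood number.
#' @export
sherwood_number <- function(h, d_eff, length_scale) {
  stop_if_not_positive(h = h, d_eff = d_eff, length_scale = length_scale)
  h * length_scale / d_eff
}

#' One dispersion case (region x species)
#'
#' @param region `"cortical"` or `"spinal"`.
#' @param species `"tracer"` or `"hemoglobin"`.
#' @param length_scale Characteristic transverse length, m: the minimum gap
#'   width for the cortical SAS (~2 mm) and the mean spinal hydraulic
#'   diameter (5.87 mm) for the spinal SAS.
#' @param d_mol Molecular diffusivity of the species, m^2/s.
#' @param nu Kinematic viscosity, m^2/s (momentum diffusivity of water at
#'   room temperature, 0.89e-6).
#' @param omega Angular frequency of the CSF pulsation, s^-1.
#' @param p Non-dimensional pressure parameter.
#' @param h Optional convective velocity scale for the Sherwood number, m/s.
#' @return A `dispersion_case` list.
#' @export
dispersion_case <- function(region, species, length_scale, d_mol,
                            nu = 0.89e-6, omega = 6.98, p = 152.6,
                            h = NULL) {
  stop_if_not_positive(
    length_scale = length_scale, d_mol = d_mol, nu = nu, omega = omega,
    p = p
  )
  if (!is.null(h)) stop_if_not_positive(h = h)
  structure(
    list(
      region = match.arg(region, c("cortical", "spinal")),
      species = match.arg(species, c("tracer", "hemoglobin")),
      length_scale = length_scale, d_mol = d_mol, nu = nu, omega = omega,
      p = p, h = h
    ),
    class = "dispersion_case"
  )
}

#' Default cortical/spinal x tracer/hemoglobin case grid
#'
#' @param fluid A [csf_fluid()] supplying the molecular diffusivities.
#' @param length_cortical,length_spinal Characteristic lengths, m.
#' @param nu,omega,p Shared physical constants, see [dispersion_case()].
#' @param h_cortical,h_spinal Optional convective velocity scales, m/s.
#' @return A list of four `dispersion_case` objects.
#' @export
default_dispersion_cases <- function(fluid = csf_fluid(),
                                     length_cortical = 2e-3,
                                     length_spinal = 5.87e-3,
                                     nu = 0.89e-6, omega = 6.98, p = 152.6,
                                     h_cortical = NULL, h_spinal = NULL) {
  specs <- expand.grid(
    region = c("cortical", "spinal"),
    species = c("tracer", "hemoglobin"),
    stringsAsFactors = FALSE
  )
  purrr::pmap(specs, function(region, species) {
    dispersion_case(
      region = region, species = species,
      length_scale = if (region == "cortical") length_cortical
        else length_spinal,
      d_mol = if (species == "tracer") fluid$diffusivity_tracer
        else fluid$diffusivity_hemoglobin,
      nu = nu, omega = omega, p = p,
      h = if (region == "cortical") h_cortical else h_spinal
    )
  })
}

#' Similitude table of dimensionless dispersion groups
#'
#' Evaluates the full similitude chain for a set of dispersion cases and
#' checks that the effective diffusivity agrees between tracer and
#' hemoglobin within each region (the similitude argument for using a
#' fluorescein tracer as a hemoglobin surrogate).
#'
#' @param cases A list of [dispersion_case()] objects; must cover all four
#'   region x species combinations (see [default_dispersion_cases()]).
#' @param check_similitude If `TRUE` (default), error unless each region is
#'   present for both species.
#' @return A tibble of class `similitude_table` with one row per case and
#'   columns `region`, `species`, `length_scale_m`, `schmidt`, `beta_sq`,
#'   `alpha_sq`, `r_max`, `d_eff_m2s` and `sherwood` (NA when no `h` was
#'   supplied). The attribute `similitude_rel_diff` holds the relative
#'   difference of `d_eff` between species per region.
#' @examples
#' similitude_table()
#' @export
similitude_table <- function(cases = default_dispersion_cases(),
                             check_similitude = TRUE) {
  rows <- purrr::map_dfr(cases, function(cs) {
    sc <- schmidt_number(cs$nu, cs$d_mol)
    b2 <- oscillatory_peclet_sq(cs$length_scale, cs$omega, cs$d_mol)
    a2 <- womersley_sq(b2, sc)
    rmax <- dispersion_enhancement(cs$p, sc, a2)
    deff <- effective_diffusivity(rmax, cs$d_mol)
    tibble::tibble(
      region = cs$region, species = cs$species,
      length_scale_m = cs$length_scale,
      schmidt = sc, beta_sq = b2, alpha_sq = a2, r_max = rmax,
      d_eff_m2s = deff,
      sherwood = if (is.null(cs$h)) NA_real_ else
        sherwood_number(cs$h, deff, cs$length_scale)
    )
  })
  rel <- NULL
  if (check_similitude) {
    by_region <- split(rows, rows$region)
    rel <- purrr::map_dbl(by_region, function(d) {
      if (!all(c("tracer", "hemoglobin") %in% d$species)) {
        rlang::abort(paste(
          "Incomplete similitude table: region", d$region[1],
          "is missing a species."
        ))
      }
      dt <- d$d_eff_m2s[d$species == "tracer"]
      dh <- d$d_eff_m2s[d$species == "hemoglobin"]
      abs(dt - dh) / dt
    })
  }
  structure(
    rows,
    similitude_rel_diff = rel,
    class = c("similitude_table", class(rows))
  )
}
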