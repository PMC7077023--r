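#' Compartment volume bookkeeping for the CSF space
#'
#' Takes the seven primitive compartment volumes of the CSF space and fills in
#' the derived totals. The spinal subarachnoid CSF is the dural volume minus
#' the space occupied by the cord and nerve roots; the intracranial CSF is the
#' sum of cortical subarachnoid space (SAS), ventricles, cerebellar SAS and
#' basal cisterns. Defaults are the subject-like reference volumes used by the
#' synthetic neuroaxis.
#'
#' @param spinal_cord,nerve_roots,dura Spinal primitive volumes, mL.
#' @param cortical_sas,ventricular_system,cerebellar_sas,basal_cisterns
#'   Intracranial primitive volumes, mL.
#'
#' @return A one-row tibble with the seven primitives plus
#'   `total_spinal_csf`, `total_intracranial_csf` and `total_csf` (mL).
#' @examples
#' compartment_volumes()$total_csf # 321.9
#' @export
compartment_volumes <- function(spinal_cord = 19.6,
                                nerve_roots = 6.0,
                                dura = 125.9,
                                cortical_sas = 153.6,
                                ventricular_system = 19.7,
                                cerebellar_sas = 21.8,
                                basal_cisterns = 26.5) {
  stop_if_not_positive(
    spinal_cord = spinal_cord, nerve_roots = nerve_roots, dura = dura,
    cortical_sas = cortical_sas, ventricular_system = ventricular_system,
    cerebellar_sas = cerebellar_sas, basal_cisterns = basal_cisterns,
    .allow_zero = TRUE
  )
  total_spinal <- dura - (nerve_roots + spinal_cord)
  if (total_spinal < 0) {
    rlang::abort(
      "Invalid geometry: dura volume is smaller than cord + nerve roots."
    )
  }
  total_cranial <- cortical_sas + ventricular_system + cerebellar_sas +
    basal_cisterns
  tibble::tibble(
    spinal_cord = spinal_cord,
    nerve_roots = nerve_roots,
    dura = dura,
    cortical_sas = cortical_sas,
    ventricular_system = ventricular_system,
    cerebellar_sas = cerebellar_sas,
    basal_cisterns = basal_cisterns,
    total_spinal_csf = total_spinal,
    total_intracranial_csf = total_cranial,
    total_csf = total_spinal + total_cranial
  )
}

# Raw (unscaled) spinal area shape versus distance below the foramen magnum.
# Cervical enlargement, gradual thoracic taper, a lumbar narrowing and a mild
# caudal widening toward the thecal sac; units are arbitrary before volume
# scaling. `s` is metres caudal of the foramen magnum (positive).
spinal_area_shape <- function(s, length_spinal) {
  base <- 2.3 - 0.95 * s / length_spinal
  dip <- -0.55 * exp(-((s - 0.47) / 0.055)^2)
  sac <- 0.12 * exp(-((s - length_spinal + 0.02) / 0.04)^2)
  base + dip + sac
}

cranial_area_shape <- function(z, length_cranial) {
  dome <- sin(pi * pmin(pmax(z / length_cranial, 0), 1))^0.9
  ventricles <- 0.22 * exp(-((z - 0.05) / 0.015)^2)
  skull_base <- 0.35 * exp(-(z / 0.03)^2)
  dome + ventricles + skull_base
}

#' Generate a synthetic subject-like neuroaxis profile
#'
#' Builds a one-dimensional discretisation of the cranial plus spinal
#' subarachnoid space: cross-sectional area, wetted perimeter, hydraulic
#' diameter and slice volume on a uniform axial grid. The axial coordinate has
#' its origin at the foramen magnum, positive cranial and negative caudal.
#' Piecewise-smooth parametric shapes (cranial dome with a ventricular bulge,
#' cervical enlargement, thoracic taper, lumbar narrowing, caudal thecal sac)
#' are scaled so that the integrated spinal and intracranial volumes, the
#' total length, and the spinal-mean hydraulic diameter match the requested
#' targets exactly. The hydraulic diameter has its local maximum at the
#' foramen magnum, and the largest areas and perimeters occur in the cranium.
#'
#' @param dz Slice thickness, m. Default 3 mm; 1 mm is convenient for
#'   hydrodynamic profiling.
#' @param total_length Total neuroaxis length, m.
#' @param cranial_length Cranial extent above the foramen magnum, m.
#' @param spinal_volume_ml,cranial_volume_ml Integrated volume targets, mL.
#' @param dh_spinal_mean Target mean hydraulic diameter over the spinal
#'   slices, m.
#' @param uniform_radius If non-`NULL`, ignore the parametric shapes and
#'   return a uniform circular tube of this radius (useful for verification:
#'   the hydraulic diameter then equals the diameter everywhere).
#' @param jitter Relative amplitude of a smooth random area perturbation
#'   (0 disables). Volume targets are re-imposed after perturbing.
#' @param seed Integer seed for the perturbation; the profile is bit-identical
#'   for a fixed seed.
#'
#' @return A tibble of class `neuraxis_profile` with columns `z_m`, `region`
#'   (`"spinal"`/`"cranial"`), `area_m2`, `perimeter_m`, `dh_m`,
#'   `slice_volume_m3`, and attributes `dz`, `spinal_volume_m3`,
#'   `cranial_volume_m3`.
#' @examples
#' prof <- neuraxis_profile()
#' sum(prof$slice_volume_m3) * 1e6 # 321.9 mL
#' @export
neuraxis_profile <- function(dz = 0.003,
                             total_length = 0.756,
                             cranial_length = 0.15,
                             spinal_volume_ml = 100.3,
                             cranial_volume_ml = 221.6,
                             dh_spinal_mean = 5.87e-3,
                             uniform_radius = NULL,
                             jitter = 0,
                             seed = NULL) {
  stop_if_not_positive(
    dz = dz, total_length = total_length, cranial_length = cranial_length,
    spinal_volume_ml = spinal_volume_ml, cranial_volume_ml = cranial_volume_ml,
    dh_spinal_mean = dh_spinal_mean
  )
  if (cranial_length >= total_length) {
    rlang::abort("`cranial_length` must be smaller than `total_length`.")
  }
  length_spinal <- total_length - cranial_length
  n <- round(total_length / dz)
  z <- seq(-length_spinal + dz / 2, by = dz, length.out = n)
  spinal <- z < 0

  if (!is.null(uniform_radius)) {
    stop_if_not_positive(uniform_radius = uniform_radius)
    area <- rep(pi * uniform_radius^2, n)
    dh <- rep(2 * uniform_radius, n)
  } else {
    area <- numeric(n)
    area[spinal] <- spinal_area_shape(-z[spinal], length_spinal)
    area[!spinal] <- cranial_area_shape(z[!spinal], cranial_length)

    if (jitter > 0) {
      if (is.null(seed)) {
        rlang::abort("A `seed` is required when `jitter` > 0.")
      }
      noise <- with_preserved_seed(seed, stats::rnorm(n))
      # smooth the white noise so the perturbation is anatomically plausible
      noise <- stats::filter(noise, rep(1 / 15, 15), circular = TRUE)
      area <- area * (1 + jitter * as.numeric(noise))
      if (any(area <= 0)) {
        rlang::abort("Jitter amplitude produced non-positive areas.")
      }
    }

    # impose the integrated volume targets exactly, per region
    area[spinal] <- area[spinal] *
      (spinal_volume_ml * 1e-6) / sum(area[spinal] * dz)
    area[!spinal] <- area[!spinal] *
      (cranial_volume_ml * 1e-6) / sum(area[!spinal] * dz)

    # hydraulic diameter: gentle caudal taper with a bump at the foramen
    # magnum (its local maximum), scaled to the spinal-mean target; the
    # cranial SAS is a wide thin sheet whose D_H decays away from the foramen
    dh <- numeric(n)
    dh_sp_raw <- 1 - 0.10 * (-z[spinal] / length_spinal) +
      0.45 * exp(-(z[spinal] / 0.025)^2)
    dh[spinal] <- dh_sp_raw * dh_spinal_mean / mean(dh_sp_raw)
    dh[!spinal] <- 7.2e-3 + (dh[spinal][sum(spinal)] - 7.2e-3) *
      exp(-(z[!spinal] / 0.03)^2)
  }

  out <- tibble::tibble(
    z_m = z,
    region = ifelse(spinal, "spinal", "cranial"),
    area_m2 = area,
    dh_m = dh,
    perimeter_m = 4 * area / dh,
    slice_volume_m3 = area * dz
  )
  out <- out[, c(
    "z_m", "region", "area_m2", "perimeter_m", "dh_m", "slice_volume_m3"
  )]
  structure(
    out,
    dz = dz,
    spinal_volume_m3 = sum(out$slice_volume_m3[spinal]),
    cranial_volume_m3 = sum(out$slice_volume_m3[!spinal]),
    class = c("neuraxis_profile", class(out))
  )
}

#' Write / read an axial profile as delimited text
#'
#' Tab-separated with a header; columns `z_m`, `area_m2`, `perimeter_m`,
#' `dh_m`, `slice_volume_m3`.
#'
#' @param profile A `neuraxis_profile` (or compatible data frame).
#' @param path File path.
#' @return `read_profile()` returns a `neuraxis_profile` tibble.
#' @export
write_profile <- function(profile, path) {
  readr::write_tsv(
    profile[, c("z_m", "area_m2", "perimeter_m", "dh_m", "slice_volume_m3")],
    path
  )
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("z_m", "area_m2", "perimeter_m", "dh_m", "slice_volume_m3")
  if (!all(need %in% names(x))) {
    rlang::abort(paste(
      "Profile file must contain columns:", paste(need, collapse = ", ")
    ))
  }
  if (is.unsorted(x$z_m, strictly = TRUE)) {
    rlang::abort("Profile z grid must be strictly increasing.")
  }
  dz <- diff(x$z_m)
  if (max(abs(dz - dz[1])) > 1e-9 * dz[1]) {
    rlang::abort("Profile z grid must be uniform.")
  }
  x$region <- ifelse(x$z_m < 0, "spinal", "cranial")
  x <- x[, c(
    "z_m", "region", "area_m2", "perimeter_m", "dh_m", "slice_volume_m3"
  )]
  structure(
    tibble::as_tibble(x),
    dz = dz[1],
    spinal_volume_m3 = sum(x$slice_volume_m3[x$region == "spinal"]),
    cranial_volume_m3 = sum(x$slice_volume_m3[x$region == "cranial"]),
    class = c("neuraxis_profile", class(tibble::tibble()))
  )
}
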