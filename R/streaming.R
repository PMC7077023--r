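#' Periodic velocity field container
#'
#' Holds per-cell axial velocities sampled at equally spaced phases over one
#' cardiac cycle, together with cell volumes and the mapping of cells to
#' axial slices. This is the gridded input from which steady streaming is
#' quantified.
#'
#' @param u_z Numeric matrix, cells x phase samples, of z-velocities (m/s,
#'   positive cranial).
#' @param cell_volume Cell volumes, m^3 (length = rows of `u_z`).
#' @param cell_slice Integer slice index per cell (1-based, into the axial
#'   profile grid).
#' @param phase_s Phase sample times over one cycle, s; must be equally
#'   spaced.
#' @return A `velocity_field` list.
#' @export
velocity_field <- function(u_z, cell_volume, cell_slice, phase_s) {
  u_z <- as.matrix(u_z)
  if (ncol(u_z) < 2) {
    rlang::abort("At least two phase samples per cycle are required.")
  }
  if (length(phase_s) != ncol(u_z)) {
    rlang::abort("`phase_s` must have one entry per column of `u_z`.")
  }
  dphi <- diff(phase_s)
  if (any(dphi <= 0) || max(abs(dphi - dphi[1])) > 1e-9 * dphi[1]) {
    rlang::abort("Phase samples must be strictly increasing and equispaced.")
  }
  stop_if_not_positive(cell_volume = cell_volume)
  if (length(cell_volume) != nrow(u_z) ||
    length(cell_slice) != nrow(u_z)) {
    rlang::abort("`cell_volume` and `cell_slice` must match rows of `u_z`.")
  }
  if (anyNA(cell_slice) || any(cell_slice < 1) ||
    any(cell_slice != round(cell_slice))) {
    rlang::abort("`cell_slice` must be positive integer slice indices.")
  }
  structure(
    list(
      u_z = u_z, cell_volume = as.numeric(cell_volume),
      cell_slice = as.integer(cell_slice), phase_s = as.numeric(phase_s)
    ),
    class = "velocity_field"
  )
}

#' Cycle-mean axial velocity per cell
#'
#' Arithmetic mean of the z-velocity over the equally weighted phase samples
#' of one cycle; the nonzero residue is the steady-streaming velocity.
#'
#' @param field A [velocity_field()].
#' @return Numeric vector, one cycle-mean velocity per cell (m/s, signed;
#'   positive cranial).
#' @export
cycle_mean_velocity <- function(field) {
  if (!inherits(field, "velocity_field")) {
    rlang::abort("`field` must be a velocity_field.")
  }
  rowMeans(field$u_z)
}

#' Steady-streaming velocity magnitude profile
#'
#' Volume-weighted cross-sectional average of the absolute cycle-mean
#' velocity per axial slice,
#' \eqn{U_{ss}(z) = \sum |U_{z,mean}| V / \sum V}. The magnitude is taken
#' per cell before averaging, so opposing bidirectional currents within a
#' cross-section do not cancel.
#'
#' @param field A [velocity_field()].
#' @param profile A [neuraxis_profile()] defining the slice grid.
#' @return A tibble of class `streaming_profile` with columns `z_m`,
#'   `uss_ms` (zero for slices containing no cells), `qss` (`NA`, see
#'   [qss_profile()]) and `qnet_m3s` (zero; see [parametric_streaming()]).
#' @export
uss_profile <- function(field, profile) {
  if (!inherits(field, "velocity_field")) {
    rlang::abort("`field` must be a velocity_field.")
  }
  n <- nrow(profile)
  if (any(field$cell_slice > n)) {
    rlang::abort("A cell maps to a slice outside the profile grid.")
  }
  umean <- abs(cycle_mean_velocity(field))
  wsum <- as.numeric(rowsum(
    umean * field$cell_volume,
    group = field$cell_slice, reorder = TRUE
  ))
  vsum <- as.numeric(rowsum(
    field$cell_volume,
    group = field$cell_slice, reorder = TRUE
  ))
  idx <- sort(unique(field$cell_slice))
  uss <- numeric(n)
  uss[idx] <- wsum / vsum
  new_streaming(profile$z_m, uss, qss = rep(NA_real_, n),
    qnet = numeric(n))
}

#' Non-dimensional steady-streaming flow fraction
#'
#' \eqn{Q_{ss}(z) = U_{ss}(z) A_{cs} / (2 Q_{peak})}: the cycle-mean
#' streaming throughput as a fraction of the peak-to-peak oscillatory flow.
#'
#' @param uss Steady-streaming velocity magnitude per slice, m/s (or a
#'   `streaming_profile`, whose `uss_ms` column is used).
#' @param area Cross-sectional area per slice, m^2.
#' @param q_peak Peak oscillatory flow magnitude, m^3/s (> 0).
#' @return Numeric vector of dimensionless flow fractions.
#' @export
qss_profile <- function(uss, area, q_peak) {
  if (inherits(uss, "streaming_profile")) uss <- uss$uss_ms
  stop_if_not_positive(q_peak = q_peak, area = area)
  if (any(uss < 0)) rlang::abort("`uss` must be non-negative.")
  uss * area / (2 * q_peak)
}

new_streaming <- function(z, uss, qss, qnet) {
  out <- tibble::tibble(z_m = z, uss_ms = uss, qss = qss, qnet_m3s = qnet)
  structure(out, class = c("streaming_profile", class(out)))
}

#' Net continuity flow induced by the therapy ports
#'
#' Integrates the port source/sink densities (Gaussian kernels) along the
#' axis to obtain the net cycle-mean flow through each cross-section in a
#' rigid domain: zero at both closed ends, piecewise-constant between ports,
#' and exactly conserving (its discrete divergence equals the per-slice
#' source rates).
#'
#' @param profile A [neuraxis_profile()].
#' @param therapy A [therapy_config()].
#' @return List with `q_face` (face flows, length `nrow(profile) + 1`, m^3/s,
#'   positive cranial; entries 1 and n+1 are zero) and `source_m3s`
#'   (per-slice net source rates).
#' @export
net_bulk_flow <- function(profile, therapy) {
  z <- profile$z_m
  n <- length(z)
  src <- numeric(n)
  hw <- therapy$kernel_halfwidth
  add <- function(src, q, z0) {
    if (q == 0) return(src)
    src + q * port_kernel(z, z0, hw)
  }
  src <- add(src, -therapy$aspiration - therapy$drain, therapy$z_aspiration)
  src <- add(src, therapy$return_flow, therapy$z_return)
  src <- add(src, therapy$production, therapy$z_production)
  q_face <- c(0, cumsum(src))
  if (abs(q_face[n + 1]) > 1e-15 * max(1e-30, max(abs(q_face)))) {
    rlang::abort("Port flows do not balance; net flow at the cranial end.")
  }
  q_face[n + 1] <- 0
  list(q_face = q_face, source_m3s = src)
}

#' Parametric steady-streaming profile under therapy
#'
#' The full transient computation of steady streaming requires resolving the
#' nonlinear three-dimensional oscillatory flow; at desk scale the package
#' instead uses a calibrated parametric profile carrying the printed summary
#' structure: a plateau of enhanced streaming between the aspiration and
#' return ports (therapy-dependent level; the flow loop of Neurapheresis
#' therapy raises it by ~60% over lumbar drain), a baseline level elsewhere
#' in the spine, and a cranial level attenuated by a large factor (~50x).
#' The inter-port mean is imposed exactly by construction.
#'
#' @param profile A [neuraxis_profile()].
#' @param therapy A [therapy_config()].
#' @param interport_uss Target mean streaming velocity magnitude between the
#'   aspiration and return ports, m/s. Defaults by mode: 0.37 mm/s for
#'   Neurapheresis, 0.23 mm/s for lumbar drain, the baseline for `"none"`.
#' @param baseline_uss Baseline spinal streaming level outside the inter-port
#'   region, m/s.
#' @param cranial_attenuation Factor by which the spinal-mean streaming is
#'   divided in the cranial SAS.
#' @param edge_width Smoothing width of the plateau edges and of the
#'   spinal-to-cranial transition, m.
#' @return A `streaming_profile` tibble with columns `z_m`, `uss_ms`, `qss`
#'   (`NA` until scaled by a waveform, see [qss_profile()]) and `qnet_m3s`
#'   (the net continuity flow at the caudal face of each slice).
#' @export
parametric_streaming <- function(profile, therapy,
                                 interport_uss = NULL,
                                 baseline_uss = 0.15e-3,
                                 cranial_attenuation = 50,
                                 edge_width = 0.01) {
  z <- profile$z_m
  n <- length(z)
  if (therapy$z_aspiration < min(z) || therapy$z_return > max(z)) {
    rlang::abort("Therapy ports fall outside the axial grid.")
  }
  if (is.null(interport_uss)) {
    interport_uss <- switch(therapy$mode,
      neurapheresis = 0.37e-3,
      lumbar_drain = 0.23e-3,
      none = baseline_uss
    )
  }
  stop_if_not_positive(
    interport_uss = interport_uss, baseline_uss = baseline_uss,
    cranial_attenuation = cranial_attenuation, edge_width = edge_width
  )

  plateau <- 0.5 * (tanh((z - therapy$z_aspiration) / edge_width) -
    tanh((z - therapy$z_return) / edge_width))
  sig_cran <- 1 / (1 + exp(-z / (edge_width / 2)))
  ip <- z >= therapy$z_aspiration & z <= therapy$z_return
  spinal <- profile$region == "spinal"

  # solve the plateau amplitude so the inter-port mean is exact, then the
  # cranial level so cranial mean = spinal mean / attenuation (two-pass
  # fixed point; the sigmoid couples the regions only near the foramen)
  cran_level <- baseline_uss / cranial_attenuation
  for (i in 1:3) {
    amp <- (interport_uss - mean(baseline_uss * (1 - sig_cran[ip]) +
      cran_level * sig_cran[ip])) / mean(plateau[ip] * (1 - sig_cran[ip]))
    u_sp <- baseline_uss + amp * plateau
    uss <- u_sp * (1 - sig_cran) + cran_level * sig_cran
    target_cran <- mean(uss[spinal]) / cranial_attenuation
    m0 <- mean((u_sp * (1 - sig_cran))[!spinal])
    cran_level <- max(0, (target_cran - m0) / mean(sig_cran[!spinal]))
  }
  flows <- net_bulk_flow(profile, therapy)
  new_streaming(z, uss, qss = rep(NA_real_, n),
    qnet = flows$q_face[seq_len(n)])
}

#' Write a streaming profile as delimited text
#' @param streaming A `streaming_profile`.
#' @param path File path.
#' @export
write_streaming <- function(streaming, path) {
  readr::write_tsv(streaming, path)
  invisible(path)
}
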