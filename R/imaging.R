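#' Optics configuration for the synthetic fluorescence emulator
#'
#' Net optical parameters of the bench-top time-lapse measurement: detector
#' gain (intensity units per unit tracer fraction at the reference
#' concentration scale), additive pixel noise, a single-exponential
#' photobleach rate shared by sample and baseline vial, a static background
#' (fixed-pattern) image, and a quadratic axial lens-distortion warp of the
#' pixel-to-position mapping.
#'
#' @param gain Intensity per unit volume fraction, a.u.
#' @param noise_sd Additive Gaussian pixel noise, a.u.
#' @param bleach_rate Photobleach rate, 1/s (0 disables).
#' @param background_level Mean background intensity, a.u.
#' @param background_texture_sd Fixed-pattern background variation, a.u.
#' @param distortion Quadratic warp coefficient (relative, 0 = ideal lens).
#' @param n_rows,n_cols Pixel grid size (columns sample the axial
#'   direction).
#' @param reference_fraction Tracer volume fraction corresponding to the
#'   known-concentration baseline vial. The quantification formula
#'   normalises by the baseline, so recovered fractions are multiples of
#'   this reference; with the default 0.1 the map is on the same scale as
#'   the transport model (fraction-of-reference versus fraction-of-initial
#'   is a pure rescaling).
#' @return An `optics_config` list.
#' @export
optics_config <- function(gain = 1200, noise_sd = 4, bleach_rate = 2e-6,
                          background_level = 120,
                          background_texture_sd = 6,
                          distortion = 0.08, n_rows = 32, n_cols = 512,
                          reference_fraction = 0.1) {
  stop_if_not_positive(
    gain = gain, background_level = background_level, n_rows = n_rows,
    n_cols = n_cols, reference_fraction = reference_fraction
  )
  stop_if_not_positive(
    noise_sd = noise_sd, bleach_rate = bleach_rate,
    background_texture_sd = background_texture_sd, .allow_zero = TRUE
  )
  structure(
    list(
      gain = gain, noise_sd = noise_sd, bleach_rate = bleach_rate,
      background_level = background_level,
      background_texture_sd = background_texture_sd,
      distortion = distortion, n_rows = n_rows, n_cols = n_cols,
      reference_fraction = reference_fraction
    ),
    class = "optics_config"
  )
}

# Quadratic axial warp: the camera's optical axis is centred on the model,
# so pixel columns sample true positions displaced toward the frame centre
# at the edges. The stack stores the true (corrected) position per column.
warp_pixel_z <- function(z_lin, distortion) {
  zmid <- (max(z_lin) + min(z_lin)) / 2
  span <- (max(z_lin) - min(z_lin)) / 2
  z_lin + distortion * span * ((z_lin - zmid) / span)^2 *
    sign(zmid - z_lin)
}

#' Synthesize a fluorescence time-lapse image stack
#'
#' Builds a pixel-grid-by-time intensity stack from a simulated
#' concentration field: static background plus `gain * alpha * bleach(t)`
#' plus Gaussian noise, with a baseline vial at the reference concentration
#' imaged alongside and subject to the same photobleaching. Deterministic
#' for a fixed seed.
#'
#' @param sim A `tracer_sim` from [simulate_transport()].
#' @param optics An [optics_config()].
#' @param seed Integer seed for background texture and pixel noise.
#' @return An `image_stack`: list with `intensity` (rows x cols x times
#'   array), `timestamps`, `background` (noise-free calibration image),
#'   `baseline_series`, `baseline_background`, `pixel_z` (true axial
#'   position per column, m) and `reference_fraction`.
#' @export
synthesize_stack <- function(sim, optics = optics_config(), seed = 1) {
  if (!inherits(sim, "tracer_sim")) {
    rlang::abort("`sim` must be a tracer_sim.")
  }
  nr <- optics$n_rows
  nc <- optics$n_cols
  nt <- length(sim$time_s)
  z_lin <- seq(min(sim$z_m), max(sim$z_m), length.out = nc)
  pixel_z <- warp_pixel_z(z_lin, optics$distortion)

  with_preserved_seed(seed, {
    background <- matrix(
      optics$background_level +
        stats::rnorm(nr * nc, sd = optics$background_texture_sd),
      nr, nc
    )
    bleach <- exp(-optics$bleach_rate * sim$time_s)
    intensity <- array(0, dim = c(nr, nc, nt))
    for (i in seq_len(nt)) {
      a_col <- stats::approx(
        sim$z_m, sim$map[i, ],
        xout = pixel_z, rule = 2
      )$y
      signal <- matrix(optics$gain * a_col * bleach[i],
        nr, nc,
        byrow = TRUE
      )
      intensity[, , i] <- background + signal +
        stats::rnorm(nr * nc, sd = optics$noise_sd)
    }
    baseline_background <- optics$background_level
    baseline_series <- baseline_background +
      optics$gain * optics$reference_fraction * bleach +
      stats::rnorm(nt, sd = optics$noise_sd / sqrt(64))
  })

  structure(
    list(
      intensity = intensity, timestamps = sim$time_s,
      background = background, baseline_series = baseline_series,
      baseline_background = baseline_background, pixel_z = pixel_z,
      reference_fraction = optics$reference_fraction
    ),
    class = "image_stack"
  )
}

#' Fit the baseline photobleach decay
#'
#' Fits a single-exponential decay `I_b(t) = background + A exp(-r t)` to
#' the baseline-vial intensity series by log-linear least squares, used to
#' interpolate a denoised baseline when converting intensity to
#' concentration.
#'
#' @param timestamps Times, s (>= 3 points).
#' @param baseline_series Baseline intensities, a.u.
#' @param background Known background intensity at the baseline vial, a.u.
#' @return A `baseline_decay` list with `rate` (1/s), `rate_se`,
#'   `amplitude`, `background` and `predict(t)`.
#' @export
baseline_decay_fit <- function(timestamps, baseline_series, background = 0) {
  if (length(timestamps) < 3) {
    rlang::abort("At least three baseline time points are required.")
  }
  net <- baseline_series - background
  if (any(net <= 0)) {
    rlang::abort("Baseline intensities must exceed the background.")
  }
  if (net[length(net)] > net[1] * (1 + 1e-9)) {
    rlang::abort(
      "Baseline series increases over time; photobleach decay cannot rise."
    )
  }
  fit <- stats::lm(log(net) ~ timestamps)
  rate <- -unname(stats::coef(fit)[2])
  amplitude <- exp(unname(stats::coef(fit)[1]))
  rss <- sum(stats::residuals(fit)^2)
  sxx <- sum((timestamps - mean(timestamps))^2)
  rate_se <- sqrt(rss / (length(timestamps) - 2) / sxx)
  structure(
    list(
      rate = rate, rate_se = rate_se, amplitude = amplitude,
      background = background,
      predict = function(t) background + amplitude * exp(-rate * t)
    ),
    class = "baseline_decay"
  )
}

#' Quantify an image stack into a concentration map
#'
#' Inverts the imaging model: per-pixel tracer fraction
#' `alpha = ref * (I - I0) / (I_b(t) - I0)` with the time-matched fitted
#' baseline, averaged down the pixel rows and then into axial slabs using
#' the corrected pixel positions.
#'
#' @param stack An `image_stack`.
#' @param z_grid Target slab centres, m (e.g. the transport grid). If
#'   `NULL`, uniform slabs spanning the imaged range are used.
#' @param slab_thickness Slab thickness, m.
#' @return A long tibble (`time_s`, `z_m`, `alpha`): a spatio-temporal
#'   concentration map comparable with [axial_concentration()] output.
#' @export
quantify_stack <- function(stack, z_grid = NULL, slab_thickness = 0.003) {
  if (!inherits(stack, "image_stack")) {
    rlang::abort("`stack` must be an image_stack.")
  }
  decay <- baseline_decay_fit(
    stack$timestamps, stack$baseline_series, stack$baseline_background
  )
  ib <- decay$predict(stack$timestamps)
  i0b <- stack$baseline_background
  if (any(ib <= i0b)) {
    rlang::abort("Calibration failure: baseline does not exceed background.")
  }
  if (is.null(z_grid)) {
    z_grid <- seq(
      min(stack$pixel_z) + slab_thickness / 2, max(stack$pixel_z),
      by = slab_thickness
    )
  }
  # nearest-slab assignment of each (corrected) pixel column
  idx <- findInterval(
    stack$pixel_z,
    c(-Inf, z_grid[-length(z_grid)] + diff(z_grid) / 2, Inf)
  )
  nt <- length(stack$timestamps)
  out <- purrr::map_dfr(seq_len(nt), function(i) {
    apix <- stack$reference_fraction *
      (stack$intensity[, , i] - stack$background) / (ib[i] - i0b)
    a_col <- colMeans(apix)
    tibble::tibble(
      time_s = stack$timestamps[i],
      z_m = z_grid,
      alpha = as.numeric(tapply(a_col, factor(idx, levels = seq_along(z_grid)),
        mean
      ))
    )
  })
  # slabs not covered by any pixel column (possible at warped frame edges)
  out[!is.na(out$alpha), ]
}
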