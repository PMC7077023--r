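#' Cardiac-driven CSF pulsation waveform
#'
#' Generates one period of the oscillatory CSF flow-rate signal imposed at the
#' caudal end of the neuroaxis. The default `"cardiac"` shape is a zero-mean
#' two-harmonic signal whose caudal (systolic, negative) peak exceeds the
#' cranial (diastolic, positive) peak by the requested ratio; `"sine"` gives a
#' symmetric oscillation. The one-cycle mean is zero by construction: net
#' flows enter the model only through the therapy source/sink terms.
#'
#' @param period Cardiac period, s. The angular frequency is
#'   \eqn{\omega = 2\pi/T}.
#' @param amplitude Peak systolic flow magnitude, m^3/s. If `NULL` and
#'   `profile` is given, the amplitude is calibrated so that the largest
#'   caudally-directed mean velocity over the spinal slices equals
#'   `target_systolic_velocity`.
#' @param shape `"cardiac"` (asymmetric) or `"sine"`.
#' @param n Number of equally spaced phase samples per cycle.
#' @param peak_ratio Systolic-to-diastolic peak magnitude ratio for the
#'   cardiac shape. Default 4.7/2.8, the lumbar peak-velocity ratio.
#' @param profile Optional [neuraxis_profile()] used for amplitude
#'   calibration.
#' @param target_systolic_velocity Signed peak systolic mean velocity used
#'   for calibration, m/s (negative = caudal).
#'
#' @return A tibble of class `pulsation_waveform` with columns `phase_s` and
#'   `flow_m3s`, and attributes `period`, `angular_frequency`, `amplitude`,
#'   `peak_systolic_flow` (negative) and `peak_diastolic_flow` (positive).
#' @examples
#' wf <- cardiac_waveform(amplitude = 5e-6)
#' attr(wf, "angular_frequency") # 6.98 s^-1
#' @export
cardiac_waveform <- function(period = 0.9,
                             amplitude = NULL,
                             shape = c("cardiac", "sine"),
                             n = 360,
                             peak_ratio = 4.7 / 2.8,
                             profile = NULL,
                             target_systolic_velocity = -0.047) {
  shape <- match.arg(shape)
  stop_if_not_positive(period = period, n = n, peak_ratio = peak_ratio)
  if (is.null(amplitude)) {
    if (is.null(profile)) {
      rlang::abort("Supply `amplitude` or a `profile` to calibrate it from.")
    }
    sp <- profile$area_m2[profile$region == "spinal"]
    amplitude <- abs(target_systolic_velocity) * min(sp)
  }
  stop_if_not_positive(amplitude = amplitude)

  theta <- 2 * pi * seq(0, n - 1) / n
  if (shape == "sine") {
    w <- -sin(theta)
  } else {
    # first harmonic plus a phase-shifted second harmonic,
    # f = sin(theta) + c cos(2 theta): the cos term sharpens and deepens
    # the negative (systolic) excursion while blunting the positive one;
    # c is solved so |systolic peak| / |diastolic peak| = peak_ratio
    th_fine <- seq(0, 2 * pi, length.out = 8192)
    ratio_of <- function(cc) {
      f <- sin(th_fine) + cc * cos(2 * th_fine)
      abs(min(f)) / max(f)
    }
    cc <- stats::uniroot(
      function(cc) ratio_of(cc) - peak_ratio,
      interval = c(1e-6, 0.99), tol = 1e-12
    )$root
    f <- sin(theta) + cc * cos(2 * theta)
    w <- f / abs(min(sin(th_fine) + cc * cos(2 * th_fine)))
  }
  flow <- amplitude * w

  out <- tibble::tibble(phase_s = theta * period / (2 * pi), flow_m3s = flow)
  structure(
    out,
    period = period,
    angular_frequency = 2 * pi / period,
    amplitude = amplitude,
    shape = shape,
    peak_systolic_flow = min(flow),
    peak_diastolic_flow = max(flow),
    class = c("pulsation_waveform", class(out))
  )
}

#' Write / read a pulsation waveform as delimited text
#' @param waveform A `pulsation_waveform`.
#' @param path File path.
#' @export
write_waveform <- function(waveform, path) {
  readr::write_tsv(waveform[, c("phase_s", "flow_m3s")], path)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("phase_s", "flow_m3s") %in% names(x))) {
    rlang::abort("Waveform file must contain columns phase_s, flow_m3s.")
  }
  dt <- diff(x$phase_s)
  period <- x$phase_s[nrow(x)] + dt[1]
  structure(
    tibble::as_tibble(x),
    period = period,
    angular_frequency = 2 * pi / period,
    amplitude = max(abs(x$flow_m3s)),
    peak_systolic_flow = min(x$flow_m3s),
    peak_diastolic_flow = max(x$flow_m3s),
    class = c("pulsation_waveform", class(tibble::tibble()))
  )
}
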