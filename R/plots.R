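# ggplot2 displays for the main result types.

#' Plot an axial neuroaxis profile
#'
#' Area, perimeter and hydraulic diameter against distance from the foramen
#' magnum.
#'
#' @param profile A [neuraxis_profile()].
#' @return A ggplot object.
#' @export
plot_profile <- function(profile) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(profile,
      `area (cm^2)` = .data$area_m2 * 1e4,
      `perimeter (cm)` = .data$perimeter_m * 1e2,
      `hydraulic diameter (mm)` = .data$dh_m * 1e3
    ),
    cols = c("area (cm^2)", "perimeter (cm)", "hydraulic diameter (mm)"),
    names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$z_m * 100, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(
      x = "distance from foramen magnum (cm, negative caudal)", y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a steady-streaming profile
#' @param streaming A `streaming_profile`.
#' @return A ggplot object.
#' @export
plot_streaming <- function(streaming) {
  ggplot2::ggplot(
    streaming, ggplot2::aes(.data$z_m * 100, .data$uss_ms * 1e3)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(
      x = "distance from foramen magnum (cm)",
      y = expression(U[ss] ~ "(mm/s)")
    ) +
    ggplot2::theme_minimal()
}

#' Spatio-temporal concentration map display
#'
#' @param map A long concentration map (`time_s`, `z_m`, `alpha`) or a
#'   `tracer_sim`.
#' @return A ggplot object (position versus time, fill = concentration %).
#' @export
plot_concentration_map <- function(map) {
  if (inherits(map, "tracer_sim")) map <- axial_concentration(map)
  ggplot2::ggplot(
    map,
    ggplot2::aes(.data$time_s / 3600, .data$z_m * 100,
      fill = .data$alpha * 100
    )
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "tracer (%)") +
    ggplot2::labs(
      x = "time (h)", y = "distance from foramen magnum (cm)"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tracer_sim <- function(object, ...) {
  plot_concentration_map(object)
}

#' Scatter and Bland-Altman panels for an agreement fit
#'
#' @param object An [agreement_stats()] object.
#' @param ... Unused.
#' @return A ggplot object with two panels: B against A with the fitted
#'   line, and difference against mean with bias and limits of agreement.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.agreement_stats <- function(object, ...) {
  p <- object$pairs
  d <- tibble::tibble(
    panel = c(rep("regression", nrow(p)), rep("Bland-Altman", nrow(p))),
    x = c(p$a, (p$a + p$b) / 2),
    y = c(p$b, p$b - p$a)
  )
  lines <- tibble::tibble(
    panel = c("regression", rep("Bland-Altman", 3)),
    slope = c(object$slope, 0, 0, 0),
    intercept = c(
      object$intercept, object$bias, object$loa_lower, object$loa_upper
    ),
    kind = c("fit", "bias", "loa", "loa")
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(
        slope = .data$slope, intercept = .data$intercept,
        linetype = .data$kind
      )
    ) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
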