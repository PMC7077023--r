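# Agreement statistics between two spatio-temporal concentration maps
# (e.g. the frozen-field simulation versus the quantified imaging
# emulation): ordinary least-squares regression of map B on map A plus
# Bland-Altman bias and 95% limits of agreement.

#' Pair two concentration maps on a shared grid
#'
#' Joins two long concentration maps (`time_s`, `z_m`, `alpha`) on their
#' time-by-position grid, which must match exactly, and optionally excludes
#' points through a mask.
#'
#' @param map_a,map_b Long tibbles with columns `time_s`, `z_m`, `alpha`.
#' @param mask Optional predicate `function(time_s, z_m)` returning `TRUE`
#'   for pairs to keep (e.g. excluding the cranial extremes).
#' @return A tibble with `time_s`, `z_m`, `a`, `b`. Zero rows (with a
#'   warning) if the mask excludes everything.
#' @export
paired_flatten <- function(map_a, map_b, mask = NULL) {
  need <- c("time_s", "z_m", "alpha")
  if (!all(need %in% names(map_a)) || !all(need %in% names(map_b))) {
    rlang::abort("Maps must have columns time_s, z_m, alpha.")
  }
  a <- dplyr::arrange(map_a, .data$time_s, .data$z_m)
  b <- dplyr::arrange(map_b, .data$time_s, .data$z_m)
  keys_a <- paste(signif(a$time_s, 10), signif(a$z_m, 10))
  keys_b <- paste(signif(b$time_s, 10), signif(b$z_m, 10))
  common <- intersect(keys_a, keys_b)
  if (length(common) < length(keys_a) || length(common) < length(keys_b)) {
    if (length(common) == 0) {
      rlang::abort("Maps share no grid points; grids do not conform.")
    }
  }
  a <- a[keys_a %in% common, ]
  b <- b[keys_b %in% common, ]
  if (!isTRUE(all.equal(a$time_s, b$time_s)) ||
    !isTRUE(all.equal(a$z_m, b$z_m))) {
    rlang::abort("Concentration map grids do not conform.")
  }
  out <- tibble::tibble(
    time_s = a$time_s, z_m = a$z_m, a = a$alpha, b = b$alpha
  )
  if (!is.null(mask)) {
    keep <- mask(out$time_s, out$z_m)
    out <- out[keep, ]
  }
  out <- out[stats::complete.cases(out), ]
  if (nrow(out) == 0) {
    rlang::warn("Mask excluded every paired point; returning zero rows.")
  }
  out
}

#' Agreement statistics between two concentration maps
#'
#' Ordinary least-squares regression of B on A (optionally through the
#' origin) with the coefficient of determination, plus Bland-Altman
#' analysis: the bias is the mean difference B - A and the 95% limits of
#' agreement are `bias +/- 1.96 * SD` of the differences.
#'
#' @param pairs A paired tibble from [paired_flatten()] (or anything with
#'   numeric columns `a` and `b`).
#' @param through_origin Force the regression through the origin.
#' @return An `agreement_stats` object; see [tidy.agreement_stats()] and
#'   [glance.agreement_stats()].
#' @export
agreement_stats <- function(pairs, through_origin = FALSE) {
  if (nrow(pairs) < 3) {
    rlang::abort("At least three paired points are required.")
  }
  if (stats::var(pairs$a) == 0) {
    rlang::abort("Degenerate pairs: no variance in map A.")
  }
  fit <- if (through_origin) {
    stats::lm(b ~ a + 0, data = pairs)
  } else {
    stats::lm(b ~ a, data = pairs)
  }
  coefs <- stats::coef(fit)
  slope <- unname(coefs[["a"]])
  intercept <- if (through_origin) 0 else unname(coefs[["(Intercept)"]])
  rss <- sum(stats::residuals(fit)^2)
  tss <- if (through_origin) sum(pairs$b^2) else
    sum((pairs$b - mean(pairs$b))^2)
  r2 <- 1 - rss / tss
  d <- pairs$b - pairs$a
  bias <- mean(d)
  sd_d <- stats::sd(d)
  structure(
    list(
      slope = slope, intercept = intercept, r_squared = r2,
      bias = bias, sd_diff = sd_d,
      loa_lower = bias - 1.96 * sd_d, loa_upper = bias + 1.96 * sd_d,
      n_points = nrow(pairs), through_origin = through_origin,
      pairs = pairs, fit = fit
    ),
    class = "agreement_stats"
  )
}

#' Regression part of the agreement analysis
#' @inheritParams agreement_stats
#' @return A one-row tibble with `slope`, `intercept`, `r_squared`,
#'   `n_points`.
#' @export
agreement_regression <- function(pairs, through_origin = FALSE) {
  x <- agreement_stats(pairs, through_origin = through_origin)
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
    n_points = x$n_points
  )
}

#' Bland-Altman part of the agreement analysis
#' @inheritParams agreement_stats
#' @return A one-row tibble with `bias`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, `n_points`.
#' @export
bland_altman <- function(pairs) {
  if (nrow(pairs) < 3) {
    rlang::abort("At least three paired points are required.")
  }
  d <- pairs$b - pairs$a
  bias <- mean(d)
  sd_d <- stats::sd(d)
  tibble::tibble(
    bias = bias, sd_diff = sd_d,
    loa_lower = bias - 1.96 * sd_d, loa_upper = bias + 1.96 * sd_d,
    n_points = nrow(pairs)
  )
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat("<agreement_stats> n =", x$n_points, "\n")
  cat(sprintf(
    "  regression: slope %.3f, intercept %.4g, R^2 %.3f\n",
    x$slope, x$intercept, x$r_squared
  ))
  cat(sprintf(
    "  Bland-Altman: bias %.4g, 95%% LoA [%.4g, %.4g]\n",
    x$bias, x$loa_lower, x$loa_upper
  ))
  invisible(x)
}

#' Tidy an agreement fit
#'
#' @param x An [agreement_stats()] object.
#' @param ... Unused.
#' @return A tibble with one row per quantity (`term`, `estimate`).
#' @importFrom generics tidy
#' @export
tidy.agreement_stats <- function(x, ...) {
  tibble::tibble(
    term = c(
      "slope", "intercept", "r_squared", "bias", "loa_lower", "loa_upper"
    ),
    estimate = c(
      x$slope, x$intercept, x$r_squared, x$bias, x$loa_lower, x$loa_upper
    )
  )
}

#' One-row summary of an agreement fit
#'
#' @param x An [agreement_stats()] object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @importFrom generics glance
#' @export
glance.agreement_stats <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
    bias = x$bias, loa_lower = x$loa_lower, loa_upper = x$loa_upper,
    n_points = x$n_points
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
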