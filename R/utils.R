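# Internal helpers shared across modules.

ML_PER_M3 <- 1e6
M3S_PER_ML_MIN <- 1e-6 / 60

#' @keywords internal
ml_min_to_m3s <- function(x) x * M3S_PER_ML_MIN

#' @keywords internal
m3_to_ml <- function(x) x * ML_PER_M3

stop_if_not_positive <- function(..., .allow_zero = FALSE) {
  vals <- list(...)
  nms <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || anyNA(v)) {
      rlang::abort(sprintf("`%s` must be numeric and non-missing.", nms[i]))
    }
    bad <- if (.allow_zero) any(v < 0) else any(v <= 0)
    if (bad) {
      rlang::abort(sprintf(
        "`%s` must be strictly positive%s.", nms[i],
        if (.allow_zero) " or zero" else ""
      ))
    }
  }
  invisible(TRUE)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Truncated Gaussian weights for distributing a port flow over grid cells.
# Returns a vector over z that sums to one.
port_kernel <- function(z, centre, halfwidth) {
  w <- exp(-((z - centre) / halfwidth)^2)
  w[abs(z - centre) > 3 * halfwidth] <- 0
  s <- sum(w)
  if (s <= 0) {
    rlang::abort("Port location falls outside the axial grid.")
  }
  w / s
}
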