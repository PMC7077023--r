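# Shared fixtures: small hand-built geometries and streaming profiles so the
# transport solver can be exercised against closed forms cheaply.

# Uniform tube profile with full neuraxis_profile semantics. The grid spans
# mostly negative (spinal) z with an optional cranial tail.
make_tube_profile <- function(n = 20, dz = 0.03, area = 1.5e-4,
                              dh = 6e-3, z_max = 0.1) {
  z <- seq(z_max - (n - 0.5) * dz, by = dz, length.out = n)
  out <- tibble::tibble(
    z_m = z,
    region = ifelse(z < 0, "spinal", "cranial"),
    area_m2 = rep(area, n),
    perimeter_m = rep(4 * area / dh, n),
    dh_m = rep(dh, n),
    slice_volume_m3 = rep(area * dz, n)
  )
  structure(
    out,
    dz = dz,
    spinal_volume_m3 = sum(out$slice_volume_m3[out$region == "spinal"]),
    cranial_volume_m3 = sum(out$slice_volume_m3[out$region == "cranial"]),
    class = c("neuraxis_profile", class(out))
  )
}

# Constant-level streaming profile on a given grid.
make_uniform_streaming <- function(profile, uss = 2e-4) {
  out <- tibble::tibble(
    z_m = profile$z_m,
    uss_ms = rep(uss, nrow(profile)),
    qss = rep(NA_real_, nrow(profile)),
    qnet_m3s = rep(0, nrow(profile))
  )
  structure(out, class = c("streaming_profile", class(out)))
}

# Single-cell "stirred tank" profile for closed-form decay checks.
make_tank_profile <- function(volume = 3e-4) {
  dz <- 0.1
  out <- tibble::tibble(
    z_m = -0.05, region = "spinal", area_m2 = volume / dz,
    perimeter_m = 4 * sqrt(pi * volume / dz), dh_m = 0.01,
    slice_volume_m3 = volume
  )
  structure(out,
    dz = dz, spinal_volume_m3 = volume, cranial_volume_m3 = 0,
    class = c("neuraxis_profile", class(out))
  )
}

# Random small periodic velocity field for streaming-operator oracles.
make_random_field <- function(n_cells, n_slices, n_phases, seed) {
  set.seed(seed)
  velocity_field(
    u_z = matrix(stats::rnorm(n_cells * n_phases, sd = 1e-3),
      n_cells, n_phases
    ),
    cell_volume = stats::runif(n_cells, 1e-9, 5e-9),
    cell_slice = sample.int(n_slices, n_cells, replace = TRUE),
    phase_s = seq(0, 0.9, length.out = n_phases + 1)[seq_len(n_phases)]
  )
}

# Independent brute-force implementation of the streaming average operator:
# plain double loop over slices and cells.
brute_force_uss <- function(field, n_slices) {
  umean <- numeric(nrow(field$u_z))
  for (i in seq_len(nrow(field$u_z))) {
    umean[i] <- mean(field$u_z[i, ])
  }
  out <- numeric(n_slices)
  for (s in seq_len(n_slices)) {
    num <- 0
    den <- 0
    for (i in seq_len(nrow(field$u_z))) {
      if (field$cell_slice[i] == s) {
        num <- num + abs(umean[i]) * field$cell_volume[i]
        den <- den + field$cell_volume[i]
      }
    }
    out[s] <- if (den > 0) num / den else 0
  }
  out
}
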