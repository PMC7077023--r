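# A short lumbar-drain run provides a spatio-temporally varying field for
# the imaging round-trips.
imaging_sim <- local({
  prof <- neuraxis_profile(dz = 0.006)
  th <- therapy_config("lumbar_drain")
  strm <- parametric_streaming(prof, th)
  simulate_transport(prof, strm, th,
    transport_closure(sweep_efficiency = 0.44, d_cranial = 2.3e-7),
    duration_s = 7200, store_every_s = 600
  )
})

test_that("zero concentration imaged as pure background plus noise", {
  prof <- make_tube_profile(n = 10)
  strm <- make_uniform_streaming(prof)
  sim <- simulate_transport(prof, strm, therapy_config("none"),
    duration_s = 1800, store_every_s = 600, initial_fraction = 0
  )
  opt <- optics_config(noise_sd = 0, background_texture_sd = 0)
  stack <- synthesize_stack(sim, opt, seed = 1)
  expect_equal(
    as.numeric(stack$intensity),
    rep(opt$background_level, length(stack$intensity)),
    tolerance = 1e-12
  )
})

test_that("noise-free constant field gives spatially flat intensity", {
  prof <- make_tube_profile(n = 10)
  strm <- make_uniform_streaming(prof)
  sim <- simulate_transport(prof, strm, therapy_config("none"),
    duration_s = 1800, store_every_s = 600, initial_fraction = 0.08
  )
  opt <- optics_config(
    noise_sd = 0, background_texture_sd = 0, bleach_rate = 0
  )
  stack <- synthesize_stack(sim, opt, seed = 1)
  frame <- stack$intensity[, , 3]
  expect_lt(diff(range(frame)), 1e-9)
  expect_equal(
    frame[1, 1], opt$background_level + opt$gain * 0.08,
    tolerance = 1e-12
  )
})

test_that("intensity normalisation inverts exactly at the anchors", {
  # hand-built stack: three pixels at background, midpoint and baseline
  nt <- 4
  times <- seq(0, 900, by = 300)
  i0 <- matrix(100, 2, 3)
  stack <- structure(
    list(
      intensity = array(0, dim = c(2, 3, nt)),
      timestamps = times,
      background = i0,
      baseline_series = rep(600, nt), # no bleach
      baseline_background = 100,
      pixel_z = c(-0.3, 0, 0.3),
      reference_fraction = 0.1
    ),
    class = "image_stack"
  )
  for (t in seq_len(nt)) {
    stack$intensity[, , t] <- matrix(c(100, 100, 350, 350, 600, 600), 2, 3)
  }
  map <- quantify_stack(stack, z_grid = c(-0.3, 0, 0.3))
  one_t <- map[map$time_s == 0, ]
  expect_equal(one_t$alpha, c(0, 0.05, 0.1), tolerance = 1e-9)
})

test_that("baseline decay fit recovers exact and noisy exponentials", {
  t <- seq(0, 86400, by = 300)
  # constant series -> zero rate
  fit0 <- baseline_decay_fit(t, rep(500, length(t)), background = 100)
  expect_equal(fit0$rate, 0, tolerance = 1e-12)
  # exact exponential -> rate recovered to 1e-6 relative
  rate <- 2.3e-6
  ib <- 100 + 450 * exp(-rate * t)
  fit <- baseline_decay_fit(t, ib, background = 100)
  expect_equal(fit$rate, rate, tolerance = 1e-6)
  expect_equal(fit$amplitude, 450, tolerance = 1e-6)
  expect_equal(fit$predict(c(0, 43200)), 100 + 450 * exp(-rate * c(0, 43200)),
    tolerance = 1e-6
  )
  # noisy exponential -> within 3 fitted standard errors
  set.seed(5)
  noisy <- ib + rnorm(length(t), sd = 0.5)
  fitn <- baseline_decay_fit(t, noisy, background = 100)
  expect_lt(abs(fitn$rate - rate), 3 * fitn$rate_se)
  # increasing series is rejected
  expect_error(
    baseline_decay_fit(t[1:5], c(200, 210, 220, 230, 240), 100),
    "increases"
  )
  expect_error(baseline_decay_fit(t[1:2], c(2, 1)), "three")
})

test_that("ideal optics give an exact quantify-synthesize identity", {
  sim <- imaging_sim
  opt <- optics_config(
    noise_sd = 0, background_texture_sd = 0, distortion = 0,
    bleach_rate = 1e-6, n_cols = length(sim$z_m), n_rows = 4
  )
  stack <- synthesize_stack(sim, opt, seed = 2)
  # with one pixel column per grid cell, image-side slab averaging equals
  # the volume-weighted axial averaging of the underlying field
  map <- quantify_stack(stack, z_grid = sim$z_m, slab_thickness = 0.006)
  truth <- axial_concentration(sim, slab_thickness = 0.006)
  pairs <- paired_flatten(truth, map)
  expect_gt(nrow(pairs), 1000)
  expect_lt(max(abs(pairs$a - pairs$b)), 1e-10)
})

test_that("noisy round-trip recovers the field within the noise bound", {
  sim <- imaging_sim
  opt <- optics_config() # defaults: noise, bleach, distortion
  stack <- synthesize_stack(sim, opt, seed = 3)
  map <- quantify_stack(stack, z_grid = unique(
    axial_concentration(sim, slab_thickness = 0.006)$z_m
  ), slab_thickness = 0.006)
  truth <- axial_concentration(sim, slab_thickness = 0.006)
  pairs <- paired_flatten(truth, map)
  rmse <- sqrt(mean((pairs$b - pairs$a)^2))
  # pixel noise propagated through the normalisation and averaging:
  # sd(alpha_pixel) = noise_sd / (gain * bleach); averaged over rows and
  # the columns mapped to each slab (>= 1), plus margin for the warp
  # resampling bias
  worst_bleach <- exp(-opt$bleach_rate * max(sim$time_s))
  bound <- 2 * opt$noise_sd / (opt$gain * worst_bleach * sqrt(opt$n_rows))
  expect_lt(rmse, bound + 5e-4)
  # same seed reproduces the stack bit-for-bit
  stack2 <- synthesize_stack(sim, opt, seed = 3)
  expect_identical(stack$intensity, stack2$intensity)
})
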