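test_that("closed system leaves the field unchanged", {
  prof <- make_tube_profile(n = 15)
  strm <- make_uniform_streaming(prof)
  none <- therapy_config("none")
  sim <- simulate_transport(prof, strm, none,
    duration_s = 1800, store_every_s = 600
  )
  expect_equal(sim$map[nrow(sim$map), ], rep(0.1, 15), tolerance = 1e-10)
  expect_equal(sim$budget$removed_m3, 0)
})

test_that("initial state is uniform with the correct tracer inventory", {
  prof <- neuraxis_profile()
  st <- initialize_tracer(prof, 0.1)
  expect_equal(unique(st$alpha), 0.1)
  expect_equal(sum(st$alpha * prof$slice_volume_m3) * 1e6, 32.19,
    tolerance = 1e-9
  )
  expect_equal(initialize_tracer(prof, 0)$alpha, rep(0, nrow(prof)))
  expect_error(initialize_tracer(prof, 1.5), "\\[0, 1\\]")
})

test_that("stirred tank with clean return decays exponentially", {
  prof <- make_tank_profile(volume = 3e-4)
  strm <- make_uniform_streaming(prof)
  th <- therapy_config("neurapheresis",
    aspiration_ml_min = 2, return_ml_min = 2, production_ml_min = 0,
    z_aspiration = -0.05, z_return = -0.05
  )
  cl <- transport_closure(sweep_efficiency = 1)
  sim <- simulate_transport(prof, strm, th, cl,
    duration_s = 7200, dt = 0.5, store_every_s = 600
  )
  q <- th$aspiration
  expected <- 0.1 * exp(-q * sim$time_s / 3e-4)
  expect_equal(as.numeric(sim$map[, 1]), expected, tolerance = 1e-3)
})

test_that("compiled and reference engines agree to machine precision", {
  prof <- make_tube_profile(n = 12, dz = 0.06, z_max = 0.12)
  strm <- make_uniform_streaming(prof)
  th <- therapy_config("lumbar_drain",
    z_aspiration = -0.3, z_production = 0.05
  )
  cl <- transport_closure(sweep_efficiency = 0.6, d_cranial = 3e-7)
  a <- simulate_transport(prof, strm, th, cl,
    duration_s = 1200, store_every_s = 300, engine = "cpp"
  )
  b <- simulate_transport(prof, strm, th, cl,
    duration_s = 1200, store_every_s = 300, engine = "r"
  )
  expect_equal(a$map, b$map, tolerance = 1e-13)
  expect_equal(a$removed_m3, b$removed_m3, tolerance = 1e-13)
})

test_that("single explicit step matches the reference engine and guards dt", {
  prof <- make_tube_profile(n = 10, dz = 0.06, z_max = 0.1)
  strm <- make_uniform_streaming(prof)
  th <- therapy_config("lumbar_drain",
    z_aspiration = -0.3, z_production = 0.05
  )
  st <- initialize_tracer(prof, 0.1)
  st2 <- transport_step(st, prof, strm, th, transport_closure(), dt = 0.5)
  expect_equal(st2$time_s, 0.5)
  expect_true(all(st2$alpha >= 0 & st2$alpha <= 0.1 + 1e-15))
  expect_error(
    transport_step(st, prof, strm, th, transport_closure(), dt = 1e7),
    "stability bound"
  )
})

test_that("tracer bookkeeping closes and the field stays bounded", {
  prof <- neuraxis_profile(dz = 0.006)
  for (mode in c("neurapheresis", "lumbar_drain")) {
    th <- therapy_config(mode)
    strm <- parametric_streaming(prof, th)
    sim <- simulate_transport(prof, strm, th,
      transport_closure(sweep_efficiency = 0.44, d_cranial = 2.3e-7),
      duration_s = 21600, store_every_s = 1800
    )
    expect_lt(sim$budget$conservation_residual, 1e-10)
    expect_true(all(sim$map >= -1e-12 & sim$map <= 0.1 + 1e-12))
    # monotone non-increasing inventory under clean injections
    inventory <- as.numeric(sim$map %*% sim$cell_volume_m3)
    expect_true(all(diff(inventory) <= 1e-15))
  }
})

test_that("well-mixed limit follows the closed-form exponential", {
  prof <- make_tube_profile(n = 25, dz = 0.03, z_max = 0.15)
  strm <- make_uniform_streaming(prof, uss = 2e-4)
  th <- therapy_config("neurapheresis",
    z_aspiration = -0.45, z_return = -0.15, z_production = 0.1
  )
  # huge mixing coefficient; full sweep so the aspiration throughput is the
  # only clearance pathway
  cl <- transport_closure(
    k_mix = 1e6, sweep_efficiency = 1, d_cranial = 0
  )
  sim <- simulate_transport(prof, strm, th, cl,
    duration_s = 21600, store_every_s = 3600
  )
  v_tot <- sum(prof$slice_volume_m3)
  g <- global_concentration(sim)
  expected <- 0.1 * exp(-th$aspiration * sim$time_s / v_tot)
  expect_equal(g[length(g)], expected[length(expected)],
    tolerance = 0.01
  )
})

test_that("slab averaging: identity, weighted mean and tower property", {
  prof <- make_tube_profile(n = 12, dz = 0.01, z_max = 0.06)
  out <- axial_concentration(rep(0.07, 12), prof, slab_thickness = 0.03)
  expect_equal(out$alpha, rep(0.07, 4))
  # hand-computed volume-weighted slab mean: (0.2*1 + 0.0*3) / 4 = 0.05
  prof2 <- make_tube_profile(n = 2, dz = 0.01, z_max = 0.0)
  prof2$slice_volume_m3 <- c(1e-6, 3e-6)
  out2 <- axial_concentration(c(0.2, 0), prof2, slab_thickness = 0.02)
  expect_equal(out2$alpha, 0.05)
  # slab averages recombine exactly to the global volume average
  set.seed(9)
  alpha <- runif(12, 0, 0.1)
  slabs <- axial_concentration(alpha, prof, slab_thickness = 0.03)
  vols <- rowsum(prof$slice_volume_m3, rep(1:4, each = 3))
  global_from_slabs <- sum(slabs$alpha * vols) / sum(vols)
  expect_equal(global_from_slabs,
    sum(alpha * prof$slice_volume_m3) / sum(prof$slice_volume_m3),
    tolerance = 1e-12
  )
  expect_error(
    axial_concentration(alpha, prof, slab_thickness = 0.025),
    "integer multiple"
  )
})

test_that("clearance summary reports the initial condition and regions", {
  prof <- neuraxis_profile(dz = 0.006)
  th <- therapy_config("neurapheresis")
  strm <- parametric_streaming(prof, th)
  sim <- simulate_transport(prof, strm, th,
    duration_s = 600, store_every_s = 300
  )
  cs <- clearance_summary(sim, prof)
  expect_equal(
    cs$alpha_pct[cs$time_s == 0], rep(10, 5),
    tolerance = 1e-9
  )
  expect_setequal(
    unique(cs$region), c("global", "spinal", "cranial", "interport", "T6")
  )
  bad <- tibble::tibble(region = "empty", z_min = 10, z_max = 11)
  expect_error(clearance_summary(sim, prof, bad), "no grid cells")
})

test_that("therapy configuration validates the global fluid balance", {
  expect_error(
    therapy_config("neurapheresis", aspiration_ml_min = 2.5),
    "balance"
  )
  expect_error(
    therapy_config("lumbar_drain", drain_ml_min = 0.5),
    "balance"
  )
  th <- therapy_config("neurapheresis")
  expect_equal(th$production + th$return_flow, th$aspiration + th$drain)
})
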