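test_that("cycle-mean velocity: constant, zero-mean and offset cases", {
  phases <- seq(0, 0.9, length.out = 37)[1:36]
  n <- 5
  const <- velocity_field(
    matrix(3e-4, n, 36), rep(1e-9, n), rep(1, n), phases
  )
  expect_equal(cycle_mean_velocity(const), rep(3e-4, n))
  sine <- velocity_field(
    matrix(sin(2 * pi * phases / 0.9), n, 36, byrow = TRUE) * 1e-3,
    rep(1e-9, n), rep(1, n), phases
  )
  expect_lt(max(abs(cycle_mean_velocity(sine))), 1e-12)
  offset <- velocity_field(
    t(1e-4 + 1e-3 * sin(2 * pi * phases / 0.9) %o% rep(1, n)),
    rep(1e-9, n), rep(1, n), phases
  )
  expect_equal(cycle_mean_velocity(offset), rep(1e-4, n), tolerance = 1e-9)
})

test_that("unequal phase spacing is rejected", {
  expect_error(
    velocity_field(
      matrix(0, 2, 3), rep(1e-9, 2), rep(1, 2), c(0, 0.1, 0.5)
    ),
    "equispaced"
  )
})

test_that("magnitude is taken per cell before cross-section averaging", {
  prof <- make_tube_profile(n = 2)
  phases <- c(0, 0.45)
  a <- 2.5e-4
  field <- velocity_field(
    matrix(c(a, -a, a, -a), 2, 2), # cells at +a and -a, constant in phase
    cell_volume = c(1e-9, 1e-9), cell_slice = c(1, 1), phase_s = phases
  )
  strm <- uss_profile(field, prof)
  expect_equal(strm$uss_ms[1], a) # not zero
  zero_field <- velocity_field(
    matrix(0, 4, 2), rep(1e-9, 4), c(1, 1, 2, 2), phases
  )
  expect_equal(uss_profile(zero_field, prof)$uss_ms, c(0, 0))
})

test_that("streaming average equals the brute-force double loop", {
  prof <- make_tube_profile(n = 8)
  for (seed in 1:5) {
    field <- make_random_field(
      n_cells = 200, n_slices = 8, n_phases = 12, seed = seed
    )
    strm <- uss_profile(field, prof)
    expect_equal(strm$uss_ms, brute_force_uss(field, 8), tolerance = 1e-12)
  }
})

test_that("unmapped cells are rejected", {
  prof <- make_tube_profile(n = 3)
  field <- make_random_field(10, 5, 4, seed = 1)
  expect_error(uss_profile(field, prof), "outside the profile grid")
})

test_that("Qss formula: zero, identity and direct substitution", {
  expect_equal(qss_profile(0, 1e-4, 1e-6), 0)
  expect_equal(qss_profile(2 * 1e-6 / 1e-4, 1e-4, 1e-6), 1)
  set.seed(3)
  u <- runif(10, 0, 1e-3)
  a <- runif(10, 1e-5, 1e-3)
  q <- 4.5e-6
  expect_equal(qss_profile(u, a, q), u * a / (2 * q), tolerance = 1e-12)
  expect_error(qss_profile(u, a, -1), "positive")
})

test_that("parametric streaming hits the calibrated inter-port means", {
  prof <- neuraxis_profile()
  nt <- therapy_config("neurapheresis")
  ld <- therapy_config("lumbar_drain")
  snt <- parametric_streaming(prof, nt)
  sld <- parametric_streaming(prof, ld)
  ip <- prof$z_m >= nt$z_aspiration & prof$z_m <= nt$z_return
  m_nt <- mean(snt$uss_ms[ip])
  m_ld <- mean(sld$uss_ms[ip])
  expect_equal(m_nt * 1e3, 0.37, tolerance = 0.01)
  expect_equal(m_ld * 1e3, 0.23, tolerance = 0.01)
  # the filtration loop raises inter-port streaming by 60% +/- 2%
  expect_equal(m_nt / m_ld, 1.6087, tolerance = 0.02)
})

test_that("cranial streaming is attenuated ~50x relative to the spine", {
  prof <- neuraxis_profile()
  for (mode in c("neurapheresis", "lumbar_drain")) {
    s <- parametric_streaming(prof, therapy_config(mode))
    sp <- prof$region == "spinal"
    ratio <- mean(s$uss_ms[sp]) / mean(s$uss_ms[!sp])
    expect_equal(ratio, 50, tolerance = 0.05)
  }
})

test_that("ports outside the grid are a configuration failure", {
  prof <- make_tube_profile(n = 5, dz = 0.01, z_max = 0.05)
  nt <- therapy_config("neurapheresis") # aspiration at -0.44, off-grid
  expect_error(parametric_streaming(prof, nt), "outside the axial grid")
})

test_that("net continuity flow conserves and vanishes at both ends", {
  prof <- neuraxis_profile()
  for (mode in c("neurapheresis", "lumbar_drain")) {
    th <- therapy_config(mode)
    fl <- net_bulk_flow(prof, th)
    n <- nrow(prof)
    expect_equal(fl$q_face[1], 0)
    expect_equal(fl$q_face[n + 1], 0)
    # discrete continuity: flux divergence equals the source density
    div <- diff(fl$q_face)
    expect_equal(div, fl$source_m3s, tolerance = 1e-12)
    # piecewise constant away from the port kernels
    mid <- prof$z_m > -0.35 & prof$z_m < -0.25
    expect_lt(diff(range(fl$q_face[c(mid, FALSE)])), 1e-18)
    # inter-port magnitude equals the aspiration-side throughput
    ip <- prof$z_m > -0.40 & prof$z_m < -0.20
    expected <- switch(mode,
      neurapheresis = -(th$aspiration + th$drain),
      lumbar_drain = -(th$aspiration + th$drain)
    )
    expect_equal(mean(fl$q_face[c(ip, FALSE)]), expected, tolerance = 1e-9)
  }
})
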