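# The similitude chain is checked two ways: each operation against direct
# substitution of its defining formula (independent code path, 1e-12), and
# the default table against frozen hand-computed values for the reference
# constants (nu = 0.89e-6 m^2/s, omega = 6.98 1/s, P = 152.6,
# D = 4.25e-10 / 1.02e-10 m^2/s, L = 2 / 5.87 mm).

test_that("individual dimensionless groups match direct substitution", {
  set.seed(11)
  for (i in 1:25) {
    nu <- runif(1, 1e-7, 1e-5)
    d <- runif(1, 1e-11, 1e-8)
    len <- runif(1, 5e-4, 1e-2)
    om <- runif(1, 1, 10)
    p <- runif(1, 10, 500)
    h <- runif(1, 1e-6, 1)
    sc <- schmidt_number(nu, d)
    b2 <- oscillatory_peclet_sq(len, om, d)
    a2 <- womersley_sq(b2, sc)
    rm <- dispersion_enhancement(p, sc, a2)
    de <- effective_diffusivity(rm, d)
    expect_equal(sc, nu / d, tolerance = 1e-12)
    expect_equal(b2, (len / 2)^2 * om / d, tolerance = 1e-12)
    expect_equal(a2, (len / 2)^2 * om / nu, tolerance = 1e-12)
    expect_equal(rm, p^2 * sc / a2, tolerance = 1e-12)
    expect_equal(de, (1 + rm) * d, tolerance = 1e-12)
    expect_equal(sherwood_number(h, de, len), h * len / de,
      tolerance = 1e-12
    )
  }
})

test_that("identity and limit cases behave", {
  expect_equal(schmidt_number(1e-6, 1e-6), 1)
  expect_equal(womersley_sq(2094, 2094), 1)
  expect_equal(dispersion_enhancement(0, 2000, 7.8), 0)
  expect_equal(effective_diffusivity(0, 4.25e-10), 4.25e-10)
  expect_equal(sherwood_number(2e-7 / 5.87e-3, 2e-7, 5.87e-3), 1)
  # beta^2 -> 0 as D grows
  expect_lt(oscillatory_peclet_sq(5.87e-3, 6.98, 1), 1e-4)
  # Sh linear in h
  expect_equal(
    sherwood_number(2e-4, 3e-4, 5.87e-3),
    2 * sherwood_number(1e-4, 3e-4, 5.87e-3)
  )
  expect_error(dispersion_enhancement(152.6, 2094, 0), "positive")
})

test_that("Schmidt numbers for the two species match hand division", {
  expect_equal(schmidt_number(0.89e-6, 4.25e-10), 2094.1, tolerance = 1e-4)
  expect_equal(schmidt_number(0.89e-6, 1.02e-10), 8725.5, tolerance = 1e-4)
})

test_that("default similitude table reproduces the reference values", {
  st <- similitude_table()
  pick <- function(region, species, col) {
    st[[col]][st$region == region & st$species == species]
  }
  # squared Womersley numbers, identical across species per region
  expect_equal(pick("cortical", "tracer", "alpha_sq"), 7.84,
    tolerance = 5e-4
  )
  expect_equal(pick("spinal", "tracer", "alpha_sq"), 67.56,
    tolerance = 5e-4
  )
  expect_equal(
    pick("cortical", "tracer", "alpha_sq"),
    pick("cortical", "hemoglobin", "alpha_sq")
  )
  expect_equal(
    pick("spinal", "tracer", "alpha_sq"),
    pick("spinal", "hemoglobin", "alpha_sq")
  )
  # oscillatory Peclet numbers squared (3 s.f.)
  expect_equal(pick("cortical", "tracer", "beta_sq"), 1.64e4,
    tolerance = 5e-3
  )
  expect_equal(pick("cortical", "hemoglobin", "beta_sq"), 6.84e4,
    tolerance = 5e-3
  )
  expect_equal(pick("spinal", "tracer", "beta_sq"), 1.41e5,
    tolerance = 5e-3
  )
  expect_equal(pick("spinal", "hemoglobin", "beta_sq"), 5.89e5,
    tolerance = 5e-3
  )
  # maximum enhancements
  expect_equal(pick("cortical", "tracer", "r_max"), 6.22e6,
    tolerance = 5e-3
  )
  expect_equal(pick("cortical", "hemoglobin", "r_max"), 2.59e7,
    tolerance = 5e-3
  )
  expect_equal(pick("spinal", "tracer", "r_max"), 7.2e5, tolerance = 5e-3)
  expect_equal(pick("spinal", "hemoglobin", "r_max"), 3.0e6,
    tolerance = 5e-3
  )
  # effective diffusivities
  expect_equal(signif(pick("cortical", "tracer", "d_eff_m2s"), 2), 0.0026)
  expect_equal(pick("spinal", "tracer", "d_eff_m2s"), 3.0677e-4,
    tolerance = 1e-4
  )
})

test_that("effective diffusivity is species-independent per region", {
  st <- similitude_table()
  rel <- attr(st, "similitude_rel_diff")
  expect_true(all(rel < 0.02))
  # algebraic reason: R_max * D = P^2 nu / alpha^2 has no D in it
  cs <- dispersion_case("spinal", "tracer", 5.87e-3, 4.25e-10)
  sc <- schmidt_number(cs$nu, cs$d_mol)
  a2 <- womersley_sq(
    oscillatory_peclet_sq(cs$length_scale, cs$omega, cs$d_mol), sc
  )
  expect_equal(
    dispersion_enhancement(cs$p, sc, a2) * cs$d_mol,
    cs$p^2 * cs$nu / a2,
    tolerance = 1e-12
  )
})

test_that("incomplete case sets are rejected", {
  cases <- default_dispersion_cases()[c(1, 2)] # both tracer rows only
  expect_error(similitude_table(cases), "missing a species")
})

test_that("sherwood accepts both velocity-scale conventions", {
  # streaming-derived scale
  expect_equal(sherwood_number(5.02e-4, 3.0677e-4, 5.87e-3), 9.6e-3,
    tolerance = 1e-3
  )
  # peak-systolic scale is selectable via h in the case definition
  cases <- default_dispersion_cases(h_cortical = 0.26, h_spinal = 2.4)
  st <- similitude_table(cases)
  expect_true(all(is.finite(st$sherwood)))
})
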