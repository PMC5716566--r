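test_that("geometry factor matches brute-force segment quadrature", {
  cases <- expand.grid(r = c(0.3, 1, 2, 7), theta = c(5, 30, 90, 150),
                       L = c(0.3, 0.4))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], expect_lt(
      rel_diff(geometry_factor(r, theta, L), quad_geometry_factor(r, theta, L)),
      1e-6))
  }
  # spec'd spot cases
  expect_lt(rel_diff(geometry_factor(1, 90, 0.3),
                     quad_geometry_factor(1, 90, 0.3)), 1e-6)
  expect_lt(rel_diff(geometry_factor(2, 30, 0.4),
                     quad_geometry_factor(2, 30, 0.4)), 1e-6)
})

test_that("geometry factor limits: point source, on-axis closed form, far field", {
  expect_identical(geometry_factor(1, 90, 0), 1)
  expect_equal(geometry_factor(2, 37, 0), 0.25)
  # on-axis closed form 1/(r^2 - L^2/4)
  expect_equal(geometry_factor(1, 0, 0.3), 1 / (1 - 0.3^2 / 4))
  expect_equal(geometry_factor(0.5, 180, 0.3), 1 / (0.25 - 0.3^2 / 4))
  # G_L * r^2 -> 1 as r -> infinity (checked at r = 100 L)
  for (L in c(0.3, 0.4)) {
    r <- 100 * L
    expect_equal(geometry_factor(r, 63, L) * r^2, 1, tolerance = 1e-4)
  }
})

test_that("points inside the active segment are rejected", {
  expect_error(geometry_factor(0.1, 0, 0.3), "inside the active segment")
  expect_error(geometry_factor(0.14, 180, 0.3), "inside the active segment")
  expect_error(geometry_factor(-1, 90, 0.3), "r > 0")
  # just beyond the tip is fine
  expect_gt(geometry_factor(0.16, 0, 0.3), 0)
})

test_that("radial interpolation is exact at nodes, log-linear between them", {
  iai <- load_source_model("IAI-125A")$radial
  expect_equal(interp_radial(iai, 0.50), 1.038)
  expect_identical(interp_radial(iai, 1.0), 1.0)
  # independent log-space fit between (0.50, 1.038) and (0.60, 1.032);
  # the table's own held-out node at 0.55 (1.034) agrees to ~1e-3
  hand <- exp((log(1.038) + log(1.032)) / 2)
  sub <- radial_dose_table(c(0.50, 0.60, 1.0), c(1.038, 1.032, 1.0))
  expect_equal(interp_radial(sub, 0.55), hand, tolerance = 1e-12)
  expect_equal(interp_radial(iai, 0.55), 1.034)
  expect_equal(hand, 1.034, tolerance = 1e-3)
})

test_that("radial interpolation clamps below the grid and extrapolates beyond it", {
  tab <- radial_dose_table(c(0.5, 1, 2, 4), c(1.04, 1, 0.8, 0.5))
  expect_equal(interp_radial(tab, 0.05), 1.04)            # clamp
  # log-linear continuation of the last segment
  slope <- (log(0.5) - log(0.8)) / 2
  expect_equal(interp_radial(tab, 6), exp(log(0.5) + 2 * slope))
  # continuity across the last node
  expect_equal(interp_radial(tab, 4 - 1e-9), interp_radial(tab, 4 + 1e-9),
               tolerance = 1e-6)
})

test_that("radial interpolation preserves monotone table segments", {
  iai <- load_source_model("IAI-125A")$radial
  r <- seq(1.0, 10, by = 0.01)   # g decreases monotonically beyond 1 cm
  g <- interp_radial(iai, r)
  expect_true(all(diff(g) < 0))
})

test_that("anisotropy interpolation honors sentinel, normalization and mirror symmetry", {
  sent <- anisotropy_sentinel()
  expect_equal(interp_anisotropy(sent, c(0.3, 2, 8), c(1, 90, 179)),
               c(1, 1, 1))
  tab <- anisotropy_table(c(0.5, 1, 5), c(0, 30, 60, 90),
                          matrix(c(0.61, 0.64, 0.71,
                                   0.83, 0.85, 0.88,
                                   0.955, 0.96, 0.97,
                                   1, 1, 1), 3, 4))
  expect_equal(interp_anisotropy(tab, c(0.5, 1, 5), 90), c(1, 1, 1))
  expect_equal(interp_anisotropy(tab, 0.7, 30), interp_anisotropy(tab, 0.7, 150))
  # exact at grid nodes, clamped outside the radial range
  expect_equal(interp_anisotropy(tab, 1, 30), 0.85)
  expect_equal(interp_anisotropy(tab, 0.1, 0), 0.61)
  expect_equal(interp_anisotropy(tab, 50, 60), 0.97)
  # bilinear between nodes
  expect_equal(interp_anisotropy(tab, 0.75, 45),
               mean(c(0.83, 0.85, 0.955, 0.96)))
})

test_that("single-seed dose rate follows the TG-43 normalization and term product", {
  iai <- load_source_model("IAI-125A")
  # at the reference point the dose rate equals the dose-rate constant
  expect_equal(dose_rate_single(iai, 1, 90), 0.979)
  # term-by-term assembly at (0.5 cm, 90 deg) with sentinel anisotropy
  gl_ratio <- quad_geometry_factor(0.5, 90, 0.3) / quad_geometry_factor(1, 90, 0.3)
  expect_equal(dose_rate_single(iai, 0.5, 90), 0.979 * gl_ratio * 1.038,
               tolerance = 1e-6)
  # linearity in the dose-rate constant
  iai2 <- iai
  iai2$dose_rate_constant <- 2 * iai$dose_rate_constant
  r <- c(0.3, 1, 2, 6); th <- c(20, 90, 120, 70)
  expect_equal(dose_rate_single(iai2, r, th), 2 * dose_rate_single(iai, r, th))
})

test_that("inverse-square limit holds for the flat point source", {
  toy <- make_toy_source()
  r <- c(0.2, 0.5, 1, 2, 5, 9)
  expect_equal(dose_rate_single(toy, r, 90), 1 / r^2)
  expect_equal(dose_rate_single(toy, 2, 37), 0.25)
  expect_equal(dose_rate_single(toy, 1, 37), 1)
})

test_that("decay integral matches quadrature and its closed-form limits", {
  expect_lt(rel_diff(decay_integral(59.4, 6), quad_decay_integral(59.4, 6)),
            1e-9)
  expect_lt(rel_diff(decay_integral(9.689, 6), quad_decay_integral(9.689, 6)),
            1e-9)
  expect_equal(decay_integral(59.4, 6), 139.07, tolerance = 1e-4)
  expect_equal(decay_integral(9.689, 6), 117.08, tolerance = 1e-4)
  # infinite implant: full decay
  expect_equal(decay_integral(10, Inf), 24 * 10 / log(2))
  expect_error(decay_integral(-1, 6), "positive")
})
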