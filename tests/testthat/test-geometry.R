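test_that("eye frame places the standard landmarks", {
  eye <- make_eye()
  expect_equal(eye$inner_radius, 11.3)
  expect_equal(eye$center_z, 11.3)
  # opposite-pole inner retina at 22.6 mm on the axis
  expect_true(region_contains(eye, c(0, 0, 22.6 - 1e-9)))
  expect_false(region_contains(eye, c(0, 0, 22.6 + 1e-9)))
  # sclera = 0: origin on the eyeball surface
  eye0 <- make_eye(24.6, 0)
  expect_equal(eye0$inner_radius, 12.3)
  expect_true(region_contains(eye0, c(0, 0, 0)))
  expect_error(make_eye(2, 1.5), "exceed")
})

test_that("tumor membership follows the dome-within-eye predicate", {
  tum <- make_tumor(make_eye())
  expect_true(region_contains(tum, c(0, 0, 3)))       # on axis, mid-height
  expect_false(region_contains(tum, c(0, 0, 6.5)))    # beyond the apex
  expect_false(region_contains(tum, c(0, 0, -0.5)))   # behind the base plane
  # wide base rim is trimmed by the curved sclera
  expect_false(region_contains(tum, c(5.9, 0, 0.1)))
  expect_true(region_contains(tum, c(3.0, 0, 0.5)))
  expect_error(make_tumor(make_eye(), height = 30), "exceeds")
})

test_that("tumor volume agrees with rejection sampling of the membership predicate", {
  tum <- make_tumor(make_eye(), major = 6, minor = 5, height = 4)
  n <- 2e5
  pts <- eyeplaque:::.with_seed(421, {
    cbind(runif(n, -3, 3), runif(n, -2.5, 2.5), runif(n, 0, 4))
  })
  box <- 6 * 5 * 4
  mc <- box * mean(region_contains(tum, pts))
  # independent layer-integral oracle for the dome trimmed by the curved
  # sclera: circular dome sections capped by the eyeball section radius
  # (the flat-based dome always protrudes through the sphere near z = 0,
  # so the untrimmed half-ellipsoid is only an upper bound)
  zc <- seq(0.0005, tum$h - 0.0005, by = 0.001)
  R <- tum$eye$inner_radius
  rho_eye2 <- pmax(0, 2 * R * zc - zc^2)
  frac <- function(z, rho2) {
    # area of the ellipse section (x/ax)^2+(y/by)^2<=s2 clipped to a disc
    ax <- tum$a * sqrt(1 - (z / tum$h)^2)
    by <- tum$b * sqrt(1 - (z / tum$h)^2)
    re <- sqrt(rho2)
    if (re >= max(ax, by)) return(pi * ax * by)
    if (re <= min(ax, by)) return(pi * rho2)
    # numeric angular integral of min(ellipse, circle) radius
    th <- seq(0, 2 * pi, length.out = 721)[-721]
    rell2 <- 1 / ((cos(th) / ax)^2 + (sin(th) / by)^2)
    mean(pmin(rell2, rho2)) * pi
  }
  vol <- sum(vapply(seq_along(zc),
                    function(i) frac(zc[i], rho_eye2[i]), numeric(1))) * 0.001
  expect_equal(mc, vol, tolerance = 0.01)
  expect_lt(vol, dome_volume(tum))
})

test_that("COMS-16 layout: 13 equidistant seeds, central seed on axis", {
  eye <- make_eye()
  plq <- coms16_plaque(eye)
  expect_equal(plq$n_seeds, 13)
  expect_equal(nrow(plq$seeds), 13)
  # all seed centres on a sphere concentric with the eye
  d <- sqrt(rowSums(sweep(plq$seeds * 10, 2, c(0, 0, eye$center_z))^2))
  expect_equal(d, rep(eye$inner_radius + 2.75, 13))
  # central seed on the axis at Z = -depth
  expect_equal(unname(plq$seeds[1, ]) * 10, c(0, 0, -2.75))
  # unit orientations
  expect_equal(rowSums(plq$orientations^2), rep(1, 13))
  expect_error(coms16_plaque(eye, ring_radii = c(3, 9)), "exceeds")
})

test_that("seed active cores stay clear of one another", {
  # the active segments must never intersect (the line-source geometry
  # factor is undefined on them) and should keep at least one capsule
  # radius (0.4 mm) of clearance; the 4.5 mm capsules of the tightly packed
  # COMS outer ring approach tip-to-tip by design (4.44 mm chord), so the
  # requirement applies to the 3-4 mm active cores
  seg_gap <- function(plq, Lmm = 4) {
    p <- plq$seeds * 10
    u <- plq$orientations
    gap <- Inf
    for (i in seq_len(nrow(p) - 1)) for (j in (i + 1):nrow(p)) {
      ti <- seq(-Lmm / 2, Lmm / 2, length.out = 31)
      ai <- p[rep(i, 31), ] + outer(ti, u[i, ])
      aj <- p[rep(j, 31), ] + outer(ti, u[j, ])
      dd <- sqrt(outer(rowSums(ai^2), rowSums(aj^2), "+") - 2 * ai %*% t(aj))
      gap <- min(gap, dd)
    }
    gap
  }
  expect_gt(seg_gap(coms16_plaque()), 0.4)
  expect_gt(seg_gap(nag16_plaque()), 0.4)
})

test_that("seed centres stay within the plaque cap and geometry is deterministic", {
  for (plq in list(coms16_plaque(), nag16_plaque())) {
    rho <- sqrt(rowSums(plq$seeds[, 1:2, drop = FALSE]^2)) * 10
    expect_true(all(rho <= plq$diameter / 2 + 1e-9))
  }
  expect_identical(coms16_plaque()$seeds, coms16_plaque()$seeds)
  expect_identical(nag16_plaque(), nag16_plaque())
})

test_that("NAG-16 layout: two 4-fold squares mapped onto themselves by 90 deg rotation", {
  plq <- nag16_plaque()
  expect_equal(plq$n_seeds, 8)
  rot <- function(p) cbind(-p[, 2], p[, 1], p[, 3])
  rotated <- rot(plq$seeds)
  # every rotated seed coincides with an original seed
  for (i in seq_len(8)) {
    dd <- sqrt(rowSums(sweep(plq$seeds, 2, rotated[i, ])^2))
    expect_lt(min(dd), 1e-12)
  }
  # central-axis dose rate is invariant under the rotation
  m <- load_source_model("IAI-125A")
  plq_rot <- plq
  plq_rot$seeds <- rotated
  plq_rot$orientations <- rot(plq$orientations)
  z <- cbind(0, 0, c(0, 3, 6, 12))
  expect_equal(superpose(plq_rot, m, z)$values, superpose(plq, m, z)$values)
})

test_that("plaque config files reproduce the generator output", {
  eye <- make_eye()
  coms_cfg <- read_plaque_config(system.file("extdata", "coms16.cfg",
                                             package = "eyeplaque"), eye)
  expect_identical(coms_cfg$seeds, coms16_plaque(eye)$seeds)
  nag_cfg <- read_plaque_config(system.file("extdata", "nag16.cfg",
                                            package = "eyeplaque"), eye)
  expect_identical(nag_cfg$seeds, nag16_plaque(eye)$seeds)
  # overrides are honored
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("type: nag16", "seed_center_depth: 2.0"), f)
  expect_identical(read_plaque_config(f, eye)$seeds,
                   nag16_plaque(eye, seed_center_depth = 2.0)$seeds)
  writeLines(c("type: wedge"), f)
  expect_error(read_plaque_config(f, eye), "unknown plaque type")
})
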