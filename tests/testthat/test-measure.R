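test_that("the angle formulas follow their projection definitions", {
  # rim line perpendicular to Z: zero tilt, x-offsets ignored
  expect_equal(volar_tilt(c(2, 8, 1), c(-1, -8, 1)), 0)
  expect_equal(volar_tilt(c(0, 10, 1.82), c(0, -10, -1.82)),
               atan2(3.64, 20) * 180 / pi)
  expect_equal(volar_tilt(c(5, 10, -3), c(0, -10, 3)),
               atan2(-6, 20) * 180 / pi)
  expect_error(volar_tilt(c(0, -1, 0), c(0, 1, 0)), "dorsal")

  expect_equal(radial_inclination(c(40, 0, 18)), atan2(18, 40) * 180 / pi)
  expect_equal(radial_inclination(c(40, 0, 0)), 0)
  expect_equal(radial_inclination(c(30, 40, 0)), 0)
  expect_error(radial_inclination(c(0, 0, 10)), "Z-axis")
})

test_that("repeated runs are bit-identical (full reproducibility)", {
  g <- cached_radius()
  m1 <- measure_radius(g$mesh, side = "right")
  m2 <- measure_radius(g$mesh, side = "right")
  expect_identical(m1$volar_tilt, m2$volar_tilt)
  expect_identical(m1$radial_inclination, m2$radial_inclination)
  expect_identical(m1$landmarks, m2$landmarks)
})

test_that("measurements are invariant to the input pose", {
  g <- cached_radius()
  m0 <- measure_radius(g$mesh, side = "right")
  set.seed(31)
  for (i in 1:4) {
    moved <- apply_transform(g$mesh, random_rigid_transform())
    mi <- measure_radius(moved, side = "right")
    expect_lt(abs(mi$volar_tilt - m0$volar_tilt), 0.1)
    expect_lt(abs(mi$radial_inclination - m0$radial_inclination), 0.1)
  }
})

test_that("a left model and its mirrored right twin measure identically", {
  gl <- generate_radius(synthetic_radius_spec(side = "left", seed = 14))
  gr <- generate_radius(synthetic_radius_spec(side = "right", seed = 14))
  ml <- measure_radius(gl$mesh)
  mr <- measure_radius(gr$mesh)
  expect_identical(ml$side, "left")
  expect_lt(abs(ml$volar_tilt - mr$volar_tilt), 1e-6)
  expect_lt(abs(ml$radial_inclination - mr$radial_inclination), 1e-6)
})

test_that("angles recover the generator ground truth", {
  g <- cached_radius(key = "rec", vt_true = 10, ri_true = 22, seed = 6)
  m <- measure_radius(g$mesh, side = "right")
  expect_lt(abs(m$volar_tilt - 10), 1.5)
  expect_lt(abs(m$radial_inclination - 22), 1.5)
})

test_that("a dorsal metaphyseal wedge drives the volar tilt negative", {
  g <- cached_radius(key = "wedge", vt_true = -14, ri_true = 18, seed = 8,
                     malunion = list(apex_offset_from_crp = 20,
                                     wedge_angle = 25, direction = "dorsal"))
  m <- measure_radius(g$mesh, side = "right")
  expect_lt(m$volar_tilt, 0)
  expect_lt(abs(m$volar_tilt + 14), 1.5)
})

test_that("reports serialize losslessly and echo the configuration", {
  g <- cached_radius()
  m <- measure_radius(g$mesh, side = "right")
  path <- withr::local_tempfile(fileext = ".json")
  write_measurement_report(m, path)
  rep <- read_measurement_report(path)
  expect_equal(rep$volar_tilt_deg, m$volar_tilt, tolerance = 1e-12)
  expect_equal(rep$radial_inclination_deg, m$radial_inclination, tolerance = 1e-12)
  expect_equal(rep$config$shaft_band, m$config$shaft_band)
  expect_equal(unname(unlist(rep$landmarks$styloid)),
               unname(m$landmarks$styloid), tolerance = 1e-12)
})
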