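test_that("generation is seed-deterministic and seed-sensitive", {
  g1 <- generate_radius(synthetic_radius_spec(seed = 1))
  g1b <- generate_radius(synthetic_radius_spec(seed = 1))
  g2 <- generate_radius(synthetic_radius_spec(seed = 2))
  expect_identical(g1$mesh, g1b$mesh)
  expect_identical(g1$truth$styloid, g1b$truth$styloid)
  expect_false(isTRUE(all.equal(g1$mesh$vertices, g2$mesh$vertices)))
})

test_that("the annotations reproduce the requested angles to numerical precision", {
  specs <- list(
    synthetic_radius_spec(vt_true = -20, ri_true = 12, seed = 3,
                          malunion = list(apex_offset_from_crp = 17,
                                          wedge_angle = 24, direction = "dorsal")),
    synthetic_radius_spec(vt_true = 22, ri_true = 30, seed = 4),
    synthetic_radius_spec(vt_true = 0, ri_true = 5, seed = 5))
  for (spec in specs) {
    g <- generate_radius(spec)
    ang <- truth_angles(g$truth)
    expect_lt(abs(ang$vt - spec$vt_true), 1e-6)
    expect_lt(abs(ang$ri - spec$ri_true), 1e-6)
  }
})

test_that("the proximal head is rounder than the distal metaphysis", {
  g <- cached_radius()
  zr <- range(g$mesh$vertices[, 3])
  c_prox <- circularity(cross_section(g$mesh, c(0, 0, zr[1] + 0.08 * diff(zr)),
                                      c(0, 0, 1)))
  c_dist <- circularity(cross_section(g$mesh, c(0, 0, zr[1] + 0.92 * diff(zr)),
                                      c(0, 0, 1)))
  expect_gt(c_prox, c_dist + 0.02)
})

test_that("generated meshes pass validation and the full pipeline", {
  g <- cached_radius()
  expect_gt(nrow(g$mesh$triangles), 100)
  expect_true(all(is.finite(g$mesh$vertices)))
  expect_s3_class(measure_radius(g$mesh, side = "right"), "radius_measurement")
})

test_that("cohorts are reproducible with the stated composition", {
  c1 <- radius_cohort(16, "mixed", seed = 7)
  dirs <- vapply(c1, function(g) {
    mal <- g$truth$spec$malunion
    if (is.null(mal)) "healthy" else mal$direction
  }, "")
  expect_equal(sum(dirs == "dorsal"), 13L)
  expect_equal(sum(dirs == "volar"), 3L)

  c2 <- radius_cohort(5, "healthy", seed = 1)
  c3 <- radius_cohort(5, "healthy", seed = 1)
  expect_identical(lapply(c2, function(g) g$truth$vt_true),
                   lapply(c3, function(g) g$truth$vt_true))
  expect_true(all(vapply(c2, function(g) g$truth$vt_true, 0) > 0))
  expect_true(all(vapply(c2, function(g) is.null(g$truth$spec$malunion), TRUE)))
})

test_that("invalid specifications are rejected", {
  expect_error(synthetic_radius_spec(length = 80), "exceed 100")
  expect_error(synthetic_radius_spec(malunion = list(apex_offset_from_crp = 20,
                                                     wedge_angle = 55,
                                                     direction = "dorsal")),
               "wedge_angle")
})
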