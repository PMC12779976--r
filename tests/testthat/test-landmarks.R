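canonical_fixture <- function() {
  if (is.null(.fixture_cache$canonical)) {
    g <- cached_radius()
    .fixture_cache$canonical <- canonical_pose(g$mesh, side = "right")$mesh
  }
  .fixture_cache$canonical
}

test_that("the distal refinement contracts toward a stable frame", {
  # re-running the refinement from its own output moves the frame by a
  # bounded, shrinking amount (the z-selections move with every rotation, so
  # the map is a contraction rather than an exact fixed point)
  rot_angle <- function(t)
    acos(min(1, max(-1, (sum(diag(t$rotation)) - 1) / 2))) * 180 / pi
  rf1 <- refine_distal_frame(canonical_fixture())
  rf2 <- refine_distal_frame(rf1$mesh)
  rf3 <- refine_distal_frame(rf2$mesh)
  expect_lt(max(abs(rf2$transform$translation)), 1)
  expect_lt(rot_angle(rf2$transform), 10)
  expect_lt(rot_angle(rf3$transform), rot_angle(rf2$transform) + 0.5)
  expect_lt(max(abs(rf3$transform$translation)), 1)
})

test_that("refinement fails informatively when the distal selection is sparse", {
  # a tube with a needle apex: the top 8% holds only the needle's 3 facets
  tube <- cylinder_mesh(r = 10, len = 100, n = 64)
  nv <- nrow(tube$vertices)
  v <- rbind(tube$vertices, c(0, 0, 150))
  top_ring <- which(abs(tube$vertices[, 3] - 100) < 1e-9 &
                      abs(sqrt(rowSums(tube$vertices[, 1:2]^2)) - 10) < 1e-6)[1:3]
  f <- rbind(tube$triangles,
             cbind(top_ring, c(top_ring[-1], top_ring[1]), nv + 1L))
  needle <- triangle_mesh(v, f, clean = FALSE)
  expect_error(refine_distal_frame(needle), "refine_distal_frame")
})

test_that("the styloid is the unique distal apex on the radial side", {
  rf <- refine_distal_frame(canonical_fixture())
  sty <- find_styloid(rf$mesh)
  expect_gt(sty$styloid[1], 0)
  # among the distal selection it is the global z-maximum
  F_sel <- radtilt:::select_triangles_z(sty$mesh, -5)
  P <- sty$mesh$vertices[unique(as.vector(F_sel)), ]
  expect_equal(sty$styloid[3], max(P[P[, 1] > 0, 3]))
})

test_that("ulnar corner detection and CRP agree with the construction midpoint", {
  rf <- refine_distal_frame(canonical_fixture())
  sty <- find_styloid(rf$mesh)
  crn <- find_ulnar_corners(sty$mesh)
  expect_gt(crn$dorsal[2], 0)
  expect_lt(crn$volar[2], 0)
  # origin moved to the corner midpoint in x and y
  expect_equal(crn$dorsal[1] + crn$volar[1], 0, tolerance = 1e-9)
  expect_equal(crn$dorsal[2] + crn$volar[2], 0, tolerance = 1e-9)
  crp <- find_crp(crn$mesh)
  # the CRP lies near the corner midpoint by construction
  expect_lt(sqrt(sum(crp$crp_before[1:2]^2)), 2)
})

test_that("swapping the corner tilt signs swaps the dorsal and volar labels", {
  rf <- refine_distal_frame(canonical_fixture())
  sty <- find_styloid(rf$mesh)
  m <- sty$mesh
  F_sel <- radtilt:::select_triangles_z(m, -5)
  P <- m$vertices[unique(as.vector(F_sel)), ]
  P <- P[P[, 1] < 0, ]
  score <- function(rx) as.numeric(P %*% (rotation_y(25) %*% rotation_x(rx))[3, ])
  d <- P[which.max(score(25)), ]
  v <- P[which.max(score(-25)), ]
  expect_gt(d[2], 0)
  expect_lt(v[2], 0)
})

test_that("margins run from the CRP to the styloid on their own sides", {
  rf <- refine_distal_frame(canonical_fixture())
  sty <- find_styloid(rf$mesh)
  crn <- find_ulnar_corners(sty$mesh)
  crp <- find_crp(crn$mesh)
  styloid <- transform_points(crp$transform,
                              transform_points(crn$transform, sty$styloid))
  mg <- extract_margins(crp$mesh, styloid)
  # away from the styloid (where both margins converge to the apex) the
  # margins stay on their own sides
  inner <- 2:17
  expect_true(all(mg$dorsal[inner, 2] > 0))
  expect_true(all(mg$volar[inner, 2] < 0))
  expect_equal(mg$dorsal[1, ], c(0, 0, 0))
  expect_equal(mg$dorsal[22, ], styloid)
  expect_error(extract_margins(crp$mesh, c(-5, 0, 0)), "radial")
})

test_that("arc-length interpolation follows the stated arithmetic", {
  straight <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(point_at_fraction(straight, 0.33), c(3.3, 0, 0))
  bent <- rbind(c(0, 0, 0), c(6, 0, 0), c(6, 8, 0))
  expect_equal(point_at_fraction(bent, 0.57), c(6, 1.98, 0), tolerance = 1e-12)
  expect_equal(point_at_fraction(bent, 1), c(6, 8, 0))
  expect_error(point_at_fraction(rbind(c(0, 0, 0), c(0, 0, 0)), 0.5), "zero-length")
  refs <- margin_reference_points(bent, straight)
  expect_equal(refs$dorsal_ref, c(6, 1.98, 0), tolerance = 1e-12)
  expect_equal(refs$volar_ref, c(3.3, 0, 0))
})

test_that("landmarks match the generator ground truth within tolerance", {
  for (seed in c(2, 5)) {
    g <- cached_radius(key = paste0("lm", seed), seed = seed,
                       vt_true = if (seed == 2) 12 else -18,
                       ri_true = if (seed == 2) 24 else 15,
                       malunion = if (seed == 5)
                         list(apex_offset_from_crp = 18, wedge_angle = 20,
                              direction = "dorsal") else NULL)
    m <- measure_radius(g$mesh, side = "right")
    gt <- truth_in_cs(g$truth)
    for (k in c("styloid", "ulnar_dorsal_corner", "ulnar_volar_corner")) {
      d <- sqrt(sum((m$landmarks[[k]] - gt[[k]])^2))
      expect_lt(d, 2)
    }
    expect_lt(sqrt(sum((m$landmarks$crp - gt$crp)^2)), 1.5)
  }
})
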