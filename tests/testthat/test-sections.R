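test_that("plane cuts of simple solids give the analytic loops", {
  cube <- box_mesh(1, 1, 1)
  cs <- cross_section(cube, c(0.5, 0.5, 0.5), c(0, 0, 1))
  lp <- cs$loops[[cs$principal]]
  expect_true(lp$closed)
  expect_equal(radtilt:::polyline_length(lp$uv), 4, tolerance = 1e-9)

  cyl <- cylinder_mesh(r = 10, len = 100, n = 256)
  cs <- cross_section(cyl, c(0, 0, 50), c(0, 0, 1))
  area <- abs(radtilt:::polygon_area_signed(cs$loops[[cs$principal]]$uv))
  expect_lt(abs(area - pi * 100) / (pi * 100), 0.005)

  # oblique cut of a cylinder: ellipse with b = r / cos(theta)
  th <- 25 * pi / 180
  cs <- cross_section(cyl, c(0, 0, 50), c(0, sin(th), cos(th)))
  area <- abs(radtilt:::polygon_area_signed(cs$loops[[cs$principal]]$uv))
  expect_lt(abs(area - pi * 10 * 10 / cos(th)) / (pi * 100 / cos(th)), 0.005)

  expect_error(cross_section(cube, c(0, 0, 5), c(0, 0, 1)), "intersect")
})

test_that("the principal loop of a multi-body cut is the largest one", {
  small <- box_mesh(1, 1, 1)
  big <- box_mesh(3, 3, 1, origin = c(10, 0, 0))
  both <- triangle_mesh(rbind(small$vertices, big$vertices),
                        rbind(small$triangles, big$triangles + nrow(small$vertices)),
                        clean = FALSE)
  cs <- cross_section(both, c(0, 0, 0.5), c(0, 0, 1))
  expect_length(cs$loops, 2L)
  # brute force: the principal loop must have the larger perimeter
  per <- vapply(cs$loops, function(lp) radtilt:::polyline_length(lp$uv), 0)
  expect_equal(cs$principal, which.max(per))
  expect_equal(max(per), 12, tolerance = 1e-9)
})

test_that("circularity matches the isoperimetric values for canonical shapes", {
  cyl <- cylinder_mesh(r = 10, len = 20, n = 512)
  circ <- cross_section(cyl, c(0, 0, 10), c(0, 0, 1))
  expect_equal(circularity(circ), 1.0, tolerance = 1e-3)

  sq <- cross_section(box_mesh(2, 2, 2), c(1, 1, 1), c(0, 0, 1))
  expect_equal(circularity(sq), pi / 4, tolerance = 1e-9)

  rect <- cross_section(box_mesh(2, 1, 1), c(1, 0.5, 0.5), c(0, 0, 1))
  expect_equal(circularity(rect), 8 * pi / 36, tolerance = 1e-9)

  # invariance under rigid motion
  t1 <- rigid_transform(rotation_y(33) %*% rotation_x(12), c(5, -3, 7))
  moved <- apply_transform(box_mesh(2, 1, 1), t1)
  rect2 <- cross_section(moved, transform_points(t1, c(1, 0.5, 0.5)),
                         as.numeric(t1$rotation %*% c(0, 0, 1)))
  expect_equal(circularity(rect2), circularity(rect), tolerance = 1e-9)
})

test_that("loop centroids follow the shoelace oracle and translate equivariantly", {
  sq <- cross_section(box_mesh(1, 1, 1), c(0.5, 0.5, 0.5), c(0, 0, 1))
  expect_equal(loop_centroid(sq)[1:2], c(0.5, 0.5), tolerance = 1e-9)

  # L-shape built from two boxes sharing a face: centroid of the union
  a <- box_mesh(2, 1, 1)
  b <- box_mesh(1, 1, 1, origin = c(0, -1, 0))
  L <- triangle_mesh(rbind(a$vertices, b$vertices),
                     rbind(a$triangles, b$triangles + nrow(a$vertices)))
  cs <- cross_section(L, c(0.1, 0.1, 0.5), c(0, 0, 1))
  # shoelace oracle: union of [0,2]x[0,1] and [0,1]x[-1,0]
  exp_c <- (2 * c(1, 0.5) + 1 * c(0.5, -0.5)) / 3
  got <- loop_centroid(cs)
  expect_equal(got[1:2], exp_c, tolerance = 1e-6)

  shift <- rigid_transform(diag(3), c(3, -2, 1))
  cs2 <- cross_section(apply_transform(L, shift), c(3.1, -1.9, 1.5), c(0, 0, 1))
  expect_equal(loop_centroid(cs2), got + c(3, -2, 1), tolerance = 1e-6)
})

test_that("curve principal axes find the elongation direction and flag isotropy", {
  rect <- cross_section(box_mesh(4, 1, 1), c(2, 0.5, 0.5), c(0, 0, 1))
  ax <- principal_axis_of_curve(rect, reference = c(1, 0, 0))
  expect_equal(abs(ax[1]), 1, tolerance = 1e-9)

  ell <- cross_section(cylinder_mesh(r = 20, len = 10, n = 512, elliptic_b = 5),
                       c(0, 0, 5), c(0, 0, 1))
  ax <- principal_axis_of_curve(ell, reference = c(1, 0, 0))
  expect_lt(angle_between(ax, c(1, 0, 0)), 0.5)

  circ <- cross_section(cylinder_mesh(r = 10, len = 10, n = 256),
                        c(0, 0, 5), c(0, 0, 1))
  expect_warning(ax <- principal_axis_of_curve(circ, reference = c(0, 1, 0)),
                 "isotropic")
  expect_equal(ax, c(0, 1, 0))
})

test_that("triangle-selection principal axes recover tube and plate directions", {
  tube <- cylinder_mesh(r = 8, len = 120, n = 128)
  ax <- principal_axis_of_triangles(tube, c(10, 110), reference = c(0, 0, 1))
  expect_lt(angle_between(ax, c(0, 0, 1)), 0.5)

  plate <- cylinder_mesh(r = 20, len = 1, n = 128, elliptic_b = 5)
  ax <- principal_axis_of_triangles(plate, c(-1, 2), reference = c(1, 0, 0))
  expect_lt(angle_between(ax, c(1, 0, 0)), 0.5)

  sph <- sphere_mesh(r = 30)
  expect_warning(ax <- principal_axis_of_triangles(sph, c(-40, 40),
                                                   reference = c(0, 0, 1)),
                 "isotropic")
  expect_equal(ax, c(0, 0, 1))

  expect_error(principal_axis_of_triangles(tube, c(500, 600)), "triangles")
})

test_that("triangle-axis estimates are invariant under rigid motion", {
  tube <- cylinder_mesh(r = 8, len = 120, n = 128)
  ax0 <- principal_axis_of_triangles(tube, c(10, 110), reference = c(0, 0, 1))
  set.seed(5)
  t1 <- random_rigid_transform()
  moved <- apply_transform(tube, t1)
  # selection interval must follow the motion: select along the rotated axis
  # by re-expressing the mesh in the original frame
  back <- apply_transform(moved, invert_transform(t1))
  ax1 <- principal_axis_of_triangles(back, c(10, 110), reference = c(0, 0, 1))
  expect_lt(angle_between(ax0, ax1), 0.1)
})

test_that("the most prominent inflection finds a ridge apex and warns on smooth loops", {
  # circle with one triangular spike at azimuth 40 degrees
  n <- 128
  th <- (seq_len(n) - 1) / n * 2 * pi
  r <- rep(10, n)
  spike_at <- which.min(abs(th - 40 * pi / 180))
  r[spike_at] <- 13
  zs <- c(0, 4)
  V <- do.call(rbind, lapply(zs, function(z) cbind(r * cos(th), r * sin(th), z)))
  V <- rbind(V, c(0, 0, 0), c(0, 0, 4))
  idx <- function(k, j) (k - 1L) * n + ((j - 1L) %% n) + 1L
  j <- seq_len(n)
  F <- rbind(cbind(idx(1, j), idx(1, j + 1), idx(2, j)),
             cbind(idx(2, j), idx(1, j + 1), idx(2, j + 1)),
             cbind(idx(1, j + 1), idx(1, j), rep(2 * n + 1, n)),
             cbind(idx(2, j), idx(2, j + 1), rep(2 * n + 2, n)))
  spiked <- triangle_mesh(V, F, clean = FALSE)
  cs <- cross_section(spiked, c(0, 0, 2), c(0, 0, 1))
  p <- most_prominent_inflection(cs)
  expect_equal(atan2(p[2], p[1]) * 180 / pi, 40, tolerance = 3)
  expect_true(attr(p, "prominent"))

  # exhaustive oracle: the spike apex is the known extremal vertex
  apex <- c(13 * cos(th[spike_at]), 13 * sin(th[spike_at]))
  expect_lt(sqrt(sum((p[1:2] - apex)^2)), 0.5)

  ell <- cross_section(cylinder_mesh(r = 20, len = 10, n = 256, elliptic_b = 15),
                       c(0, 0, 5), c(0, 0, 1))
  expect_warning(most_prominent_inflection(ell), "prominent")
})
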