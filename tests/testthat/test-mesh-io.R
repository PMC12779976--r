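tetra_ascii <- function(path) {
  # unit tetrahedron, 4 facets
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  m <- triangle_mesh(v, f, clean = FALSE)
  write_stl(m, path, ascii = TRUE)
  m
}

test_that("ASCII STL of a tetrahedron reads back with merged vertices", {
  path <- withr::local_tempfile(fileext = ".stl")
  tetra_ascii(path)
  m <- read_stl(path, check_extent = FALSE)
  expect_equal(nrow(m$vertices), 4L)
  expect_equal(nrow(m$triangles), 4L)
})

test_that("binary and ASCII dialects give identical geometry", {
  pa <- withr::local_tempfile(fileext = ".stl")
  pb <- withr::local_tempfile(fileext = ".stl")
  m0 <- tetra_ascii(pa)
  write_stl(m0, pb, ascii = FALSE)
  ma <- read_stl(pa, check_extent = FALSE)
  mb <- read_stl(pb, check_extent = FALSE)
  oa <- ma$vertices[do.call(order, as.data.frame(ma$vertices)), ]
  ob <- mb$vertices[do.call(order, as.data.frame(mb$vertices)), ]
  expect_equal(oa, ob, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(nrow(ma$triangles), nrow(mb$triangles))
})

test_that("a synthetic radius round-trips through binary STL to 1e-4 mm", {
  g <- cached_radius()
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(g$mesh, path)
  m <- read_stl(path, side = "right", check_extent = FALSE)
  expect_equal(nrow(m$vertices), nrow(g$mesh$vertices))
  # every original vertex has a read-back vertex within tolerance
  set.seed(8)
  idx <- sample(nrow(g$mesh$vertices), 200)
  for (i in idx) {
    d2 <- colSums((t(m$vertices) - g$mesh$vertices[i, ])^2)
    expect_lt(sqrt(min(d2)), 1e-4)
  }
})

test_that("read_stl rejects missing, truncated and empty inputs", {
  expect_error(read_stl(file.path(tempdir(), "nope.stl")), "not found")
  p <- withr::local_tempfile(fileext = ".stl")
  writeBin(as.raw(rep(0L, 90)), p)       # header + bogus count, no facets
  expect_error(read_stl(p), "truncated|corrupt|malformed|empty")
})

test_that("mirror_x is an involution that flips the recorded side", {
  g <- cached_radius()
  m <- g$mesh
  mm <- mirror_x(m)
  expect_equal(mm$vertices[, 1], -m$vertices[, 1])
  expect_equal(mm$vertices[, 2:3], m$vertices[, 2:3])
  expect_identical(mm$side, "left")
  expect_identical(mirror_x(mm), m)
})

test_that("rigid transforms preserve pairwise distances; scale warning fires", {
  g <- cached_radius()
  set.seed(3)
  idx <- sample(nrow(g$mesh$vertices), 40)
  t1 <- random_rigid_transform()
  m2 <- apply_transform(g$mesh, t1)
  d1 <- dist(g$mesh$vertices[idx, ])
  d2 <- dist(m2$vertices[idx, ])
  expect_lt(max(abs(d1 - d2)), 1e-9)

  expect_warning(triangle_mesh(box_mesh()$vertices * 1000, box_mesh()$triangles,
                               check_extent = TRUE),
                 "millimetres")
})
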