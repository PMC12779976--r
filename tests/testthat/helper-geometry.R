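# Analytic fixture meshes, built in code.

# closed axis-aligned box [0,a]x[0,b]x[0,c] as 12 triangles
box_mesh <- function(a = 1, b = 1, c = 1, origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(x = c(0, a), y = c(0, b), z = c(0, c)))
  v <- sweep(v, 2L, -origin)
  # faces as quads (vertex indices into the 8 corners), split into triangles
  quads <- rbind(c(1, 3, 4, 2), c(5, 6, 8, 7), c(1, 2, 6, 5),
                 c(3, 7, 8, 4), c(1, 5, 7, 3), c(2, 4, 8, 6))
  tri <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  triangle_mesh(v, tri, clean = FALSE)
}

# closed cylinder of radius r, length len along +Z starting at z0
cylinder_mesh <- function(r = 10, len = 100, n = 256, z0 = 0,
                          elliptic_b = r) {
  th <- (seq_len(n) - 1) / n * 2 * pi
  nz <- max(8L, round(len / (2 * pi * r / n) / 4))
  zs <- seq(z0, z0 + len, length.out = nz)
  rings <- lapply(zs, function(z) cbind(r * cos(th), elliptic_b * sin(th), z))
  V <- do.call(rbind, rings)
  V <- rbind(V, c(0, 0, z0), c(0, 0, z0 + len))
  p1 <- nrow(V) - 1L; p2 <- nrow(V)
  idx <- function(k, j) (k - 1L) * n + ((j - 1L) %% n) + 1L
  j <- seq_len(n)
  tri <- list()
  for (k in seq_len(length(zs) - 1L))
    tri[[k]] <- rbind(cbind(idx(k, j), idx(k, j + 1L), idx(k + 1L, j)),
                      cbind(idx(k + 1L, j), idx(k, j + 1L), idx(k + 1L, j + 1L)))
  tri[[length(tri) + 1L]] <- cbind(idx(1L, j + 1L), idx(1L, j), rep(p1, n))
  tri[[length(tri) + 1L]] <- cbind(idx(length(zs), j), idx(length(zs), j + 1L), rep(p2, n))
  triangle_mesh(V, do.call(rbind, tri), clean = FALSE)
}

# unit icosphere-ish mesh via subdivided octahedron projected to the sphere
sphere_mesh <- function(r = 50, subdiv = 4L) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(5, 1, 3), c(5, 3, 2), c(5, 2, 4), c(5, 4, 1),
             c(6, 3, 1), c(6, 2, 3), c(6, 4, 2), c(6, 1, 4))
  for (s in seq_len(subdiv)) {
    nf <- list()
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      m1 <- (v[a, ] + v[b, ]) / 2; m2 <- (v[b, ] + v[c, ]) / 2
      m3 <- (v[c, ] + v[a, ]) / 2
      base <- nrow(v)
      v <- rbind(v, m1, m2, m3)
      nf[[i]] <- rbind(c(a, base + 1, base + 3), c(base + 1, b, base + 2),
                       c(base + 3, base + 2, c), c(base + 1, base + 2, base + 3))
    }
    f <- do.call(rbind, nf)
  }
  v <- v / sqrt(rowSums(v^2)) * r
  triangle_mesh(v, f, clean = TRUE)
}

random_rigid_transform <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  rigid_transform(radtilt:::axis_angle_rotation(ax, stats::runif(1, 0, 360)),
                  stats::runif(3, -50, 50))
}

# session cache for expensive synthetic fixtures
.fixture_cache <- new.env(parent = emptyenv())
cached_radius <- function(key = "default", ...) {
  if (is.null(.fixture_cache[[key]])) {
    args <- list(...)
    spec <- do.call(synthetic_radius_spec, args)
    .fixture_cache[[key]] <- generate_radius(spec)
  }
  .fixture_cache[[key]]
}
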