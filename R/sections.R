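#' Planar cross-section of a triangle mesh
#'
#' Intersects the mesh (or a triangle subset) with a plane, chains the
#' per-triangle intersection segments into polylines, and flags the principal
#' loop (largest perimeter). Cuts through a watertight region give closed
#' loops; cuts through a selected open shell give open chains, which are valid
#' carriers for length-weighted centroid/inertia computations. Open chains in
#' a nominally watertight cut are closed when the gap is at most `close_gap`.
#'
#' @param mesh a [triangle_mesh()], or an n x 3 vertex matrix with `triangles`.
#' @param point a point on the plane (length-3).
#' @param normal the plane normal (length-3, normalised internally).
#' @param triangles optional m x 3 index matrix restricting the cut to a
#'   triangle subset (defaults to all triangles of `mesh`).
#' @param close_gap maximum endpoint gap (mm) closed when chaining loops.
#' @return An object of class `section_curve`: the plane (`point`, `normal`,
#'   in-plane basis `e1`, `e2`), `loops` (each a list with `points` n x 3,
#'   `uv` n x 2 in-plane coordinates, `closed` flag) and `principal`, the
#'   index of the largest-perimeter loop.
#' @export
cross_section <- function(mesh, point, normal, triangles = NULL,
                          close_gap = 1.0) {
  if (inherits(mesh, "triangle_mesh")) {
    V <- mesh$vertices
    F <- if (is.null(triangles)) mesh$triangles else triangles
  } else {
    V <- mesh
    F <- triangles
  }
  n <- normal / sqrt(sum(normal^2))
  d <- as.numeric(V %*% n) - sum(point * n)
  # deterministic nudge for vertices exactly on the plane
  d[d == 0] <- 1e-12

  d1 <- d[F[, 1]]; d2 <- d[F[, 2]]; d3 <- d[F[, 3]]
  s1 <- d1 > 0; s2 <- d2 > 0; s3 <- d3 > 0
  cross12 <- s1 != s2
  cross23 <- s2 != s3
  cross31 <- s3 != s1
  hit <- cross12 | cross23 | cross31
  if (!any(hit))
    stop("cross_section: plane does not intersect the mesh", call. = FALSE)

  edge_point <- function(ia, ib, da, db) {
    t <- da / (da - db)
    V[ia, , drop = FALSE] + (V[ib, , drop = FALSE] - V[ia, , drop = FALSE]) * t
  }
  # canonical edge order (small index first) so shared edges yield identical points
  edge_pt_for <- function(rows, a_col, b_col) {
    ia <- F[rows, a_col]; ib <- F[rows, b_col]
    da <- d[ia]; db <- d[ib]
    swap <- ia > ib
    tmp <- ia[swap]; ia[swap] <- ib[swap]; ib[swap] <- tmp
    tmp <- da[swap]; da[swap] <- db[swap]; db[swap] <- tmp
    edge_point(ia, ib, da, db)
  }

  rows <- which(hit)
  c12 <- cross12[rows]; c23 <- cross23[rows]; c31 <- cross31[rows]
  p12 <- matrix(NA_real_, length(rows), 3L)
  p23 <- p12; p31 <- p12
  if (any(c12)) p12[c12, ] <- edge_pt_for(rows[c12], 1L, 2L)
  if (any(c23)) p23[c23, ] <- edge_pt_for(rows[c23], 2L, 3L)
  if (any(c31)) p31[c31, ] <- edge_pt_for(rows[c31], 3L, 1L)

  # each crossing triangle contributes exactly two edge points
  segs_a <- matrix(NA_real_, length(rows), 3L)
  segs_b <- segs_a
  two12_23 <- c12 & c23
  two23_31 <- c23 & c31
  two31_12 <- c31 & c12
  segs_a[two12_23, ] <- p12[two12_23, ]; segs_b[two12_23, ] <- p23[two12_23, ]
  segs_a[two23_31, ] <- p23[two23_31, ]; segs_b[two23_31, ] <- p31[two23_31, ]
  segs_a[two31_12, ] <- p31[two31_12, ]; segs_b[two31_12, ] <- p12[two31_12, ]

  ok <- stats::complete.cases(segs_a) & stats::complete.cases(segs_b)
  segs_a <- segs_a[ok, , drop = FALSE]
  segs_b <- segs_b[ok, , drop = FALSE]
  # drop zero-length segments (plane grazing an edge)
  nz <- rowSums((segs_a - segs_b)^2) > 1e-20
  segs_a <- segs_a[nz, , drop = FALSE]
  segs_b <- segs_b[nz, , drop = FALSE]
  if (nrow(segs_a) == 0L)
    stop("cross_section: degenerate intersection", call. = FALSE)

  loops <- chain_segments(segs_a, segs_b, close_gap = close_gap)

  # in-plane basis (deterministic)
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- cross3(ref, n); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(n, e1)

  loops <- lapply(loops, function(lp) {
    P <- lp$points
    uv <- cbind(as.numeric(sweep(P, 2L, point) %*% e1),
                as.numeric(sweep(P, 2L, point) %*% e2))
    list(points = P, uv = uv, closed = lp$closed)
  })
  perims <- vapply(loops, function(lp) polyline_length(lp$uv, lp$closed), 0)
  structure(list(point = point, normal = n, e1 = e1, e2 = e2,
                 loops = loops, principal = which.max(perims)),
            class = "section_curve")
}

# Chain unordered segments into polylines by matching endpoints.
chain_segments <- function(a, b, close_gap = 1.0, tol = 1e-7) {
  m <- nrow(a)
  pts <- rbind(a, b)                      # endpoint i of seg s: s and s+m
  key <- paste(round(pts[, 1] / tol), round(pts[, 2] / tol), round(pts[, 3] / tol))
  grp <- match(key, key)                  # endpoint group id
  # adjacency: for each group, the endpoint slots in it
  slots_by_grp <- split(seq_len(2L * m), grp)
  used <- logical(m)
  other_end <- function(slot) if (slot > m) slot - m else slot + m
  seg_of <- function(slot) ((slot - 1L) %% m) + 1L

  loops <- list()
  for (s0 in seq_len(m)) {
    if (used[s0]) next
    # walk forward from segment s0 starting at its 'a' end
    path_slots <- c(s0, s0 + m)           # ordered endpoint slots of the chain
    used[s0] <- TRUE
    repeat {
      tail_slot <- path_slots[length(path_slots)]
      g <- grp[tail_slot]
      nxt <- setdiff(slots_by_grp[[as.character(g)]],
                     path_slots[length(path_slots)])
      nxt <- nxt[!used[seg_of(nxt)]]
      if (length(nxt) == 0L) break
      nslot <- nxt[1L]
      used[seg_of(nslot)] <- TRUE
      path_slots <- c(path_slots, nslot, other_end(nslot))
    }
    # walk backward from the 'a' end
    repeat {
      head_slot <- path_slots[1L]
      g <- grp[head_slot]
      nxt <- setdiff(slots_by_grp[[as.character(g)]], path_slots[1L])
      nxt <- nxt[!used[seg_of(nxt)]]
      if (length(nxt) == 0L) break
      nslot <- nxt[1L]
      used[seg_of(nslot)] <- TRUE
      path_slots <- c(other_end(nslot), nslot, path_slots)
    }
    # ordered unique points along the chain
    slot_pts <- pts[path_slots, , drop = FALSE]
    keep <- c(TRUE, rowSums((slot_pts[-1L, , drop = FALSE] -
                               slot_pts[-nrow(slot_pts), , drop = FALSE])^2) > 1e-20)
    P <- slot_pts[keep, , drop = FALSE]
    gap <- sqrt(sum((P[1L, ] - P[nrow(P), ])^2))
    closed <- gap < tol * 10
    if (closed) P <- P[-nrow(P), , drop = FALSE]
    loops[[length(loops) + 1L]] <- list(points = P, closed = closed, gap = gap)
  }
  # close small gaps in nominally closed cuts
  loops <- lapply(loops, function(lp) {
    if (!lp$closed && lp$gap <= close_gap && nrow(lp$points) >= 3L)
      lp$closed <- TRUE
    lp[c("points", "closed")]
  })
  loops
}

#' @export
print.section_curve <- function(x, ...) {
  cat(sprintf("section_curve: %d loop(s), principal = %d (%s, %d points)\n",
              length(x$loops), x$principal,
              if (x$loops[[x$principal]]$closed) "closed" else "open",
              nrow(x$loops[[x$principal]]$points)))
  invisible(x)
}

polyline_length <- function(uv, closed = TRUE) {
  P <- uv
  if (closed) P <- rbind(P, P[1L, ])
  sum(sqrt(rowSums((P[-1L, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2)))
}

principal_loop <- function(curve) curve$loops[[curve$principal]]

# Signed polygon area (shoelace) of a closed 2D loop.
polygon_area_signed <- function(uv) {
  x <- uv[, 1]; y <- uv[, 2]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  0.5 * sum(x * yn - xn * y)
}

#' Circularity of a section curve
#'
#' The isoperimetric shape factor `4*pi*A / P^2` of the principal loop:
#' 1 for a circle, `pi/4` for a square, lower for elongated sections. Used to
#' tell the round proximal radial head from the elliptical distal metaphysis.
#'
#' @param curve a [cross_section()] result.
#' @return Circularity in (0, 1].
#' @export
circularity <- function(curve) {
  lp <- principal_loop(curve)
  if (nrow(lp$points) < 3L)
    stop("circularity: principal loop has fewer than 3 points", call. = FALSE)
  A <- abs(polygon_area_signed(lp$uv))
  P <- polyline_length(lp$uv, closed = TRUE)
  if (P < 1e-12)
    stop("circularity: zero perimeter", call. = FALSE)
  4 * pi * A / P^2
}

#' Area centroid of the principal loop
#'
#' Polygon (area) centroid of the principal loop, returned as a 3D point on
#' the section plane. Falls back with a warning to the perimeter-weighted
#' centroid when the polygon is numerically degenerate.
#'
#' @param curve a [cross_section()] result.
#' @return Length-3 point (mm).
#' @export
loop_centroid <- function(curve) {
  lp <- principal_loop(curve)
  uv <- lp$uv
  A <- polygon_area_signed(uv)
  if (abs(A) < 1e-9) {
    warning("loop_centroid: degenerate polygon area; using perimeter-weighted centroid",
            call. = FALSE)
    cuv <- curve_centroid_uv(uv, lp$closed)
  } else {
    x <- uv[, 1]; y <- uv[, 2]
    xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
    f <- x * yn - xn * y
    cuv <- c(sum((x + xn) * f), sum((y + yn) * f)) / (6 * A)
  }
  curve$point + cuv[1] * curve$e1 + cuv[2] * curve$e2
}

# Length-weighted centroid of a polyline in 2D.
curve_centroid_uv <- function(uv, closed = TRUE) {
  P <- uv
  if (closed) P <- rbind(P, P[1L, ])
  a <- P[-nrow(P), , drop = FALSE]; b <- P[-1L, , drop = FALSE]
  w <- sqrt(rowSums((b - a)^2))
  mid <- (a + b) / 2
  colSums(mid * w) / sum(w)
}

# Length-weighted centroid and principal axes over ALL loops of a section
# (used by the distal refinement steps, where the cut shell is open).
section_inertia <- function(curve) {
  A <- NULL; B <- NULL
  for (lp in curve$loops) {
    P <- lp$uv
    if (lp$closed) P <- rbind(P, P[1L, ])
    if (nrow(P) < 2L) next
    A <- rbind(A, P[-nrow(P), , drop = FALSE])
    B <- rbind(B, P[-1L, , drop = FALSE])
  }
  w <- sqrt(rowSums((B - A)^2))
  keep <- w > 1e-12
  A <- A[keep, , drop = FALSE]; B <- B[keep, , drop = FALSE]; w <- w[keep]
  W <- sum(w)
  mid <- (A + B) / 2
  ctr <- colSums(mid * w) / W
  dm <- sweep(mid, 2L, ctr)
  dseg <- B - A
  # exact second moment of straight segments: midpoint term + segment term
  M <- (t(dm) %*% (dm * w)) + (t(dseg) %*% (dseg * w)) / 12
  eig <- eigen(M / W, symmetric = TRUE)
  list(centroid_uv = ctr, values = eig$values, vectors = eig$vectors, weight = W)
}

uv_to_3d <- function(curve, uv) {
  curve$point + uv[1] * curve$e1 + uv[2] * curve$e2
}

uvdir_to_3d <- function(curve, duv) {
  v <- duv[1] * curve$e1 + duv[2] * curve$e2
  v / sqrt(sum(v^2))
}

#' Principal inertia axis of a section curve
#'
#' Major principal axis (largest second moment, segment-length weighted) of
#' the principal loop boundary, returned as a unit 3-vector in the section
#' plane. The sign is chosen toward `reference`. Near-isotropic loops
#' (eigenvalue ratio below 1.05) raise an ambiguity warning and return the
#' reference axis unchanged.
#'
#' @param curve a [cross_section()] result.
#' @param reference axis used for sign (and the fallback for isotropic loops).
#' @return Unit length-3 vector.
#' @export
principal_axis_of_curve <- function(curve, reference = c(0, 1, 0)) {
  lp <- principal_loop(curve)
  if (nrow(lp$points) < 3L)
    stop("principal_axis_of_curve: degenerate loop", call. = FALSE)
  si <- section_inertia_of_loop(curve, lp)
  if (si$values[1] / max(si$values[2], 1e-300) < 1.05) {
    warning("principal_axis_of_curve: near-isotropic loop; keeping reference axis",
            call. = FALSE)
    return(reference / sqrt(sum(reference^2)))
  }
  ax <- uvdir_to_3d(curve, si$vectors[, 1])
  if (sum(ax * reference) < 0) ax <- -ax
  ax
}

section_inertia_of_loop <- function(curve, lp) {
  P <- lp$uv
  if (lp$closed) P <- rbind(P, P[1L, ])
  a <- P[-nrow(P), , drop = FALSE]; b <- P[-1L, , drop = FALSE]
  w <- sqrt(rowSums((b - a)^2))
  W <- sum(w)
  mid <- (a + b) / 2
  ctr <- colSums(mid * w) / W
  dm <- sweep(mid, 2L, ctr)
  dseg <- b - a
  M <- (t(dm) %*% (dm * w)) + (t(dseg) %*% (dseg * w)) / 12
  eig <- eigen(M / W, symmetric = TRUE)
  list(centroid_uv = ctr, values = eig$values, vectors = eig$vectors)
}

#' Principal inertia axis of a triangle selection
#'
#' Principal axis of the area-weighted covariance of triangle centroids within
#' a z-interval of the current frame. Among the three eigenvectors the one
#' with maximal `|dot|` with `reference` is returned, sign-aligned to it --
#' selection by alignment rather than eigenvalue rank prevents 90-degree
#' flips between refinement iterations on stubby segments. Near-equal
#' eigenvalues raise an ambiguity warning and return the reference axis.
#'
#' @param mesh a [triangle_mesh()].
#' @param z_range length-2 z-interval (mm) selecting triangles by centroid z;
#'   `c(-Inf, Inf)` uses the whole surface.
#' @param reference the working axis used for eigenvector selection and sign.
#' @param min_triangles minimum selected triangles (default 50).
#' @return Unit length-3 vector.
#' @export
principal_axis_of_triangles <- function(mesh, z_range = c(-Inf, Inf),
                                        reference = c(0, 0, 1),
                                        min_triangles = 50L) {
  cz <- triangle_centroids(mesh$vertices, mesh$triangles)[, 3]
  keep <- cz > z_range[1] & cz < z_range[2]
  if (sum(keep) < min_triangles)
    stop(sprintf("principal_axis_of_triangles: only %d triangles in z-range [%g, %g]",
                 sum(keep), z_range[1], z_range[2]), call. = FALSE)
  F <- mesh$triangles[keep, , drop = FALSE]
  ctr <- triangle_centroids(mesh$vertices, F)
  w <- triangle_areas(mesh$vertices, F)
  W <- sum(w)
  m <- colSums(ctr * w) / W
  dc <- sweep(ctr, 2L, m)
  M <- t(dc) %*% (dc * w) / W
  eig <- eigen(M, symmetric = TRUE)
  if (eig$values[1] < 1e-300 ||
      (eig$values[1] - eig$values[3]) / eig$values[1] < 0.05) {
    warning("principal_axis_of_triangles: near-isotropic selection; keeping reference axis",
            call. = FALSE)
    return(reference / sqrt(sum(reference^2)))
  }
  al <- abs(as.numeric(reference %*% eig$vectors))
  ax <- eig$vectors[, which.max(al)]
  if (sum(ax * reference) < 0) ax <- -ax
  ax
}

#' Most prominent inflection point of a section curve
#'
#' The loop vertex maximising discrete convex curvature after arc-length
#' smoothing (2 mm window); ties broken by greatest distance from the loop
#' centroid. On the 35%-level shaft section this is the apex of the
#' interosseous ridge and identifies the ulnar direction. An all-smooth loop
#' (maximum below 1.5x the median curvature) raises a prominence warning.
#'
#' @param curve a [cross_section()] result whose principal loop is closed.
#' @param window smoothing window (mm of arc length), default 2.
#' @return Length-3 point; attribute `"prominent"` is `FALSE` when the
#'   prominence warning fired.
#' @export
most_prominent_inflection <- function(curve, window = 2.0) {
  lp <- principal_loop(curve)
  uv <- lp$uv
  n <- nrow(uv)
  if (n < 32L)
    stop("most_prominent_inflection: loop has fewer than 32 points", call. = FALSE)
  # orient counter-clockwise so convex curvature is positive
  if (polygon_area_signed(uv) < 0) uv <- uv[n:1, , drop = FALSE]
  prv <- uv[c(n, 1:(n - 1L)), , drop = FALSE]
  nxt <- uv[c(2:n, 1L), , drop = FALSE]
  v1 <- uv - prv
  v2 <- nxt - uv
  l1 <- sqrt(rowSums(v1^2)); l2 <- sqrt(rowSums(v2^2))
  turn <- atan2(v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1],
                v1[, 1] * v2[, 1] + v1[, 2] * v2[, 2])
  kappa <- turn / pmax((l1 + l2) / 2, 1e-12)
  ks <- smooth_circular(kappa, (l1 + l2) / 2, window)
  # a ridge is a localized peak: the maximum must stand clear of the bulk of
  # the smoothed curvature distribution (a smooth ellipse varies gradually,
  # so its maximum sits near the upper quantiles)
  q90 <- stats::quantile(ks, 0.9, names = FALSE)
  prominent <- max(ks) >= 1.5 * max(q90, 1e-12)
  if (!prominent)
    warning("most_prominent_inflection: no prominent convex feature on this loop",
            call. = FALSE)
  best <- which(ks == max(ks))
  if (length(best) > 1L) {
    ctr <- curve_centroid_uv(uv, closed = TRUE)
    d2 <- rowSums(sweep(uv[best, , drop = FALSE], 2L, ctr)^2)
    best <- best[which.max(d2)]
  }
  p <- uv_to_3d(curve, uv[best, ])
  attr(p, "prominent") <- prominent
  p
}

# Moving average over a closed polyline, window in arc-length units.
smooth_circular <- function(x, step, window) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- x[i] * step[i]; wsum <- step[i]
    j <- i; s <- 0
    while (s < window / 2) {
      j <- if (j == n) 1L else j + 1L
      s <- s + step[j]
      acc <- acc + x[j] * step[j]; wsum <- wsum + step[j]
      if (j == i) break
    }
    j <- i; s <- 0
    while (s < window / 2) {
      j <- if (j == 1L) n else j - 1L
      s <- s + step[j]
      acc <- acc + x[j] * step[j]; wsum <- wsum + step[j]
      if (j == i) break
    }
    out[i] <- acc / wsum
  }
  out
}
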