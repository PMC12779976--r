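#' Landmark detection on the distal radius
#'
#' Steps of the knowledge-based chain that run after canonical pose: iterative
#' refinement of a distal frame aligned with the articular surface, radial
#' styloid detection, ulnar volar/dorsal corner detection, the central
#' reference point (CRP), the dorsal and volar cortical-margin curves, and the
#' 33%/57% normalised-arc-length reference points used for volar tilt. All
#' selections take whole triangles by centroid z; all argmax ties break
#' lexicographically (z, then x, then y) so the chain is fully deterministic.
#'
#' @name landmark_detection
NULL

identity_transform <- function() rigid_transform()

select_triangles_z <- function(mesh, zmin, by = c("centroid", "any_vertex")) {
  by <- match.arg(by)
  z <- if (by == "centroid")
    triangle_centroids(mesh$vertices, mesh$triangles)[, 3]
  else
    pmax(mesh$vertices[mesh$triangles[, 1], 3],
         mesh$vertices[mesh$triangles[, 2], 3],
         mesh$vertices[mesh$triangles[, 3], 3])
  mesh$triangles[z > zmin, , drop = FALSE]
}

argmax_lex <- function(P, score) {
  ord <- order(-score, -P[, 1], -P[, 2])
  ord[1L]
}

# Translate + rotate helper returning updated mesh and cumulative transform.
push_transform <- function(mesh, total, step) {
  list(mesh = apply_transform(mesh, step),
       transform = compose_transform(step, total))
}

section_axis_3d <- function(curve, si, reference) {
  a1 <- uvdir_to_3d(curve, si$vectors[, 1])
  a2 <- uvdir_to_3d(curve, si$vectors[, 2])
  cand <- cbind(a1, a2)
  al <- abs(as.numeric(reference %*% cand))
  ax <- cand[, which.max(al)]
  if (sum(ax * reference) < 0) ax <- -ax
  ax
}

#' Refine the distal frame onto the articular surface
#'
#' From the canonical pose: (a) the origin is moved to the cross-section at
#' 8% of the length from the distal end, the inertia axis of the distal
#' (z > 0) triangles -- an estimate of the articular-surface direction -- is
#' aligned with X and the origin is placed on the articular surface; then
#' (b) five fixed iterations of: YZ-plane section of the distal selection,
#' recentre the origin on its length-weighted centroid and align its inertia
#' axis with Y, reselect triangles with z > -1 mm. The origin ends just
#' distal to the articular surface. After refinement the articular surface
#' lies approximately in the XY-plane, which is what makes the subsequent
#' rim-point searches well-posed even for strongly tilted malunions.
#'
#' @param mesh a [triangle_mesh()] in canonical pose.
#' @param iterations number of refinement iterations (default 5).
#' @return List with `mesh` (refined frame) and `transform` (cumulative, from
#'   the canonical frame).
#' @export
refine_distal_frame <- function(mesh, iterations = 5L) {
  total <- identity_transform()

  # (a) origin at the 8%-from-distal section level
  z0 <- z_at_fraction(mesh, 0.92)
  st <- push_transform(mesh, total, rigid_transform(diag(3), c(0, 0, -z0)))
  mesh <- st$mesh; total <- st$transform

  F_sel <- select_triangles_z(mesh, 0)
  if (nrow(F_sel) < 20L)
    stop("refine_distal_frame: empty distal selection at initialisation",
         call. = FALSE)
  ax <- principal_axis_of_triangles(mesh, c(0, Inf), reference = c(1, 0, 0),
                                    min_triangles = 20L)
  # area-weighted median z: seats the origin on the articular surface proper,
  # robust to the styloid prominence
  w <- triangle_areas(mesh$vertices, F_sel)
  czs <- triangle_centroids(mesh$vertices, F_sel)[, 3]
  o <- order(czs)
  zb <- czs[o][which(cumsum(w[o]) >= 0.5 * sum(w))[1]]
  st <- push_transform(mesh, total, rigid_transform(diag(3), c(0, 0, -zb)))
  mesh <- st$mesh; total <- st$transform
  st <- push_transform(mesh, total,
                       rigid_transform(rotation_between(ax, c(1, 0, 0))))
  mesh <- st$mesh; total <- st$transform

  # (b) iterative recentring on the YZ section
  F_sel <- select_triangles_z(mesh, 0)
  curve <- NULL
  for (it in seq_len(iterations)) {
    if (nrow(F_sel) < 10L)
      stop(sprintf("refine_distal_frame: empty selection at iteration %d", it),
           call. = FALSE)
    curve <- tryCatch(
      cross_section(mesh, c(0, 0, 0), c(1, 0, 0), triangles = F_sel),
      error = function(e)
        stop(sprintf("refine_distal_frame: no YZ section at iteration %d", it),
             call. = FALSE))
    si <- section_inertia(curve)
    c3 <- uv_to_3d(curve, si$centroid_uv)
    st <- push_transform(mesh, total, rigid_transform(diag(3), -c3))
    mesh <- st$mesh; total <- st$transform
    ax <- section_axis_3d(curve, si, c(0, 1, 0))
    st <- push_transform(mesh, total,
                         rigid_transform(rotation_between(ax, c(0, 1, 0))))
    mesh <- st$mesh; total <- st$transform
    F_sel <- select_triangles_z(mesh, -1)
  }

  # origin just distal to the articular surface: top of the central profile
  curve <- cross_section(mesh, c(0, 0, 0), c(1, 0, 0), triangles = F_sel)
  zmax <- max(vapply(curve$loops, function(lp) max(lp$points[, 3]), 0))
  st <- push_transform(mesh, total, rigid_transform(diag(3), c(0, 0, -zmax)))
  list(mesh = st$mesh, transform = st$transform)
}

#' Detect the radial styloid
#'
#' Five iterations of: select triangles with z > -5 mm, cut them with the
#' XZ-plane, recentre the origin on the section's length-weighted centroid
#' and align its inertia axis with X (flattening the styloid-to-sigmoid-notch
#' line). The styloid is then the vertex with maximum z among the distal
#' selection's vertices on the radial (x > 0) side.
#'
#' @param mesh a [triangle_mesh()] in the refined distal frame.
#' @param iterations number of XZ recentring iterations (default 5).
#' @return List with `styloid` (length-3 point in the returned frame), `mesh`
#'   and `transform` (cumulative).
#' @export
find_styloid <- function(mesh, iterations = 5L) {
  total <- identity_transform()
  for (it in seq_len(iterations)) {
    F_sel <- select_triangles_z(mesh, -5)
    if (nrow(F_sel) < 10L)
      stop(sprintf("find_styloid: empty distal selection at iteration %d", it),
           call. = FALSE)
    curve <- tryCatch(
      cross_section(mesh, c(0, 0, 0), c(0, 1, 0), triangles = F_sel),
      error = function(e)
        stop(sprintf("find_styloid: no XZ section at iteration %d", it),
             call. = FALSE))
    si <- section_inertia(curve)
    c3 <- uv_to_3d(curve, si$centroid_uv)
    st <- push_transform(mesh, total, rigid_transform(diag(3), -c3))
    mesh <- st$mesh; total <- st$transform
    ax <- section_axis_3d(curve, si, c(1, 0, 0))
    st <- push_transform(mesh, total,
                         rigid_transform(rotation_between(ax, c(1, 0, 0))))
    mesh <- st$mesh; total <- st$transform
  }
  F_sel <- select_triangles_z(mesh, -5)
  vid <- sort(unique(as.vector(F_sel)))
  P <- mesh$vertices[vid, , drop = FALSE]
  P <- P[P[, 1] > 0, , drop = FALSE]
  if (nrow(P) == 0L)
    stop("find_styloid: no vertices on the radial (x > 0) side; check side flag",
         call. = FALSE)
  sty <- P[argmax_lex(P, P[, 3]), ]
  list(styloid = as.numeric(sty), mesh = mesh, transform = total)
}

#' Detect the ulnar dorsal and volar corners
#'
#' The dorsal corner is the point with the highest z-coordinate on the ulnar
#' (x < 0) side after tilting the model 25 degrees about both X and Y (which
#' raises the dorsal-ulnar quadrant distally); the volar corner likewise
#' under -25 degrees about X and +25 about Y. Both searches run over the
#' vertices of the z > -5 mm distal selection and are evaluated in the tilted
#' frames without mutating the working frame; the origin is then translated
#' in x and y to the corner midpoint.
#'
#' @param mesh a [triangle_mesh()] in the frame after styloid detection.
#' @return List with `dorsal`, `volar` (corner points, returned-frame
#'   coordinates), `mesh` and `transform`.
#' @export
find_ulnar_corners <- function(mesh) {
  F_sel <- select_triangles_z(mesh, -5)
  vid <- sort(unique(as.vector(F_sel)))
  P <- mesh$vertices[vid, , drop = FALSE]
  P <- P[P[, 1] < 0, , drop = FALSE]
  if (nrow(P) == 0L)
    stop("find_ulnar_corners: no vertices on the ulnar (x < 0) side",
         call. = FALSE)
  score_d <- as.numeric(P %*% (rotation_y(25) %*% rotation_x(25))[3, ])
  score_v <- as.numeric(P %*% (rotation_y(25) %*% rotation_x(-25))[3, ])
  dorsal <- as.numeric(P[argmax_lex(P, score_d), ])
  volar <- as.numeric(P[argmax_lex(P, score_v), ])
  mid <- (dorsal + volar) / 2
  step <- rigid_transform(diag(3), c(-mid[1], -mid[2], 0))
  list(dorsal = transform_points(step, dorsal),
       volar = transform_points(step, volar),
       mesh = apply_transform(mesh, step),
       transform = step)
}

#' Detect the central reference point (CRP)
#'
#' With the model tilted 25 degrees about Y (raising the ulnar side),
#' triangles with z > -10 mm are selected, cut with the XZ-plane, and the
#' section point with the highest (tilted) z becomes the CRP -- the midpoint
#' of the sigmoid-notch edge of the articular surface. The working origin
#' moves to it: the CRP is the final origin of the anatomical coordinate
#' system.
#'
#' @param mesh a [triangle_mesh()] with origin at the ulnar-corner midpoint.
#' @return List with `crp` (always `c(0,0,0)` in the returned frame), `mesh`
#'   and `transform`.
#' @export
find_crp <- function(mesh) {
  R <- rotation_y(25)
  tilted <- mesh
  tilted$vertices <- mesh$vertices %*% t(R)
  F_sel <- select_triangles_z(tilted, -10)
  if (nrow(F_sel) < 10L)
    stop("find_crp: empty distal selection", call. = FALSE)
  curve <- tryCatch(
    cross_section(tilted, c(0, 0, 0), c(0, 1, 0), triangles = F_sel),
    error = function(e) stop("find_crp: no XZ section", call. = FALSE))
  pts <- do.call(rbind, lapply(curve$loops, function(lp) lp$points))
  crp_tilted <- pts[argmax_lex(pts, pts[, 3]), ]
  crp <- as.numeric(t(R) %*% crp_tilted)
  step <- rigid_transform(diag(3), -crp)
  list(crp = c(0, 0, 0), crp_before = crp,
       mesh = apply_transform(mesh, step), transform = step)
}

#' Extract the dorsal and volar cortical-margin curves
#'
#' Twenty planes parallel to the YZ-plane are spaced between the CRP (origin)
#' and the styloid at `x_i = (i - 0.5)/20 * x_styloid` (centre-of-bin spacing
#' avoids degenerate cuts exactly at either landmark). On each plane's
#' section of the z > -5 mm selection, the point with the highest z under a
#' +5 degree tilt about X is the dorsal margin point, and under -5 degrees
#' the volar margin point. Each margin polyline runs CRP, the 20 points
#' ordered by x, then the styloid, so that its normalised arc length spans
#' CRP (0%) to styloid (100%).
#'
#' @param mesh a [triangle_mesh()] with origin at the CRP.
#' @param styloid styloid point in the same frame.
#' @param n_sections number of section planes (default 20).
#' @param tilt_deg margin disambiguation tilt in degrees (default 5).
#' @return List with `dorsal` and `volar`, each an (n_sections + 2) x 3
#'   matrix.
#' @export
extract_margins <- function(mesh, styloid, n_sections = 20L, tilt_deg = 5) {
  xs <- styloid[1]
  if (xs <= 0)
    stop("extract_margins: styloid not on the radial (x > 0) side", call. = FALSE)
  # inclusive selection (any vertex above the threshold): keeps the thin
  # rim slivers next to the sigmoid-notch corners in the near-CRP sections
  F_sel <- select_triangles_z(mesh, -5, by = "any_vertex")
  if (nrow(F_sel) < 10L)
    stop("extract_margins: empty distal selection", call. = FALSE)
  s <- sin(tilt_deg * pi / 180); c <- cos(tilt_deg * pi / 180)
  dorsal <- matrix(NA_real_, n_sections, 3L)
  volar <- matrix(NA_real_, n_sections, 3L)
  for (i in seq_len(n_sections)) {
    xi <- (i - 0.5) / n_sections * xs
    curve <- tryCatch(
      cross_section(mesh, c(xi, 0, 0), c(1, 0, 0), triangles = F_sel),
      error = function(e)
        stop(sprintf("extract_margins: empty section at plane %d (x = %.2f mm)",
                     i, xi), call. = FALSE))
    pts <- do.call(rbind, lapply(curve$loops, function(lp) lp$points))
    dorsal[i, ] <- pts[argmax_lex(pts, pts[, 2] * s + pts[, 3] * c), ]
    volar[i, ] <- pts[argmax_lex(pts, -pts[, 2] * s + pts[, 3] * c), ]
  }
  list(dorsal = rbind(c(0, 0, 0), dorsal, styloid),
       volar = rbind(c(0, 0, 0), volar, styloid))
}

#' Reference points at fixed fractions of the margin arc length
#'
#' Linear interpolation along each margin polyline at the stated fraction of
#' its normalised cumulative arc length (CRP = 0, styloid = 1): the volar
#' reference at 33% and the dorsal reference at 57%. These two points define
#' the articular-surface line for volar tilt.
#'
#' @param dorsal,volar margin polylines from [extract_margins()].
#' @param dorsal_fraction,volar_fraction arc-length fractions (defaults 0.57
#'   and 0.33).
#' @return List with `dorsal_ref` and `volar_ref` (length-3 points).
#' @export
margin_reference_points <- function(dorsal, volar,
                                    dorsal_fraction = 0.57,
                                    volar_fraction = 0.33) {
  list(dorsal_ref = point_at_fraction(dorsal, dorsal_fraction),
       volar_ref = point_at_fraction(volar, volar_fraction))
}

#' Interpolate a point at a fraction of a polyline's arc length
#'
#' @param polyline n x 3 matrix with at least 2 rows.
#' @param fraction in \[0, 1\].
#' @return Length-3 point.
#' @export
point_at_fraction <- function(polyline, fraction) {
  P <- as.matrix(polyline)
  if (nrow(P) < 2L)
    stop("point_at_fraction: polyline needs at least 2 points", call. = FALSE)
  seg <- sqrt(rowSums((P[-1L, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  L <- sum(seg)
  if (L < 1e-12)
    stop("point_at_fraction: zero-length polyline", call. = FALSE)
  target <- fraction * L
  cum <- c(0, cumsum(seg))
  i <- findInterval(target, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(P) - 1L)
  t <- (target - cum[i]) / max(seg[i], 1e-300)
  t <- min(max(t, 0), 1)
  as.numeric(P[i, ] + t * (P[i + 1L, ] - P[i, ]))
}
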