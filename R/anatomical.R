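#' Final anatomical coordinate system
#'
#' Steps that lock the coordinate system used for the angle measurements:
#' the longitudinal Z-axis is taken from shaft inertia axes (first in a band
#' 40-60 mm proximal to the styloid, then, definitively, 28.8-53.3 mm
#' proximal to the CRP -- the segment reported to best reproduce the 2D
#' longitudinal axis), the origin is the CRP, and X points from the CRP
#' toward the styloid, perpendicular to Z.
#'
#' @name anatomical_cs
NULL

#' Central-line axis of a shaft band
#'
#' Estimates the longitudinal axis of the shaft segment inside a z-interval
#' as the major principal axis of area-weighted thin-slice centroids. Unlike
#' the raw triangle covariance, slice centroids are unbiased when the band is
#' selected in a frame still tilted relative to the shaft (an oblique thin
#' slice of a tube is a complete elliptical band centred on the tube axis),
#' which makes the two alignment passes convergent.
#'
#' @param mesh a [triangle_mesh()].
#' @param z_range length-2 z-interval (mm) selecting triangles by centroid z.
#' @param n_slices number of slices (default 8).
#' @param min_triangles minimum triangles in the band.
#' @return Unit length-3 vector, sign-aligned with +Z.
#' @export
shaft_band_axis <- function(mesh, z_range, n_slices = 8L, min_triangles = 50L) {
  cz <- triangle_centroids(mesh$vertices, mesh$triangles)[, 3]
  keep <- cz > z_range[1] & cz < z_range[2]
  if (sum(keep) < min_triangles)
    stop(sprintf("shaft_band_axis: only %d triangles in z-range [%g, %g]",
                 sum(keep), z_range[1], z_range[2]), call. = FALSE)
  F <- mesh$triangles[keep, , drop = FALSE]
  ctr <- triangle_centroids(mesh$vertices, F)
  w <- triangle_areas(mesh$vertices, F)
  edges <- seq(z_range[1], z_range[2], length.out = n_slices + 1L)
  sl <- findInterval(ctr[, 3], edges, rightmost.closed = TRUE)
  cents <- NULL; wts <- NULL
  for (s in seq_len(n_slices)) {
    in_s <- sl == s
    if (!any(in_s)) next
    ws <- w[in_s]
    cents <- rbind(cents, colSums(ctr[in_s, , drop = FALSE] * ws) / sum(ws))
    wts <- c(wts, sum(ws))
  }
  if (is.null(cents) || nrow(cents) < 3L)
    stop("shaft_band_axis: too few usable slices", call. = FALSE)
  mu <- colSums(cents * wts) / sum(wts)
  dc <- sweep(cents, 2L, mu)
  M <- t(dc) %*% (dc * wts) / sum(wts)
  ax <- eigen(M, symmetric = TRUE)$vectors[, 1]
  if (ax[3] < 0) ax <- -ax
  ax
}

#' Align the Z-axis with the radial shaft
#'
#' Two successive alignment passes: origin to the styloid with the inertia
#' axis of triangles in \[-60, -40\] mm rotated onto Z, then origin to the CRP
#' with the inertia axis of triangles in \[-53.3, -28.8\] mm rotated onto Z.
#' Band membership is by triangle centroid z. A model too short for a band
#' fails with an error naming the band. The returned frame has its origin at
#' the CRP.
#'
#' @param mesh a [triangle_mesh()] with origin at the CRP (post landmark
#'   detection).
#' @param styloid,crp landmark points in the same frame.
#' @param styloid_band,crp_band z-intervals (mm, relative to the respective
#'   landmark) whose triangles define the shaft axis. Defaults are the
#'   published constants.
#' @return List with `mesh`, `transform` (cumulative), and
#'   `band_axis_split`, the angle (degrees) between the inertia axes of the
#'   proximal and distal halves of the CRP band -- near zero for a straight
#'   shaft, large when a deformity crosses the band (the known failure mode
#'   for very proximal malunions).
#' @export
align_shaft_axes <- function(mesh, styloid, crp,
                             styloid_band = c(-60, -40),
                             crp_band = c(-53.3, -28.8)) {
  total <- identity_transform()
  lm <- rbind(styloid = styloid, crp = crp)

  pass <- function(mesh, total, lm, anchor_name, band, band_name) {
    anchor <- lm[anchor_name, ]
    step <- rigid_transform(diag(3), -anchor)
    mesh <- apply_transform(mesh, step)
    lm <- transform_points(step, lm)
    total <- compose_transform(step, total)
    ax <- tryCatch(
      shaft_band_axis(mesh, band),
      error = function(e)
        stop(sprintf("align_shaft_axes: %s band [%g, %g] mm is empty or too sparse",
                     band_name, band[1], band[2]), call. = FALSE))
    step <- rigid_transform(rotation_between(ax, c(0, 0, 1)))
    mesh <- apply_transform(mesh, step)
    lm <- transform_points(step, lm)
    total <- compose_transform(step, total)
    list(mesh = mesh, total = total, lm = lm)
  }

  p1 <- pass(mesh, total, lm, "styloid", styloid_band, "styloid")
  # the CRP-band pass is repeated until the incremental rotation is small:
  # with the frame still tilted, band selection is oblique and one pass
  # under-corrects; the fixed point is reached in 2-3 passes
  p2 <- pass(p1$mesh, p1$total, p1$lm, "crp", crp_band, "CRP")
  for (i in 1:3) {
    prev <- p2$total$rotation
    p2 <- pass(p2$mesh, p2$total, p2$lm, "crp", crp_band, "CRP")
    inc <- p2$total$rotation %*% t(prev)
    if (acos(min(1, max(-1, (sum(diag(inc)) - 1) / 2))) * 180 / pi < 0.2) break
  }

  # deformity check: do the central-line directions of the proximal and
  # distal halves of the band disagree? A deformity apex inside the band
  # bends the centroid line; a straight shaft gives a fraction of a degree.
  split_angle <- tryCatch({
    ctr_of <- function(rng) {
      cz <- triangle_centroids(p2$mesh$vertices, p2$mesh$triangles)[, 3]
      keep <- cz > rng[1] & cz < rng[2]
      if (sum(keep) < 25L) stop("sparse band quarter")
      Fh <- p2$mesh$triangles[keep, , drop = FALSE]
      w <- triangle_areas(p2$mesh$vertices, Fh)
      colSums(triangle_centroids(p2$mesh$vertices, Fh) * w) / sum(w)
    }
    q <- seq(crp_band[1], crp_band[2], length.out = 5L)
    d1 <- ctr_of(q[3:4] + c(0, 0)) - ctr_of(q[1:2])   # proximal half direction
    d2 <- ctr_of(q[4:5]) - ctr_of(q[2:3])             # distal half direction
    th <- angle_between(d1, d2)
    min(th, 180 - th)
  }, error = function(e) NA_real_)

  list(mesh = p2$mesh, transform = p2$total, band_axis_split = split_angle)
}

#' Refine the styloid position
#'
#' Replaces the styloid by the vertex with the highest z-coordinate within a
#' 2-mm Euclidean radius of the previous styloid point; the input point is
#' kept if no neighbour beats it.
#'
#' @param mesh a [triangle_mesh()] in the final frame.
#' @param styloid current styloid point.
#' @param radius search radius in mm (default 2).
#' @return Length-3 refined styloid point.
#' @export
refine_styloid <- function(mesh, styloid, radius = 2) {
  V <- mesh$vertices
  d2 <- (V[, 1] - styloid[1])^2 + (V[, 2] - styloid[2])^2 + (V[, 3] - styloid[3])^2
  near <- V[d2 <= radius^2, , drop = FALSE]
  if (nrow(near) == 0L || max(near[, 3]) <= styloid[3]) return(as.numeric(styloid))
  as.numeric(near[argmax_lex(near, near[, 3]), ])
}

#' Build the anatomical coordinate system
#'
#' Origin at the CRP; X is the component of (styloid - CRP) orthogonal to the
#' given Z-axis, normalised; Y completes the right-handed frame (`Z x X`),
#' pointing dorsally in canonical form. A styloid lying on the Z-axis leaves
#' X undefined and is an error.
#'
#' @param crp CRP point (origin).
#' @param styloid styloid point, same frame.
#' @param z_axis unit Z-axis (defaults to `c(0,0,1)`, the frame axis after
#'   [align_shaft_axes()]).
#' @return An object of class `anatomical_cs` with `origin`, `x_axis`,
#'   `y_axis`, `z_axis`.
#' @export
build_cs <- function(crp, styloid, z_axis = c(0, 0, 1)) {
  z <- z_axis / sqrt(sum(z_axis^2))
  v <- styloid - crp
  x <- v - sum(v * z) * z
  nx <- sqrt(sum(x^2))
  if (nx < 1e-6)
    stop("build_cs: styloid lies on the Z-axis; X-axis undefined", call. = FALSE)
  x <- x / nx
  y <- cross3(z, x)
  structure(list(origin = as.numeric(crp), x_axis = x, y_axis = y, z_axis = z),
            class = "anatomical_cs")
}

#' @export
print.anatomical_cs <- function(x, ...) {
  cat("anatomical_cs (origin = CRP)\n")
  cat(sprintf("  origin: %s\n", paste(sprintf("%.3f", x$origin), collapse = ", ")))
  for (ax in c("x_axis", "y_axis", "z_axis"))
    cat(sprintf("  %s: %s\n", ax, paste(sprintf("%.6f", x[[ax]]), collapse = ", ")))
  invisible(x)
}

#' Express points in an anatomical coordinate system
#'
#' @param cs an [build_cs()] result.
#' @param points n x 3 matrix or length-3 vector, frame of `cs`.
#' @return Coordinates relative to the CS origin and axes, same shape.
#' @export
to_cs_coordinates <- function(cs, points) {
  R <- rbind(cs$x_axis, cs$y_axis, cs$z_axis)
  if (is.null(dim(points))) as.numeric(R %*% (points - cs$origin))
  else sweep(points, 2L, cs$origin) %*% t(R)
}
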