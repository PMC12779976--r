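#' Rigid transforms
#'
#' A rigid transform is a proper rotation (3x3 orthonormal, det +1) followed by
#' a translation, applied as `p -> R p + t`. These carry every "rotated about
#' the origin" / "translated along the Z-axis" step of the measurement
#' pipeline so that the cumulative map from the imported frame to the final
#' anatomical frame is always available.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 translation in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rigid_transform: rotation must be 3x3 and translation length 3", call. = FALSE)
  if (!is_rotation_matrix(rotation))
    stop("rigid_transform: rotation is not orthonormal with det +1 (tol 1e-9)",
         call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation (mm):", paste(round(x$translation, 4), collapse = ", "), "\n")
  invisible(x)
}

is_rotation_matrix <- function(R, tol = 1e-9) {
  is.numeric(R) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < 1e-6
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` returns the transform equivalent to applying `b`
#' first and `a` second.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param t A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(t) {
  Rt <- t(t$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% t$translation))
}

#' Apply a rigid transform to points
#'
#' @param t A `rigid_transform`.
#' @param points An n x 3 matrix (or length-3 vector) of points.
#' @return Transformed points, same shape as the input.
#' @export
transform_points <- function(t, points) {
  if (is.null(dim(points))) {
    as.numeric(t$rotation %*% points) + t$translation
  } else {
    sweep(points %*% t(t$rotation), 2L, t$translation, "+")
  }
}

#' Elementary rotations (degrees)
#'
#' Right-handed rotations about the coordinate axes; angles in degrees.
#' `rotation_x(25)` tips +Y toward +Z (the dorsal side distally, in the
#' canonical frame).
#'
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_x <- function(angle_deg) {
  a <- angle_deg * pi / 180; c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' @rdname rotation_x
#' @export
rotation_y <- function(angle_deg) {
  a <- angle_deg * pi / 180; c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' @rdname rotation_x
#' @export
rotation_z <- function(angle_deg) {
  a <- angle_deg * pi / 180; c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Minimal rotation mapping one direction onto another
#'
#' Returns the rotation about `from x to` (the smallest-angle rotation)
#' that maps unit vector `from` onto unit vector `to`. Antiparallel inputs
#' rotate 180 degrees about a deterministic perpendicular axis.
#'
#' @param from,to non-zero 3-vectors (normalised internally).
#' @return 3x3 rotation matrix.
#' @export
rotation_between <- function(from, to) {
  f <- from / sqrt(sum(from^2))
  t <- to / sqrt(sum(to^2))
  v <- cross3(f, t)
  s <- sqrt(sum(v^2))
  c <- sum(f * t)
  if (s < 1e-12) {
    if (c > 0) return(diag(3))
    # 180 degrees: pick any axis perpendicular to f, deterministically
    ref <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- cross3(f, ref)
    axis <- axis / sqrt(sum(axis^2))
    return(axis_angle_rotation(axis, 180))
  }
  vx <- skew3(v)
  diag(3) + vx + vx %*% vx * ((1 - c) / s^2)
}

axis_angle_rotation <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  axis <- axis / sqrt(sum(axis^2))
  K <- skew3(axis)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

#' Angle between two vectors
#'
#' @param u,v non-zero 3-vectors.
#' @return Angle in degrees, in \[0, 180\].
#' @export
angle_between <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12)
    stop("angle_between: zero vector", call. = FALSE)
  d <- sum(u * v) / (nu * nv)
  d <- min(1, max(-1, d))
  acos(d) * 180 / pi
}
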