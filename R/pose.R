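#' Canonical pose estimation
#'
#' Standardises an imported radius model, initially in arbitrary orientation,
#' so that the origin is at the (surface) centre of mass, +Z points distally,
#' +X radially and +Y dorsally. Three stages: whole-surface inertia alignment,
#' proximal/distal disambiguation by cross-section circularity at the 8% and
#' 92% levels, and radial-ulnar orientation from the interosseous-ridge
#' inflection on the 35% section.
#'
#' @name canonical_pose
NULL

z_at_fraction <- function(mesh, f) {
  zr <- range(mesh$vertices[, 3])
  zr[1] + f * (zr[2] - zr[1])
}

#' Align the longitudinal axis with Z
#'
#' Rotates the largest principal axis of the whole surface onto the Z-axis
#' (minimal rotation) and translates the area-weighted surface centroid to
#' the origin. A near-isotropic mesh (extent ratio of the two largest
#' principal radii below 2) is rejected as not a long bone.
#'
#' @param mesh a [triangle_mesh()].
#' @return A partial pose result: list with `mesh` (aligned), `transform`
#'   (input frame to aligned frame).
#' @export
align_long_axis <- function(mesh) {
  ctr <- triangle_centroids(mesh$vertices, mesh$triangles)
  w <- triangle_areas(mesh$vertices, mesh$triangles)
  W <- sum(w)
  com <- colSums(ctr * w) / W
  dc <- sweep(ctr, 2L, com)
  M <- t(dc) %*% (dc * w) / W
  eig <- eigen(M, symmetric = TRUE)
  if (sqrt(eig$values[1] / max(eig$values[2], 1e-300)) < 2)
    stop("align_long_axis: mesh is not elongated enough to be a long bone",
         call. = FALSE)
  R <- rotation_between(eig$vectors[, 1], c(0, 0, 1))
  t <- rigid_transform(R, as.numeric(-R %*% com))
  list(mesh = apply_transform(mesh, t), transform = t)
}

#' Orient the proximal end toward -Z
#'
#' Compares cross-section circularity at 8% and 92% of the model's z-extent:
#' the more circular end is the proximal radial head. If it lies toward +Z
#' the model is flipped 180 degrees about X so that the proximal end aligns
#' with -Z. Scores within 0.02 of each other abort with an end-ambiguity
#' error.
#'
#' @param pose result of [align_long_axis()].
#' @return The pose list, with `proximal_score` / `distal_score` added.
#' @export
orient_proximal_distal <- function(pose) {
  mesh <- pose$mesh
  c_lo <- circularity(cross_section(mesh, c(0, 0, z_at_fraction(mesh, 0.08)),
                                    c(0, 0, 1)))
  c_hi <- circularity(cross_section(mesh, c(0, 0, z_at_fraction(mesh, 0.92)),
                                    c(0, 0, 1)))
  if (abs(c_lo - c_hi) < 0.02)
    stop(sprintf(paste0("orient_proximal_distal: end circularities too similar ",
                        "(%.3f vs %.3f); cannot tell proximal from distal"),
                 c_lo, c_hi), call. = FALSE)
  if (c_hi > c_lo) {     # proximal (rounder) end is at +Z: flip about X
    t <- rigid_transform(rotation_x(180))
    mesh <- apply_transform(mesh, t)
    pose$transform <- compose_transform(t, pose$transform)
    pose$mesh <- mesh
    pose$proximal_score <- c_hi
    pose$distal_score <- c_lo
  } else {
    pose$proximal_score <- c_lo
    pose$distal_score <- c_hi
  }
  pose
}

#' Orient the radial-ulnar axis from the interosseous ridge
#'
#' Cuts the model at 35% of its length from the proximal (-Z) end and finds
#' the most prominent inflection point, the apex of the interosseous ridge,
#' which points toward the ulna. The model is rotated about Z so the line
#' through this point perpendicular to Z becomes the X-axis with negative X
#' ulnar; Y completes the right-handed frame, putting +Y dorsal for
#' right-side (canonical) models. Left models must be mirrored with
#' [mirror_x()] before this step.
#'
#' @param pose result of [orient_proximal_distal()].
#' @return The pose list with `ulnar_point` and `low_confidence` flag added.
#' @export
orient_radial_ulnar <- function(pose) {
  mesh <- pose$mesh
  cs <- cross_section(mesh, c(0, 0, z_at_fraction(mesh, 0.35)), c(0, 0, 1))
  prominent <- TRUE
  p <- withCallingHandlers(
    most_prominent_inflection(cs),
    warning = function(w) {
      if (grepl("prominent", conditionMessage(w))) {
        prominent <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  ctr <- loop_centroid(cs)
  azim <- atan2(p[2] - ctr[2], p[1] - ctr[1]) * 180 / pi
  # rotate so the ridge apex sits at azimuth 180 degrees (ulnar = -X)
  t <- rigid_transform(rotation_z(180 - azim))
  pose$mesh <- apply_transform(mesh, t)
  pose$transform <- compose_transform(t, pose$transform)
  pose$ulnar_point <- transform_points(t, as.numeric(p))
  pose$low_confidence <- !prominent
  pose
}

#' Full canonical pose
#'
#' Runs [align_long_axis()], [orient_proximal_distal()] and
#' [orient_radial_ulnar()] in sequence; left-side meshes are mirrored to the
#' canonical right-radius form first.
#'
#' @param mesh a [triangle_mesh()].
#' @param side overrides the side recorded on the mesh (`"left"`, `"right"`).
#' @return Pose list: `mesh` (canonical), `transform` (from the, possibly
#'   mirrored, input frame), `proximal_score`, `distal_score`, `ulnar_point`,
#'   `low_confidence`, `mirrored`.
#' @export
canonical_pose <- function(mesh, side = NULL) {
  if (!is.null(side)) mesh$side <- match.arg(side, c("left", "right", "unknown"))
  mirrored <- FALSE
  if (identical(mesh$side, "left")) {
    mesh <- mirror_x(mesh)
    mirrored <- TRUE
  }
  pose <- align_long_axis(mesh)
  pose <- orient_proximal_distal(pose)
  pose <- orient_radial_ulnar(pose)
  pose$mirrored <- mirrored
  pose
}
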