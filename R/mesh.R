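#' Triangle mesh of a radius model
#'
#' The sole geometric input of the measurement pipeline: an indexed triangle
#' surface in millimetres. Construction merges duplicate vertices (tolerance
#' 1e-6 mm, so STL "facet soup" becomes a connected surface), drops degenerate
#' triangles, and records the anatomical side.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param side `"left"`, `"right"` or `"unknown"`.
#' @param clean merge duplicate vertices and drop degenerate triangles
#'   (default `TRUE`).
#' @param check_extent warn when the longest extent falls outside
#'   \[100, 400\] mm (an adult radius is roughly 200-290 mm; out-of-range
#'   extents usually mean metre- or inch-scaled files).
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `triangles`, `side`.
#' @export
triangle_mesh <- function(vertices, triangles, side = c("unknown", "left", "right"),
                          clean = TRUE, check_extent = FALSE) {
  side <- match.arg(side)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L || ncol(triangles) != 3L)
    stop("triangle_mesh: vertices and triangles must have 3 columns", call. = FALSE)
  if (nrow(triangles) < 1L || nrow(vertices) < 3L)
    stop("triangle_mesh: empty mesh", call. = FALSE)
  if (!all(is.finite(vertices)))
    stop("triangle_mesh: non-finite vertex coordinates", call. = FALSE)
  if (min(triangles) < 1L || max(triangles) > nrow(vertices))
    stop("triangle_mesh: triangle index out of range", call. = FALSE)

  if (clean) {
    merged <- merge_vertices(vertices, triangles, tol = 1e-6)
    vertices <- merged$vertices
    triangles <- merged$triangles
    keep <- triangle_areas(vertices, triangles) > 1e-12 &
      triangles[, 1] != triangles[, 2] &
      triangles[, 2] != triangles[, 3] &
      triangles[, 1] != triangles[, 3]
    triangles <- triangles[keep, , drop = FALSE]
    if (nrow(triangles) < 1L)
      stop("triangle_mesh: no non-degenerate triangles left after cleaning",
           call. = FALSE)
  }

  mesh <- structure(list(vertices = vertices, triangles = triangles, side = side),
                    class = "triangle_mesh")
  if (check_extent) {
    ext <- max(apply(vertices, 2L, function(v) diff(range(v))))
    if (ext < 100 || ext > 400)
      warning(sprintf(paste0("mesh extent %.1f mm outside [100, 400] mm; ",
                             "check that the model is in millimetres"), ext),
              call. = FALSE)
  }
  mesh
}

merge_vertices <- function(vertices, triangles, tol = 1e-6) {
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  idx <- match(key, key)                 # first occurrence of each key
  keep <- which(idx == seq_along(idx))
  remap <- integer(nrow(vertices))
  remap[keep] <- seq_along(keep)
  remap <- remap[idx]
  list(vertices = vertices[keep, , drop = FALSE],
       triangles = matrix(remap[triangles], ncol = 3L))
}

triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c <- vertices[triangles[, 3], , drop = FALSE]
  u <- b - a; v <- c - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

triangle_centroids <- function(vertices, triangles) {
  (vertices[triangles[, 1], , drop = FALSE] +
     vertices[triangles[, 2], , drop = FALSE] +
     vertices[triangles[, 3], , drop = FALSE]) / 3
}

#' @export
print.triangle_mesh <- function(x, ...) {
  ext <- apply(x$vertices, 2L, range)
  cat(sprintf("triangle_mesh: %d vertices, %d triangles, side = %s\n",
              nrow(x$vertices), nrow(x$triangles), x$side))
  cat(sprintf("  extent (mm): x %.1f..%.1f  y %.1f..%.1f  z %.1f..%.1f\n",
              ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2], ext[1, 3], ext[2, 3]))
  invisible(x)
}

#' Apply a rigid transform to a mesh
#'
#' Maps every vertex by rotation then translation; triangle topology and side
#' are unchanged. All pairwise vertex distances are preserved.
#'
#' @param mesh a `triangle_mesh`.
#' @param t a `rigid_transform`.
#' @return The transformed `triangle_mesh`.
#' @export
apply_transform <- function(mesh, t) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (!inherits(t, "rigid_transform"))
    stop("apply_transform: t must be a rigid_transform", call. = FALSE)
  mesh$vertices <- transform_points(t, mesh$vertices)
  mesh
}

#' Mirror a mesh across the YZ-plane
#'
#' Negates x-coordinates and reverses triangle winding so outward normals are
#' preserved; the recorded side flips. Left radii are mirrored to the
#' canonical right-radius form at import so that one code path serves both
#' sides. Mirroring twice restores the original mesh exactly.
#'
#' @param mesh a `triangle_mesh`.
#' @return The mirrored `triangle_mesh`.
#' @export
mirror_x <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  mesh$vertices[, 1] <- -mesh$vertices[, 1]
  mesh$triangles <- mesh$triangles[, c(1L, 3L, 2L), drop = FALSE]
  mesh$side <- switch(mesh$side, left = "right", right = "left", "unknown")
  mesh
}
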