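#' Volar tilt from the margin reference points
#'
#' The angle, projected on the YZ-plane, between the line joining the dorsal
#' and volar margin reference points and the Y-axis:
#' `VT = atan2(z_dorsal - z_volar, y_dorsal - y_volar)` in degrees.
#' Positive values mean the articular surface faces volarly (dorsal rim more
#' distal); negative values indicate a dorsally tilted malunion.
#' X-components are ignored (pure lateral projection, as on a lateral
#' radiograph).
#'
#' @param dorsal_ref,volar_ref reference points in anatomical CS coordinates.
#' @return Volar tilt in degrees.
#' @export
volar_tilt <- function(dorsal_ref, volar_ref) {
  dy <- dorsal_ref[2] - volar_ref[2]
  dz <- dorsal_ref[3] - volar_ref[3]
  if (dy <= 0)
    stop("volar_tilt: dorsal reference is not dorsal of the volar reference",
         call. = FALSE)
  atan2(dz, dy) * 180 / pi
}

#' Radial inclination from the styloid
#'
#' Elevation of the CRP-to-styloid line above the XY-plane:
#' `RI = atan2(z, sqrt(x^2 + y^2))` in degrees, with the styloid in
#' anatomical CS coordinates (CRP at the origin). Because the X-axis is
#' constructed in the styloid-Z plane this equals the angle between the
#' CRP-styloid line and the X-axis, i.e. the conventional frontal-projection
#' definition.
#'
#' @param styloid styloid point in anatomical CS coordinates.
#' @return Radial inclination in degrees.
#' @export
radial_inclination <- function(styloid) {
  r <- sqrt(styloid[1]^2 + styloid[2]^2)
  if (r < 1e-9)
    stop("radial_inclination: styloid is on the Z-axis", call. = FALSE)
  atan2(styloid[3], r) * 180 / pi
}

#' Measurement configuration
#'
#' All algorithm constants, default-locked to the published values; any
#' override is echoed into the measurement report.
#'
#' @param shaft_band z-interval (mm proximal of the CRP) defining the
#'   longitudinal axis (default `c(-53.3, -28.8)`).
#' @param styloid_band first-pass shaft band relative to the styloid
#'   (default `c(-60, -40)`).
#' @param margin_fractions volar and dorsal arc-length fractions
#'   (default `c(volar = 0.33, dorsal = 0.57)`).
#' @param n_margin_sections number of margin section planes (default 20).
#' @param corner_tilt_deg ulnar-corner search tilt (default 25).
#' @param margin_tilt_deg margin disambiguation tilt (default 5).
#' @param refine_iterations distal/styloid refinement iterations (default 5).
#' @return A list of class `radtilt_config`.
#' @export
radtilt_config <- function(shaft_band = c(-53.3, -28.8),
                           styloid_band = c(-60, -40),
                           margin_fractions = c(volar = 0.33, dorsal = 0.57),
                           n_margin_sections = 20L,
                           corner_tilt_deg = 25,
                           margin_tilt_deg = 5,
                           refine_iterations = 5L) {
  structure(list(shaft_band = shaft_band, styloid_band = styloid_band,
                 margin_fractions = margin_fractions,
                 n_margin_sections = as.integer(n_margin_sections),
                 corner_tilt_deg = corner_tilt_deg,
                 margin_tilt_deg = margin_tilt_deg,
                 refine_iterations = as.integer(refine_iterations)),
            class = "radtilt_config")
}

#' Measure volar tilt and radial inclination on a radius model
#'
#' The full automatic pipeline: mirror left models to canonical right form,
#' estimate the canonical pose, refine the distal frame onto the articular
#' surface, detect the styloid, ulnar corners, CRP and cortical-margin
#' reference points, align the final Z-axis with the mid-shaft inertia axis,
#' and compute the two angles. Deterministic: repeated runs on the same mesh
#' are bit-identical. Errors in any stage propagate with the stage name;
#' partial angles are never returned.
#'
#' @param mesh a [triangle_mesh()] (or an STL path, read with [read_stl()]).
#' @param side `"left"`, `"right"` or `NULL` (use the side recorded on the
#'   mesh).
#' @param config a [radtilt_config()].
#' @return An object of class `radius_measurement`: `volar_tilt`,
#'   `radial_inclination` (degrees), `landmarks` (all in anatomical CS
#'   coordinates, mm), `cs` (axes in the final working frame), `side`,
#'   `flags` (character vector of warnings), `config`.
#' @export
measure_radius <- function(mesh, side = NULL, config = radtilt_config()) {
  if (is.character(mesh)) mesh <- read_stl(mesh, side = if (is.null(side)) "unknown" else side)
  stopifnot(inherits(mesh, "triangle_mesh"))
  flags <- character(0)

  pose <- canonical_pose(mesh, side = side)
  if (isTRUE(pose$low_confidence))
    flags <- c(flags, "ulnar_ridge_low_confidence")
  work <- pose$mesh

  rf <- refine_distal_frame(work, iterations = config$refine_iterations)
  work <- rf$mesh

  sty <- find_styloid(work, iterations = config$refine_iterations)
  work <- sty$mesh
  styloid <- sty$styloid

  crn <- find_ulnar_corners(work)
  work <- crn$mesh
  styloid <- transform_points(crn$transform, styloid)
  corners <- list(dorsal = crn$dorsal, volar = crn$volar)

  crp_res <- find_crp(work)
  work <- crp_res$mesh
  styloid <- transform_points(crp_res$transform, styloid)
  corners <- lapply(corners, function(p) transform_points(crp_res$transform, p))
  crp <- c(0, 0, 0)

  margins <- extract_margins(work, styloid,
                             n_sections = config$n_margin_sections,
                             tilt_deg = config$margin_tilt_deg)

  shaft <- align_shaft_axes(work, styloid, crp,
                            styloid_band = config$styloid_band,
                            crp_band = config$shaft_band)
  work <- shaft$mesh
  tr <- shaft$transform
  styloid <- transform_points(tr, styloid)
  crp <- transform_points(tr, crp)
  corners <- lapply(corners, function(p) transform_points(tr, p))
  margins <- lapply(margins, function(m) transform_points(tr, m))
  if (!is.na(shaft$band_axis_split) && shaft$band_axis_split > 3)
    flags <- c(flags, "shaft_band_deformity")

  styloid <- refine_styloid(work, styloid)
  cs <- build_cs(crp, styloid, c(0, 0, 1))

  lm_cs <- list(
    crp = to_cs_coordinates(cs, crp),
    styloid = to_cs_coordinates(cs, styloid),
    ulnar_dorsal_corner = to_cs_coordinates(cs, corners$dorsal),
    ulnar_volar_corner = to_cs_coordinates(cs, corners$volar),
    dorsal_margin = to_cs_coordinates(cs, margins$dorsal),
    volar_margin = to_cs_coordinates(cs, margins$volar))
  refs <- margin_reference_points(lm_cs$dorsal_margin, lm_cs$volar_margin,
                                  dorsal_fraction = config$margin_fractions[["dorsal"]],
                                  volar_fraction = config$margin_fractions[["volar"]])
  lm_cs$dorsal_ref <- refs$dorsal_ref
  lm_cs$volar_ref <- refs$volar_ref

  vt <- volar_tilt(lm_cs$dorsal_ref, lm_cs$volar_ref)
  ri <- radial_inclination(lm_cs$styloid)

  structure(list(volar_tilt = vt, radial_inclination = ri,
                 landmarks = lm_cs, cs = cs,
                 side = mesh$side, flags = flags, config = config,
                 band_axis_split = shaft$band_axis_split,
                 pose = list(proximal_score = pose$proximal_score,
                             distal_score = pose$distal_score,
                             mirrored = pose$mirrored)),
            class = "radius_measurement")
}

#' @export
print.radius_measurement <- function(x, ...) {
  cat("radius measurement\n")
  cat(sprintf("  side: %s%s\n", x$side,
              if (isTRUE(x$pose$mirrored)) " (mirrored to right-canonical)" else ""))
  cat(sprintf("  volar tilt:         %6.1f deg\n", x$volar_tilt))
  cat(sprintf("  radial inclination: %6.1f deg\n", x$radial_inclination))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a measurement report to JSON
#'
#' Angles at full precision, landmarks in anatomical CS coordinates, the CS
#' axes, flags, and a configuration echo so any non-default constant is
#' auditable. The report round-trips losslessly through
#' [read_measurement_report()].
#'
#' @param x a `radius_measurement`.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_measurement_report <- function(x, path) {
  stopifnot(inherits(x, "radius_measurement"))
  rep <- list(
    volar_tilt_deg = x$volar_tilt,
    radial_inclination_deg = x$radial_inclination,
    side = x$side,
    mirrored = isTRUE(x$pose$mirrored),
    flags = as.list(x$flags),
    landmarks = lapply(x$landmarks, function(p) {
      if (is.matrix(p)) unname(apply(p, 1L, as.numeric, simplify = FALSE))
      else as.numeric(p)
    }),
    cs = list(origin = as.numeric(x$cs$origin), x_axis = x$cs$x_axis,
              y_axis = x$cs$y_axis, z_axis = x$cs$z_axis),
    band_axis_split_deg = x$band_axis_split,
    config = unclass(x$config),
    tool = paste0("radtilt ", as.character(utils::packageVersion("radtilt"))))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read back a measurement report
#' @param path path written by [write_measurement_report()].
#' @return The report as a list.
#' @export
read_measurement_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
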