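#' Read an STL surface model
#'
#' Reads binary or ASCII STL (auto-detected), merges duplicate vertices within
#' 1e-6 mm, drops degenerate facets and records the anatomical side. Models
#' are expected in millimetres; an extent outside \[100, 400\] mm triggers a
#' scale warning unless `check_extent = FALSE`.
#'
#' @param path path to an `.stl` file.
#' @param side `"left"`, `"right"` or `"unknown"`. The measurement pipeline
#'   requires a declared side (automatic side detection is unreliable on
#'   malunions and is never silently trusted).
#' @param check_extent warn on implausible physical extent (default `TRUE`).
#' @return A [triangle_mesh()].
#' @export
read_stl <- function(path, side = c("unknown", "left", "right"),
                     check_extent = TRUE) {
  side <- match.arg(side)
  if (!file.exists(path))
    stop(sprintf("read_stl: file not found: %s", path), call. = FALSE)
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80L)
  close(con)
  if (length(head) < 80L) {
    # too short for binary; try ASCII
    tri <- read_stl_ascii(path)
  } else if (stl_is_ascii(path, head)) {
    tri <- read_stl_ascii(path)
  } else {
    tri <- read_stl_binary(path)
  }
  if (nrow(tri) < 3L)
    stop("read_stl: empty or truncated STL", call. = FALSE)
  n_fac <- nrow(tri) / 3L
  triangle_mesh(tri, matrix(seq_len(3L * n_fac), ncol = 3L, byrow = TRUE),
                side = side, clean = TRUE, check_extent = check_extent)
}

stl_is_ascii <- function(path, head) {
  if (!identical(rawToChar(head[1:5]), "solid")) return(FALSE)
  # some binary files start with "solid"; check the declared facet count
  sz <- file.size(path)
  if (sz < 84) return(TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  !is.na(n) && (84 + 50 * as.numeric(n) != sz)
}

read_stl_binary <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (is.na(n) || n < 1L || 84 + 50 * as.numeric(n) > sz)
    stop("read_stl: truncated or corrupt binary STL", call. = FALSE)
  rec <- readBin(con, "raw", 50L * n)
  # each 50-byte record: 12 floats-normal(3)+vertices(9), then uint16 attr
  dim(rec) <- c(50L, n)
  fl <- readBin(as.raw(rec[1:48, ]), "double", size = 4L, n = 12L * n,
                endian = "little")
  fl <- matrix(fl, nrow = 12L)           # cols = facets; rows 4:12 = vertices
  verts <- matrix(as.numeric(fl[4:12, ]), ncol = 3L, byrow = TRUE)
  verts
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) < 3L || length(vlines) %% 3L != 0L)
    stop("read_stl: malformed ASCII STL", call. = FALSE)
  nums <- lapply(strsplit(trimws(vlines), "\\s+"), function(x) as.numeric(x[2:4]))
  verts <- do.call(rbind, nums)
  if (anyNA(verts))
    stop("read_stl: non-numeric vertex in ASCII STL", call. = FALSE)
  verts
}

#' Write a mesh to STL
#'
#' Binary STL by default; `ascii = TRUE` writes the ASCII dialect. Facet
#' normals are recomputed from the winding.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param ascii write ASCII STL instead of binary.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  V <- mesh$vertices; F <- mesh$triangles
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  u <- b - a; v <- c - a
  nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len < 1e-30] <- 1
  nrm <- nrm / len

  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid radtilt", con)
    for (i in seq_len(nrow(F))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", a[i, 1], a[i, 2], a[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", b[i, 1], b[i, 2], b[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", c[i, 1], c[i, 2], c[i, 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid radtilt", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(formatC("radtilt binary STL", width = -80)), con)
    writeBin(as.integer(nrow(F)), con, size = 4L, endian = "little")
    block <- rbind(t(nrm), t(a), t(b), t(c))   # 12 floats per facet, in cols
    flraw <- writeBin(as.numeric(block), raw(), size = 4L, endian = "little")
    dim(flraw) <- c(48L, nrow(F))
    rec <- rbind(flraw, matrix(as.raw(0L), 2L, nrow(F)))
    writeBin(as.vector(rec), con)
  }
  invisible(path)
}
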