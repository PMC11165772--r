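# Triangle meshes in millimetre coordinates, and surface extraction from
# binary masks.
#
# Isosurfacing uses the voxel-boundary ("cuberille") surface: every exposed
# face of a foreground voxel cube becomes two triangles. For a binary mask
# this IS the 0.5-level set under nearest-neighbour interpolation; it is
# watertight for face-connected masks and keeps mm units exact, which is all
# the downstream extent measurements need.

#' Construct a triangle mesh
#'
#' @param vertices n x 3 matrix of mm coordinates.
#' @param faces m x 3 integer matrix of vertex indices (1-based), outward
#'   counter-clockwise winding.
#' @param side optional side label (`"left"`/`"right"`).
#' @return object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, side = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face vertex indices out of range")
  structure(list(vertices = vertices, faces = faces, side = side),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("<triangle_mesh> %d vertices, %d faces%s\n", nrow(x$vertices),
              nrow(x$faces), if (!is.null(x$side)) paste0(", side ", x$side) else ""))
  cat(sprintf("  extents X %.1f..%.1f  Y %.1f..%.1f  Z %.1f..%.1f mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Signed enclosed volume of a closed mesh (divergence theorem)
#' @param mesh a [triangle_mesh] with outward winding.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  cr <- cbind(v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2],
              v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3],
              v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  sum(v1 * cr) / 6
}

#' Is every edge shared by exactly two faces?
#' @param mesh a [triangle_mesh].
#' @return logical.
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

face_areas <- function(mesh) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  e1 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE] - v1
  e2 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE] - v1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Extract the cavity surface from a binary mask
#'
#' Builds the voxel-boundary surface of the largest connected foreground
#' component at the 0.5 level, in mm coordinates. Warns if other components
#' larger than 10% of the largest are discarded.
#'
#' @param volume a [voxel_volume] (non-zero voxels are foreground).
#' @param side optional side label attached to the mesh.
#' @return a closed [triangle_mesh].
#' @export
extract_isosurface <- function(volume, side = NULL) {
  stopifnot(inherits(volume, "voxel_volume"))
  mask <- volume$data != 0
  if (!any(mask)) stop("mask is empty")
  lc <- largest_component(mask)
  if (length(lc$sizes) > 1L && any(lc$sizes[-1] > 0.1 * lc$sizes[1]))
    warning(sprintf("mask has %d connected components (sizes %s); keeping the largest",
                    length(lc$sizes), paste(lc$sizes, collapse = ", ")))
  mask <- lc$mask
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  exposed <- function(di, dj, dk)
    which(core & !pad[2:(d[1] + 1) + di, 2:(d[2] + 1) + dj, 2:(d[3] + 1) + dk],
          arr.ind = TRUE)
  # corner (ci,cj,ck) in 1..d+1 -> world = origin + (c - 1.5) * spacing
  quads_i <- list(); quads_c <- list()
  emit <- function(vox, corners4) {
    # corners4: 4 x 3 integer offsets added to the voxel index
    if (nrow(vox) == 0L) return()
    n <- nrow(vox)
    cs <- lapply(1:4, function(q) sweep(vox, 2, corners4[q, ], `+`))
    quads_i[[length(quads_i) + 1L]] <<- do.call(rbind, cs)
    quads_c[[length(quads_c) + 1L]] <<- n
  }
  # orderings give outward CCW winding (verified by positive mesh_volume)
  emit(exposed(+1, 0, 0), rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1), c(1, 0, 1)))
  emit(exposed(-1, 0, 0), rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1), c(0, 1, 0)))
  emit(exposed(0, +1, 0), rbind(c(0, 1, 0), c(0, 1, 1), c(1, 1, 1), c(1, 1, 0)))
  emit(exposed(0, -1, 0), rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(0, 0, 1)))
  emit(exposed(0, 0, +1), rbind(c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)))
  emit(exposed(0, 0, -1), rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 0, 0)))
  counts <- unlist(quads_c)
  nq <- sum(counts)
  # stack per-type corner blocks into per-quad rows: block b holds its quads'
  # corner q at rows ((q-1)*n_b + 1) .. q*n_b
  corner <- matrix(0L, nq * 4L, 3L)
  offset <- 0L
  qoff <- 0L
  for (b in seq_along(quads_i)) {
    n <- counts[b]
    blk <- quads_i[[b]]
    for (q in 1:4)
      corner[(qoff + seq_len(n) - 1L) * 4L + q, ] <- blk[(q - 1L) * n + seq_len(n), ]
    qoff <- qoff + n
  }
  key <- (corner[, 1]) + (d[1] + 2L) * (corner[, 2] + (d[2] + 2L) * corner[, 3])
  uk <- unique(key)
  vid <- match(key, uk)
  ucorner <- corner[match(uk, key), , drop = FALSE]
  vertices <- sweep(sweep(ucorner - 0.5, 2, volume$spacing, `*`), 2,
                    volume$origin - volume$spacing, `+`)
  q <- matrix(vid, ncol = 4, byrow = TRUE)
  faces <- rbind(q[, c(1, 2, 3), drop = FALSE], q[, c(1, 3, 4), drop = FALSE])
  triangle_mesh(vertices, faces, side = side)
}

# ---- PLY / STL ---------------------------------------------------------

#' Write a mesh as ASCII PLY
#' @param mesh a [triangle_mesh].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0", "comment units mm",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY mesh
#' @param path path to a PLY file written by [write_ply] (or any ASCII PLY
#'   with xyz vertices and triangular faces).
#' @return a [triangle_mesh].
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("only ASCII PLY is supported")
  hdr_end <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  vl <- lines[hdr_end + seq_len(nv)]
  fl <- lines[hdr_end + nv + seq_len(nf)]
  verts <- matrix(scan(text = vl, quiet = TRUE), ncol = 3, byrow = TRUE)
  fm <- matrix(scan(text = fl, quiet = TRUE), ncol = 4, byrow = TRUE)
  if (any(fm[, 1] != 3)) stop("non-triangular faces in ", path)
  triangle_mesh(verts, fm[, 2:4] + 1L)
}

#' Write a mesh as ASCII STL
#' @param mesh a [triangle_mesh].
#' @param path output path.
#' @param name solid name.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, name = "cavity") {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  fmt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
  body <- paste0("facet normal ", fmt(n), "\n outer loop\n  vertex ",
                 fmt(v1), "\n  vertex ", fmt(v2), "\n  vertex ", fmt(v3),
                 "\n endloop\nendfacet")
  writeLines(c(paste("solid", name), body, paste("endsolid", name)), path)
  invisible(path)
}
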