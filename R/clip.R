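# Anatomical boundary surfaces and mesh clipping.
#
# The upper (cranial base), lateral (periorbital) and medial (middle
# turbinate) limits are explicit geometric inputs: oriented planes or
# single-valued heightfields with an inside direction. Clipping keeps the
# part of the mesh inside every boundary's half-space; cut triangles are
# re-triangulated along the boundary, so the result may be open along the
# cut loops. The inferior limit is deliberately NOT clipped: the cavity's
# own lower envelope serves as the inferior boundary.

#' Oriented boundary plane
#'
#' @param point a point on the plane (mm).
#' @param inside_normal normal pointing into the kept half-space.
#' @return a boundary surface usable in [boundary_spec].
#' @export
boundary_plane <- function(point, inside_normal) {
  structure(list(type = "plane", point = as.numeric(point),
                 inside_normal = unitize(as.numeric(inside_normal),
                                         "inside_normal")),
            class = "boundary_surface")
}

#' Heightfield boundary
#'
#' A single-valued surface z = f(x, y); `keep` selects which side survives.
#' Edge crossings are located by linear interpolation of the signed value,
#' exact for planes and first-order for curved fields.
#'
#' @param f function of (x, y) vectors returning the surface height z (mm).
#' @param keep `"below"` (keep z <= f, e.g. a cranial-base roof) or `"above"`.
#' @return a boundary surface usable in [boundary_spec].
#' @export
boundary_heightfield <- function(f, keep = c("below", "above")) {
  keep <- match.arg(keep)
  structure(list(type = "heightfield", f = f, keep = keep),
            class = "boundary_surface")
}

#' Cavity boundary specification
#'
#' @param upper,lateral,medial boundary surfaces ([boundary_plane] /
#'   [boundary_heightfield]) or `NULL` to skip that limit.
#' @return object of class `boundary_spec`.
#' @export
boundary_spec <- function(upper = NULL, lateral = NULL, medial = NULL) {
  b <- list(upper = upper, lateral = lateral, medial = medial)
  for (nm in names(b))
    if (!is.null(b[[nm]]) && !inherits(b[[nm]], "boundary_surface"))
      stop("'", nm, "' must be a boundary surface or NULL")
  structure(b, class = "boundary_spec")
}

# signed inside-value of a boundary surface at points (>= 0 means kept)
boundary_field <- function(surface, pts) {
  if (surface$type == "plane") {
    sweep(pts, 2, surface$point) %*% surface$inside_normal
  } else {
    h <- surface$f(pts[, 1], pts[, 2])
    if (surface$keep == "below") h - pts[, 3] else pts[, 3] - h
  }
}

# Clip a mesh against one scalar field: keep field >= 0, split crossing
# triangles (Sutherland-Hodgman per triangle).
clip_mesh_by_field <- function(mesh, vals, tol = 1e-9) {
  keep <- vals >= -tol
  fkeep <- matrix(keep[mesh$faces], ncol = 3)
  nin <- rowSums(fkeep)
  full <- mesh$faces[nin == 3L, , drop = FALSE]
  mixed <- which(nin == 1L | nin == 2L)
  newv <- list(); newf <- list()
  nv <- nrow(mesh$vertices)
  vcache <- new.env()  # edge midpoint cache: "i_j" -> vertex id
  edge_point <- function(i, j) {
    keyn <- paste0(min(i, j), "_", max(i, j))
    id <- vcache[[keyn]]
    if (!is.null(id)) return(id)
    t <- vals[i] / (vals[i] - vals[j])
    p <- mesh$vertices[i, ] + t * (mesh$vertices[j, ] - mesh$vertices[i, ])
    newv[[length(newv) + 1L]] <<- p
    id <- nv + length(newv)
    vcache[[keyn]] <- id
    id
  }
  for (fi in mixed) {
    tri <- mesh$faces[fi, ]
    ins <- fkeep[fi, ]
    if (sum(ins) == 1L) {
      a <- tri[ins]
      # winding preserved: a, then the crossing points toward the two
      # outside vertices in original order
      ia <- which(ins)
      nxt <- tri[(ia %% 3L) + 1L]; prv <- tri[((ia + 1L) %% 3L) + 1L]
      p1 <- edge_point(a, nxt); p2 <- edge_point(a, prv)
      newf[[length(newf) + 1L]] <- c(a, p1, p2)
    } else {
      ia <- which(!ins)
      out <- tri[ia]
      nxt <- tri[(ia %% 3L) + 1L]; prv <- tri[((ia + 1L) %% 3L) + 1L]
      p1 <- edge_point(out, nxt); p2 <- edge_point(out, prv)
      # quad prv, p2 ... keep winding: (nxt, prv, p2) and (nxt, p2, p1)
      newf[[length(newf) + 1L]] <- c(nxt, prv, p2)
      newf[[length(newf) + 1L]] <- c(nxt, p2, p1)
    }
  }
  verts <- rbind(mesh$vertices, do.call(rbind, newv))
  faces <- rbind(full, do.call(rbind, newf))
  if (is.null(faces) || nrow(faces) == 0L) return(NULL)
  # drop unreferenced vertices
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(verts)); remap[used] <- seq_along(used)
  triangle_mesh(verts[used, , drop = FALSE],
                matrix(remap[faces], ncol = 3), side = mesh$side)
}

#' Clip a cavity mesh by its anatomical boundaries
#'
#' @param mesh a [triangle_mesh].
#' @param boundary a [boundary_spec].
#' @return the clipped [triangle_mesh] (possibly open along cut loops).
#' @export
clip_by_boundary <- function(mesh, boundary) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(boundary, "boundary_spec"))
  out <- mesh
  for (nm in c("upper", "lateral", "medial")) {
    surf <- boundary[[nm]]
    if (is.null(surf)) next
    vals <- as.numeric(boundary_field(surf, out$vertices))
    if (all(vals >= 0)) next
    out <- clip_mesh_by_field(out, vals)
    if (is.null(out))
      stop("boundary excludes entire cavity (", nm, " surface removed all faces)")
  }
  out
}

# ---- boundary JSON -----------------------------------------------------

#' Read a boundary specification from JSON
#'
#' Schema: `{"upper": {"type": "plane", "point": [x,y,z],
#' "inside_normal": [x,y,z]}, "lateral": ..., "medial": ...}`; omitted keys
#' skip that boundary. Heightfields are code-level inputs and have no JSON
#' form.
#'
#' @param path path to JSON.
#' @return a [boundary_spec].
#' @export
read_boundary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(b) {
    if (is.null(b)) return(NULL)
    if (!identical(b$type, "plane"))
      stop("only plane boundaries are supported in JSON")
    boundary_plane(b$point, b$inside_normal)
  }
  boundary_spec(upper = mk(obj$upper), lateral = mk(obj$lateral),
                medial = mk(obj$medial))
}

#' Write a plane-only boundary specification to JSON
#' @param boundary a [boundary_spec] composed of planes.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_boundary <- function(boundary, path) {
  obj <- Filter(Negate(is.null), lapply(unclass(boundary), function(b) {
    if (is.null(b)) return(NULL)
    if (b$type != "plane") stop("only plane boundaries can be serialized")
    list(type = "plane", point = b$point, inside_normal = b$inside_normal)
  }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
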