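# Rigid transforms named by the anatomical VIEW in which each rotation is
# observed: sagittal (about +X), axial (about +Z), coronal (about +Y).
# A misorientation with angles (s, a, c) has rotation
#     M = Rx(s) %*% Rz(a) %*% Ry(c)
# i.e. the coronal rotation is applied first, then axial, then sagittal.
# A correcting transform (inverse = TRUE) stores the SAME angles -- the
# detected misorientation -- but applies t(M), so that
# report_misorientation() always reads off the per-plane misorientation.

rot_x <- function(t) { c <- cos(t); s <- sin(t)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3) }
rot_y <- function(t) { c <- cos(t); s <- sin(t)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3) }
rot_z <- function(t) { c <- cos(t); s <- sin(t)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3) }

# Factor M = Rx(s) Rz(a) Ry(c); returns degrees (sagittal, axial, coronal).
euler_xzy <- function(M) {
  M <- unname(M)
  a <- asin(max(-1, min(1, -M[1, 2])))
  c <- atan2(M[1, 3], M[1, 1])
  s <- atan2(M[3, 2], M[2, 2])
  rad2deg(c(sagittal = s, axial = a, coronal = c))
}

#' Construct a rigid transform
#'
#' Rotations are expressed as one angle per anatomical plane (the view in
#' which the rotation is observed) and composed coronal -> axial -> sagittal.
#'
#' @param sagittal_deg,axial_deg,coronal_deg rotation angles in degrees.
#' @param translation length-3 translation (mm), applied after rotation.
#' @param center rotation centre (mm).
#' @param inverse if `TRUE` the transform applies the inverse rotation (a
#'   correction); the angle fields still record the misorientation.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(sagittal_deg = 0, axial_deg = 0, coronal_deg = 0,
                            translation = c(0, 0, 0), center = c(0, 0, 0),
                            inverse = FALSE) {
  for (nm in c("sagittal_deg", "axial_deg", "coronal_deg"))
    stopifnot_scalar(get(nm), nm)
  structure(list(sagittal_deg = sagittal_deg, axial_deg = axial_deg,
                 coronal_deg = coronal_deg,
                 translation = as.numeric(translation),
                 center = as.numeric(center), inverse = isTRUE(inverse),
                 order = "coronal.axial.sagittal"),
            class = "rigid_transform")
}

#' Rotation matrix of a rigid transform
#' @param t a [rigid_transform].
#' @return 3x3 orthonormal matrix (determinant +1).
#' @export
rotation_matrix <- function(t) {
  M <- rot_x(deg2rad(t$sagittal_deg)) %*% rot_z(deg2rad(t$axial_deg)) %*%
    rot_y(deg2rad(t$coronal_deg))
  if (t$inverse) t(M) else M
}

#' Invert a rigid transform
#' @param t a [rigid_transform].
#' @return the inverse `rigid_transform` (same angle record, flipped sense).
#' @export
invert_transform <- function(t) {
  R <- rotation_matrix(t)
  out <- rigid_transform(t$sagittal_deg, t$axial_deg, t$coronal_deg,
                         translation = as.numeric(-crossprod(R, t$translation)),
                         center = t$center, inverse = !t$inverse)
  out
}

transform_points <- function(t, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  R <- rotation_matrix(t)
  centred <- sweep(pts, 2, t$center)
  out <- centred %*% t(R)
  sweep(out, 2, t$center + t$translation, `+`)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform%s> sagittal %.3f deg, axial %.3f deg, coronal %.3f deg\n",
              if (x$inverse) " (correction)" else "",
              x$sagittal_deg, x$axial_deg, x$coronal_deg))
  cat(sprintf("  translation (%.3f, %.3f, %.3f) mm, order %s\n",
              x$translation[1], x$translation[2], x$translation[3], x$order))
  invisible(x)
}

#' Apply a rigid transform
#'
#' Meshes, landmark sets and point matrices are transformed exactly; voxel
#' volumes are resampled onto a grid of the same spacing with
#' nearest-neighbour interpolation (mask-preserving).
#'
#' @param x a `triangle_mesh`, `head_landmarks`, `voxel_volume`, or n x 3
#'   point matrix.
#' @param t a [rigid_transform].
#' @param ... passed to methods; for volumes, `pad` (`"error"` or `"auto"`).
#' @return object of the same type as `x`.
#' @export
apply_transform <- function(x, t, ...) UseMethod("apply_transform")

#' @export
apply_transform.default <- function(x, t, ...) transform_points(t, x)

#' @export
apply_transform.triangle_mesh <- function(x, t, ...) {
  x$vertices <- transform_points(t, x$vertices)
  x
}

#' @export
apply_transform.head_landmarks <- function(x, t, ...) {
  x$cranial_base <- transform_points(t, x$cranial_base)
  x$nasal_septum <- transform_points(t, x$nasal_septum)
  if (!is.null(x$coronal_check)) x$coronal_check <- transform_points(t, x$coronal_check)
  x
}

#' @rdname apply_transform
#' @param pad for volumes: `"error"` refuses output grids that would clip
#'   foreground (reporting the padding needed); `"auto"` grows the grid.
#' @export
apply_transform.voxel_volume <- function(x, t, pad = c("error", "auto"), ...) {
  pad <- match.arg(pad)
  is_ident <- max(abs(rotation_matrix(t) - diag(3))) < 1e-12 &&
    all(abs(t$translation) < 1e-12)
  if (is_ident) return(x)
  idx <- which(x$data != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty")
  fg_new <- transform_points(t, voxel_to_world(x, idx))
  lo <- apply(fg_new, 2, min); hi <- apply(fg_new, 2, max)
  d <- dim(x$data)
  grid_lo <- x$origin - x$spacing / 2
  grid_hi <- x$origin + (d - 0.5) * x$spacing
  if (pad == "error" && (any(lo < grid_lo) || any(hi > grid_hi))) {
    need <- pmax(0, ceiling(pmax(grid_lo - lo, hi - grid_hi) / x$spacing))
    stop(sprintf(paste0("transformed foreground falls outside the field of view; ",
                        "pad by at least (%d, %d, %d) voxels per side or use pad = \"auto\""),
                 need[1], need[2], need[3]))
  }
  if (pad == "auto") {
    origin <- pmin(x$origin, floor((lo - x$spacing) / x$spacing) * x$spacing + x$spacing / 2)
    far <- pmax(x$origin + (d - 1) * x$spacing, hi + x$spacing)
    d_out <- as.integer(ceiling((far - origin) / x$spacing)) + 1L
  } else {
    origin <- x$origin
    d_out <- d
  }
  # inverse-map output voxel centres into the input grid, nearest neighbour
  inv <- invert_transform(t)
  R <- rotation_matrix(inv)
  gx <- origin[1] + (seq_len(d_out[1]) - 1) * x$spacing[1]
  gy <- origin[2] + (seq_len(d_out[2]) - 1) * x$spacing[2]
  gz <- origin[3] + (seq_len(d_out[3]) - 1) * x$spacing[3]
  pts <- cbind(rep(gx, times = d_out[2] * d_out[3]),
               rep(rep(gy, each = d_out[1]), times = d_out[3]),
               rep(gz, each = d_out[1] * d_out[2]))
  src <- sweep(pts, 2, inv$center) %*% t(R)
  src <- sweep(src, 2, inv$center + inv$translation, `+`)
  ijk <- round(sweep(sweep(src, 2, x$origin), 2, x$spacing, `/`)) + 1
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] & ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  vals <- array(0L, d_out)
  lin <- (ijk[ok, 3] - 1) * d[1] * d[2] + (ijk[ok, 2] - 1) * d[1] + ijk[ok, 1]
  vals[ok] <- as.integer(x$data[lin] != 0)
  voxel_volume(vals, spacing = x$spacing, origin = origin)
}

#' Report per-plane misorientation
#'
#' For a single transform, the magnitude of the rotation observed in each
#' anatomical plane (degrees); for a list of transforms, per-plane mean and
#' SD across the cohort. Magnitudes are reported because the source data do
#' not state a sign convention for averaged angles.
#'
#' For cohort aggregation the mean is taken over magnitudes (matching how
#' average orientation differences are usually quoted) while the SD is that
#' of the signed angles, so that it estimates the dispersion of the sampling
#' distribution.
#'
#' @param t a [rigid_transform] or list of them.
#' @return named numeric vector `(sagittal, axial, coronal)` or a data.frame
#'   with `plane`, `mean_abs_deg`, `sd_deg`.
#' @export
report_misorientation <- function(t) {
  if (inherits(t, "rigid_transform"))
    return(abs(c(sagittal = t$sagittal_deg, axial = t$axial_deg,
                 coronal = t$coronal_deg)))
  stopifnot(is.list(t), all(vapply(t, inherits, TRUE, "rigid_transform")))
  signed <- t(vapply(t, function(x) c(sagittal = x$sagittal_deg,
                                      axial = x$axial_deg,
                                      coronal = x$coronal_deg), numeric(3)))
  data.frame(plane = colnames(signed), mean_abs_deg = colMeans(abs(signed)),
             sd_deg = apply(signed, 2, stats::sd), row.names = NULL)
}
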