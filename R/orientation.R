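# Landmark-based reorientation to the Frankfurt-plane convention.
#
# In the aligned head: the cranial-base line runs along +Y (anteroposterior)
# and the nasal-septum line along +Z (inferosuperior). compute_reorientation
# builds the rotation that restores this state from the two landmark lines.

#' Construct a head landmark set
#'
#' @param cranial_base >= 2 points (mm) clicked along the cranial base line
#'   (sagittal view), ordered anterior to posterior.
#' @param nasal_septum >= 2 points (mm) along the nasal septum line, ordered
#'   inferior to superior.
#' @param coronal_check optional extra points (unused by the solver).
#' @return object of class `head_landmarks`.
#' @export
head_landmarks <- function(cranial_base, nasal_septum, coronal_check = NULL) {
  cb <- matrix(as.numeric(cranial_base), ncol = 3)
  ns <- matrix(as.numeric(nasal_septum), ncol = 3)
  for (nm in c("cranial_base", "nasal_septum")) {
    m <- if (nm == "cranial_base") cb else ns
    if (nrow(m) < 2L) stop("'", nm, "' needs at least 2 points")
    if (max(stats::dist(m)) <= 1)
      stop("'", nm, "' points are (near-)coincident: line length <= 1 mm")
  }
  structure(list(cranial_base = cb, nasal_septum = ns,
                 coronal_check = coronal_check),
            class = "head_landmarks")
}

# Total-least-squares line direction (first principal axis); sign fixed by
# the point ordering (first -> last).
fit_line_direction <- function(pts, what) {
  ctr <- colMeans(pts)
  d <- if (nrow(pts) == 2L) {
    pts[2, ] - pts[1, ]
  } else {
    sv <- svd(sweep(pts, 2, ctr))
    sv$v[, 1]
  }
  d <- unitize(d, paste(what, "line direction"))
  if (sum(d * (pts[nrow(pts), ] - pts[1, ])) < 0) d <- -d
  d
}

#' Compute the reorienting transform from head landmarks
#'
#' Builds the rotation that makes the cranial-base line horizontal in the
#' sagittal and coronal views and the septum line vertical in the axial and
#' coronal views. The returned transform's angle fields record the detected
#' per-plane misorientation; applying the transform corrects it.
#'
#' @param landmarks a [head_landmarks].
#' @return a [rigid_transform] with `inverse = TRUE` (a correction).
#' @export
compute_reorientation <- function(landmarks) {
  stopifnot(inherits(landmarks, "head_landmarks"))
  b <- fit_line_direction(landmarks$cranial_base, "cranial_base")
  s <- fit_line_direction(landmarks$nasal_septum, "nasal_septum")
  x <- cross3(b, s)
  if (vnorm(x) < sin(deg2rad(1)))
    stop("degenerate landmarks: nasal_septum line is (near-)parallel to the ",
         "cranial_base line; cannot define the mediolateral axis")
  x <- x / vnorm(x)
  z <- cross3(x, b)
  # rows of R_align are the measured axes; R_align maps b -> e_y, so
  # R_align = M^T where M is the applied misorientation
  M <- t(rbind(x, b, z))
  ang <- euler_xzy(M)
  rigid_transform(sagittal_deg = ang[["sagittal"]], axial_deg = ang[["axial"]],
                  coronal_deg = ang[["coronal"]], inverse = TRUE)
}

# ---- landmark JSON I/O -------------------------------------------------

#' Write landmarks to JSON
#' @param landmarks a [head_landmarks].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  obj <- list(
    convention = paste("mm coordinates; +X mediolateral (left to right),",
                       "+Y anteroposterior, +Z inferosuperior"),
    cranial_base = unname(split(landmarks$cranial_base,
                                row(landmarks$cranial_base))),
    nasal_septum = unname(split(landmarks$nasal_septum,
                                row(landmarks$nasal_septum))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read landmarks from JSON
#' @param path path to a landmarks JSON file.
#' @return a [head_landmarks].
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  head_landmarks(obj$cranial_base, obj$nasal_septum)
}
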