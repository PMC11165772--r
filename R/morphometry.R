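# Proportional cross-sectioning and per-section width/height/aspect-ratio
# measurement.
#
# The reoriented cavity is sectioned by planes perpendicular to the
# anteroposterior (Y) axis at every `step`% of its length. Each section's
# cutting points (plane-mesh intersection) are fitted with a closed periodic
# cubic spline; the section width W_i is the mediolateral (X) extent of the
# fitted curve, the height H_i the superoinferior (Z) extent, and
# AR_i = W_i / H_i. The 0% plane passes through the frontmost point of the
# cavity (ties broken by minimum Z then minimum X), the 100% plane through
# the backmost point, and L is the distance between them.

#' Measure cavity length and end-plane positions
#'
#' @param mesh a reoriented [triangle_mesh].
#' @return list with `length_mm`, `y0` (0% plane), `y100` (100% plane) and
#'   `front_point` (the frontmost vertex after tie-breaking).
#' @export
measure_length <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$vertices) == 0L) stop("mesh is empty")
  y <- mesh$vertices[, 2]
  y0 <- min(y); y100 <- max(y)
  if (y100 - y0 < 1e-9) stop("zero anteroposterior extent")
  cand <- which(y < y0 + 1e-9)
  cand <- cand[order(mesh$vertices[cand, 3], mesh$vertices[cand, 1])]
  list(length_mm = y100 - y0, y0 = y0, y100 = y100,
       front_point = mesh$vertices[cand[1], ])
}

#' Cut a section at a proportional position
#'
#' Intersects the mesh with the plane perpendicular to Y at `fraction`% of
#' the cavity length. Planes passing exactly through vertices (including
#' the 0%/100% planes on flat end caps) are nudged inward by 1e-6 mm so
#' that every intersection is a clean set of crossing segments. The
#' segments are chained into closed loops; `cutting_points` holds the
#' pooled loop vertices ordered by polar angle about their in-plane
#' centroid, while the loop structure is kept for curve fitting. Where the
#' plane is tangent (typically the 0% and 100% planes of a smoothly closed
#' cavity) a degenerate contour is returned and flagged.
#'
#' @param mesh a reoriented [triangle_mesh].
#' @param fraction section position, percent of length (0..100).
#' @return object of class `section_contour` with fields `fraction`,
#'   `plane_y`, `cutting_points` (n x 3 mm), `loops`, `degenerate`.
#' @export
cut_section <- function(mesh, fraction) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (fraction < 0 || fraction > 100) stop("fraction must be in [0, 100]")
  len <- measure_length(mesh)
  plane_y <- len$y0 + fraction / 100 * len$length_mm
  eps <- 1e-6
  # nudge planes off vertices (end planes always sit on extreme vertices)
  adjust <- if (fraction >= 50) -eps else eps
  if (min(abs(mesh$vertices[, 2] - plane_y)) < eps / 2)
    plane_y <- plane_y + adjust
  loops <- plane_mesh_loops(mesh, plane_y)
  if (is.null(loops) && fraction > 0 && fraction < 100)
    stop("empty intersection at interior fraction ", fraction,
         "%: mesh not contiguous along AP axis")
  pts <- if (!is.null(loops)) do.call(rbind, loops)
  contour <- structure(list(fraction = fraction, plane_y = plane_y,
                            cutting_points = pts, loops = loops,
                            degenerate = FALSE, curve = NULL),
                       class = "section_contour")
  if (is.null(pts) || nrow(pts) < 4L || contour_rank(pts) < 2L ||
      max(diff(range(pts[, 1])), diff(range(pts[, 3]))) < 0.01) {
    contour$degenerate <- TRUE
    if (is.null(pts))
      contour$cutting_points <- matrix(c(len$front_point[1], plane_y,
                                         len$front_point[3]), 1, 3)
  } else {
    xz <- pts[, c(1, 3), drop = FALSE]
    ctr <- colMeans(xz)
    ord <- order(atan2(xz[, 2] - ctr[2], xz[, 1] - ctr[1]),
                 sqrt(rowSums(sweep(xz, 2, ctr)^2)))
    contour$cutting_points <- pts[ord, , drop = FALSE]
  }
  contour
}

# Intersect the mesh with the plane y = plane_y: one segment per strictly
# crossing triangle, chained into loops (open chains from clipped meshes
# are closed). Returns a list of n x 3 point matrices in cyclic order, or
# NULL for an empty intersection.
plane_mesh_loops <- function(mesh, plane_y, tol = 1e-12) {
  v <- mesh$vertices
  dy <- v[, 2] - plane_y
  f <- mesh$faces
  pos <- matrix(dy[f] > 0, ncol = 3)
  npos <- rowSums(pos)
  cross_f <- which(npos == 1L | npos == 2L)
  if (length(cross_f) == 0L) return(NULL)
  seg_a <- matrix(0, length(cross_f), 3)
  seg_b <- matrix(0, length(cross_f), 3)
  for (s in seq_along(cross_f)) {
    tri <- f[cross_f[s], ]
    odd <- if (npos[cross_f[s]] == 1L) which(pos[cross_f[s], ]) else which(!pos[cross_f[s], ])
    o <- tri[odd]; rest <- tri[-odd]
    t1 <- dy[o] / (dy[o] - dy[rest[1]])
    t2 <- dy[o] / (dy[o] - dy[rest[2]])
    seg_a[s, ] <- v[o, ] + t1 * (v[rest[1], ] - v[o, ])
    seg_b[s, ] <- v[o, ] + t2 * (v[rest[2], ] - v[o, ])
  }
  seg_a[, 2] <- plane_y; seg_b[, 2] <- plane_y
  keep <- rowSums((seg_a - seg_b)^2) > tol
  seg_a <- seg_a[keep, , drop = FALSE]; seg_b <- seg_b[keep, , drop = FALSE]
  if (nrow(seg_a) == 0L) return(NULL)
  key <- function(m) paste(round(m[, 1], 6), round(m[, 3], 6))
  ka <- key(seg_a); kb <- key(seg_b)
  nodes <- unique(c(ka, kb))
  ia <- match(ka, nodes); ib <- match(kb, nodes)
  coords <- rbind(seg_a, seg_b)[match(nodes, c(ka, kb)), , drop = FALSE]
  # adjacency: up to first two segments per node
  nseg <- length(ia)
  adj <- vector("list", length(nodes))
  for (s in seq_len(nseg)) {
    adj[[ia[s]]] <- c(adj[[ia[s]]], s)
    adj[[ib[s]]] <- c(adj[[ib[s]]], s)
  }
  used <- logical(nseg)
  loops <- list()
  walk <- function(start_node) {
    path <- start_node
    repeat {
      tail_node <- path[length(path)]
      nxt <- adj[[tail_node]][!used[adj[[tail_node]]]]
      if (length(nxt) == 0L) break
      s <- nxt[1]
      used[s] <<- TRUE
      path <- c(path, if (ia[s] == tail_node) ib[s] else ia[s])
    }
    path
  }
  for (s0 in seq_len(nseg)) {
    if (used[s0]) next
    used[s0] <- TRUE
    fwd <- walk(ib[s0])
    bwd <- walk(ia[s0])          # extend the other way for open chains
    path <- c(rev(bwd), fwd)
    if (path[1] == path[length(path)]) path <- path[-length(path)]
    loops[[length(loops) + 1L]] <- coords[path, , drop = FALSE]
  }
  loops
}

# planar rank of the in-plane (x, z) coordinates: 0 point, 1 collinear, 2 areal
contour_rank <- function(pts, tol = 1e-7) {
  xz <- sweep(pts[, c(1, 3), drop = FALSE], 2,
              colMeans(pts[, c(1, 3), drop = FALSE]))
  sum(svd(xz)$d > tol)
}

# does the closed polygon (x, y) self-intersect? brute-force segment pairs
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  if (n < 4L) return(FALSE)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  idx <- which(outer(seq_len(n), seq_len(n), function(i, j)
    j > i + 1L & !(i == 1L & j == n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  o <- function(ax, ay, bx, by, cx, cy) sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  d1 <- o(x[i], y[i], x2[i], y2[i], x[j], y[j])
  d2 <- o(x[i], y[i], x2[i], y2[i], x2[j], y2[j])
  d3 <- o(x[j], y[j], x2[j], y2[j], x[i], y[i])
  d4 <- o(x[j], y[j], x2[j], y2[j], x2[i], y2[i])
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

# split chords longer than `lim` by inserting collinear points
subdivide_polygon <- function(u, w, lim) {
  n <- length(u)
  uo <- c(); wo <- c()
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    uo <- c(uo, u[i]); wo <- c(wo, w[i])
    len <- sqrt((u[j] - u[i])^2 + (w[j] - w[i])^2)
    if (len > lim) {
      k <- ceiling(len / lim)
      tt <- seq_len(k - 1) / k
      uo <- c(uo, u[i] + tt * (u[j] - u[i]))
      wo <- c(wo, w[i] + tt * (w[j] - w[i]))
    }
  }
  cbind(uo, wo)
}

#' Fit a closed periodic spline to a section contour
#'
#' Fits a closed periodic cubic spline, parameterised by cumulative chord
#' length, through the ordered section polygon. A single intersection loop
#' is used in its own cyclic order; multiple loops (internal air-cell
#' partitions) are pooled and their convex-hull envelope is fitted, so
#' extents are envelope extents. If no loop structure is available the
#' points are ordered by polar angle about their centroid, with a
#' convex-hull fallback when that ordering self-intersects. Chords longer
#' than 2 mm are subdivided before fitting to keep the interpolant free of
#' long-chord ringing; the curve still passes through every original
#' point. With `smoothing > 0` the ordered points are first smoothed by a
#' circular moving average of that half-width (in points), for noisy
#' voxelized contours.
#'
#' @param contour a `section_contour` from [cut_section].
#' @param smoothing non-negative integer half-width; 0 interpolates.
#' @param n_samples number of curve samples for extent queries (>= 360).
#' @return the contour with `curve` (n x 3 sampled curve) filled in.
#' @export
fit_closed_bspline <- function(contour, smoothing = 0, n_samples = 720) {
  stopifnot(inherits(contour, "section_contour"))
  if (contour$degenerate) return(contour)
  if (!is.null(contour$loops) && length(contour$loops) == 1L &&
      nrow(contour$loops[[1]]) >= 4L) {
    u <- contour$loops[[1]][, 1]; w <- contour$loops[[1]][, 3]
  } else if (!is.null(contour$loops) && length(contour$loops) > 1L) {
    pts <- do.call(rbind, contour$loops)
    h <- grDevices::chull(pts[, 1], pts[, 3])
    u <- pts[h, 1]; w <- pts[h, 3]
  } else {
    pts <- contour$cutting_points
    cu <- mean(pts[, 1]); cw <- mean(pts[, 3])
    ord <- order(atan2(pts[, 3] - cw, pts[, 1] - cu),
                 sqrt((pts[, 1] - cu)^2 + (pts[, 3] - cw)^2))
    u <- pts[ord, 1]; w <- pts[ord, 3]
    if (polygon_self_intersects(u, w)) {
      warning("angular ordering self-intersects; falling back to convex hull")
      h <- grDevices::chull(pts[, 1], pts[, 3])
      u <- pts[h, 1]; w <- pts[h, 3]
    }
  }
  if (smoothing > 0) {
    k <- as.integer(smoothing)
    n <- length(u)
    sm <- function(v) {
      ext <- c(v[(n - k + 1):n], v, v[1:k])
      stats::filter(ext, rep(1 / (2 * k + 1), 2 * k + 1))[(k + 1):(k + n)]
    }
    u <- as.numeric(sm(u)); w <- as.numeric(sm(w))
  }
  sub <- subdivide_polygon(u, w, lim = 2)
  u <- sub[, 1]; w <- sub[, 2]
  # chord-length parameterisation of the closed polygon
  tpar <- c(0, cumsum(sqrt(diff(c(u, u[1]))^2 + diff(c(w, w[1]))^2)))
  keep <- c(TRUE, diff(tpar) > 1e-12)
  ut <- u[keep[-length(keep)]]; wt <- w[keep[-length(keep)]]
  tp <- tpar[-length(tpar)][keep[-length(keep)]]
  Tper <- tpar[length(tpar)]
  if (length(tp) < 4L) { contour$degenerate <- TRUE; return(contour) }
  # periodic shape-preserving cubic: wrap 3 points on each side so the
  # local Hermite slopes match exactly across the seam
  k <- min(3L, length(tp))
  wrap <- function(v) c(v[(length(v) - k + 1):length(v)], v, v[1:k])
  te <- c(tp[(length(tp) - k + 1):length(tp)] - Tper, tp, tp[1:k] + Tper)
  xout <- seq(0, Tper, length.out = max(360, n_samples) + 1)
  sx <- stats::splinefun(te, wrap(ut), method = "monoH.FC")(xout)
  sz <- stats::splinefun(te, wrap(wt), method = "monoH.FC")(xout)
  contour$curve <- cbind(sx, contour$plane_y, sz)
  contour$ordered_points <- cbind(ut, contour$plane_y, wt)
  contour
}

#' Width, height and aspect ratio of a fitted section
#'
#' @param contour a `section_contour` with a fitted curve (or degenerate).
#' @return a one-row data.frame: `fraction`, `W_mm`, `H_mm`, `AR`,
#'   `degenerate`. Degenerate sections report `W = H = 0`, `AR = NA`.
#' @export
section_dims <- function(contour) {
  stopifnot(inherits(contour, "section_contour"))
  if (contour$degenerate)
    return(data.frame(fraction = contour$fraction, W_mm = 0, H_mm = 0,
                      AR = NA_real_, degenerate = TRUE))
  if (is.null(contour$curve)) stop("contour has no fitted curve; call fit_closed_bspline()")
  W <- diff(range(contour$curve[, 1]))
  H <- diff(range(contour$curve[, 3]))
  data.frame(fraction = contour$fraction, W_mm = W, H_mm = H,
             AR = if (H > 0) W / H else NA_real_, degenerate = FALSE)
}

#' Full morphometric profile of one sinus
#'
#' Runs length measurement and per-fraction sectioning (default every 10%),
#' returning the length and all section metrics.
#'
#' @param mesh a reoriented, clipped [triangle_mesh].
#' @param subject subject identifier.
#' @param sex `"male"` or `"female"` (or `NA`).
#' @param side `"left"` or `"right"` (or `NA`).
#' @param step fraction step in percent; must divide 100.
#' @param smoothing passed to [fit_closed_bspline].
#' @return object of class `sinus_profile`: `subject`, `sex`, `side`,
#'   `length_mm`, and `metrics` (one row per fraction).
#' @export
profile_sinus <- function(mesh, subject = NA, sex = NA, side = NA,
                          step = 10, smoothing = 0) {
  if (100 %% step != 0) stop("'step' must divide 100")
  len <- measure_length(mesh)
  fractions <- seq(0, 100, by = step)
  metrics <- do.call(rbind, lapply(fractions, function(f) {
    section_dims(fit_closed_bspline(cut_section(mesh, f), smoothing = smoothing))
  }))
  structure(list(subject = subject, sex = sex,
                 side = if (is.na(side)) mesh$side %||% NA else side,
                 length_mm = len$length_mm, metrics = metrics),
            class = "sinus_profile")
}

#' @export
print.sinus_profile <- function(x, ...) {
  cat(sprintf("<sinus_profile> subject %s, %s, %s side: L = %.1f mm\n",
              x$subject, x$sex, x$side, x$length_mm))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Flatten profiles to the long cohort table
#'
#' @param profiles a `sinus_profile` or list of them.
#' @return data.frame with columns `subject`, `sex`, `side`, `fraction`,
#'   `W_mm`, `H_mm`, `AR`, `length_mm` (class `cohort_table`).
#' @export
profiles_to_table <- function(profiles) {
  if (inherits(profiles, "sinus_profile")) profiles <- list(profiles)
  out <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(subject = p$subject, sex = p$sex, side = p$side,
               fraction = p$metrics$fraction, W_mm = p$metrics$W_mm,
               H_mm = p$metrics$H_mm, AR = p$metrics$AR,
               length_mm = p$length_mm)
  }))
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write / read the profile CSV
#'
#' Schema: `subject,sex,side,fraction,W_mm,H_mm,AR,length_mm` (optionally
#' `age`).
#'
#' @param table a cohort table (long data.frame).
#' @param path CSV path.
#' @return `path` / the table.
#' @export
write_profiles <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_profile_schema(out)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Validate the profile-table schema
#' @param table a data.frame.
#' @return `TRUE` invisibly; errors listing missing columns otherwise.
#' @export
check_profile_schema <- function(table) {
  need <- c("subject", "sex", "side", "fraction", "W_mm", "H_mm", "AR", "length_mm")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("profile table is missing columns: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}
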