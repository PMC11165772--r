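# Fixture builders: analytic and voxelized test shapes, all generated in
# code. Voxel grids use half-offset centres (centres at k + 0.5 times the
# spacing) so that shape boundaries fall between samples.

# voxelized ellipsoid mask with semi-axes (a, b, c) mm along (X, Y, Z)
make_ellipsoid_mask <- function(a, b, c, spacing = 1) {
  gx <- seq(-(a + 1.5), a + 1.5, by = spacing)
  gy <- seq(-(b + 1.5), b + 1.5, by = spacing)
  gz <- seq(-(c + 1.5), c + 1.5, by = spacing)
  arr <- array(FALSE, c(length(gx), length(gy), length(gz)))
  for (k in seq_along(gz))
    arr[, , k] <- outer(gx^2 / a^2, gy^2 / b^2, `+`) + gz[k]^2 / c^2 <= 1
  voxel_volume(arr, spacing = rep(spacing, 3),
               origin = c(gx[1], gy[1], gz[1]))
}

make_sphere_mask <- function(r, spacing = 1) make_ellipsoid_mask(r, r, r, spacing)

# analytic UV-triangulated ellipsoid mesh; poles on the Y (AP) axis
make_ellipsoid_mesh <- function(a, b, c, n_theta = 96, n_phi = 96) {
  theta <- seq(0, pi, length.out = n_theta + 1)[2:n_theta]
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  ring <- function(t) cbind(a * sin(t) * cos(phi), -b * cos(t),
                            c * sin(t) * sin(phi))
  verts <- rbind(c(0, -b, 0), do.call(rbind, lapply(theta, ring)), c(0, b, 0))
  idx <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  faces <- list()
  for (j in seq_len(n_phi)) {
    faces[[length(faces) + 1L]] <- c(1L, idx(1, j), idx(1, j + 1))
    faces[[length(faces) + 1L]] <- c(nrow(verts), idx(n_theta - 1, j + 1),
                                     idx(n_theta - 1, j))
  }
  for (i in seq_len(n_theta - 2)) for (j in seq_len(n_phi)) {
    faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
    faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  triangle_mesh(verts, do.call(rbind, faces))
}

# axis-aligned box mesh spanning [x0,x1] x [y0,y1] x [z0,z1]
make_box_mesh <- function(x0, x1, y0, y1, z0, z1) {
  v <- as.matrix(expand.grid(x = c(x0, x1), y = c(y0, y1), z = c(z0, z1)))
  # faces as quads on the cube corners (indices into expand.grid order)
  quads <- rbind(c(1, 3, 7, 5), c(2, 6, 8, 4), c(1, 5, 6, 2),
                 c(3, 4, 8, 7), c(1, 2, 4, 3), c(5, 7, 8, 6))
  faces <- rbind(quads[, c(1, 2, 3)], quads[, c(1, 3, 4)])
  triangle_mesh(v, faces)
}

# wrap 2D in-plane points as a section_contour (single loop, plane y = 0)
make_contour <- function(xz, fraction = 50) {
  pts <- cbind(xz[, 1], 0, xz[, 2])
  structure(list(fraction = fraction, plane_y = 0, cutting_points = pts,
                 loops = list(pts), degenerate = FALSE, curve = NULL),
            class = "section_contour")
}

aligned_landmarks <- function() {
  head_landmarks(cranial_base = rbind(c(0, -45, 25), c(0, -5, 25), c(0, 35, 25)),
                 nasal_septum = rbind(c(0, -40, -15), c(0, -40, 5), c(0, -40, 25)))
}

# foreground voxels as world-coordinate keys, for grid-independent Dice
mask_world_dice <- function(a, b, digits = 3) {
  keyf <- function(v) {
    idx <- which(v$data != 0, arr.ind = TRUE)
    w <- sweep(sweep(idx - 1, 2, v$spacing, `*`), 2, v$origin, `+`)
    paste(round(w[, 1], digits), round(w[, 2], digits), round(w[, 3], digits))
  }
  ka <- keyf(a); kb <- keyf(b)
  2 * length(intersect(ka, kb)) / (length(ka) + length(kb))
}

interior <- seq(10, 90, by = 10)

# long cohort table from explicit per-sinus AR profiles (for stats tests)
table_from_ar <- function(ar_by_sinus, sex = "male", H = 15) {
  do.call(rbind, lapply(seq_along(ar_by_sinus), function(i) {
    ar <- ar_by_sinus[[i]]
    data.frame(subject = sprintf("s%02d", (i + 1) %/% 2), sex = sex,
               side = c("left", "right")[1 + (i - 1) %% 2],
               fraction = seq(0, 100, by = 10),
               W_mm = ar * H, H_mm = H, AR = ar, length_mm = 40)
  }))
}
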