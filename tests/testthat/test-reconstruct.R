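# isosurfacing and boundary clipping

test_that("voxelized sphere mesh has 20 mm extents and is closed", {
  mesh <- extract_isosurface(make_sphere_mask(10))
  ext <- apply(mesh$vertices, 2, function(v) diff(range(v)))
  expect_true(all(abs(ext - 20) <= 1))
  expect_true(mesh_is_closed(mesh))
  expect_true(all(sinusect:::face_areas(mesh) > 1e-9))
  # volume close to (4/3) pi r^3
  expect_equal(mesh_volume(mesh), 4 / 3 * pi * 1000, tolerance = 0.05)
})

test_that("a single foreground voxel yields a tiny closed mesh", {
  arr <- array(FALSE, c(3, 3, 3)); arr[2, 2, 2] <- TRUE
  mesh <- extract_isosurface(voxel_volume(arr))
  expect_true(mesh_is_closed(mesh))
  ext <- apply(mesh$vertices, 2, function(v) diff(range(v)))
  expect_true(all(ext <= 2))
  expect_equal(mesh_volume(mesh), 1)
})

test_that("synthetic cavity mesh volume matches the analytic tube integral", {
  spec <- synthetic_spec(n_subjects_per_sex = 1,
                         misorientation_sd_deg = c(0, 0, 0), seed = 4)
  cav <- generate_cavity(spec, 1, "male", "left")
  mesh <- extract_isosurface(cav$volume)
  # oracle: numeric integral of the elliptic cross-section area profile
  f <- seq(0, 1, length.out = 2001)
  a <- approx(seq(0, 1, 0.1), cav$truth$table$W_mm / 2, xout = f)$y
  b <- approx(seq(0, 1, 0.1), cav$truth$table$H_mm / 2, xout = f)$y
  v_true <- mean(pi * a * b) * cav$truth$true_length_mm
  expect_equal(mesh_volume(mesh), v_true, tolerance = 0.05)
  expect_true(mesh_is_closed(mesh))
})

test_that("isosurface stays within the mask bounding box plus one voxel", {
  vol <- make_ellipsoid_mask(5, 8, 6)
  mesh <- extract_isosurface(vol)
  bb <- sinusect:::mask_bbox(vol)
  expect_true(all(mesh$vertices >= rep(bb[1, ] - 1, each = nrow(mesh$vertices))))
  expect_true(all(mesh$vertices <= rep(bb[2, ] + 1, each = nrow(mesh$vertices))))
})

test_that("empty masks error and stray components warn", {
  expect_error(extract_isosurface(voxel_volume(array(0, c(3, 3, 3)))), "empty")
  arr <- array(FALSE, c(14, 6, 6))
  arr[2:5, 2:5, 2:5] <- TRUE
  arr[8:12, 2:5, 2:5] <- TRUE
  expect_warning(mesh <- extract_isosurface(voxel_volume(arr)), "components")
  expect_true(mesh_is_closed(mesh))
})

test_that("clipping far outside the mesh is a no-op", {
  mesh <- extract_isosurface(make_sphere_mask(5))
  b <- boundary_spec(upper = boundary_plane(c(0, 0, 100), c(0, 0, -1)),
                     lateral = boundary_plane(c(100, 0, 0), c(-1, 0, 0)))
  expect_identical(clip_by_boundary(mesh, b), mesh)
})

test_that("half-box clip retains half the height", {
  box <- make_box_mesh(-5, 5, -5, 5, 0, 18)
  cut <- clip_by_boundary(box, boundary_spec(
    upper = boundary_plane(c(0, 0, 9), c(0, 0, -1))))
  expect_equal(diff(range(cut$vertices[, 3])), 9)
  expect_equal(diff(range(cut$vertices[, 1])), 10)
  # every retained vertex satisfies the half-space within tolerance
  expect_true(all(cut$vertices[, 3] <= 9 + 1e-6))
})

test_that("lateral shave reduces widths by the analytic overlap", {
  spec <- synthetic_spec(n_subjects_per_sex = 1,
                         misorientation_sd_deg = c(0, 0, 0), seed = 3)
  cav <- generate_cavity(spec, 1, "female", "left")
  mesh <- extract_isosurface(cav$volume)
  xplane <- max(mesh$vertices[, 1]) - 2
  b <- boundary_spec(lateral = boundary_plane(c(xplane, 0, 0), c(-1, 0, 0)))
  cut <- clip_by_boundary(mesh, b)
  for (f in c(40, 50, 60, 80)) {
    c0 <- fit_closed_bspline(cut_section(mesh, f))
    c1 <- fit_closed_bspline(cut_section(cut, f))
    xmin0 <- min(c0$curve[, 1]); xmax0 <- max(c0$curve[, 1])
    expected_W <- min(xmax0, xplane) - xmin0
    expect_equal(section_dims(c1)$W_mm, expected_W, tolerance = 0.1)
  }
})

test_that("tightening a boundary never increases widths", {
  spec <- synthetic_spec(n_subjects_per_sex = 1,
                         misorientation_sd_deg = c(0, 0, 0), seed = 3)
  cav <- generate_cavity(spec, 1, "male", "right")
  mesh <- extract_isosurface(cav$volume)
  xmax <- max(mesh$vertices[, 1])
  W50 <- Inf
  for (shave in c(0.5, 1.5, 2.5, 3.5)) {
    b <- boundary_spec(lateral = boundary_plane(c(xmax - shave, 0, 0), c(-1, 0, 0)))
    w <- section_dims(fit_closed_bspline(cut_section(clip_by_boundary(mesh, b), 50)))$W_mm
    expect_lte(w, W50 + 1e-9)
    W50 <- w
  }
})

test_that("a boundary that excludes the whole cavity errors", {
  mesh <- extract_isosurface(make_sphere_mask(4))
  b <- boundary_spec(upper = boundary_plane(c(0, 0, -100), c(0, 0, -1)))
  expect_error(clip_by_boundary(mesh, b), "excludes entire cavity")
})

test_that("heightfield boundaries clip curved roofs", {
  box <- make_box_mesh(-5, 5, -5, 5, 0, 10)
  roof <- boundary_heightfield(function(x, y) 6 + 0.2 * x, keep = "below")
  cut <- clip_by_boundary(box, boundary_spec(upper = roof))
  zmax_at <- function(m, xlo, xhi) max(m$vertices[m$vertices[, 1] >= xlo &
                                                  m$vertices[, 1] <= xhi, 3])
  expect_equal(zmax_at(cut, 4.9, 5.1), 7, tolerance = 0.05)
  expect_equal(zmax_at(cut, -5.1, -4.9), 5, tolerance = 0.05)
})

test_that("PLY and STL round trips preserve geometry", {
  mesh <- extract_isosurface(make_sphere_mask(4))
  ply <- tempfile(fileext = ".ply")
  write_ply(mesh, ply)
  back <- read_ply(ply)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-6)
  expect_identical(back$faces, mesh$faces)
  stl <- tempfile(fileext = ".stl")
  write_stl(mesh, stl)
  expect_true(any(grepl("facet normal", readLines(stl, n = 5))))
  unlink(c(ply, stl))
})
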