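# length, sectioning, closed-curve fitting, section metrics, profiles

test_that("length of an ellipsoid is its AP diameter", {
  mesh <- make_ellipsoid_mesh(6, 20, 9)
  len <- measure_length(mesh)
  expect_equal(len$length_mm, 40, tolerance = 1e-9)
  expect_equal(len$y0, -20)
  expect_error(measure_length(triangle_mesh(cbind(0:1, 0, 0:1),
                                            matrix(c(1, 2, 1), 1))),
               "anteroposterior")
})

test_that("central and off-centre ellipsoid sections match the slice oracle", {
  mesh <- make_ellipsoid_mesh(6, 20, 9)
  d50 <- section_dims(fit_closed_bspline(cut_section(mesh, 50)))
  expect_equal(d50$W_mm, 12, tolerance = 0.05)
  expect_equal(d50$H_mm, 18, tolerance = 0.05)
  expect_equal(d50$AR, 2 / 3, tolerance = 0.005)
  # at 80% the slice scales by sqrt(1 - 0.6^2) = 0.8
  d80 <- section_dims(fit_closed_bspline(cut_section(mesh, 80)))
  expect_equal(d80$W_mm, 9.6, tolerance = 0.05)
  expect_equal(d80$H_mm, 14.4, tolerance = 0.05)
})

test_that("tangent end planes give flagged degenerate sections", {
  mesh <- make_ellipsoid_mesh(6, 20, 9)
  c0 <- cut_section(mesh, 0)
  expect_true(c0$degenerate)
  d0 <- section_dims(fit_closed_bspline(c0))
  expect_equal(d0$W_mm, 0)
  expect_equal(d0$H_mm, 0)
  expect_true(is.na(d0$AR))
})

test_that("interior gaps along the AP axis are reported", {
  b1 <- make_box_mesh(0, 4, 0, 4, 0, 4)
  b2 <- make_box_mesh(0, 4, 8, 12, 0, 4)
  mesh <- triangle_mesh(rbind(b1$vertices, b2$vertices),
                        rbind(b1$faces, b2$faces + nrow(b1$vertices)))
  expect_error(cut_section(mesh, 50), "not contiguous")
})

test_that("closed-curve fit reproduces circle, ellipse and square extents", {
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  circ <- fit_closed_bspline(make_contour(cbind(5 * cos(th), 5 * sin(th))))
  expect_equal(diff(range(circ$curve[, 1])), 10, tolerance = 0.01)
  expect_equal(diff(range(circ$curve[, 3])), 10, tolerance = 0.01)
  ell <- fit_closed_bspline(make_contour(cbind(6 * cos(th), 9 * sin(th))))
  expect_equal(diff(range(ell$curve[, 1])), 12, tolerance = 0.05)
  expect_equal(diff(range(ell$curve[, 3])), 18, tolerance = 0.05)
  sq <- rbind(c(5, 5), c(0, 5), c(-5, 5), c(-5, 0), c(-5, -5), c(0, -5),
              c(5, -5), c(5, 0))
  sqf <- fit_closed_bspline(make_contour(sq))
  expect_equal(diff(range(sqf$curve[, 1])), 10, tolerance = 1e-9)
  expect_equal(diff(range(sqf$curve[, 3])), 10, tolerance = 1e-9)
})

test_that("fitted curves are closed and pass through the cutting points", {
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  ct <- fit_closed_bspline(make_contour(cbind(6 * cos(th), 9 * sin(th))))
  expect_equal(ct$curve[1, ], ct$curve[nrow(ct$curve), ], tolerance = 1e-9)
  d <- apply(ct$cutting_points, 1, function(p)
    min(sqrt((ct$curve[, 1] - p[1])^2 + (ct$curve[, 3] - p[3])^2)))
  expect_lt(max(d), 0.1)
})

test_that("fewer than four points flags the contour instead of fitting", {
  ct <- make_contour(rbind(c(0, 0), c(1, 0), c(0, 1)))
  ct$loops <- NULL
  out <- fit_closed_bspline(ct)
  expect_true(out$degenerate)
  expect_null(out$curve)
})

test_that("section metrics implement W, H and AR = W/H", {
  th <- seq(0, 2 * pi, length.out = 91)[-91]
  d <- section_dims(fit_closed_bspline(make_contour(cbind(6 * cos(th), 9 * sin(th)))))
  expect_equal(d$W_mm, 12, tolerance = 0.01)
  expect_equal(d$H_mm, 18, tolerance = 0.01)
  expect_equal(d$AR, 0.667, tolerance = 0.002)
  circ <- section_dims(fit_closed_bspline(make_contour(cbind(5 * cos(th), 5 * sin(th)))))
  expect_equal(circ$AR, 1, tolerance = 0.002)       # AR = 1: circular section
  ell <- section_dims(fit_closed_bspline(make_contour(cbind(5 * cos(th), 9 * sin(th)))))
  expect_equal(ell$AR, 0.556, tolerance = 0.002)    # elliptical anterior regime
})

test_that("profiles recover generator truth within one voxel", {
  spec <- synthetic_spec(n_subjects_per_sex = 1,
                         misorientation_sd_deg = c(0, 0, 0), seed = 6)
  cav <- generate_cavity(spec, 1, "female", "left")
  mesh <- apply_transform(extract_isosurface(cav$volume),
                          compute_reorientation(cav$landmarks))
  p <- profile_sinus(mesh, subject = "s01_f", sex = "female", side = "left")
  sel <- p$metrics$fraction %in% interior
  expect_true(all(abs(p$metrics$W_mm[sel] - cav$truth$table$W_mm[sel]) <= 1))
  expect_true(all(abs(p$metrics$H_mm[sel] - cav$truth$table$H_mm[sel]) <= 1))
  expect_equal(p$length_mm, cav$truth$true_length_mm, tolerance = 1)
})

test_that("constant-profile tubes have constant interior aspect ratio", {
  spec <- synthetic_spec(n_subjects_per_sex = 1,
                         misorientation_sd_deg = c(0, 0, 0),
                         width_profile = rep(10, 11),
                         height_profile = rep(18, 11), seed = 8)
  cav <- generate_cavity(spec, 1, "female", "left")
  p <- profile_sinus(extract_isosurface(cav$volume))
  ar <- p$metrics$AR[p$metrics$fraction %in% interior]
  expect_lt(diff(range(ar)), 0.01)
})

test_that("metrics are invariant to left-right mirroring", {
  spec <- synthetic_spec(n_subjects_per_sex = 1,
                         misorientation_sd_deg = c(0, 0, 0), seed = 9)
  cav <- generate_cavity(spec, 1, "male", "left")
  mesh <- extract_isosurface(cav$volume)
  mirrored <- mesh
  mirrored$vertices[, 1] <- -mirrored$vertices[, 1]
  p1 <- profile_sinus(mesh); p2 <- profile_sinus(mirrored)
  expect_equal(p2$metrics$W_mm, p1$metrics$W_mm, tolerance = 1e-9)
  expect_equal(p2$metrics$H_mm, p1$metrics$H_mm, tolerance = 1e-9)
})

test_that("scaling a mesh scales lengths and leaves AR unchanged", {
  mesh <- make_ellipsoid_mesh(6, 20, 9, n_theta = 48, n_phi = 48)
  s <- 1.7
  scaled <- triangle_mesh(mesh$vertices * s, mesh$faces)
  p1 <- profile_sinus(mesh); p2 <- profile_sinus(scaled)
  sel <- p1$metrics$fraction %in% interior
  expect_equal(p2$length_mm, s * p1$length_mm, tolerance = 1e-9)
  expect_equal(p2$metrics$W_mm[sel], s * p1$metrics$W_mm[sel], tolerance = 1e-6)
  expect_equal(p2$metrics$AR[sel], p1$metrics$AR[sel], tolerance = 1e-6)
})

test_that("misorient + reorient leaves mesh metrics within 2%", {
  spec <- synthetic_spec(n_subjects_per_sex = 1,
                         misorientation_sd_deg = c(0, 0, 0), seed = 10)
  cav <- generate_cavity(spec, 1, "male", "left")
  mesh <- extract_isosurface(cav$volume)
  p0 <- profile_sinus(mesh)
  for (ang in list(c(10, 0, 0), c(8, 4, -3), c(-14, 2, 2))) {
    t <- rigid_transform(ang[1], ang[2], ang[3], center = c(14, 0, 0))
    rot <- apply_transform(mesh, t)
    lm <- apply_transform(aligned_landmarks(), t)
    back <- apply_transform(rot, compute_reorientation(lm))
    p1 <- profile_sinus(back)
    sel <- p0$metrics$fraction %in% interior
    expect_equal(p1$length_mm, p0$length_mm, tolerance = 0.02 * p0$length_mm)
    expect_true(all(abs(p1$metrics$W_mm[sel] / p0$metrics$W_mm[sel] - 1) < 0.02))
    expect_true(all(abs(p1$metrics$H_mm[sel] / p0$metrics$H_mm[sel] - 1) < 0.02))
  }
})

test_that("multi-loop sections (septa) measure the outer envelope", {
  spec <- synthetic_spec(n_subjects_per_sex = 1,
                         misorientation_sd_deg = c(0, 0, 0),
                         septa_count = 3, seed = 5)
  cav <- generate_cavity(spec, 1, "male", "left")
  p <- profile_sinus(extract_isosurface(cav$volume))
  sel <- p$metrics$fraction %in% interior
  expect_true(all(abs(p$metrics$W_mm[sel] - cav$truth$table$W_mm[sel]) <= 1))
  expect_true(all(abs(p$metrics$H_mm[sel] - cav$truth$table$H_mm[sel]) <= 1))
})

test_that("profile tables serialize through CSV with a stable schema", {
  mesh <- make_ellipsoid_mesh(6, 20, 9, n_theta = 48, n_phi = 48)
  tab <- profiles_to_table(profile_sinus(mesh, subject = "s01_m", sex = "male",
                                         side = "left"))
  path <- tempfile(fileext = ".csv")
  write_profiles(tab, path)
  back <- read_profiles(path)
  expect_equal(back$W_mm, tab$W_mm, tolerance = 1e-6)
  expect_error(check_profile_schema(tab[, -4]), "fraction")
  unlink(path)
})

test_that("fraction step must divide 100 and controls section count", {
  mesh <- make_ellipsoid_mesh(6, 20, 9, n_theta = 48, n_phi = 48)
  expect_error(profile_sinus(mesh, step = 15), "divide")
  p <- profile_sinus(mesh, step = 20)
  expect_equal(nrow(p$metrics), 6)
})
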