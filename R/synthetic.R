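# Synthetic sinus cavity cohort with stored ground truth.
#
# A cavity is a superellipse tube along the anteroposterior axis: at
# fraction f of its length the cross-section is |x/a(f)|^p + |z/b(f)|^p <= 1
# with semi-axes linearly interpolated between the 11 per-fraction profile
# values (a = W/2, b = H/2). Male widths are the female profile times
# sex_width_multiplier. Each subject's head is misoriented by per-plane
# angles drawn from centred normals; the rotated analytic shape is
# voxelized directly (a single voxelization, no resampling), and landmarks
# are generated consistently with the applied misorientation. Optional
# surface noise perturbs the boundary radially by a smooth random field;
# optional septa erase thin interior walls without touching the outer
# envelope, mimicking ethmoid air-cell partitions.

default_width_profile <- c(7.2, 8.4, 8.9, 9.2, 9.5, 9.8, 10.0, 10.2, 10.3, 10.1, 9.2)
default_height_profile <- c(12.6, 14.8, 16.2, 17.4, 18.0, 17.2, 15.4, 13.6, 12.4, 11.6, 10.6)

#' Specification of a synthetic cohort
#'
#' Defaults emulate the study population this generator stands in for:
#' 21 male + 15 female subjects (two sinuses each, 72 sinuses), cavity
#' length 40.7 +/- 5 mm, a female width/height profile whose aspect ratio
#' rises from ~0.57 anteriorly to ~0.87 posteriorly, a 1.2x male width
#' multiplier, misorientation SDs of (10, 2, 2) degrees dominated by the
#' sagittal plane, and 1 mm isotropic voxels.
#'
#' @param n_subjects_per_sex subjects per sex; scalar or `c(male, female)`.
#' @param length_mean_mm,length_sd_mm cavity length distribution (mm).
#' @param width_profile,height_profile length-11 per-fraction extents (mm)
#'   at fractions 0%,10%,...,100% (female baseline).
#' @param sex_width_multiplier male widths = female profile x this (> 0).
#' @param misorientation_sd_deg per-plane angle SDs, `(sagittal, axial,
#'   coronal)` degrees.
#' @param voxel_spacing_mm voxel spacing, length 3 (mm).
#' @param surface_noise_sd_mm SD of the radial boundary noise field (mm).
#' @param septa_count number of internal septa (thin erased walls).
#' @param superellipse_exponent cross-section exponent (2 = ellipse).
#' @param seed integer RNG seed; identical spec + seed gives a bit-identical
#'   cohort.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects_per_sex = c(male = 21, female = 15),
                           length_mean_mm = 40.7, length_sd_mm = 5.0,
                           width_profile = default_width_profile,
                           height_profile = default_height_profile,
                           sex_width_multiplier = 1.2,
                           misorientation_sd_deg = c(10, 2, 2),
                           voxel_spacing_mm = c(1, 1, 1),
                           surface_noise_sd_mm = 0,
                           septa_count = 0,
                           superellipse_exponent = 2,
                           seed = 1L) {
  if (length(n_subjects_per_sex) == 1L)
    n_subjects_per_sex <- rep(n_subjects_per_sex, 2)
  n_subjects_per_sex <- stats::setNames(as.integer(n_subjects_per_sex),
                                        c("male", "female"))
  if (any(n_subjects_per_sex < 0)) stop("subject counts must be >= 0")
  if (length(width_profile) != 11L || length(height_profile) != 11L)
    stop("profiles must have exactly 11 entries (fractions 0%,10%,...,100%)")
  if (any(width_profile < 0) || any(height_profile < 0) ||
      length_mean_mm < 0 || length_sd_mm < 0 || surface_noise_sd_mm < 0)
    stop("mm quantities must be >= 0")
  stopifnot_scalar(sex_width_multiplier, "sex_width_multiplier", positive = TRUE)
  if (length(misorientation_sd_deg) != 3L || any(misorientation_sd_deg < 0))
    stop("misorientation_sd_deg must be 3 non-negative values")
  if (length(voxel_spacing_mm) != 3L || any(voxel_spacing_mm <= 0))
    stop("voxel_spacing_mm must be 3 positive values")
  structure(list(n_subjects_per_sex = n_subjects_per_sex,
                 length_mean_mm = length_mean_mm, length_sd_mm = length_sd_mm,
                 width_profile = width_profile, height_profile = height_profile,
                 sex_width_multiplier = sex_width_multiplier,
                 misorientation_sd_deg = misorientation_sd_deg,
                 voxel_spacing_mm = voxel_spacing_mm,
                 surface_noise_sd_mm = surface_noise_sd_mm,
                 septa_count = as.integer(septa_count),
                 superellipse_exponent = superellipse_exponent,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# sexed width profile
spec_width <- function(spec, sex) {
  if (sex == "male") spec$width_profile * spec$sex_width_multiplier
  else spec$width_profile
}

#' Sample per-plane misorientation angles
#'
#' Centred normal draws with the spec's per-plane SDs; one triple per
#' subject (both sides of a head share one scan).
#'
#' @param spec a [synthetic_spec].
#' @param n number of subjects.
#' @return n x 3 matrix, columns `sagittal`, `axial`, `coronal` (degrees).
#' @export
sample_misorientation_angles <- function(spec, n) {
  m <- cbind(sagittal = stats::rnorm(n, 0, spec$misorientation_sd_deg[1]),
             axial = stats::rnorm(n, 0, spec$misorientation_sd_deg[2]),
             coronal = stats::rnorm(n, 0, spec$misorientation_sd_deg[3]))
  m
}

# Subject-level draws: one scan misorientation per head, shared by both
# sides. Cavity length is drawn per sinus (below): sides are analysed as
# independent sampling units, so the generator keeps them independent.
subject_params <- function(spec, subject_index, sex) {
  with_seed(derive_seed(spec$seed, subject_index, sex), {
    list(angles = drop(sample_misorientation_angles(spec, 1)))
  })
}

sinus_length <- function(spec, subject_index, sex, side) {
  with_seed(derive_seed(spec$seed, subject_index, sex, side, "len"),
            max(10, stats::rnorm(1, spec$length_mean_mm, spec$length_sd_mm)))
}

# canonical (aligned) landmark set for a head whose cavity sits near the
# origin: cranial base along +Y, nasal septum along +Z
canonical_landmarks <- function() {
  head_landmarks(
    cranial_base = rbind(c(0, -45, 25), c(0, -5, 25), c(0, 35, 25)),
    nasal_septum = rbind(c(0, -40, -15), c(0, -40, 5), c(0, -40, 25)))
}

# Smooth random radial noise field delta(theta, f) in mm with pointwise SD
# `sd`. Only the FIRST circumferential harmonic is used: delta = A(f) *
# cos(theta + phi(f)) displaces each cross-section rigidly in-plane (a
# bent, wobbling cavity axis) and leaves section extents unchanged to
# second order. Higher harmonics would dilate sections and invalidate the
# stored analytic ground truth as the reference for noisy cavities.
make_noise_field <- function(sd) {
  if (sd <= 0) return(function(theta, f) 0)
  K <- 6L
  m <- rep(1L, K)
  l <- sample(0:3, K, replace = TRUE)
  phi <- stats::runif(K, 0, 2 * pi)
  psi <- stats::runif(K, 0, 2 * pi)
  amp <- stats::rnorm(K)
  # normalise empirically so the field SD over the domain equals sd
  tg <- seq(0, 2 * pi, length.out = 41)[-41]
  fgr <- seq(0, 1, length.out = 21)
  grid <- as.matrix(expand.grid(theta = tg, f = fgr))
  base <- function(theta, f) {
    out <- 0
    for (k in seq_len(K))
      out <- out + amp[k] * cos(m[k] * theta + phi[k]) * cos(pi * l[k] * f + psi[k])
    out
  }
  s0 <- stats::sd(base(grid[, 1], grid[, 2]))
  function(theta, f) sd / s0 * base(theta, f)
}

#' Generate one synthetic sinus cavity
#'
#' Returns the voxelized (misoriented) cavity mask, landmarks consistent
#' with the applied misorientation, and the analytic ground truth.
#'
#' @param spec a [synthetic_spec].
#' @param subject_index subject number within the sex.
#' @param sex `"male"` or `"female"`.
#' @param side `"left"` or `"right"`.
#' @param voxelize if `FALSE`, skip mask generation (truth and landmarks
#'   only; fast path for cohort-scale bookkeeping).
#' @return list with `volume` ([voxel_volume] or `NULL`), `landmarks`
#'   ([head_landmarks]), `truth` (a `ground_truth`: subject, sex, side,
#'   true_length_mm, applied angles, and the per-fraction table).
#' @export
generate_cavity <- function(spec, subject_index, sex = c("male", "female"),
                            side = c("left", "right"), voxelize = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sex <- match.arg(sex); side <- match.arg(side)
  sp <- spec$voxel_spacing_mm
  Wp <- spec_width(spec, sex); Hp <- spec$height_profile
  if (min(c(Wp, Hp)) / max(sp[c(1, 3)]) < 3)
    stop(sprintf(paste0("voxel spacing too coarse: smallest profile extent ",
                        "%.1f mm is < 3 voxels across at spacing %.1f mm"),
                 min(c(Wp, Hp)), max(sp[c(1, 3)])))
  pars <- subject_params(spec, subject_index, sex)
  L <- sinus_length(spec, subject_index, sex, side)
  fractions <- seq(0, 100, by = 10)
  truth <- structure(list(
    subject = sprintf("s%02d_%s", subject_index, substr(sex, 1, 1)),
    sex = sex, side = side, true_length_mm = L,
    angles_deg = pars$angles,
    table = data.frame(fraction = fractions, W_mm = Wp, H_mm = Hp,
                       AR = ifelse(Hp > 0, Wp / Hp, NA_real_))),
    class = "ground_truth")
  misorient <- rigid_transform(pars$angles[1], pars$angles[2], pars$angles[3])
  landmarks <- apply_transform(canonical_landmarks(), misorient)
  volume <- NULL
  if (voxelize) {
    volume <- with_seed(derive_seed(spec$seed, subject_index, sex, side, "vox"),
                        voxelize_cavity(spec, Wp, Hp, L, misorient, side))
  }
  list(volume = volume, landmarks = landmarks, truth = truth)
}

# rasterise the (rotated) analytic tube onto a half-offset voxel grid
voxelize_cavity <- function(spec, Wp, Hp, L, misorient, side) {
  sp <- spec$voxel_spacing_mm
  p <- spec$superellipse_exponent
  x_off <- if (side == "left") 14 else -14
  noise <- make_noise_field(spec$surface_noise_sd_mm)
  # rotated bounding box from a cloud of canonical boundary points
  fg <- seq(0, 1, length.out = 33)
  th <- seq(0, 2 * pi, length.out = 49)[-49]
  ag <- as.matrix(expand.grid(f = fg, theta = th))
  a <- stats::approx(seq(0, 1, 0.1), Wp / 2, xout = ag[, "f"])$y
  b <- stats::approx(seq(0, 1, 0.1), Hp / 2, xout = ag[, "f"])$y
  rb <- (abs(cos(ag[, "theta"]))^p / a^p + abs(sin(ag[, "theta"]))^p / b^p)^(-1 / p)
  cloud <- cbind(x_off + rb * cos(ag[, "theta"]),
                 (ag[, "f"] - 0.5) * L,
                 rb * sin(ag[, "theta"]))
  cloud <- transform_points(misorient, cloud)
  margin <- 3 * spec$surface_noise_sd_mm + 2 * max(sp)
  lo <- apply(cloud, 2, min) - margin
  hi <- apply(cloud, 2, max) + margin
  origin <- (floor(lo / sp)) * sp + sp / 2     # voxel centres on half-offsets
  d <- as.integer(ceiling((hi - origin) / sp)) + 1L
  gx <- origin[1] + (seq_len(d[1]) - 1) * sp[1]
  gy <- origin[2] + (seq_len(d[2]) - 1) * sp[2]
  gz <- origin[3] + (seq_len(d[3]) - 1) * sp[3]
  pts <- cbind(rep(gx, times = d[2] * d[3]),
               rep(rep(gy, each = d[1]), times = d[3]),
               rep(gz, each = d[1] * d[2]))
  Rt <- t(rotation_matrix(misorient))
  q <- pts %*% t(Rt)                            # back to canonical frame
  qx <- q[, 1] - x_off; qy <- q[, 2]; qz <- q[, 3]
  f <- qy / L + 0.5
  inside <- f >= 0 & f <= 1
  mask <- logical(nrow(pts))
  if (any(inside)) {
    fi <- f[inside]
    ai <- stats::approx(seq(0, 1, 0.1), Wp / 2, xout = fi)$y
    bi <- stats::approx(seq(0, 1, 0.1), Hp / 2, xout = fi)$y
    xi <- qx[inside]; zi <- qz[inside]
    r <- sqrt(xi^2 + zi^2)
    Fv <- (abs(xi) / ai)^p + (abs(zi) / bi)^p
    rbv <- ifelse(r > 0, r / Fv^(1 / p), Inf)
    delta <- noise(atan2(zi, xi), fi)
    keep <- r <= rbv + delta
    if (spec$septa_count > 0) {
      fs <- seq_len(spec$septa_count) / (spec$septa_count + 1)
      wall <- 0.6 * sp[2] / L
      rim <- 1.5 * max(sp)
      for (s in fs)
        keep <- keep & !(abs(fi - s) < wall & r < rbv - rim)
    }
    mask[inside] <- keep
  }
  vol <- voxel_volume(array(as.integer(mask), d), spacing = sp, origin = origin)
  vol$data <- array(as.integer(largest_component(vol$data)$mask), d)
  vol
}

#' Generate a full synthetic cohort
#'
#' Two sinuses (left, right) per subject. With `dir` set, writes each mask
#' as NIfTI (`<id>.nii.gz`), its landmarks as `<id>.json`, and the truth
#' table as `truth.csv`.
#'
#' @param spec a [synthetic_spec].
#' @param dir optional output directory.
#' @param voxelize generate voxel masks (slow) or truth/landmarks only.
#' @return list with `sinuses` (list of [generate_cavity] results) and
#'   `truth` (long `cohort_table`: subject, sex, side, fraction, W_mm, H_mm,
#'   AR, length_mm).
#' @export
generate_cohort <- function(spec, dir = NULL, voxelize = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (sum(spec$n_subjects_per_sex) < 1) stop("need at least one subject")
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sinuses <- list()
  rows <- list()
  for (sex in c("male", "female")) {
    for (i in seq_len(spec$n_subjects_per_sex[[sex]])) {
      for (side in c("left", "right")) {
        cav <- generate_cavity(spec, i, sex, side, voxelize = voxelize)
        id <- paste0(cav$truth$subject, "_", side)
        sinuses[[id]] <- cav
        rows[[id]] <- data.frame(subject = cav$truth$subject, sex = sex,
                                 side = side,
                                 fraction = cav$truth$table$fraction,
                                 W_mm = cav$truth$table$W_mm,
                                 H_mm = cav$truth$table$H_mm,
                                 AR = cav$truth$table$AR,
                                 length_mm = cav$truth$true_length_mm)
        if (!is.null(dir)) {
          if (voxelize)
            write_nifti(cav$volume, file.path(dir, paste0(id, ".nii.gz")))
          write_landmarks(cav$landmarks, file.path(dir, paste0(id, ".json")))
        }
      }
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  class(truth) <- c("cohort_table", "data.frame")
  if (!is.null(dir)) write_profiles(truth, file.path(dir, "truth.csv"))
  list(sinuses = sinuses, truth = truth)
}

#' Summary-level cohort simulator
#'
#' Draws per-sinus morphometric summaries directly from the stated
#' population model, bypassing voxelization: per-sinus lognormal
#' multiplicative scales on width and height (mean one), small per-fraction
#' lognormal jitter, and normal cavity lengths. Used for cohort-statistics
#' validation at paper scale, where only the summary distribution matters.
#'
#' @param n_subjects_per_sex subjects per sex, `c(male, female)`.
#' @param width_profile,height_profile length-11 female mean extents (mm).
#' @param sex_width_multiplier male widths = profile x this.
#' @param length_mean_mm length mean (mm); a scalar (no sex effect, as in
#'   the cavity generator) or `c(male, female)`.
#' @param length_sd_mm length SD (mm); lengths are drawn per sinus.
#' @param width_cv,height_cv per-sinus coefficient of variation.
#' @param fraction_cv per-fraction jitter CV.
#' @param seed RNG seed.
#' @return a long `cohort_table` with an `age` column (uniform 21..99).
#' @export
simulate_cohort <- function(n_subjects_per_sex = c(male = 21, female = 15),
                            width_profile = default_width_profile,
                            height_profile = default_height_profile,
                            sex_width_multiplier = 1.2,
                            length_mean_mm = 40.7,
                            length_sd_mm = 5.0,
                            width_cv = 0.21, height_cv = 0.20,
                            fraction_cv = 0.04, seed = 1L) {
  if (length(n_subjects_per_sex) == 1L) n_subjects_per_sex <- rep(n_subjects_per_sex, 2)
  if (length(length_mean_mm) == 1L) length_mean_mm <- rep(length_mean_mm, 2)
  fractions <- seq(0, 100, by = 10)
  ln_scale <- function(n, cv) {
    s <- sqrt(log(1 + cv^2))
    exp(stats::rnorm(n, -s^2 / 2, s))           # mean exactly 1
  }
  with_seed(seed, {
    nm <- n_subjects_per_sex[[1]]; nf <- n_subjects_per_sex[[2]]
    ns <- nm + nf
    sex_subj <- rep(c("male", "female"), c(nm, nf))
    subj <- sprintf("s%02d_%s", c(seq_len(nm), seq_len(nf)), substr(sex_subj, 1, 1))
    age <- round(stats::runif(ns, 21, 99))
    nsin <- 2L * ns                      # sinus = subject x side
    s_of <- rep(seq_len(ns), each = 2)
    side <- rep(c("left", "right"), ns)
    len <- pmax(10, stats::rnorm(nsin, length_mean_mm[rep(1:2, c(nm, nf))][s_of],
                                 length_sd_mm))
    mw <- ln_scale(nsin, width_cv); mh <- ln_scale(nsin, height_cv)
    wmult <- ifelse(sex_subj[s_of] == "male", sex_width_multiplier, 1)
    # rows: 11 fractions within sinus, sinuses stacked
    W <- rep(width_profile, nsin) * rep(wmult * mw, each = 11) *
      ln_scale(11 * nsin, fraction_cv)
    H <- rep(height_profile, nsin) * rep(mh, each = 11) *
      ln_scale(11 * nsin, fraction_cv)
    out <- data.frame(subject = rep(subj[s_of], each = 11),
                      sex = rep(sex_subj[s_of], each = 11),
                      age = rep(age[s_of], each = 11),
                      side = rep(side, each = 11),
                      fraction = rep(fractions, nsin),
                      W_mm = W, H_mm = H, AR = W / H,
                      length_mm = rep(len, each = 11))
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}
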