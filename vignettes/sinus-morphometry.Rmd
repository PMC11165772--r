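---
title: "Measuring ethmoid-sinus morphology in 3D: models, choices, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ethmoid-sinus morphology in 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

The ethmoid sinus (ES) is an irregular complex of air cells whose
cross-sectional shape changes continuously from anterior (taller than wide,
elliptical) to posterior (nearly circular). Planar CT measurements of such
a structure are confounded by head orientation at scan time: a few degrees
of tilt in the sagittal plane changes apparent lengths and widths. The
pipeline in this package makes three moves to get orientation-independent
numbers out of a segmented cavity mask:

* a **coordinate normalization** step that rotates the model to the
  Frankfurt-plane convention using two landmark lines — the cranial base
  (which must end up horizontal in the sagittal and coronal views) and the
  nasal septum (vertical in the axial and coronal views);
* a **surface reconstruction and boundary clipping** step that turns the
  mask into a triangle mesh and removes everything outside the anatomical
  limits of the ES (cranial base above, periorbital wall laterally, middle
  turbinate medially);
* a **proportional sectioning** step that measures the cavity where it is,
  not at fixed depths: cutting planes perpendicular to the anteroposterior
  (AP) axis at 0%, 10%, ..., 100% of the cavity length `L`, a closed curve
  fitted to each plane-mesh intersection, and per-section width `W_i`
  (mediolateral extent of the curve), height `H_i` (superoinferior extent)
  and aspect ratio `AR_i = W_i / H_i`.

Axes follow the radiological convention used throughout the code:
+X mediolateral (left to right), +Y anteroposterior, +Z inferosuperior, all
in millimetres.

# Orientation model

A rotation is named by the anatomical *view* in which it is observed:
sagittal (about +X), axial (about +Z), coronal (about +Y). A misorientation
with angles $(s, a, c)$ is the matrix $M = R_x(s)\,R_z(a)\,R_y(c)$ — the
coronal rotation applied first, then axial, then sagittal. This convention
is arbitrary but fixed and documented; recovery is tested against the same
convention. `compute_reorientation()` builds an orthonormal frame from the
two landmark lines (total-least-squares directions when more than two
points are clicked, sign fixed by the click order), yielding exactly
$M^{-1}$ for landmark-exact input; the returned object stores the detected
misorientation angles and applies the correction. Angle *magnitudes* are
reported per plane because a sign convention for averaged clinical angles
is not well defined; cohort aggregation reports the mean of magnitudes and
the SD of the signed angles.

Two practical notes. Degeneracy (septum line parallel to the cranial-base
line) is refused with an error naming the offending landmark set, at a 1
degree threshold. And volumes are resampled with nearest-neighbour
interpolation (mask-preserving) only when a resampled volume is explicitly
requested; the pipeline itself rotates the reconstructed *mesh*, which is
exact and costs none of the ~1 voxel of extent accuracy that
nearest-neighbour resampling does.

# Surface reconstruction

The mask's surface is extracted as the voxel-boundary ("cuberille")
surface: every exposed face of a foreground voxel cube becomes two
triangles, with vertices on the voxel-cube corners in mm coordinates. For
binary data this *is* the 0.5-level set under nearest-neighbour
interpolation. It is watertight for face-connected masks, exact in mm, and
— unlike marching cubes on binary data — has no interpolation ambiguities.
Its quantization behaviour is easy to state: each extent is measured within
(−1, +1] voxel of the analytic value, with the face placed half a voxel
beyond the outermost foreground centre (the same midpoint convention
marching cubes would use on 0/1 data). The largest connected component is
kept, with a warning if discarded components exceed 10% of the largest.

Boundary clipping takes explicit geometric surfaces — oriented planes or
single-valued heightfields with an inside direction — rather than a
hand-drawn boundary, making the removal step reproducible. Crossing
triangles are split along the boundary (exact for planes, first-order for
curved heightfields), and the result may be open along the cut loops. The
*inferior* boundary is deliberately not clipped: the lowest point of each
section curve serves as the inferior limit, so the cavity's own lower
envelope defines `H_i`.

# Sectioning and the closed-curve fit

Cutting planes that pass exactly through mesh vertices (always true for the
0%/100% planes on flat-capped voxel models) are nudged inward by $10^{-6}$
mm so that every intersection is a clean set of crossing segments. The
segments are chained into loops by endpoint connectivity; the pooled loop
vertices, ordered by polar angle about their in-plane centroid, are the
section's *cutting points*. When a section contains several loops (internal
air-cell partitions), the convex-hull envelope of the pooled points is
fitted, so extents are envelope extents — internal partitioning does not
change a section's width or height.

The closed curve is a chord-length-parameterised periodic cubic through the
ordered points. Two numerical choices matter:

* **Shape preservation.** The interpolant uses monotone (Fritsch–Carlson)
  Hermite cubics per coordinate, wrapped cyclically. A classical C2
  periodic spline rings ~0.2 mm outward at the right-angle corners of voxel
  staircase contours, which would consume a fifth of the one-voxel accuracy
  budget; the shape-preserving cubic passes through every cutting point and
  cannot overshoot the data extents. (Whether the original measurement
  software's curve fit interpolates or smooths is unknowable from its
  description; interpolation is the default here, and a circular
  moving-average `smoothing` parameter is available for rough masks.)
* **Chord subdivision.** Chords longer than 2 mm (e.g. the straight edge
  left by a boundary clip) are subdivided with collinear points before
  fitting, which pins the curve to the polygon and prevents long-chord
  ringing.

Sections are flagged degenerate — `W = H = 0`, `AR` undefined — when the
plane is tangent (fewer than 4 points, collinear points, or in-plane extent
below 0.01 mm). This happens by construction at 0% and 100% on smoothly
closed cavities; flat voxel end caps instead produce a full-size cap
contour, which is kept. Cohort statistics use the interior sections
(10%–90%) either way.

The front plane ties are broken deterministically (minimum AP, then minimum
SI, then minimum ML coordinate).

# The synthetic world

No public dataset accompanies the kind of clinical cohort this pipeline
targets, so the generator is a first-class module with stored ground truth
rather than a test fixture.

A cavity is a superellipse tube along +Y: at fraction $f$ of its length the
cross-section is $|x/a(f)|^p + |z/b(f)|^p \le 1$ with $p = 2$ by default
and $a = W/2$, $b = H/2$ linearly interpolated between 11 per-fraction
profile values. Defaults state the world the cohort statistics are
validated in:

| parameter | default | why |
|---|---|---|
| subjects | 21 male + 15 female, 2 sinuses each | the 72-sinus design the statistics mirror |
| length | 40.7 ± 5.0 mm, per sinus | published ES lengths cluster near 40 mm; one sex-free mean (no length effect) |
| width profile (female) | 7.2–10.3 mm, peak at 80% | anterior-narrow, posterior-wide |
| height profile | 12.6–18.0 mm, peak at 40% | tall anterior vault, low posterior end |
| implied AR | ~0.57 anterior rising to ~0.87 posterior | elliptical-anterior / circular-posterior regime |
| sex width multiplier | 1.2 | male sections ~20% wider, heights equal |
| misorientation SD | (10, 2, 2) degrees | sagittal-dominated scanner tilt |
| voxel spacing | 1 mm isotropic | 1 mm slice-thickness acquisition |

Choices a maintainer should know about:

* **Misorientation** is sampled per *subject* (both sides share one scan)
  and applied analytically before voxelization — each mask is voxelized
  exactly once, on a half-offset grid (centres at $k + 0.5$ voxels).
  Landmarks are generated consistently with the applied rotation.
* **Lengths are independent per sinus.** The analysis treats the 72
  sinuses as independent units; had left/right shared a length, the length
  *t*-test's type-I error would inflate to ~0.18. Real within-subject
  correlation is therefore deliberately *not* modelled; this is the main
  respect in which a green statistical test here understates what clinical
  data would do, and the `subject_level` flag exists for the conservative
  analysis.
* **Surface noise is extent-preserving.** The noise field uses only the
  first circumferential harmonic, $\delta(\theta, f) = A(f)\cos(\theta +
  \phi(f))$, with pointwise SD `surface_noise_sd_mm`: it displaces and
  bends cross-sections (a wobbling cavity axis) without changing their
  extents beyond second order. This is a requirement, not an aesthetic: the
  stored ground truth must remain the correct reference for a noisy
  cavity, otherwise "recovery within 2 voxels" would compare against a
  number that the noise itself had invalidated.
* **Septa** are thin erased walls that spare a 1.5-voxel rim, so the
  cavity stays connected and the outer envelope — hence the truth — is
  unchanged, mimicking air-cell partitions that the envelope measurement
  is supposed to ignore.
* **Voxel-resolution guard.** Generation is refused when the smallest
  profile extent spans fewer than 3 voxels.
* The voxel generator varies length and orientation but not girth; the
  population spread needed for cohort statistics (width CV ~0.21, height
  CV ~0.20, mean-one lognormal per sinus) lives in the summary-level
  simulator `simulate_cohort()`, which draws per-sinus morphometric
  summaries directly and is what the statistical acceptance checks use at
  1000-replicate scale.

# Statistics

Sex comparisons are two-sided pooled-variance *t*-tests per parameter and
section (Welch and Holm variants behind flags, off by default to match the
per-section *p*-values the analysis mirrors). The normality screen is a
one-sample Kolmogorov–Smirnov test against a normal with estimated mean
and SD — uncorrected, as in common SPSS workflows. That choice is
conservative: against exponential data at $n = 100$ it rejects ~90% of the
time, while the Monte-Carlo Lilliefors correction (`lilliefors = TRUE`)
rejects essentially always.

The anterior/posterior contrast takes anterior = sections 10–40%,
posterior = 60–90%, with the 50% section as the divide belonging to
neither mean; the mirrored-pair tests (10 vs 90, 20 vs 80, 30 vs 70,
40 vs 60) likewise exclude it. The conventional labels for these ranges
("10–50%" and "50–90%") overlap at the midpoint, and no percent difference
can satisfy both memberships at once; the disjoint definition reproduces
the quoted arithmetic exactly — a step profile at 0.600/0.744 gives
$(1 - 0.600/0.744) \times 100 = 19.4\%$. Left-right symmetry is a paired
*t*-test on per-subject mean AR. Post-hoc power uses the exact noncentral
*t* distribution and is validated against a Monte-Carlo rejection-rate
oracle to ±0.01.

Degenerate inputs are never silent: single-observation groups yield
NA-flagged rows with a warning, zero-variance paired differences map to
$p = 1$ (no effect) or $p = 0$ (constant nonzero effect), and zero-variance
normality input is an error.

# What the acceptance battery establishes — and what it does not

`tests/testthat/test-acceptance.R` (and `scripts/acceptance.R`, which
recomputes the same quantities from scratch) checks: the analytic
ellipsoid slice oracle at 1 mm voxels; ground-truth recovery within one
voxel per axis over 40 zero-noise sinuses (within two voxels at 0.5 mm
surface noise) — "per axis" meaning one voxel on the in-plane extent plus
the truth profile evaluated within one voxel of the nominal plane position
along the AP axis, since the measured end planes inherit ±0.5 voxel of cap
quantization each; landmark-exact reorientation recovery over 200 sampled
misorientations and metric stability within 2% after mesh-level
misorient + reorient; type-I error 0.05 ± 0.02 and width power ≥ 0.9 (with
length nonsignificant) at 42/30 sinuses over 1000 summary-level
replicates; closed-form agreement of the pooled *t* and Monte-Carlo
agreement of the power routine; and the 19.4% anterior/posterior contrast
on a step-AR cohort.

None of this reproduces clinical population values: the generator's
profiles are stylized conventions (the per-fraction population table they
stand in for was published only as a figure), real cavities are not
superellipse tubes, real segmentations carry correlated boundary errors
rather than extent-preserving wobble, and within-subject side correlation
is unmodelled. What a green battery does establish is that the measurement
chain — voxelization, reorientation, clipping, sectioning, curve fitting,
statistics — is internally correct to its stated tolerances on inputs
whose true answer is known.

# Known limitations

* Heightfield boundary crossings are located by linear interpolation, so
  strongly curved boundary surfaces should be supplied at adequate mesh
  resolution.
* The cuberille surface doubles triangle counts relative to marching
  cubes; at the 1 mm / cavity-scale workloads here this is irrelevant
  (~10^4 faces).
* NIfTI support covers single-file NIfTI-1 with diagonal affines — the
  format this pipeline writes and the usual export of segmentation tools;
  oblique affines are refused rather than silently resampled.
* Only binary masks are meaningful inputs; there is no intensity model.
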