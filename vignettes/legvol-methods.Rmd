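---
title: "Methods: bilateral leg volumetry from whole-body surface scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bilateral leg volumetry from whole-body surface scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(legvol)
```

## Why leg volume, and why precision

In lymphedema and lipedema care the clinical endpoint is change in limb
volume over time. Whether a 90 mL change in a 9000 mL leg is a treatment
effect or scanner noise depends entirely on the repeatability of the
measurement: a workflow with 1% scan-to-scan relative difference cannot
resolve changes smaller than about 90 mL at that volume. `legvol`
therefore treats the **relative percent difference between two
same-session scans of the same subject**,

$$\mathrm{rel\_diff} = 100 \cdot \frac{|v_1 - v_2|}{(v_1 + v_2)/2},$$

as the primary endpoint, and builds everything else — mesh processing,
phantom generation, cohort statistics — around estimating it faithfully.

## The geometric pipeline

### Canonical frame

Scans arrive in an arbitrary rigid pose. `align_to_origin()` detects the
flat turntable support plane with RANSAC over low-lying vertices,
refines it by iterated total least squares (re-selecting inliers from the
whole mesh each iteration, so the fit is not biased by the initial
candidate set), rotates the plane normal onto $+z$, and centres the
subject horizontally on the bounding-box midpoint of the support-plane
inliers. The midpoint, rather than the inlier centroid, is used because
the inlier set is truncated by noise asymmetrically and its centroid is a
biased estimate of the turntable axis; the bounding-box midpoint recovers
the axis to a few tenths of a millimetre under realistic noise.
Anteroposterior facing comes from a PCA of a torso cross-section slab
(the belly points along $-y$); when that is ambiguous — for instance a
torso with a nearly circular section — a typed
`legvol_ambiguous_orientation` error asks for a manual angle, standing in
for the interactive alignment step of a GUI workflow.

### Exact cropping and splitting

The leg band is bounded by two transverse planes at subject-specific
landmark heights: the lateral malleolus (`z_low`) and the infragluteal
fold (`z_high`). `split_by_plane()` clips triangles exactly
(Sutherland–Hodgman per triangle); intersection vertices are computed
once per cut edge and shared by both output halves, so the capped volumes
of the two halves sum to the original volume with zero residual beyond
floating point. This matters because the limited-visibility workflow
*defines* each leg's volume as a half-space volume: any leakage across
the cut would bias left against right.

### Two visibility regimes

After cropping, connected components are classified by size and position:

* **complete visibility** — the legs are two separate components; each is
  repaired and measured whole.
* **limited visibility** — in higher-BMI subjects the medial thigh
  surfaces press together and the scanner sees a single fused surface.
  The fused component is split at the median sagittal plane
  (`x = sagittal_x`, the turntable axis by default) and each half is
  treated as one leg. The per-leg quantity being estimated is then the
  flat-capped half-space volume, which is the natural operational
  definition when the true medial boundary is invisible.

A scan with only one leg-like component and no fused signature, or a
degenerate split, raises a typed error rather than returning a silent
wrong answer; `run_cohort()` records such subjects in a `failures` table
and continues.

### Surface repair

Repair runs in a fixed order chosen so each step cannot create work for
an earlier one:

1. **Spike removal** first (before any filling, so large patch triangles
   are never mistaken for spikes). A vertex is a spike candidate when its
   *shortest* incident edge exceeds `spike_edge_factor` (default 4) times
   the global median edge length — a vertex yanked off the surface is far
   from *all* of its neighbours, whereas its neighbours keep their short
   lateral edges — confirmed against the local 1-ring median, and
   accepted only if at least one of its face normals deviates more than
   `spike_normal_angle` (default 70 degrees) from the mean surrounding
   normal. The maximum per-face deviation is used rather than the mean
   because on a symmetric spike cone the mean of the cone-face normals
   points along the spike axis and the deviation cancels.
2. **Flat fill** of the sagittal cut and occlusion holes. Each boundary
   loop is fitted with a least-squares plane, projected to 2D and
   ear-clipped. Planar patches contribute no spurious volume (the flux of
   the position field through a planar cap equals exactly the volume of
   the prism it closes), so closing a planar cut is volume-exact, not an
   approximation. Loops lying in the crop planes are skipped here and
   capped in step 4. If a projected loop is not a simple polygon the fill
   warns (`legvol_fill_fallback`) and uses a centroid fan — still
   volume-exact for planar loops, since any triangulation of a planar
   loop has identical flux.
3. **Small-hole filling** closes remaining loops of at most
   `small_hole_max_edges` edges (default 25).
4. **Planar capping** of the crop-plane boundaries.

The result must be watertight and is re-oriented to consistent outward
windings; otherwise a `legvol_open_mesh_error` is raised.

### Volumetry

For a watertight, consistently oriented mesh the enclosed volume is the
exact divergence-theorem sum

$$V = \frac{1}{6}\left|\sum_{\text{faces}} v_0 \cdot (v_1 \times v_2)\right|,$$

converted from mm^3 to millilitres. This is exact for the polyhedron — a
100 mm cube returns exactly 1000 mL — so all discretization error lives
in how well the mesh approximates the body, not in the integral. For
inscribed polygonal approximations of smooth cross-sections the volume
error shrinks quadratically with the angular segment count (a factor of
about 4 per doubling), which the test suite verifies; 128 segments keeps
analytic phantoms within about 0.05% of truth.

## The phantom family

Physical reference objects are replaced by meshes whose volumes have
closed forms.

* `mesh_generalized_cylinder()` builds elliptical generalized cylinders
  from a piecewise-linear profile $(z, a(z), b(z))$, optionally sheared
  in $x$ by a per-slice centre offset $c_x(z)$. The slice area
  $\pi a b$ is quadratic in $z$ between knots, so `leg_profile_volume()`
  integrates it exactly with Simpson's rule per interval; the shear does
  not change slice areas, hence not the volume.
* `slim_leg_profile()` and `stout_leg_profile()` are leg-like profiles
  (ankle, calf, thigh knots) with medially leaning axes: feet about
  400 mm apart — a natural standing stance — with thighs converging
  toward the midline so that thigh fusion is geometrically realistic.
* `make_fused_pair()` joins two circular-section legs with a medial
  bridge $|y| \le w$ across a fusion band in which both sections are
  circular with constant radius and centre offset (validated, including
  interior profile knots). The bridge half-width snaps to the angular
  vertex grid so the horizontal "shelf" polygons share vertices exactly
  with the leg walls, keeping the union watertight by construction. The
  extra cross-section area of the bridge has the closed form
  $4 c w - 2\!\left(w\sqrt{r^2 - w^2} + r^2 \arcsin(w/r)\right)$
  (rectangle minus the two circular bites), where $2c$ is the
  centre-to-centre distance, so the fused phantom's total and per-leg
  (sagittally capped) truths are analytic.
* `make_whole_body_phantom()` adds a torso block and a turntable disc so
  orientation, torso-facing detection and cropping are exercised
  end to end.

### Simulated acquisition noise

`perturb_scan()` applies per-vertex Gaussian jitter and a random rigid
body transform. Defaults (`noise_spec()`): 0.5 mm jitter, up to
2 degrees of tilt and 10 mm of placement offset — the scale of
surface-reconstruction noise and repositioning between back-to-back scans
on a turntable system. The seed is required, so every simulated scan is
reproducible, and the global RNG stream is left untouched.

### The simulated cohort

`simulate_precision_study()` draws subjects with BMI from a truncated
normal (mean 32.3, SD 9.7, truncated to 18.5–56), age from N(41, 12),
and a 78% female share — a population in which obesity, and therefore the
limited-visibility regime, is common. Subjects with BMI of 30 or more
receive the fused-thigh anatomy; phantom scale follows the square root of
BMI so that heavier subjects have proportionally larger limbs. Each
subject gets two independently perturbed scans with deterministic
per-scan seeds. The defaults *are* the study conditions; they are not
tuned per run.

## Statistics

* `pair_measurements()` pairs the two scans per subject and side and
  computes the relative percent difference.
* `paired_t_test()` tests for systematic scan-to-scan bias; with
  noiseless inputs the differences are exactly zero and the test
  degenerates gracefully.
* `rank_sum_test()` compares relative differences between the complete-
  and limited-visibility subgroups: exact (permutation) for small,
  tie-free samples, normal approximation otherwise, with the
  Hodges–Lehmann shift and its confidence interval. When both samples are
  entirely identical the statistic is reported at its null centre
  ($W = n_a n_b / 2$, $p = 1$) rather than NaN.
* `cohort_summary()`, `demographic_summary()` and `classify_bmi()` (WHO
  classes) produce the cohort tables; `tidy()` and `glance()` methods
  give broom-style access to the test objects.

## Limitations

* The phantoms are smooth analytic solids: they validate the geometry
  and statistics engines, not scanner-specific artifacts such as motion
  blur, texture-dependent dropout or reconstruction bias.
* The limited-visibility per-leg volume is a *definition* (sagittally
  capped half-space), not a recovery of the hidden medial surface; left
  and right are individually sensitive to the sagittal-plane position,
  although their sum is not.
* Landmark heights (`crop_config()`) are treated as given per subject;
  locating anatomical landmarks on the mesh is out of scope.
* The PCA facing detector assumes a torso that is wider than it is deep
  within the sampled slab; atypical geometry raises a typed error and
  requires a manual angle.
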