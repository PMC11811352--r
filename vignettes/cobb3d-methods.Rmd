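---
title: "Measuring 3D Cobb angles from spine segmentation masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 3D Cobb angles from spine segmentation masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Scoliosis severity is classically quantified by the Cobb angle, the angle
between the most tilted vertebral endplates on a standing coronal
radiograph. Preoperative CT captures the full three-dimensional deformity,
and a natural 3D generalization of the Cobb angle is the **maximal angle
between tangent vectors of the spinal centerline**. `cobb3d` computes this
statistic from a binary segmentation mask of the spinal column (for example
the output of a deep-learning vertebra segmentation). The segmentation step
itself is out of scope: the package starts from the mask.

The pipeline is

1. resample the binary mask to a common working grid,
2. **spoke-kernel filtering** to strip transverse and spinous processes and
   sever narrow bridges between adjacent vertebrae,
3. removal of small disconnected components,
4. **K-means clustering** of the remaining (vertebral-body) voxels,
5. **least-squares cubic NURBS fitting** of the cluster centroids, giving a
   smooth spinal centerline,
6. sampling 100 points and unit tangents from the curve and reading two
   statistics off the pairwise **tangent-angle map**:
   - `PRED-3D-CA`, the maximum of the Gaussian-smoothed angle map, and
   - `MAP-2D-CA`, the maximal pairwise angle after projecting the curve
     onto the coronal plane (the classical radiographic view).

```{r}
library(cobb3d)
ph <- rasterize_phantom(phantom_spec(cobb_angle_deg = 40, seed = 7))
res <- measure_mask(ph$mask, pipeline_config())
res$result
```

## Spoke-kernel filtering

The whole-vertebra mask includes the vertebral body plus thin bony
processes; in severe scoliosis the processes of adjacent vertebrae can
touch, fusing separate vertebrae into one component and dragging any fitted
centerline posteriorly. The spoke kernel is a circular mask of radius $r$
built from the midpoint circle algorithm; each pair of centrosymmetric
perimeter pixels is joined through the center by a midpoint (Bresenham)
line, giving the set of rasterized diameters. The kernel center visits
every foreground pixel of every axial slice; if **both** endpoints of a
diameter fall on background (or outside the image), all pixels of that
diameter are marked, and the marks are applied once after the whole scan.
A structure thinner than $2r$ in some direction therefore loses its entire
cross-section, while a convex body of diameter well above $2r$ only loses a
boundary ring of depth roughly $r^2/2R$ (sagitta of the $2r$ chord at a
boundary of curvature radius $R$), plus any thin cross-sections near its
tips. For the default body radius (15 mm) and kernel radius (8 mm) this
erosion is substantial in voxel count (a quarter or so of the foreground)
but harmless: it is confined to the boundary shell, and what remains is the
body core that should drive the centerline. Filtering is strictly
monotone — output foreground is a subset of input foreground.

The default radius is 8 mm; it should exceed half the thickness of the
structures to remove and stay below half the body diameter. A radius too
large erodes the bodies themselves; the package warns when more than 75% of
the foreground disappears. Components below 500 voxels (26-connectivity)
are then discarded.

## Centerline extraction

**Cluster budget.** K-means runs on the physical (mm) coordinates of all
remaining foreground voxels with one cluster per 1000 voxels of the
reference 0.90 × 0.35 × 0.35 mm grid. Because a voxel-count rule is tied
to a grid, the budget is applied per physical volume — one cluster per
110.25 mm³ of foreground — which reduces to exactly `floor(N / 1000)` on
the reference grid and keeps the cluster density unchanged when a mask is
processed at another resolution. The count is floored at 8, the number of
spline control points, so the fit stays determined. Seeding is k-means++
under a fixed seed (the one tunable randomness of the whole pipeline),
followed by MacQueen iterations from `stats::kmeans`; a single seeded
k-means++ start replaces random restarts, which at several hundred clusters
would dominate runtime without measurably changing the fitted curve.

**Parameterization.** Each centroid gets a curve parameter proportional to
its superior–inferior coordinate. This choice matters. Centroids of a
thick, roughly cylindrical column scatter across the cross-section, so
several centroids share an axial level while differing laterally by up to a
body radius. Chord-length parameterization — the textbook default for
interpolation — strings those centroids into a zigzag polyline and assigns
the zigzag real parameter distance, and the least-squares curve then bends
to follow it; on straight-spine phantoms this inflates the measured maximal
tangent angle from ~0° to ~10°. Axial parameterization instead treats
same-level centroids as replicate observations of one curve location, and
the regression averages them. Its known limitation is shared with the
superior–inferior centroid ordering it relies on: a spine locally
perpendicular to the axial direction (not observed even at 85° Cobb angles,
where local tangents stay within ~45° of the axis) would break the
monotonicity assumption. Chord-length parameterization remains available
via `fit_nurbs(..., parameterization = "chord")`.

**Weighting.** The clustering step is a computational reduction of the
voxel cloud, and clusters summarize unequal numbers of voxels. The control
points therefore solve the voxel-count-weighted least-squares problem
$\min \sum_c n_c \lVert C(u_c) - p_c \rVert^2$, the exact
sufficient-statistic form of fitting all voxels individually with each
cluster collapsed to its mean. Besides fidelity, this de-leverages the
small clusters at the eroded tips of the end vertebrae, which otherwise
dominate the under-constrained end spans of the spline. (The NURBS weights
proper remain 1 — the fitted curve is a nonrational B-spline; the rational
form is kept in the data model.)

**Spline space.** Degree 3 with 8 control points, clamped knots (four 0s,
four 1s, four free interior knots placed by averaging the data parameters).
Eight control points over a whole spine is deliberately stiff: it blurs out
segmentation noise and small erosion asymmetries while leaving enough
freedom for a double curve. For fixed knots and parameters the solution is
the global least-squares minimum (verified in the tests by perturbation).

## The angle map and the two Cobb statistics

The curve is sampled at 100 uniform parameter values with unit tangents
from the analytic derivative. Pairwise angles
$\mathrm{Angle}(p, q) = \arccos(T_p \cdot T_q)$ are computed between the
5th and 95th samples (1-based, inclusive: 91 indices), because the curve
tails reflect incompletely imaged vertebrae at the volume borders. The
resulting 91 × 91 map is symmetric with a zero diagonal.

`PRED-3D-CA` is the maximum of the map after convolution with a 2D
Gaussian (σ = 2 map-index units, kernel truncated at 4σ, reflect
boundaries). Smoothing is a convex average, so the smoothed maximum can
only move down; a maximum supported by a broad region of the map — a
genuine arc — survives almost unchanged, while a maximum produced by one
noisy tangent pair is suppressed. σ = 2 spreads mass over roughly ±8% of
the curve, below the width of any plausible scoliotic arc.

`MAP-2D-CA` drops the anterior–posterior component of the tangents,
renormalizes, excludes samples whose projection nearly vanishes (norm
below 10⁻³; an error is raised if more than half are excluded, meaning the
curve is mostly sagittal), and takes the maximal pairwise angle of the
projected tangents, unsmoothed — the smoothing device belongs to the 3D
statistic. For a curve lying exactly in the coronal plane the projection
is the identity on tangents and the two raw statistics agree to numerical
precision; out-of-plane curvature strictly reduces the projected angle.

Angles are reported in degrees and rounded to 0.1° in output files.

## The phantom generator

Every stage is validated end-to-end on synthetic phantoms with analytically
known curvature, because clinical masks with annotated 3D Cobb angles are
not publicly available. The phantom centerline is straight–arc–straight: a
circular arc with total turning angle `cobb_angle_deg` flanked by straight
caps, tangent-continuous at the joins, either within the coronal plane or
tilted out of it. The maximal pairwise tangent angle of such a curve equals
the arc's turning angle exactly, and the caps keep the whole arc inside the
5th–95th trim window, so the declared truth is exact rather than
approximate. Vertebral bodies are ellipsoids (default radius 15 mm, height
22 mm, gap 6 mm) strung at equal arclength along the curve and oriented
along the local tangent; each carries two transverse bars and one posterior
bar of 4 mm square cross-section, emulating the processes the filter must
remove. Rasterization defaults to the 0.90 × 0.35 × 0.35 mm reference
grid, and identical spec and seed give a bit-identical mask.

Geometry choices that required care:

- **Caps cover 15% of arclength each.** Two pressures set this. The arc
  should be as long as possible, because real spines have no curvature
  discontinuities and a smooth spline rings around the synthetic curvature
  jump at a cap join, overshooting the recovered angle by ~3% of it when
  the turn is squeezed into the central 60% of the curve. But a cap must
  also contain about two vertebral bodies beyond the trimmed tail: a
  single body is wider (30 mm) than tall (22 mm), so its voxel cloud alone
  cannot orient the end of the fitted curve — only body-to-body progression
  can — and shorter caps make the fit shrink the end direction toward the
  interior, undershooting large angles by several degrees.
- **Body jitter is 0.1 mm (sd).** The seeded lateral jitter makes seeds
  meaningful, but jitter is real displacement: a jittered chain of bodies
  has genuine nonzero turning angle. At 0.1 mm the induced turning
  (~atan(2·0.1/28) ≈ 0.4°) stays well below the declared truth's
  resolution; the earlier 0.4 mm draft put ~2° of real curvature into
  nominally straight phantoms.
- Processes are axis-aligned bars, not anatomical meshes: only their
  thinness relative to the kernel matters.

What the phantom does **not** emulate: CT intensities and noise, real
vertebral shape (endplates, pedicles, canal), segmentation errors of an
upstream network, axial rotation of vertebrae, and non-circular curvature
profiles. Passing the recovery tests therefore shows that the geometry
pipeline measures what it claims on idealized columns, not that an
upstream segmentation is accurate.

## Problem sizes and numerical choices

The test suite and the acceptance script rasterize phantoms at
1.8 × 0.7 × 0.7 mm — a 2× downsampling of the reference grid with the
geometry in millimetres unchanged. With the volume-based cluster budget
the method then operates at the same cluster density as on the reference
grid (~700 clusters for a 12-vertebra column), and a full phantom →
measurement cycle takes ~10 s, so the whole recovery grid (angles 0°–80°,
three seeds each) runs in a few minutes on one CPU.

- Angle-map dot products are clamped to [−1, 1] before `acos`; the map is
  symmetrized exactly and its diagonal set to 0.
- Tangents with derivative norm below 10⁻¹² raise an error (degenerate
  curve); unit norm is enforced to 10⁻⁹ on construction.
- The spline design matrix is checked for full column rank; degenerate
  parameterizations (no axial progression) are rejected rather than
  silently fitted.
- Ties in the angle-map argmax resolve to the smallest index pair
  (column-major scan), which matters only for exactly symmetric synthetic
  maps.
- K-means uses `iter.max = 50`; MacQueen converges in 30–50 iterations on
  these data. Results are bitwise reproducible for a fixed seed.
- Resampling is nearest-neighbour on the voxel-center grid — the only
  label-preserving choice for binary masks; it preserves foreground volume
  of large structures to a few percent.

## Known limitations

- The superior–inferior ordering and axial parameterization assume the
  spine progresses monotonically along the scanner axis; extreme local
  horizontalization would violate this.
- The spoke filter operates per axial slice (the 2D form of the operator);
  a structure thin only along the slice axis would not be removed.
- The kernel radius is a fixed parameter (flag on the CLI); no automatic
  per-case adaptation is attempted.
- Vertebrae are not individually labelled; statistics are properties of
  the whole-column centerline.
- With 8 control points a triple curve with very short segments would be
  under-resolved; the control-point count is kept at the method's stated
  value rather than adapted.
- The phantom recovery guarantees hold for the default twelve-body
  geometry. Short columns (six or fewer bodies) leave less than two
  bodies per cap, under-constrain the curve ends and can misread the
  angle by several degrees — a genuine property of end-span
  extrapolation, not of the angle statistics.
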