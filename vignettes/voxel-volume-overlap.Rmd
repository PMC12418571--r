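---
title: "Voxel volume overlap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel volume overlap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vvoqc)
```

## The model

Rigid-body realignment summarises each fMRI volume's head position by six
parameters: translations $t_x, t_y, t_z$ (mm) and rotations
$r_x, r_y, r_z$ (radians, "pitch", "roll", "yaw"), reported relative to a
reference volume. `params_to_transform()` maps these to a homogeneous
transform $T = \mathrm{Trans}(t)\,R_x(r_x)\,R_y(r_y)\,R_z(r_z)$ with
right-handed, counterclockwise rotation matrices acting about the world
origin of the parameter frame — the frame in which realignment software
reports its estimates, so rotations displace material points in proportion
to their distance from that origin.

The overlap measures ask a voxel-scale question: after the motion between
two volumes, how much of a voxel's volume still coincides with where it was?
For timepoint $t$ the relevant motion is the relative transform
$T_t T_1^{-1}$ (against the first volume; slow drift) or
$T_t T_{t-1}^{-1}$ (against the preceding volume; spikes). Applying it to a
reference cuboid with the acquisition's voxel edge lengths and intersecting
with the unmoved cuboid gives

$$\mathrm{TD\_VVO} / \mathrm{STS\_VVO} = 100\cdot
\frac{\operatorname{vol}\big(T\,V \cap V\big)}{d_x d_y d_z}\ [\%].$$

Both are 100% at the first timepoint by convention, and for a pure
translation $s$ reduce to the closed form
$100\prod_i \max(0,\, 1 - |s_i|/d_i)$, which the test suite uses as an
independent oracle.

### Exact intersection by half-space clipping

No simple algebraic formula covers rotated cubes, but the intersection is
computable exactly. The reference voxel is the intersection of six
half-spaces (one per face, normals pointing inward). The moved cuboid —
eight transformed corners plus their twelve edges — is clipped against
these planes one at a time: vertices on the kept side survive, every edge
crossing the plane is cut at its linear-interpolation intersection point,
and the cut points are stitched into a new planar cap face (ordered
angularly in the cutting plane, valid because the remnant stays convex).
After all six cuts the remnant's volume is obtained by fan
tetrahedralization from the vertex centroid over the face polygons, which
for a convex body equals the volume of the convex hull of its vertices.
An independent Monte-Carlo estimator (`mc_overlap_oracle()`: uniform
samples in the moved cuboid, membership test against the reference box) is
shipped for verification and is never used for measurement.

### Representative voxels and the median

Rotation effects vary over space, so overlap is evaluated at six probe
voxels on the axes at radius 65 mm — the average adult cortical distance —
labelled A/P, R/L, S/I under RAS conventions. The per-timepoint summary is
the median of the six (with six values, the mean of the 3rd and 4th order
statistics), a robust choice given the lack of a principled preference for
any one location. `compute_vvo()` accepts arbitrary user centres (e.g.
atlas region centroids) through the `centers` argument. The conventional
TD/STS series is summarised at the same six points by default so the two
families of measures are spatially comparable; a root-sum-square aggregate
of the six raw parameters (translations plus $65\,\theta$ arc lengths) is
available behind `aggregate = "rss"` for comparability studies.

### Out-of-plane decomposition

Out-of-plane motion is disproportionately harmful (spin-history effects),
so the displaced volume $d_xd_yd_z - \operatorname{vol}(TV\cap V)$ is split
by clipping the moved cuboid to the half-spaces beyond the two reference
faces perpendicular to the through-plane axis (axial → z, coronal → y,
sagittal → x). The out-of-plane proportion is reported with the first
volume as the fixed reference, since the acquisition plane does not change
over time. Because per-centre denominators can be near zero, the default
proportion pools numerator and denominator over the six centres before
dividing; per-centre ratios are returned alongside for inspection. When a
timepoint has no displaced volume at all the proportion is undefined and
flagged rather than reported as 0 or 100. Axes are assumed cardinal
(non-oblique) and aligned with the parameter frame.

## Calibration and classification

The link between STS (mm) and STS_VVO (%) is modelled as a line forced
through (0 mm, 100%): zero motion must mean full overlap. Under that
constraint the least-squares problem becomes regression through the origin
of the overlap deficit, $100 - y = a\,x$, with the closed-form solution
$a = \sum x_i(100-y_i) / \sum x_i^2$. Only pairs with STS in the clinically
realistic window 0–1.5 mm enter the fit, and a session contributes a
coefficient only when more than 25% of its datapoints survive the
windowing; `mean_calibration()` averages `a` over included sessions.
`lookup_table()` tabulates $100 - a\cdot\mathrm{STS}$ on a 0.05 mm grid,
rounded at the second decimal half-away-from-zero and clamped at 0.

Quality labels use the default cutoffs 90% (very high), 80% (high) and 55%
(potentially acceptable; below, questionable), with 35% marking the very
lenient end of the lookup range. The published wording ("above 90%",
"below 55%") leaves equality undefined; this implementation makes the
boundaries inclusive upward, so exactly 90 classifies as very high.
`censor_regressor()` flags volumes whose median overlap falls *strictly*
below the threshold (default 55% on STS_VVO) and emits the one-hot
spike-regressor matrix GLM software expects.

## Synthetic data

The package tests itself without imaging data. `pure_shift_series()`
reproduces the ground-truth simulations: simple shifts of 0.5–3 mm in one
dimension, whose overlap is known in closed form for every voxel size.
`random_motion()` emulates a realistic trace as cumulative Gaussian drift
(default SD 0.02 mm/volume per axis) plus transient Bernoulli spikes
(rate 0.05, SD 0.5 mm), with rotations a scaled-down analogue (drift SD
0.002 rad, spike SD five times that). These defaults were chosen once to
land mean STS in the 0.07–0.26 mm range typical of adult sessions, and the
suite asserts the regime, not the exact values. `calibration_session()`
draws STS from a half-normal with scale 0.5 mm truncated to the 0–1.5 mm
window (so windowing itself removes nothing) and overlap from the
generative line plus Gaussian noise, clamped to [0, 100].

What the generator does *not* emulate: within-volume (slice-wise) motion,
spin-history and interpolation artefacts, physiological noise, or any
image content. Passing tests therefore demonstrate the geometric and
statistical machinery, not the behaviour of any particular scanner or
cohort.

## Numerical choices

* On-plane tolerance 1e-9 mm for vertex classification and deduplication;
  vertices within tolerance of a cutting plane count as kept, so grazing
  contact cannot shave slivers off the remnant.
* Degenerate remnants (empty, point, segment, planar polygon) have volume
  0 silently — they are legitimate "no 3D overlap" outcomes.
* Identity motion short-circuits to exactly 100%; results are clamped to
  [0, 100] against round-off.
* The effective (smoothness-based) resolution is supported only as
  user-supplied dimensions (`label = "effective"`); the acquired voxel
  size remains the reference standard and the package does not estimate
  smoothness from residuals.
* Problem sizes in the shipped suite: the full 6-shift × 8-size
  ground-truth grid; 200 seeded random transforms (shifts up to one voxel,
  rotations up to 0.3 rad) against a 10⁶-sample Monte-Carlo oracle; 50
  synthetic calibration sessions of 300 timepoints. These were chosen as
  the package's own validation scale.

## Known limitations

Overlap metrics summarise rigid between-volume motion only; they cannot
see intra-volume motion or signal-level consequences. Oblique acquisitions
are not modelled — the plane decomposition assumes the slab axes coincide
with the parameter axes. The default calibration slope (43.2422% per mm)
is an empirical cross-session mean at 3 mm resolution; sessions at very
different resolutions should be recalibrated with `fit_constrained()` on
their own data.
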