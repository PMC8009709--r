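---
title: "Assessing dental scan-system accuracy on a synthetic integration model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing dental scan-system accuracy on a synthetic integration model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanmetry)
```

## The problem

Digital impressions from intraoral and extraoral scanners feed directly into
CAD/CAM prosthetic workflows, so their dimensional accuracy matters
clinically. Accuracy decomposes, in the ISO 5725 sense, into *trueness*
(closeness to an accepted reference value) and *precision* (closeness of
independent replicate measurements to each other). A practical way to
benchmark scan systems is a machined single-tooth standard — an
"integration model" combining crown-like and inlay-like features in one
centrally symmetric body — whose dimensions are certified with a
coordinate measuring machine (CMM) and then re-measured on every scan.

`scanmetry` implements that whole study as a reproducible pipeline on
synthetic data: it generates the model as a watertight triangle mesh from
its design dimensions, simulates replicate scans with controlled error,
re-measures the model's six geometric indices on every scan, registers scans
to the gold standard to obtain surface RMS deviations, and summarises
trueness, precision and group comparisons.

## The model geometry

Six indices describe the model:

| index   | meaning                                        | default (mm / deg) |
|---------|------------------------------------------------|--------------------|
| `R1`    | upper (occlusal) cylinder radius               | 3.000              |
| `R2`    | base cylinder radius, at the base plane        | 5.000              |
| `L1`    | shoulder plane to occlusal rim height          | 2.000              |
| `L2`    | base plane to shoulder plane height            | 8.000              |
| `L3`    | total height (`L1 + L2`, also measured directly) | 10.000           |
| `theta` | occlusal surface inclination above the rim plane | 23.000           |

The canonical construction puts the base plane at `z = 0` with the model
axis along `z`: a base cylinder of radius `R2` and height `L2` (its wall
drafted inward by `outer_draft`, 2 degrees by default, so the body presents
no axial undercut to a scanner or a milling tool), a coaxial upper cylinder
of radius `R1` and height `L1`, and a conical occlusal cap rising from the
rim at `theta` towards an apex on the axis. This is the unique simple
axisymmetric reading of the published drawing under which `L1 + L2 = L3`
— a decomposition the certified dimensions satisfy to a micrometre — and
the constructor isolates that interpretation: if the physical drawing were
read differently only `generate_model()` would change, while the
measurement contract stays fixed.

Two perpendicular rectangular ditches (default 1.5 mm wide) mimic a
prepared MOD cavity. They cross at the axis and run the full occlusal
surface, opening through the upper wall. Their flat floor lies
`ditch_depth` (default 1.0 mm) below the *rim plane*; the constructor
requires `ditch_depth < L1` so the floor stays above the shoulder. We chose
the rim plane rather than the cone apex as the depth datum because it keeps
a single mesh topology for every admissible parameter set (the channels
always reach the lateral wall, as channels "across the occlusal surface"
should) and makes the depth independent of `theta`. Ditch dimensions are
auxiliary features, not indices; their defaults are free choices of
plausible cavity proportions.

The tessellation is assembled patchwise (caps, walls, shoulder, cone
sectors, ditch walls and floor) with shared boundary vertices generated
from identical arithmetic, then welded at 1e-6 mm and globally oriented.
Watertightness, consistent outward orientation, quarter-turn symmetry and
volume convergence are asserted by the test suite across a grid of
parameter sets. The gold standard defaults to 512 angular segments (chord
error `R (1 - cos(pi/512)) ≈ 0.1` µm, far below scanner noise); test meshes
use 96–256 segments.

## Measuring the six indices

`measure_indices()` re-implements what a reverse-engineering operator does
interactively: segment the surface into its features, fit geometric
primitives, and read lengths and angles off the fits.

Segmentation classifies faces by the angle between their normal and the
model axis (within 15° of the axis: planar; within 15° of perpendicular:
wall; otherwise slanted), combined with height-band clustering along the
axis and an azimuthal test that separates the cylindrical walls from the
vertical ditch walls. The axis itself, when no hint is given, is detected
as the common line direction of the large parallel planar clusters (base
disk, shoulder annulus, ditch floor), which is unambiguous for this shape.
Because face normals of a noisy scan are far too jittery to threshold, the
*labels* are decided on a Laplacian-smoothed copy of the mesh; all fits use
the original coordinates. The number of smoothing iterations adapts to the
measured median dihedral jitter — zero for a clean tessellation (so sharp,
narrow features such as a thin shoulder annulus are not rounded away), up
to twelve for heavy noise.

The fits are: total-least-squares planes (base, shoulder); a surface of
revolution with linear radius profile for the base wall, which handles both
a straight cylinder and a drafted (conical) wall and whose axis becomes the
measurement axis, with `R2` evaluated at the base-plane height; a
Levenberg–Marquardt cylinder for the upper wall (`R1`); and a
Levenberg–Marquardt cone for the occlusal surface, minimising orthogonal
distances, with `theta = 90° - half-angle`. Every fit is wrapped in an
iterated trimmed refit (residuals beyond 4 robust SDs dropped, a few
rounds): on clean meshes the trimming floor of 1 nm leaves the exact
solution untouched, on noisy scans it sheds mislabelled boundary vertices.
Nearly flat occlusal data (initial inclination under 0.5°) falls back to a
plane fit with a degeneracy flag and `theta = 0`.

Heights are read where the fitted planes intersect the measurement axis:
`L2` between base and shoulder, and the occlusal rim at the height where
the fitted cone meets the fitted `R1` cylinder, giving `L1` and `L3`. All
six indices are functions of fitted primitives only, hence rigid-pose
invariant (verified to 1e-6 and, with a fixed segmentation route, to
1e-13). On clean meshes the whole chain recovers the design values to
~1e-10 mm, so the 0.005 mm / 0.05° acceptance tolerances are dominated by
headroom, not by tessellation.

## Simulating scans

A `scanner_profile()` abstracts a scan system as four error mechanisms
applied in order, each along the vertex normal where relevant:

1. **stitching drift** — a smooth random field, built from ten fixed
   low-order polynomial basis functions of the coordinates scaled by a
   correlation length, with Gaussian coefficients scaled to an RMS
   amplitude. This emulates the slowly accumulating registration error of
   image stitching without simulating optics frame by frame;
2. **depth noise** — i.i.d. Gaussian displacement of SD `noise_sigma`;
3. **pose** — a random rigid transform within stated bounds (handheld
   presentation);
4. **decimation** — random face deletion to a retained fraction, chosen
   over quadric simplification to keep the operation dependency-free and
   seed-stable.

Replicate `k` seeds the RNG with `base_seed + k`, so every scan is bitwise
reproducible in isolation and the caller's RNG state is never disturbed.
The published study gives no quantitative error magnitudes for any device,
only the resulting RMS order (tens of micrometres); the three default
profiles (`default_profiles()`: sigma 0.025/0.035/0.045 mm with drift
0.012/0.020/0.028 mm) were chosen once to land in that range — the
demonstration workflow obtains mean surface RMS of about 0.027, 0.038 and
0.053 mm — and are not tuned further.

What the simulator deliberately does not model: optical wavelength and
reflectance effects, powder, frame-level stitching, operator strategy, and
outlier artefacts (spikes, holes beyond random decimation). Passing tests
on this synthetic data therefore validate the *measurement and statistics
machinery*, not any claim about a physical scanner.

## Registration and surface RMS

`icp_register()` aligns a scan to the gold standard by iterative closest
point with exact point-to-triangle correspondences (a uniform spatial grid
over reference triangles, verified against brute-force all-triangle
minimisation to 1e-9). The default hybrid scheme runs closed-form SVD
(Kabsch) point-to-point updates first — whose correspondence RMS is
provably non-increasing — and, once the relative RMS improvement per
iteration falls to the few-percent plateau typical of the remaining
azimuthal error on this nearly axisymmetric body, switches to linearised
point-to-plane Gauss–Newton steps with the rotation step capped at ~11°
and a backtracking line search on the correspondence RMS. Pure
point-to-point converges only geometrically in the azimuthal direction
(percent-level per iteration); the hybrid polishes 30°/5 mm initial
misalignments of the noise-free model to below 1e-6 (radian, mm) in a few
dozen iterations. Non-convergence is reported in the return value, never
as an error.

`deviation_map()` then gives each test vertex a signed nearest-surface
distance (positive outside the reference, by the reference face normal),
and `rms_deviation()` the per-point RMS — the "3D fitting" score. The
study formula's replicate reading, with the replicate count as divisor, is
exposed separately as `replicate_rms()`; reports label which is which.
Whether RMS is taken over signed or absolute deviations is immaterial —
the square erases the sign.

## Statistics

For reference value `rR` and measurements `rA`:

* trueness `Δr = (rR − rA)/rR × 10³` (signed, dimensionless ×10³),
* precision `Δs = s(rA)/rR × 10³` with the sample (n−1) SD,

both scale-invariant. Trueness over replicates is reported as mean ± SD of
per-replicate values (the alternative — trueness of the replicate mean —
can be derived from the same table). Surface RMS is summarised as
mean ± SD with a Student-t confidence interval on the mean. Groups are
compared with the tie-corrected Kruskal–Wallis H against the chi-square
law, plus an exact full-permutation p value for pooled samples of ten or
fewer; the implementation is cross-checked in the tests against
`stats::kruskal.test` and against the enumerated permutation distribution.
Raw p values are reported with flags at both 0.05 and 0.01 (published
conventions differ between text and figure legends), and no
multiple-testing correction is applied, matching common practice in this
literature; the report says so in its footer.

## Numerical choices

* Units are mm throughout; angles are degrees at every interface and
  radians internally. Face indices are 1-based (R convention); STL carries
  no indices, so this is internal only.
* Weld tolerance 1e-6 mm, two shifted merge grids so no coincident pair is
  split by a grid boundary. Binary STL is little-endian with attribute
  byte count 0; both STL modes store float32, so round trips are exact to
  single precision only.
* Nonlinear fits use `minpack.lm::nls.lm` with `ftol = ptol = 1e-15`;
  radius-profile parameters are profiled out analytically each step.
* ICP defaults: `tol = 1e-8` relative, `max_iter = 200`,
  `trim_fraction = 0` (clean synthetic data), at most 5000 evenly chosen
  test vertices.
* Problem sizes: the gold standard at 512 segments (~52k vertices) for the
  design-recovery checks; 256 segments for the noise calibrations (30
  replicates per noise level); 96–128 segments in unit tests. The
  demonstration workflow in `analysis/` uses 10 replicates per system.

## Known limitations

* The geometry is a reasoned reconstruction of the published drawing; a
  differently dimensioned physical model would need only a changed
  constructor.
* Segmentation assumes the canonical feature set; it refuses (with a named
  error) rather than guesses when a required region is missing, e.g. on a
  sphere, but very heavy noise on a coarse mesh (sigma comparable to the
  edge length) can still defeat the occlusal fit.
* Registration is rigid only; scanner distortion that a non-rigid
  alignment would absorb shows up in the RMS instead, which is the
  intended metrological reading.
* With a handful of error sources, simulated precision is optimistic about
  real devices; between-system *orderings* (the quantity the statistics
  compare) are meaningful, absolute values are not.
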