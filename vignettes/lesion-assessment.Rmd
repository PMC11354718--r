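---
title: "Methods: field simulation, lesion quantification, and threshold calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: field simulation, lesion quantification, and threshold calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`pfalesion` models a standard bench assay for pulsed-field ablation (PFA):
needle electrodes deliver trains of high-voltage microsecond pulses to a
potato tuber (*Solanum tuberosum*) slice submerged in Tyrode buffer; the
irreversibly electroporated region stains dark, is photographed from the top
and in cross-section, and its geometry is compared against a simulated
electric-field map to estimate the lethal electric-field threshold (EFT) —
the minimum field magnitude, in V/cm, at which tissue is killed.

The package covers four stages, each usable on its own:

1. **Field simulation** — the stationary conduction problem on the bench
   geometry (`rasterize_materials()`, `solve_potential()`).
2. **Lesion imaging** — calibration, brightness-threshold segmentation, and
   2-D metrics from top and cut views (`calibrate()`, `segment_stained()`,
   `measure_area()`, `measure_length_width()`, `trace_cut_polygon()`,
   `measure_depth()`).
3. **Volumetry** — the similarity-scaled cross-section estimator
   (`width_ratio_profile()`, `similarity_volume()`).
4. **EFT calibration** — matching lesion geometry to field superlevel sets
   (`eft_by_area_match()`, `eft_by_boundary_quantile()`).

A synthetic-image generator (`make_parametric_lesion()`,
`make_field_lesion()`, `render_views()`) provides ground-truthed inputs for
every stage, so the full pipeline is testable with no laboratory data.

# The conduction model

During a pulse the bench behaves as a resistive conductor: displacement
currents are negligible at microsecond time scales, so the potential obeys
the stationary heterogeneous conduction equation

$$\nabla \cdot (\sigma \nabla \varphi) = 0,$$

with $\sigma$ piecewise constant over the regions of the scene. Relative
permittivities are parsed and stored for completeness but play no role in
the DC steady state. The default scene is:

| region      | material | conductivity | geometry |
|-------------|----------|--------------|----------|
| bath        | Tyrode buffer | 1.8 S/m | dish 96 mm diameter, 30 mm tall |
| slab        | tuber tissue  | 0.04 S/m | 40 x 40 x 20 mm, top face 4 mm below the bath surface |
| electrodes  | stainless needles | equipotential | 0.63 mm diameter, 1.37 mm inner gap, tips touching the slab top |

One electrode carries the applied voltage (100-300 V in the reference
protocol), the other is grounded. The outer boundary carries the insulation
condition (zero normal current), standing for the glass dish and the air
above the bath.

**Electrodes as equipotential surfaces.** Stainless steel is ~10^6 S/m —
dozens of orders above the bath — so the needles are modeled as Dirichlet
surfaces at fixed potential, the standard idealization for metal in a
resistive bath. A `volumetric` electrode mode (finite conductivity, voltage
fed at the wire end) is retained for sensitivity studies, since nominal
metal conductivities for coated needles are sometimes uncertain.

**Domain truncation.** The field decays rapidly away from the mm-scale
electrode pair: at 300 V the 240 V/cm contour spans roughly ±3 mm. The
default computational domain is therefore a box centred on the pair — 8 mm
lateral half-extent, the 4 mm bath layer, and 8 mm of slab depth — with the
insulation condition on the truncated faces; the influence of the remote
dish wall is negligible because the resistive tuber already confines the
current to the neighbourhood of the needles. A `slab` domain mode covering
the whole slab plus a configurable bath margin is available when the full
geometry matters (e.g. thin slices and transmurality questions).

## Discretization and solver

The equation is discretized by a seven-point finite-volume stencil on a
uniform cell-centered grid with **harmonic-mean face conductivities**, the
standard choice that keeps normal current continuous across the 45x
bath/tuber conductivity jump. The symmetric positive-definite system is
solved matrix-free by Jacobi-preconditioned conjugate gradients (compiled
code, memory linear in the cell count), to a relative residual of 1e-8 by
default. The default spacing of 0.1 mm resolves the 0.63 mm needles with
~6 cells across the diameter; grids that resolve the diameter with fewer
than 3 cells are rejected.

Numerical choices worth knowing about:

* **Electrode rasterization.** A cell becomes a Dirichlet cell when its
  center lies within the needle radius *plus half a cell*. The staircase
  boundary effectively passes through the outermost Dirichlet cell centers,
  so this half-cell inflation places the equipotential surface at the
  nominal radius; without it the effective radius is biased small by ~h/2,
  which the analytic two-wire oracle resolves clearly (a -4.5% midpoint
  field bias at 0.05 mm spacing, reduced to ~+1% with the rule).
* **Field magnitude.** |E| is obtained by central differences of the
  potential (second-order one-sided stencils at domain faces) and reported
  in V/cm; the potential stored in Dirichlet cells makes the difference
  well defined next to the needles, and |E| is set to zero inside them.
  Cells adjacent to the needles inherit the usual staircase smearing of the
  edge singularity; all lesion-scale quantities are measured millimetres
  away, where this is immaterial.
* **Validation.** The test suite checks the discrete maximum principle,
  electrode current balance (typically conserved to the solver residual),
  exact voltage linearity, second-order convergence on a smooth
  manufactured solution with variable conductivity, fixed-geometry grid
  convergence, and the closed-form two-wire (bi-cylindrical) field at the
  electrode midpoint within 2%.

Planes are extracted by linear interpolation between cell layers
(`slice_field()`); isolines use marching squares with linear interpolation
via `grDevices::contourLines()`, whose standard saddle-cell rule applies.
Superlevel areas (`superlevel_area()`) split each grid cell into four
triangles on which the superlevel area of the linear interpolant is exact
and closed-form — the result is continuous and strictly non-increasing in
the level, which the threshold search relies on.

# Lesion imaging

Photographs are calibrated by two reference points a known distance apart
(`calibrate()`), typically a scale bar; all downstream metrics are in mm.
Segmentation follows the staining logic directly: pixels whose Rec. 601
luma ($0.299R + 0.587G + 0.114B$) falls below a brightness threshold are
stained. The default threshold is 120 on the 8-bit scale for both views —
dye-stained lesions are dark against light tuber flesh, so the margin is
wide — and is overridable per image, since lighting conditions vary and no
universal constant exists. After thresholding, the largest connected
component is kept and its holes filled: stray dye specks and glare
reflections otherwise corrupt the pixel count.

Area is the stained pixel count times the pixel area — a pixel is a unit
square, with no sub-pixel boundary correction. Length and width are not
universally standardized for lesions; the package fixes them as the maximum
Feret (caliper) diameter of the solid pixel region and the maximum extent
perpendicular to that axis. Depth comes from the cut view: the lesion
boundary is polygonized (marching squares plus Ramer-Douglas-Peucker
simplification at 1 px tolerance), clipped to the tissue side of the *top
cut line* — the user-identified line where the cut plane meets the slice
surface — and depth is the maximum extent along the perpendicular bisector
of that line, oriented into the tissue. An interactive-style path accepting
user-picked vertices exists alongside the automatic one so that both manual
workflows and scripted tests are first-class.

# Volumetry by the similarity assumption

Only two orthogonal views exist per lesion, so the volume estimator rests
on one modeling premise: lesion cross-sections at depth $z$ are
geometrically similar, scaled copies of the surface lesion. When two shapes
are similar, corresponding lengths share one ratio $r$ and areas scale as
$r^2$; taking the ratio at depth $z$ between the cut-polygon chord parallel
to the top line and the top-line length,

$$A(z) = r(z)^2 \, A_{\mathrm{top}}, \qquad
  V = \int_0^d A(z)\, dz,$$

evaluated by the trapezoidal rule on a uniform depth grid (101 samples by
default; the estimate moves by <0.2% on doubling). The premise is motivated
by the field structure: equal-field contours at increasing depth are nearly
scaled copies of the surface contour when the electrode pair is small
relative to the lesion. `validate_similarity_assumption()` quantifies the
premise for any solved field by comparing normalized superlevel contours
across depths (Jaccard distance of the normalized shapes), so users can
check how far it holds for their geometry rather than take it on faith.

Details fixed by design:

* Chords are evaluated a hair inside $[0, d]$, so the surface chord (which
  lies exactly on the clip line) and the terminal chord of flat-bottomed
  shapes (a boundary-coincident edge) are both caught; a rectangle thus
  integrates to exactly $A_{\mathrm{top}} \times d$.
* For non-convex cross-sections the chord is the **total covered length**
  (sum of sub-chords across lobes); a single-interval alternative is
  available via `chord_mode = "single"` since the operational definition
  could be read either way.
* Ratios slightly above 1 arise from digitization noise at the surface row
  and are capped at 1.05 with a warning recorded; this preserves the
  squared-ratio proportionality while bounding noise inflation.

# Threshold calibration

The lesion edge marks the weakest field that still killed tissue, which
licenses two estimators:

* **Area matching** (primary): find the level $E^*$ whose superlevel area
  on the comparison plane equals the measured lesion area. Monotonicity
  makes this a bisection on $[1\ \mathrm{V/cm}, \max|E|]$, run to a relative
  area mismatch of 0.5% or 60 iterations; lesions larger than any
  attainable superlevel area return a flagged boundary-of-range result
  rather than a silent number.
* **Boundary quantile** (cross-check): sample |E| at the registered lesion
  boundary vertices by bilinear interpolation and report a quantile —
  the median by default, quantile 0 for the literal minimum-edge-field
  reading — with the IQR as a registration-quality diagnostic.

The default comparison plane is the slab top surface, matching top-view
lesions; cut-view comparisons use the mid-electrode vertical plane.
Registration from image to scene coordinates is rigid (rotation +
translation + the calibration scale), anchored on the two electrode marks
visible in the top view: their midpoint maps to the scene origin and their
axis to the electrode axis. On noiseless synthetic lesions the two
estimators agree to a few percent; both are always reported.

# The synthetic generator

`render_views()` emulates the features of stained-slice photographs that
the measurement pipeline actually consumes: a dark lesion (default luma 40)
on a light tuber background (220), a linear illumination gradient (±10
luma), Gaussian sensor noise (sigma 8 by default), a 10 mm scale bar, and
electrode marks — at a default pitch of 0.05 mm/px, the scale of a close-up
slice photograph. Lesion shapes come either from parametric solids
(half-ellipsoids and two-lobed "peanuts", matching the semi-elliptical to
oblong shapes seen on treated slices) with closed-form or voxel-counted
truth, or from the solved field itself as the 3-D superlevel set at a given
threshold, with truth by voxel counting at the solver resolution. Truth
values are always computed independently of the estimators under test, and
a JSON sidecar carries them alongside the render transform; the RNG seed
fixes output bytes exactly, and changing it changes only the noise.

What the generator deliberately does **not** emulate: tuber texture,
oxidation drift of unstained tissue, specular glare, slice buckling, or
uneven staining. Passing tests therefore demonstrate correctness of the
measurement chain under the stated image model — not robustness to every
artifact of real photographs, where the configurable thresholds and the
interactive tracing path are the intended recourse.

# Problem sizes and runtime

The reference end-to-end computation — the 300 V solve at 0.1 mm spacing
(161 x 161 x 120 ≈ 3.1M cells), superlevel lesion construction at
240 V/cm, rendering, segmentation, and area-matched threshold recovery —
runs in about half a minute on one CPU core. The test suite uses 0.2 mm
grids on tighter domains for most solver checks and reserves the 0.1 mm
scene for the single end-to-end recovery test; the analytic two-wire oracle
runs as a single-layer (planar) solve at 0.05 mm.

# Known limitations

* No time-domain pulse waveform simulation and no electro-thermal coupling:
  the pulse train is metadata, and thresholds are tied to the recipe they
  were measured under (the reference protocol is 100 biphasic 10 µs pulses
  at 10 Hz). No field-dependent tissue conductivity during pulsing.
* The similarity volume is exact only for truly self-similar lesions; for
  shapes whose cross-sections change form with depth it is an estimate, and
  `validate_similarity_assumption()` should be consulted.
* Segmentation is brightness-only by design (matching the staining
  protocol); hue-based classification is out of scope.
* Statistical comparison across conditions is limited to per-condition
  mean ± SEM tables; inferential testing is left to general-purpose tools.
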