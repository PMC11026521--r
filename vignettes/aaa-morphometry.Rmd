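---
title: "Centerline-guided AAA morphometry: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centerline-guided AAA morphometry: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaamorph)
```

## The measurement model

Pre-operative sizing of an endovascular stent-graft for an abdominal aortic
aneurysm (AAA) rests on a small set of anatomical quantities: the diameter
and length of the aortic neck (the segment between the lowest renal artery
and the start of the aneurysm), the maximum diameter of the aneurysm, the
diameters and tortuosity of the common iliac arteries, and the angulation
between neck and aneurysm. `aaamorph` measures all seven directly on a
triangulated 3D surface model of the aorta-plus-thrombus, the kind of mesh
exported from a semantic segmentation of CT angiography.

The inputs are the five objects a vascular analyst prepares once per case:
the surface model, four centerline polylines (neck, aneurysm, right and
left common iliac), and two *iliac start planes* that separate each iliac
artery from the aortic trunk. Centerlines and planes arrive in a small JSON
schema (`read_centerlines()`); meshes as STL or PLY (`read_surface()`). All
coordinates are world millimetres.

### Cross-sectional diameters

The diameter machinery is a single loop (`max_diameter_along_centerline()`):

1. resample the centerline at a fixed arc-length step (default 1 mm);
2. at each resampled point ("station"), form the cutting plane whose origin
   is the point and whose normal is the forward-difference direction to the
   next point (the last station reuses its predecessor's direction);
3. intersect the plane with the mesh: each crossing triangle contributes a
   segment, segments are chained by shared endpoints into contours;
4. keep the longest contour of the section and measure its maximum
   point-pair chord;
5. report the station with the largest chord.

The neck diameter uses one station only — the point at half the neck's arc
length — reflecting its clinical definition as the *mid-neck* diameter.
Iliac diameters first cut the model at the corresponding start plane
(keeping the half-space the stored normal points into) so that sections
along the iliac centerline cannot pick up the trunk or the contralateral
branch.

Because cutting planes are unbounded, a section can in principle slice
geometry far away from the vessel the station belongs to. A contour whose
nearest point is farther from the station than the contour's own length
cannot enclose that station and is discarded before the longest-contour
selection. This guard is what turns a displaced centerline into an explicit
measurement failure rather than a silent measurement of the wrong vessel.

### Lengths, tortuosity, angulation

Neck length is the **arc length** of the neck centerline. The straight
start-to-end distance would be an alternative reading of "distance between
the renal artery and the aneurysm start"; arc length generalizes correctly
to angulated necks and coincides with the straight distance for straight
ones, which is why we chose it. Iliac tortuosity is the classical ratio
`arc/chord`, reported together with both lengths; it is mathematically
`>= 1`, and the package enforces that (a ratio below 1, as occasionally
seen in manually read tables, can only arise from measurement
inconsistency, not geometry). Angulation is the angle between the two
endpoint chords of the neck and aneurysm centerlines — chords, not fitted
lines, because the clinical definition refers to the lines through the
centerlines' start and end points. The arccosine of the normalized dot
product is clamped to [-1, 1] so collinear chords are exactly 0 or 180.

### Numerical conventions in the geometric kernel

* Intersection points are linear interpolations along triangle edges at the
  signed-distance zero crossing, computed on the canonically ordered edge so
  the two triangles sharing an edge produce bitwise-identical points.
* A vertex within 1e-9 mm of the plane counts as on the positive side; this
  removes the degenerate double-counting of contours that pass exactly
  through vertices.
* Segment endpoints are chained with tolerance 1e-6 mm (`tol_chain`);
  endpoints coming from a shared mesh edge are bitwise-near identical, so
  this tolerance is generous yet unambiguous at anatomical scales.
* Chains whose free ends meet are closed contours (stored without repeating
  the first point); open chains — which arise on meshes clipped by the iliac
  planes — are retained and compete for "longest contour" by their open
  length.
* `longest_contour()` breaks ties by lowest index, making the pipeline
  fully deterministic; there is no randomness anywhere in measurement.
* The maximum chord is computed over all point pairs in 3D (the points are
  coplanar, so this equals the in-plane diameter), by exhaustive pairwise
  distances — exact by construction, and cheap at contour sizes produced by
  clinical meshes.
* Mesh clipping (`cut_surface_by_plane()`) clips crossing triangles at the
  plane with the same canonical interpolation, leaves the cut rim open
  (no capping), and errors when nothing remains on the requested side.

### Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `resample_step` | 1.0 | mm | station spacing; sub-voxel relative to the 2.5–5.0 mm slice thickness of typical CT angiography, so denser sampling does not change results appreciably |
| `tol_chain` | 1e-6 | mm | segment-endpoint matching; far below mesh edge lengths, far above float noise |
| `tol_chord` | 1e-6 | mm | minimum chord for tortuosity/angulation; below this a centerline is degenerate (closed loop) |

## The phantom generator

Clinical meshes cannot ship with a package, so the tests and the acceptance
script run on parametric phantoms (`make_fusiform_phantom()`) whose seven
landmark values follow from the construction in closed form:

* **Trunk** — a swept tube whose radius profile is the neck radius along the
  neck, then a cosine-bell bulge `r(s) = r_n + (r_max - r_n) sin^2(pi s/L)`
  over the aneurysm segment. The profile is C^1 at the junction and at the
  apex, so there are no sectioning artifacts, and the apex radius is exactly
  `r_max`.
* **Neck bend** — a circular arc with total turning angle `2*beta` that
  joins the aneurysm axis tangentially. The arc's chord then makes exactly
  `beta` with the aneurysm chord, so the ledger angulation equals the
  `neck_bend_deg` parameter with no approximation.
* **Iliac branches** — constant-radius tubes along circular arcs of the
  requested arc angle `theta`, at fixed branch length `L` (the arc radius is
  `L/theta`), tilted 45 degrees off the trunk axis. The tortuosity ledger is
  `(theta/2)/sin(theta/2)`, independent of the arc radius; a zero-angle
  branch is straight with ratio exactly 1.
* **Start planes** — placed 20 mm along each branch centerline with the
  branch's initial tangent as normal. At a 45 degree tilt each branch starts
  perpendicular to the other side's plane normal, so the trunk and the
  contralateral branch lie strictly on the negative side; the generator
  verifies this separation and refuses to emit a phantom that violates it.
* **Rings** — tube cross-section rings are parallel-transported along the
  centerline (no twist), which keeps bent tubes round; with an even number
  of circumferential vertices, antipodal ring vertices exist and the
  section's maximum chord equals the tube diameter essentially exactly.

Default dimensions (neck diameter 24 mm, aneurysm 55 mm, neck length 33 mm,
iliac diameters 18/16 mm) sit at typical clinical cohort scales so phantom
measurements land in a realistic range — but ground truth is always the
analytic ledger computed from the spec, never any cohort value. The
batch-testing generator (`random_phantom_specs()`) draws neck radii
10–14 mm, neck lengths 25–45 mm, bends 0–30 degrees, aneurysm radii
20–30 mm, iliac radii 6–9.5 mm and arcs 0–90 degrees, at 64 circumferential
segments and 1.5 mm ring spacing; at that tessellation the worst landmark
recovery error across phantoms is below a tenth of the acceptance
tolerances, while a 20-phantom batch measures in well under a minute on one
CPU.

What the phantoms deliberately do **not** emulate: segmentation noise,
thrombus/calcification surface texture, non-circular (elliptical or
dissected) lumina, branch ostia, and mesh defects such as holes or
self-intersections. Passing the phantom suite therefore demonstrates the
geometric correctness of the pipeline, not robustness to segmentation
artifacts; on clinical meshes the centerline and plane inputs remain the
analyst's responsibility.

## Evaluation statistics

The metrics module mirrors how such pipelines are evaluated:

* **Dice** on label volumes, with the explicit conventions that a label
  absent from both volumes scores 1.0 (with a warning, to prevent silent
  inflation in batch summaries) and absent from exactly one scores 0.0.
* **HD95** — each directed distance is the 95th percentile (linear
  interpolation between order statistics, `stats::quantile` type 7) of
  distances from boundary voxels of one mask to the nearest boundary voxel
  of the other, in physical mm; the symmetric value is the maximum of the
  two directions. Boundary voxels are defined by 6-connectivity face
  adjacency, with the volume border counting as outside. Directionality,
  percentile interpolation, and connectivity are all conventions the
  literature leaves open; these choices are pinned here for
  reproducibility and validated against a brute-force all-pairs oracle.
* **Bland–Altman** — bias, sample SD (n-1), limits of agreement
  `bias ± 1.96 SD`; optional single-pass outlier removal outside the
  initial limits, with both passes reported.
* **ICC(2,1)** — two-way random-effects, absolute-agreement, single-rater
  intraclass correlation from the two-way ANOVA mean squares. This is the
  matching design for several observers rating the same cases when
  absolute agreement (not mere consistency) is the question; the
  constant-offset observer table shows the difference, since consistency
  would be 1.0 while ICC(2,1) is 5/6. A zero-variance table is defined as
  1.0 with a warning. Pairwise Pearson correlations are available alongside.

## Worked example

```{r example}
ph <- make_fusiform_phantom(phantom_spec())
rep <- measure_all(ph$surface, ph$centerlines)
print(rep)
unlist(ph$ledger[c("neck_diameter_mm", "aneurysm_diameter_mm", "neck_length_mm")])
```

## Known limitations

* Centerlines are inputs, not outputs: the package does not extract luminal
  centerlines from the mesh or from images. Anatomical divisions (where the
  neck ends, where the aneurysm starts) are encoded in the supplied
  centerlines.
* The longest-contour rule assumes the vessel of interest produces the
  dominant contour in its own (plane-separated) territory; grossly wrong
  start planes degrade to explicit per-landmark errors, not to silent
  misreadings, but subtly misplaced planes remain the analyst's risk.
* Meshes are used as-is: no repair, smoothing, decimation, or
  watertightness enforcement. Open meshes are supported (open section
  chains compete by open length), but a mesh with large holes near a
  measurement site will bias the chord downward.
* Binary STL stores 32-bit floats; geometry round trips through ASCII STL
  or PLY are exact to 1e-6 mm, binary STL to float precision (~1e-5 mm at
  100 mm coordinates).
* Angulation is reported as the raw chord angle in [0, 180] degrees;
  clinical thresholding (for example at 60 degrees) is intentionally left
  to the caller.
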