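# aaamorph

Automated morphometry of abdominal aortic aneurysm (AAA) surface models in R.

## The problem

Endovascular aneurysm repair (EVAR) is planned from pre-operative anatomy:
the stent-graft is selected from a handful of measurements of the aorta and
iliac arteries. Measuring these by hand on 2D CT slices is slow and poorly
reproducible — the clinically tolerated error for aortic diameter is only
±5 mm, and reading the true maximum diameter off axial/sagittal/coronal
slices of an oblique, curved vessel is error-prone. When a segmented 3D
surface model of the aorta (plus thrombus) is available, the measurements
can instead be taken directly in 3D by cutting the model with planes
generated along the vessel centerlines.

`aaamorph` implements that pipeline for the seven landmarks used in
stent-graft sizing:

1. **Aortic neck diameter** — maximum chord of the cross-section at the
   midpoint (by arc length) of the neck centerline.
2. **Aneurysm diameter** — the maximum over all neck-to-bifurcation
   stations of the cross-sectional maximum chord.
3. / 4. **Right / left iliac artery diameter** — as (2), after the model is
   cut at the iliac start plane so only the branch territory remains.
5. **Aortic neck length** — arc length of the neck centerline.
6. **Iliac tortuosity** — `T = L_curve / L_line`, centerline arc length
   over the straight start-to-end distance (`T >= 1`, `T = 1` iff straight).
7. **Neck angulation** — angle between the start-to-end chords of the neck
   and aneurysm centerlines.

The sectioning core is: for each station *s* along a resampled centerline,
build the plane through the station point with the forward-difference
direction as normal, intersect it with the triangle mesh, chain the
resulting edge segments into contours, keep the longest contour, and
measure its maximum point-pair chord `D(s) = max_{p,q} |p - q|`. The
reported diameter is `max_s D(s)`.

The package also provides the standard evaluation statistics for such a
pipeline: Dice similarity coefficient and 95th-percentile Hausdorff
distance (HD95) between label volumes, Bland–Altman limits of agreement
(`bias ± 1.96·SD` of paired differences), ICC(2,1) intraclass correlation,
and pairwise observer correlations — plus parametric vascular phantoms
(swept tubes, fusiform bulge, arced iliac branches) whose seven landmark
values are known in closed form, so every stage is testable against
analytic ground truth.

## Worked example

```r
library(aaamorph)

ph  <- make_fusiform_phantom(phantom_spec())   # defaults: neck r 12 mm, bulge r 27.5 mm
rep <- measure_all(ph$surface, ph$centerlines)
print(rep)
#> <aaa_report> seven-landmark AAA measurement
#>   neck diameter                24.003 mm
#>   aneurysm diameter            55.000 mm
#>   right iliac diameter         18.000 mm
#>   left iliac diameter          16.001 mm
#>   neck length                  32.999 mm
#>   right tortuosity ratio        1.000
#>   left tortuosity ratio         1.111
#>   neck angulation              30.000 deg
```

Each value is a physical quantity in mm / degrees; the phantom's analytic
ground truth is `ph$ledger` (neck 24, aneurysm 55, iliacs 18/16, length 33,
ratios 1 and 1.1107, angle 30°), so every landmark above is recovered to a
small fraction of a percent. `rep$stations` records where along the vessel
each diameter maximum was found; `report_to_json()` and
`report_to_csv_row()` serialize the report.

The same pipeline runs from a shell on STL/PLY + centerline-JSON inputs:

```sh
Rscript inst/cli/aaamorph.R phantom --out case1 --seed 42
Rscript inst/cli/aaamorph.R measure --surface case1/model.stl \
    --centerlines case1/centerlines.json --out case1/report.json
```

(`seg-eval` and `agree` subcommands expose the Dice/HD95 and
Bland–Altman/ICC tools; exit codes are 0 = success, 1 = input error,
2 = partial per-landmark failure.)

## Documentation

See the methods vignette (`vignettes/aaa-morphometry.Rmd`) for the
measurement model, parameter choices, phantom construction, and known
limitations.
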