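Package: aaamorph
Title: Automated Morphometry of Abdominal Aortic Aneurysm Surface Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Centerline-guided cross-sectional measurement of triangulated
    aortic surface models for endovascular aneurysm repair planning. Computes
    the seven clinical landmarks used for stent-graft sizing (aortic neck
    diameter and length, aneurysm maximum diameter, right and left iliac
    diameters, iliac tortuosity, neck angulation) by sectioning the mesh with
    planes generated along vessel centerlines and measuring the longest
    cross-sectional contour. Also provides segmentation agreement metrics
    (Dice similarity coefficient, 95th-percentile Hausdorff distance on label
    volumes), method-comparison statistics (Bland-Altman limits of agreement,
    intraclass correlation), parametric vascular phantoms with analytic
    ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    RNifti,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
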