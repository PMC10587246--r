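Package: retquant
Title: Quantitative Diabetic Retinopathy Lesion Analysis in the ETDRS Seven
    Standard Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for planimetric analysis of diabetic retinopathy (DR)
    lesion annotations on ultra-widefield fundus images. Builds the ETDRS
    seven-standard-field layout from optic-disc and fovea landmarks,
    measures lesion surface area on a spherical eye model via
    stereographic projection with local area correction, splits each
    lesion's count fractionally across fields by area overlap, grades eyes
    on the ICDR (0-4) and DRCR Protocol AA scales with explicit rule
    engines, and compares lesion metrics across severity levels with
    Kruskal-Wallis, Dunn-Bonferroni and Cohen's kappa statistics. Includes
    a calibrated synthetic cohort generator so the full pipeline is
    testable without access to clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
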