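---
title: "Quantifying diabetic retinopathy lesions in the ETDRS seven standard fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying diabetic retinopathy lesions in the ETDRS seven standard fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical diabetic retinopathy (DR) severity scales — the five-level ICDR
scale and the seventeen-level DRCR Protocol AA scale — are qualitative:
a grader compares an eye against reference standards and assigns a
category. Manual lesion segmentation on ultra-widefield (UWF) fundus
images makes a complementary quantitative description possible: for each
eye, the exact number and surface area of every hemorrhage,
microaneurysm, exudate, and so on, restricted to the region covered by
the ETDRS seven standard fields (7SF). `retquant` implements that
quantitative pipeline end to end:

1. geometry — place the seven 30°-diameter fields from the optic-disc
   and fovea landmarks, and measure lesion areas in mm² on a spherical
   eye model;
2. quantification — split each lesion's count fractionally across
   fields in proportion to the area falling in each, so field totals may
   be non-integer;
3. grading — explicit, testable rule engines for ICDR 0–4 and
   Protocol AA 10–90;
4. statistics — Kruskal–Wallis H with tie correction, Dunn's pairwise
   procedure with Bonferroni correction, Cohen's kappa, and cohort-share
   arithmetic;
5. simulation — a calibrated synthetic cohort generator, since the
   clinical images behind such studies are not public.

```{r setup}
library(retquant)
```

## Coordinates and the spherical eye model

Lesion annotations live in eye-centered angular coordinates: longitude
(temporal-positive along the disc–fovea axis) and latitude
(superior-positive), in degrees of visual angle, with the fovea at the
origin. The chart is azimuthal-equidistant, so a point's angular
eccentricity from the fovea is simply the Euclidean norm of its
coordinates.

Areas are measured on a sphere. The package's primary scale constant is
`rq_mm_per_degree()` (default 0.291 mm per degree, the conventional
schematic-eye value), and the radius of the spherical model is derived
from it as `R = mm_per_degree * 180 / pi` (about 16.68 mm). Deriving one
from the other keeps the two uses of scale — converting small angular
extents to mm and integrating areas over the sphere — exactly
consistent; with an independently chosen radius, a 1°-diameter disc at
the posterior pole would get two different areas depending on the code
path. Both constants are configurable; all reported areas scale with
`mm_per_degree` squared.

Lesion polygons are projected stereographically (a conformal map; the
package projects from the anterior point onto the plane tangent at the
posterior pole) and their spherical area is the integral of the local
area-correction factor $(1 + \rho^2/4R^2)^{-2}$ over the planar polygon,
evaluated by mid-point quadrature on a subdivided triangle fan. Edges
are interpreted as straight segments in the projection plane; for
lesions a fraction of a degree across the distinction from geodesic
edges is far below every tolerance used here.

```{r}
R <- rq_eye_radius()
cap <- cbind(10 * cos(seq(0, 2 * pi, length.out = 257)[-257]),
             10 * sin(seq(0, 2 * pi, length.out = 257)[-257]))
c(projected = polygon_area_mm2(cap, R),
  closed_form = 2 * pi * R^2 * (1 - cos(10 * pi / 180)))
```

## The seven-field layout and fractional overlap

`build_field_layout()` places the seven fields from the two landmarks:
field 1 on the disc, field 2 on the fovea, field 3 temporal to the
fovea with its nasal edge at the fovea, and fields 4–7 in the quadrants
around the disc, tangent to the axis lines through the disc center. The
placement table (`etdrs_tangency_table()`) is configuration, not code,
and left-eye layouts are automatically the mirror image of right-eye
layouts because the temporal axis is derived from the landmarks.

The seven circles overlap. For counting, each point of their union is
assigned to exactly one field — the nearest field center, ties broken
toward the lower field index — so per-field lesion areas always
partition the lesion's in-union area. Whether the vendor tooling used in
clinical studies partitions its mask this way is not documented
anywhere we could verify; nearest-center assignment is this package's
declared convention. A lesion's *frequency* contribution to a field is
its area fraction there, the only definition that both produces
non-integer field totals and sums back to the raw lesion count — the
conservation property tested throughout the suite.

With no polygon-clipping library in the dependency set, overlap
fractions are computed by deterministic midpoint quadrature on the
stereographic plane (with the spherical area weight), at a default
resolution of 96 × 96 cells over the lesion's bounding box. The test
suite checks this route against an independent random Monte-Carlo
point-assignment oracle to 0.01 absolute; lesions wholly inside one
assignment region (the vast majority) bypass quadrature via a
conservative bounding-cap test and contribute exactly 1.

## Grading engines

The ICDR engine applies, in order: proliferative lesions
(neovascularization of the disc or elsewhere, preretinal/vitreous
hemorrhage, or fibrous proliferation) give level 4; a fired 4-2-1
criterion gives level 3 (more than `h_quadrant_threshold = 20`
hemorrhages in every fovea-centered quadrant, venous beading in at
least two quadrants, or a prominent IRMA — area at least
`irma_prominence_mm2 = 0.05` mm²); microaneurysms only give level 1 (a
questionable-DR flag also maps to 1, mirroring how such eyes are binned
clinically); any other DR lesion gives level 2; otherwise 0. Quadrant
hemorrhage counts are fractional in-union masses rounded half-up.
Fibrous proliferation without active neovascularization is counted as
(inactive) proliferative disease so that the two scales can never
disagree about the PDR boundary.

The Protocol AA engine is a simplified, fully documented tier table:
10/12/14/20 for absent, non-DR, questionable, and microaneurysms-only;
35/43/47 keyed to the number of fields 2–7 involved at the extent
threshold; 53 versus 53E by whether one or at least two 4-2-1 criteria
are met; and 60/61/65/71-75 for proliferative disease (inactive, mild,
moderate by NVE area, and high-risk when NVD is present or NVE/
preretinal hemorrhage co-occur). Human grading against the ETDRS
standard photographs cannot be reproduced from published tables alone —
these thresholds are explicit conventions with configurable defaults,
and the rule trace of every graded eye records which rules fired.

## The synthetic cohort generator

The generator emulates the published per-severity lesion distributions
of a large multicenter UWF cohort (`severity_profiles()`): per (ICDR
level, lesion type), a mean and SD of the within-7SF lesion count and a
per-lesion mean area. Counts are negative-binomial — the published SDs
exceed the means, so an overdispersed count law is forced — except that
cells at or below Poisson dispersion (one venous-loop cell) fall back
to Poisson. Per-lesion areas are log-normal with unit coefficient of
variation (the published tables give only total-area dispersions, which
confound count variation, so the per-lesion CV is a modeling default).
Placement density decays exponentially with angular distance from the
fovea (`spatial_concentration`, default 0.05 per degree — a gentle
central weighting consistent with microaneurysms being more numerous
centrally; no published within-eye spatial statistics exist to
calibrate it further), and a configurable fraction of extra lesions
lands outside the 7SF union, where the quantification correctly ignores
them.

Two requirements pull against each other: cohort means must recover the
configured profile means, and every designed eye must be recoverable by
the grading engine. At the published parameters these conflict for
naive post-hoc repair — e.g. the severe-NPDR hemorrhage mean (78.67) is
below the 84 lesions needed to exceed 20 in all four quadrants, and
venous beading/IRMA means at severe are far below 1, so "add lesions
until the rule fires" would inflate exactly the grade-defining cells
by many standard errors. The generator instead assigns each designed
severe or PDR eye one guaranteed rule route up front (severe:
hemorrhage count, beading zone spanning two quadrants, or prominent
IRMA, with probabilities 0.25/0.25/0.5; PDR: NVE/NVD/preretinal
hemorrhage at 0.5/0.25/0.25) and pre-compensates the count sampler's
mean by a deterministic fixed-point solve at configuration time, so the
post-guarantee expectation equals the configured mean exactly. The cost
is that the *SDs* of grade-defining cells deviate from the configured
SDs; means, which the calibration checks target, do not. Level-2 eyes
are symmetrically protected from accidentally firing 4-2-1 (hemorrhages
are capped at 80 and placed under per-quadrant quotas of at most 20).

What passing tests show — and what they do not: the synthetic cohort
reproduces configured count/area means, guarantees designed-grade
recovery, and exercises every geometric code path, but its lesions are
smooth ellipses with independent counts across types, no montage
artifacts, no segmentation noise, and a designed truth that real images
do not have. Results on it validate the pipeline's arithmetic, not the
clinical behavior of any grader.

## Statistics

`kruskal_wallis()` computes H on mid-ranks with the standard tie
correction (delegating to the base distribution machinery) and the
chi-square p value with k − 1 degrees of freedom, matching standard
statistical software; the tests verify the statistic against an
exhaustive rank-formula oracle at n = 6 and the test's type-I error by
simulation. `dunn_bonferroni()` implements Dunn's z from mean-rank
differences with tie-corrected variance, multiplying each raw p by
k(k−1)/2 within a lesion-metric family (no cross-metric correction —
comparisons are presented per family). `cohen_kappa()` is the
unweighted kappa; `cohort_shares()` rounds half-up to one decimal
because that is how the printed percentages behave (6.25% prints as
6.3%, which banker's rounding would miss).

## Numerical choices and degenerate inputs

* Quadrature resolutions: 96 per axis for single-lesion overlap
  (cohort-scale runs may use 48; conservation is exact by construction
  at any resolution because per-field areas are fractions of the exact
  polygon area), 400 per axis for the union-area integral.
* Ties in field assignment go to the lower field index; points exactly
  on a quadrant axis count as nasal/inferior.
* Self-intersecting or degenerate polygons: `polygon_area_mm2()`
  returns 0 for a fully collapsed polygon and errors on bow-ties;
  `quantify_eye()` drops invalid lesions with a warning by default
  (`on_invalid = "error"` to fail fast) so one bad polygon does not
  void an eye.
* Eyes flagged poor-quality / RVO / interfering are never ICDR-graded;
  the Protocol AA engine returns 90/81/85 respectively, and
  `apply_exclusions()` reconciles flags with ungradable AA levels.
* Empty severity groups yield absent summary rows, not zeros.

## Problem sizes in the shipped checks

The test suite and acceptance script run, by choice, at sizes that keep
the full pipeline exercised while staying desk-scale: 200–500 eyes per
severity level for calibration and recovery suites (1000–2500 eyes),
50 random polygons against a 10⁵-point Monte-Carlo assignment oracle,
2000 null replicates for the type-I error of the Kruskal–Wallis test,
and 250 eyes per level in the acceptance script's cohort.

## Known limitations

* The grading engines encode simplified public rule tables, not the
  ETDRS standard-photograph comparisons used by human graders; engine
  output on real annotations should be treated as a reproducible
  approximation.
* The frequency definition (area-fraction split) is a convention;
  other splits (e.g. centroid assignment) would also sum to the raw
  count but distribute it differently across fields.
* The generator draws lesion types independently within an eye;
  real lesion types co-occur.
* Peripheral-versus-central lesion classification (outside the 7SF) is
  out of scope: lesions beyond the union are detected and reported as
  outside mass only.
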