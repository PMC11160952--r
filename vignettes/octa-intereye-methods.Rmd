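---
title: "Methods: quantifying intereye microvascular asymmetry on OCTA en-face images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying intereye microvascular asymmetry on OCTA en-face images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octasym)
```

## The problem

Optical coherence tomography angiography (OCTA) produces en-face maps of
perfused retinal vessels. In diabetic retinopathy (DR) the capillary bed
deteriorates, which shows up as lower vessel density (VD), lower fractal
dimension (FD, a global measure of branching complexity), a larger and more
irregular foveal avascular zone (FAZ). Because diabetes is systemic but the
two eyes can be affected unequally, the *difference between fellow eyes* is
itself a quantity of interest. `octasym` implements the measurement stack —
binarization, ETDRS-grid vessel density, box-counting FD, FAZ geometry —
and the paired-eye statistics on top of it, together with synthetic data
generators so the whole pipeline can be validated without clinical images.

## Vessel segmentation

A pixel is classified as vessel when its intensity strictly exceeds a
global threshold

$$T = \mathrm{mean} + k \cdot \mathrm{sd},$$

with the mean and standard deviation taken over all pixels of the image.
Two coefficients are used: $k = 0.5$ segments *all* vessels, and $k = 1.3$
keeps only the brightest, large arcade vessels ("big vessels"). Three
conventions are fixed so results are bit-reproducible:

* `sd` is the **population** standard deviation (divide by $N$);
* classification uses the **strict** inequality, so a constant image has
  zero vessel pixels;
* the statistics are computed over the whole image with no windowing or
  preprocessing.

To assess the microcirculation, big vessels are excluded in the
superficial plexus (SCP): the capillary map is
`all_vessels AND NOT big_vessels`, and big-vessel pixels are removed from
the measured area as well (numerator *and* denominator). Removing them only
from the numerator would depress VD in vessel-rich sectors, contradicting
the point of the exclusion. The big-vessel mask can be dilated by an exact
Euclidean disc (`dilation_radius`, default 0 px) to widen the exclusion
region. In the deep plexus (DCP) no exclusion is applied by default;
setting `dcp_exclude_projection = TRUE` applies the SCP big-vessel mask to
the DCP as an approximation of projection artifacts, which in clinical
reading is a manual step with no published algorithmic definition.

## ETDRS grid and vessel density

The grid is centered on the FAZ center (an annotation, or the centroid of
the FAZ trace) and uses the standard ETDRS diameters: central subfield
1 mm, inner ring (IR) 1–3 mm, outer ring (OR) 3–6 mm. Pixels are assigned
by the Euclidean distance of their centers, in mm, with half-open bins
$[0, 0.5)$, $[0.5, 1.5)$, $[1.5, 3.0]$; coordinates are 0-based with
x = column. The sectors are pairwise disjoint and their union is the 6-mm
disc by construction. The "total" area is the full 6-mm disc (including
the central subfield), not the 6×6 mm square. VD per sector is the vessel
pixel count divided by the measured (non-excluded) pixel count, stored as
a fraction (e.g. 0.218) and rendered as a percentage only in reports.

## Box-counting fractal dimension

The image is covered with boxes of side $s$ anchored at the top-left
corner; $N(s)$ counts boxes containing at least one foreground pixel. FD is
the negative slope of the ordinary least-squares fit of $\log N(s)$ on
$\log s$ over a dyadic ladder $s \in \{2, 4, 8, \dots, \lfloor\text{size}/4\rfloor\}$,
using all ladder points (no automatic linear-range selection). Grid-offset
averaging over four anchor offsets is available behind
`offset_average = TRUE` but off by default — single top-left anchoring is
the simplest reproducible convention. FD is computed on the
big-vessel-excluded capillary map over the full image; a `restrict` mask
limits it to the 6-mm disc when desired. Absolute FD values are
convention-dependent (ladder, anchoring, analysis region), so
cross-software comparisons should use the same convention; the package's
oracle suite pins the convention to closed-form cases (Sierpinski carpet
$\log 8/\log 3$, filled square 2, line 1).

## FAZ geometry

The canonical FAZ representation is the traced boundary polygon
(mirroring manual tracing), with vertices at pixel centers and no
smoothing. Area is the shoelace formula times pitch², perimeter the sum of
edge lengths (closing edge included) times pitch, and circularity

$$\mathrm{FAZC} = \frac{4\pi \cdot \mathrm{FAZA}}{\mathrm{FAZP}^2} \in (0, 1],$$

equal to 1 for a circle by the isoperimetric inequality. A mask input path
converts a binary FAZ mask to a polygon by marching squares at level 0.5
and then applies the same computation. Note a known quantization bias of
that path: the stairstep contour of a pixelated disc inflates the
perimeter by a few percent, so its circularity is ≈ 0.9 rather than 1.
Manual traces are not affected. Self-intersecting polygons and traces with
fewer than 3 vertices are rejected.

## Intereye asymmetry

For each patient and metric with both eyes present,

$$\delta_{abs} = |R - L|, \qquad
\mathrm{AI} = \frac{|R - L|}{(R + L)/2} \times 100,$$

the asymmetry index being scale-invariant, symmetric in the eyes, and
bounded by 200 for non-negative values. Patients lacking a fellow eye are
dropped and logged, not imputed. Pairing requires the same metric, plexus
and sector; conflicting stage labels between a patient's eyes are a
validation error.

## Cohort statistics

Stage comparisons of AI and $\delta_{abs}$ use Kruskal-Wallis tests on the
per-patient pair table; IR-vs-OR comparisons use Wilcoxon signed-rank
tests (zero differences dropped; exact p for $n \le 25$ without ties,
normal approximation with continuity correction otherwise). A fully tied
Kruskal-Wallis input reports $p = 1$ by convention — no rank variation, no
evidence against the null, and it avoids a 0/0 in the tie correction.

The central model is a linear mixed model per response metric:

```
response ~ stage + side + age + hba1c + sex + stage:side + (1 | patient)
```

fit by REML, with treatment coding (references: stage "no DR", side
"right", sex female), Wald 95% CIs for fixed effects, and F-tests for
stage and the stage-by-side interaction with Satterthwaite denominator
degrees of freedom. REML/Wald/Satterthwaite are the conventional defaults
of the R mixed-model ecosystem; they are stated explicitly because
estimates on real data shift in the third decimal across these choices.
The branching logic mirrors the clinical reporting convention: a
significant stage F-test triggers contrasts of each stage against "no DR";
a significant interaction triggers left-vs-right contrasts within each
stage; otherwise a single marginal side effect is reported. No
multiplicity correction is applied anywhere — p-values are descriptive.

Two "side estimates" exist once an interaction is in the model: the
`sideleft` coefficient is the left-eye effect *in the reference stage*,
while the marginal effect (averaged over stages, via estimated marginal
means) is the single-number summary comparable to a headline intereye
difference. The package reports both; `side_marginal` is the headline.

Degenerate designs are handled explicitly: a single-sex cohort raises an
error naming `sex` (singular design); a single-stage cohort drops the
stage terms with a logged note so small end-to-end runs remain
analyzable; rows with missing covariates (e.g. unknown HbA1c) are dropped
and logged.

## Synthetic data: what it emulates and what it does not

**Angiograms.** `generate_angiogram_pair()` draws, per eye: a FAZ polygon
from 72 radial spokes with radius $r(1 + a u)$, $u \sim U(-1, 1)$,
smoothed by a circular 5-point moving average (monotone map from the
irregularity $a$ to circularity); 2–4 bright arcade vessels as smooth
random-heading curves steered away from the fovea; and a capillary mesh of
short random-walk strokes added until a target coverage fraction is
reached inside the 6-mm disc (outside FAZ and big vessels). Intensities
default to background 10, capillaries 90, big vessels 255 (8-bit), chosen
analytically so that $\mathrm{mean} + 0.5\,\mathrm{sd}$ falls between
background and capillary intensity and $\mathrm{mean} + 1.3\,\mathrm{sd}$
between capillary and big-vessel intensity across coverage 0.15–0.30 —
the property that makes the two-coefficient thresholding scheme
meaningful. Gaussian noise is added, clipped to [0, 255] and rounded.
The generator does **not** model OCT speckle, flow decorrelation,
projection artifacts, or motion artifacts; passing tests demonstrate that
the measurement stack is correct on images whose ground truth is known,
not that segmentation is robust to device-specific noise.

**Cohorts.** `generate_metrics_cohort()` emits the exact additive
structure the mixed model assumes (stage effects, left-eye offset,
stage-by-side interaction, patient random intercept, residual), with
defaults on the SCP-VD scale: grand mean 0.218, left-eye offset −0.009,
patient SD 0.015, residual SD 0.008, 34 patients per stage — the
between/within split chosen so that the marginal eye SD (~0.017) and the
typical fellow-eye difference (~0.013) match a realistic adult DR cohort,
whose demographics (age 57.2 ± 13.1, HbA1c 7.34 ± 1.32, 66% male) the
covariates reproduce. Parameter-recovery and coverage tests on this
generator validate the inference code, not the clinical effect sizes.

All randomness derives from one integer seed, split into per-patient and
per-eye streams via a deterministic hash, so identical parameters and
seed give bit-identical images, masks and tables; the pipeline rounds
floating outputs to 6 decimals so repeat runs are byte-identical.

## Problem sizes and numerical tolerances

The test suite generates 150-px (0.04 mm/px) angiograms for speed and
500-px (0.012 mm/px) ones where the defaults matter; simulation-based
checks use 200 replicate cohorts for CI coverage and branch calibration
and 1000 replicates for rank-test type-I error. Closed-form oracles are
asserted at their exact values (square circularity $\pi/4$, Wilcoxon
fixture p = 0.0625, 13-pixel dilation disc); dimension estimates at the
fit tolerances stated alongside each oracle (±0.02 for the filled square,
±0.05 for carpet and line).

## Limitations

* Absolute FD values depend on the box-counting convention; only
  same-convention comparisons are meaningful.
* The DCP projection-artifact exclusion is an approximation (SCP
  big-vessel mask), off by default.
* The FAZ is measured on the SCP trace only, and no axial-length scaling
  correction is applied.
* The mask-to-polygon path carries the perimeter quantization bias noted
  above.
```{r session}
sessionInfo()
```
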