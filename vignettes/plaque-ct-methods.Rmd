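---
title: "Methods: CT-based carotid plaque analysis and calcification scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT-based carotid plaque analysis and calcification scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaqueCT)
```

## What the package models

Atherosclerotic plaque in the carotid bifurcation can rupture and embolise;
plaques containing acute intraplaque haemorrhage (IPH, erythrocytes on
histology) are operationally "vulnerable", all others "stable". plaqueCT
implements the quantitative CT side of a validation workflow for this
problem: tissue classification of the plaque by CT attenuation, an
Agatston-style calcification score usable both on contrast CT angiography
(CTA) and on non-contrast CT (NCCT) of the excised specimen, the
histological grading model that serves as ground truth, and the statistics
that compare the two. Because clinical scans cannot be redistributed, the
package also generates synthetic phantoms and cohorts with analytically
known ground truth, so every stage can be tested against an exact oracle.

## Component classification and the vulnerability rule

Plaque voxels are classified into five Hounsfield-unit bands:

| band | HU interval |
|---|---|
| lipid | [20, 40) |
| fibrolipid | [40, 60) |
| fibrotic | [60, 80) |
| fibrocalcified | [80, 250] |
| calcification | (250, Inf) |

The protocol prints integer ranges (20–39, 40–59, …, 80–250, >250); mapping
them to half-open intervals preserves the integer semantics while covering
real-valued HU. HU below 20 is "unclassified" and excluded from the
dominance denominator, since the scheme starts at 20 HU.

The verdict is decided by the dominant band (largest fraction of classified
plaque **volume**): lipid or fibrolipid dominance is vulnerable; fibrotic
dominance is stable unless any lipid or fibrolipid is present, in which case
the plaque is vulnerable; fibrocalcified or calcification dominance is
stable; and an ulcerated vessel is vulnerable regardless of composition.
Two choices here were genuinely open and are resolved as follows:

* **Dominance by volume.** Whether the reference software dominates by
  volume or by single-slice area is not documented; volume is the natural
  3-D aggregate and is used throughout.
* **Ties** between bands with equal maximal fraction are broken toward the
  more vulnerable band (lipid > fibrolipid > fibrotic > fibrocalcified >
  calcification) and flagged in the result. For a screening rule this is
  the conservative direction.
* **The lipid-presence override is literal**: it is stated for the fibrotic
  band only, so a fibrocalcified- or calcification-dominated plaque with
  some lipid content is still called stable. This is deliberate and worth
  knowing when interpreting calls.

```{r}
pr <- data.frame(band = c("lipid", "fibrolipid", "fibrotic",
                          "fibrocalcified", "calcification"),
                 fraction = c(0.1, 0, 0.6, 0.3, 0))
call_vulnerability(pr, ulcerated = FALSE)
```

## The calcification score (CALS)

Per axial slice, pixels strictly above 130 HU inside the plaque ROI are
grouped into 8-connected components; each component is a lesion with an
area (pixel count × in-plane pixel area) and a peak HU. The lesion weight
is 1, 2, 3 or 4 for peaks in [130, 200), [200, 300), [300, 400) and
[400, ∞) — the printed weight ranges overlap at 200/300/400 and the
half-open reading is the only self-consistent one, matching the original
Agatston convention. Lesions under 1 mm² are ignored; the remaining
area × weight scores are summed and multiplied by
`slice_thickness / 3` (0.625/3 for the 0.625 mm acquisitions), converting
to the 3 mm reference thickness of the Agatston score. The identical
aggregation runs in CTA and NCCT mode; the ex-vivo protocol's phrase "all
scores were multiplied" is read as the same summation-plus-adjustment
rather than a literal product, which would be dimensionally meaningless.
Connectivity is 2-D per slice (a calcification spanning slices contributes
one lesion per slice), because the manual protocol scores each axial slice
separately.

```{r}
les <- data.frame(lesion_id = 1:2, slice = 1L, pixels = c(64L, 32L),
                  area_mm2 = c(4, 2), peak_hu = c(350, 150),
                  weight = c(3L, 1L), score = c(12, 2))
total_cals(les)   # (4*3 + 2*1) * 0.625/3
```

## Histological ground truth

A specimen is IPH-positive when erythrocytes appear in any slice. Micro-
and macrocalcification are graded 0–3 by the fraction of plaque area
covered: 0 at exactly 0, 1 up to one third, 2 up to two thirds, 3 above
(left-open intervals, so 33% is grade 1 and 34% is grade 2, matching the
printed integer-percent bands). Specimen grades are per-slice maxima. The
morphological separation of micro- from macrocalcification carries no
numeric size threshold in the underlying protocol, so the fractions arrive
pre-separated as annotation input; the package does not attempt to infer
them from images.

## Validation statistics

Sensitivity, specificity, PPV and NPV are computed from the 2×2 table with
IPH-positive as the positive condition. The CI method behind the study's
printed intervals is not stated and no closed form reproduces all of them
exactly, so both Clopper–Pearson (default) and Wilson intervals are
available and the method is always recorded — transparency over false
precision. Mann–Whitney uses midranks, reports per-group mean ranks (the
SPSS convention) and a tie-corrected normal p-value; with group sizes
around 16–37, exact enumeration is unnecessary for 3-decimal p-values.
Spearman is the Pearson correlation of midranks with the t approximation.
Bland–Altman reports bias, SD and 1.96·SD limits, plus a drift statistic:
the Spearman correlation between the paired difference and the pair mean,
which quantifies the "disagreement grows with magnitude" pattern that the
original analysis shows only graphically. Cohen's kappa uses marginal
expected agreement and attaches the Fleiss interpretation bands
(>0.75 excellent, 0.40–0.75 fair-to-good, <0.40 poor). Degenerate inputs
(zero denominators, constant vectors, both raters constant) are flagged as
undefined rather than silently coerced to 0. Reported percentages round
half away from zero to one decimal, which is how 5/16 prints as 31.3.

## The synthetic phantoms

A phantom is a soft-tissue background (default 40 HU), optional
contrast-filled lumen cylinder (default 400 HU), plaque component discs and
calcified lesions, on a default grid of 0.25 mm in-plane spacing and
0.625 mm slices. Two design choices make the oracles exact rather than
probabilistic:

* component noise is a **Gaussian truncated to the component's band**, so
  planted band membership is never crossed by noise and classified volumes
  equal planted volumes exactly at any noise level;
* lesions have a **deterministic radial HU profile** from the peak at the
  centre down to 140 HU at the rim, so the >130 HU support, the area and
  the peak are known analytically.

The analytic CALS oracle is computed from the planted geometry alone
(area × weight(peak), filtered and adjusted) with no image processing. All
randomness flows from one integer seed through a single generator, so a
fixed seed gives bit-identical phantoms.

Phantom HU means and SDs are free parameters of the generator, not
estimates of any patient population — the source scans carry no published
HU statistics. Consequently, passing tests demonstrate algorithmic
correctness on geometrically ideal plaques; they do not certify performance
on real scans with partial-volume mixtures, motion, beam hardening or
irregular anatomy, none of which the generator emulates.

## Blooming and the CTA/NCCT experiment

On contrast CT, the dense lumen blooms: high attenuation spreads into the
vessel wall and blurs the contrast–calcification border, which is why CTA
underestimates calcification relative to NCCT of the excised specimen, and
increasingly so at high burden. The package models this in two coupled
steps:

1. `simulate_blooming()` smooths intensities with an in-plane Gaussian
   kernel (sigma `kernel_width_mm`, default 0.5 mm) **restricted to a band
   around the lumen** (about twice the kernel width). Width 0 is the
   bit-exact identity; lesions far from the lumen are untouched.
2. CTA-mode scoring (`score_cta()`) excludes the bloom-ambiguous zone — the
   lumen dilated by the blooming extent — from the scoring ROI, emulating a
   reader who cannot attribute the blurred border region to calcification
   and conservatively leaves it out. NCCT-mode scoring of the same phantom
   uses the full plaque ROI.

This is the simplest mechanism that reproduces the observed phenomenology:
lesions abut the lumen, so the excluded margin removes a segment of each
lesion whose absolute area (and weight, since denser lesions score higher
per mm²) grows with lesion size. `paired_cals_experiment()` sweeps 50
seeded phantoms across burden; NCCT minus CTA is positive throughout and
its rank correlation with the pair mean is strongly positive. The sign of
that drift, not its magnitude, is the claim being reproduced — the
magnitude depends on the free kernel width.

```{r, eval = FALSE}
exp <- paired_cals_experiment(50, seed = 7)
bland_altman(exp$cals_ncct, exp$cals_cta)[c("mean_diff", "drift_rho")]
```

## The synthetic cohort

`generate_cohort()` draws, per patient, IPH from Bernoulli(prevalence) (or
with fixed margins, matching a retrospective case series of known
composition — the default pipeline configuration mirrors 37 IPH-positive of
53), a software call with the configured sensitivity/specificity, ordinal
grades from per-stratum distributions, and paired CTA/NCCT scores from a
grade-linked gamma burden model in which CTA underestimates increasingly
with burden. The default grade distributions give the non-IPH stratum the
heavier microcalcification burden (the direction seen histologically) and
near-equal macrocalcification; they are plausibility choices, not fitted
values. The call operating point of 0.9 sensitivity / 0.3 specificity used
in examples is of the order observed for the commercial software under
validation.

## Problem sizes and numerical choices

Default test and experiment sizes — 42–60 voxel in-plane grids, 3–6
slices, 50 phantoms per sweep, 10 000-patient recovery cohorts — were
chosen so that every oracle comparison is exact or within quoted binomial
error while the whole suite runs in seconds on one core. Thresholds are
taken strictly as printed: the 130 HU lesion threshold excludes exactly
130; the <1 mm² exclusion is applied per lesion per slice, after
segmentation, before summation; peak HU is read before any blooming
correction (none is attempted, faithful to the manual protocol).

## Known limitations

* No scanner physics: no beam hardening, reconstruction kernels, DICOM, or
  motion; phantoms are geometric.
* No vessel segmentation, centerline extraction or stenosis grading; the
  plaque ROI and the ulceration flag are inputs.
* The blooming model is phenomenological; its kernel width is a free
  parameter and only ordinal/sign conclusions should be drawn from the
  paired experiment.
* A known discrepancy in the source numbers: the unique 2×2 table
  consistent with the printed specificity and PPV yields a sensitivity
  that rounds to 89.2%, one decimal off the printed 89.1%. The package
  computes from the table and does not silently correct either number.
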