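---
title: "Airway wall morphometry: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Airway wall morphometry: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwaymorph)
```

## The problem

Airway smooth muscle (ASM) mass increases in asthma, and radial
endobronchial ultrasound (EBUS) can image the bronchial wall as concentric
echo layers without taking tissue. The first hyperechoic layer (L1)
corresponds to the epithelium plus the inner extracellular matrix (ECM);
the second hypoechoic layer (L2) contains the remaining ECM and the ASM.
Quantifying remodeling from such images raises four linked problems, each
addressed by one part of this package:

1. **Geometry**: measuring internal perimeter (Pi), diameter (D), lumen
   area (LA), layer thicknesses and layer areas on traced contours, under
   partial visibility and with explicit quality control (`morphometry`
   functions).
2. **Modality reconciliation**: histology shrinks tissue and collapses the
   airway, EBUS images it distended; the concentric-annulus model converts
   areas into equivalent distended thicknesses so the two can be compared
   (`annulus_*`, `stack_layers`, `l2_composition`).
3. **Agreement**: Bland–Altman bias analysis, mixed-model association and
   intraclass correlation for paired or repeated measurements
   (`bland_altman`, `method_association`, `icc_repeatability`).
4. **Design**: where the variability lives (subject, airway or image), how
   many images per airway are enough, and how many subjects a study needs
   (`nested_varcomp`, `cv_by_n_images`, `simulate_power`).

Because no raw per-airway data are publicly available for this problem, the
package ships a first-class synthetic-data layer (`make_airway_phantom`,
`generate_hierarchical_dataset`, `generate_paired_modality`) whose ground
truth is analytic, so every measurement operation can be verified against a
closed form.

## The concentric-annulus model

A wall layer of cross-sectional area $A$ wrapped around an inner circle of
circumference $C$ (radius $r = C/2\pi$) has, if it were a homogeneous ring
on a fully distended airway, thickness

$$t = \sqrt{r^2 + A/\pi} - r,$$

the exact inverse of $A = \pi\left((r+t)^2 - r^2\right)$. `stack_layers`
applies this twice: the histological Pi is the inner circumference of the
ECM ring (epithelial thickness is treated as exactly zero), and the ECM
ring's outer circle is the inner circle of the ASM ring. In the thin-layer
limit $t \to A/C$, the flat-sheet rule; the tests verify the ratio
converges to 1 below $t/r < 10^{-3}$.

Downstream compositions follow by arithmetic:

* **Submucosal thickness**: ECM + ASM thickness at histology; L1 + L2 on
  ultrasound.
* **Shrinkage**: $100\,(\mathrm{EBUS} - \mathrm{histology}) /
  \mathrm{EBUS}$ of the submucosal thickness. The formula is the standard
  definition of linear shrinkage relative to the in vivo state and, applied
  to the published group means, reproduces the published per-subject
  average (44.25 vs 44.28 percent in controls).
* **L2 composition**: after rescaling the histological thicknesses so their
  sum matches the ultrasound submucosa (`scale_histology_to_ebus`), L1 is
  attributed entirely to ECM and the remainder of the scaled ECM thickness
  falls inside L2. If the scaled ECM is thinner than L1, the ECM content of
  L2 is clamped at zero and flagged (`clamped`); published data never show
  this case, but noisy simulated airways can.

Per-subject-first averaging is the intended use: compositions are computed
per airway, then averaged per subject, then per group — group-mean
shortcuts are used only in worked examples.

## Measurement conventions

The contour operations make the following choices where the field's
practice is not fully standardized:

* **Two perpendicular diameters**: the longest chord through the contour
  center plus the chord perpendicular to it, averaged. On open contours
  covering at least 180°, a hidden chord endpoint is completed by point
  symmetry about a least-squares circle-fit center; below 180° the diameter
  is undefined and refused.
* **Five predetermined thickness sites**: rays at 0°, 72°, 144°, 216°,
  288° from the lumen center, measured radially. Sites in a hidden arc are
  skipped and counted; the mean uses the remaining sites and is *not*
  proportionally completed (it is an average, not an extensive quantity).
* **Proportional completion** applies to arc lengths and areas only:
  measured value × 360/subtended angle.
* **Quality control**: ultrasound records are excluded when the wall is
  uninterpretable over more than 180°; histology records with quality score
  1 always, and score 2 when the missing angle is ≥ 90°.
* **Size classes** are right-closed: intermediate means Pi ≤ 31 mm; the
  three-way split uses (0, 16], (16, 31], (31, ∞) mm.
* **Normalization**: L2 area/Pi (mm) and L2 area/Pi² (dimensionless); the
  squared normalization makes the index invariant under uniform scaling,
  which the tests assert to 1e-9.
* On EBUS images Pi is traced at the lumen boundary (not the L1–L2
  interface); the composition analysis defaults to airways with histology
  Pi < 26 mm (configurable), matching how size-matched airways were
  selected for composition work.

## What the synthetic data emulate — and what they do not

`make_airway_phantom` draws from an ellipse-perturbed circle family
(eccentricity 0–0.5, i.e. axis ratio up to 3:1) with constant-thickness
parallel-offset layers. Offsets of a convex curve have closed-form
perimeter ($L + 2\pi t$) and area ($A + tL + \pi t^2$), which is what makes
the truth analytic. Published data do not characterize airway
non-circularity, so the eccentricity default is a modeling choice, not an
estimate. The rasterizer paints flat gray levels per layer with optional
additive Gaussian noise; it does not simulate ultrasound speckle, cartilage
echoes (L3–L5) or probe artifacts, so segmentation results on phantoms
bound the *geometric* error only, and say nothing about echo-texture
segmentation difficulty on real scans.

`generate_hierarchical_dataset` is an additive Gaussian random-effects
model: value = group mean + subject + airway + image effects, with the
three variance fractions given as shares of the single-image variance
$(\mathrm{CV}\cdot\mu)^2$ and the group effect applied multiplicatively in
percent. Defaults (7 subjects per group, 10 airways of Pi 10–31 mm, 3
images, 30% group effect on a 0.25 mm L2-type mean, 25% single-image CV
with fractions 0.10/0.60/0.30 for subject/airway/image) mirror the
optimized in vivo protocol scale: airway-to-airway variation dominates,
image repeats contribute a quarter or less. Because one value is recorded
per image, the image stratum *is* the residual; any unassigned variance
fraction is folded into it.

`generate_paired_modality` links the two modalities through one distended
truth: L1 and L2 thicknesses proportional to Pi (ratios 0.0068 and 0.0109,
matching intermediate bronchi where L1 ≈ 0.11 mm at Pi ≈ 16 mm), a 22% ECM
share of L2, histology shrunk linearly by 44% (areas by the square), EBUS
underestimating Pi proportionally (default slope 0.18), and multiplicative
noise on every measured field. These defaults were chosen once from the
published group-level summaries; they are the study conditions for the
tests, not tuning knobs.

## Statistical machinery

* **Bland–Altman** (`bland_altman`): differences (EBUS − histology) against
  pairwise means; limits of agreement at mean ± 1.96 SD; proportional bias
  by ordinary least squares of difference on mean, with two-sided t tests
  of slope and intercept; *systematic bias* declared when either is
  significant at 0.05. Exact fits (zero residual) are handled by treating a
  zero standard error as an exactly determined coefficient.
* **Association** (`method_association`): a random-intercept-per-subject
  model via REML (`lmerTest`), slope tested with Satterthwaite degrees of
  freedom; when the fit is degenerate (exact data collapse the df) the Wald
  normal test is used, and a single subject collapses the model to ordinary
  least squares. R² is reported as the squared correlation between fitted
  and observed values — a documented stand-in, since mixed-model R² is not
  uniquely defined.
* **ICC** (`icc_repeatability`): one-way random-effects, single-measure
  form $(MS_B - MS_W)/(MS_B + (k-1)MS_W)$, chosen because a single fixed
  observer remeasured the same images, making the observer a non-factor;
  a complete items × repeats design is required.
* **Variance components** (`nested_varcomp`): method-of-moments from the
  nested ANOVA with group as the top stratum, balanced expected-mean-square
  coefficients (average replication under mild unbalance), negative
  solutions truncated to zero before normalizing to percentages. With two
  groups the group stratum has one degree of freedom, so its percentage
  carries a sampling SD of roughly ten points at study-like sizes — single
  datasets localize the dominant stratum, not precise group percentages.
* **Sequential Bonferroni** is Holm's step-down method
  (`group_size_contrasts`), the standard reading of that phrase. The
  default per-class test is a pooled-variance t-test on per-subject class
  means — exactly the balanced random-intercept analysis, but deterministic
  and fast; `method = "lmer"` fits the mixed model instead.
* **Replicate optimization** (`cv_by_n_images`): each airway contributes
  the CV of a mean of *n* subsampled images, with the small-sample SD bias
  removed ($c_4$ correction) so the $1/\sqrt{n}$ ladder is unbiased; the
  recommended *n* is the smallest whose mean CV is within 20% (relative,
  configurable) of the value at the largest *n*. Under image-dominated
  noise this recommends 3 images, the protocol actually adopted. The
  criterion is explicit here because only the conclusion, not the rule, was
  published.
* **Power** (`simulate_power`): simulated datasets tested by the group
  contrast on per-subject means; exactly valid for balanced designs and
  deterministic given the seed. The degenerate single-airway,
  subject-noise-only case agrees with the closed-form two-sample t-test
  power within ±0.03 at 2000 replicates (asserted in the tests). Both a
  variance-fraction parameterization and a direct subject-level SD (via
  fractions = subject-only) are expressible, since the original power
  method was not fully specified.

## Numerical choices and degenerate inputs

Contours are counterclockwise n × 2 matrices in mm, not literally closed.
Open contours are detected by edges longer than 5× the median edge;
coverage is the summed angular step over non-gap edges. Ray–polygon
intersections are exact segment intersections (no interpolation) so
thickness oracles hold to 1e-6 with ≥ 8192-point contours. Self-intersection
is checked by a fast star-shape test with an exact $O(n^2)$ fallback.
Duplicate consecutive points, zero-area contours, non-nested layer pairs,
empty QC fields, non-positive perimeters and variance fractions summing
above 1 are all rejected with explicit messages. Mixed models use REML with
`lmerTest`; Monte-Carlo routines take explicit integer seeds (default
20150908) and restore the caller's RNG state.

Problem sizes in the shipped tests (50-simulation recovery runs, 1000-rep
null calibrations, 2000-rep power comparisons, 8192-point oracle contours)
were chosen so the whole suite completes in about a minute on one CPU while
keeping Monte-Carlo error well below each asserted tolerance.

## Known limitations

* Phantoms are star-shaped and smooth; real airway sections can be locally
  concave or crenellated, where radial thickness overestimates the normal
  thickness.
* The rasterizer's flat-intensity layers make segmentation much easier than
  on real speckle; `segment_radial` is a stand-in for manual tracing, not a
  clinical segmenter, and its traced perimeters are pixel-quantized (keep
  ray spacing around 2 px of arc).
* With two groups, the group variance percentage is estimable only with
  ~10-point precision from a single study-sized dataset (one degree of
  freedom); the package reports it as the decomposition defines it.
* Mixed-model R² and the composition of partially visible airway sections
  are reported under documented conventions rather than unique definitions.
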