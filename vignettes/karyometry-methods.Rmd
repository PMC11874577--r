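---
title: "Quantifying nuclear pleomorphism: models, parameters, and design choices"
author: "karyometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear pleomorphism: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyometry)
```

## The problem

Variation in nuclear size (anisokaryosis) and shape is a core histologic
criterion of malignancy, but categorical estimates of it by pathologists
reproduce poorly: the same tumor can be called "mild" by one rater and
"severe" by another, largely because each rater applies a private
threshold to the same visual impression. Morphometry replaces the
estimate with measurements of the segmented nuclei, which makes the
parameter continuous, auditable, and thresholdable at a chosen
sensitivity/specificity trade-off.

`karyometry` implements the full measurement-and-statistics chain for
this setting, aimed at tumor pathology studies that work from
fixed-area regions of interest (ROIs) cropped from whole-slide images
(the defaults assume 0.1185 mm^2 crops at 0.25 um/pixel, i.e. half a
standardized high-power field at 400x): segmentation-mask
post-processing, the per-nucleus and per-ROI parameter suite, emulators
of two manual sampling protocols, and the accuracy, prognostic,
agreement, and heterogeneity statistics used to evaluate such methods.

## Measurement model

**Per nucleus.** A nucleus is a pixel set (from a label mask or a
rasterized polygon annotation). Its descriptors are:

* *area* = pixel count x (microns per pixel)^2;
* *eccentricity* of the equivalent ellipse derived from the second
  central moments of the pixel coordinates - the focal distance over
  the major axis length, 0 for a circle, approaching 1 for elongated
  nuclei;
* *solidity* = pixel count / pixel count of the convex hull, 1 for
  convex ("smooth") nuclei, lower when the contour is indented;
* the centroid, used for sampling and bookkeeping.

A one-pixel region is defined to have eccentricity 0 and solidity 1.
The convex-hull pixel count uses a boundary-inclusive half-plane test
so that convex digital regions score exactly 1.

**Per ROI.** `roi_morphometry()` aggregates the per-nucleus values into
the distributional parameter suite: for area the mean, median, SD, 90th
percentile, 90th percentile/median, mean of the largest 10%, percentage
of large nuclei above case-independent reference sizes (defaults
37.8 and 50.3 um^2, the 90th percentile and twice the median of a
reference annotation population), and skewness; for eccentricity and
solidity the mean, SD, skewness, and the percentage of indented nuclei
(solidity below 0.913/0.936/0.943, the 2nd/5th/10th percentiles of the
same reference population). The SD of nuclear area is the primary
anisokaryosis parameter; the large-nucleus percentages and the
90th-percentile/median ratio are operational proxies for karyomegaly.

**Per case.** Each tumor contributes 3-5 ROIs; `case_morphometry()`
averages every ROI-level parameter unweighted across the case's ROIs.
Mean solidity is inverted (`invert_mean_solidity()` = 1 - mean) so that
for every parameter larger values point toward malignancy.

### Numerical conventions

Several conventions are not dictated by the measurement definitions and
had to be fixed once:

* **SD flavor**: sample SD (n - 1 denominator) throughout. Under the
  package's synthetic generative model this is the unbiased choice, and
  using one flavor everywhere keeps ROI-level and case-level statistics
  comparable.
* **Percentiles**: linear interpolation between order statistics
  (R's type 7).
* **Skewness**: adjusted Fisher-Pearson coefficient; reported as
  missing (not 0) for n < 3 or zero spread.
* **Largest-10% count**: `ceiling(0.1 n)`, so 12 nuclei contribute
  their 2 largest.
* **Strictness**: the large-nucleus percentage uses strict `>`, the
  indentation percentage strict `<`, and the small-object filter strict
  `<` against exactly 7.0 um^2. Where a boundary rule is inherently
  ambiguous ("approximately 7 um^2", "above threshold 1") the package
  fixes a documented default rather than an unstated approximation, and
  exposes it as a parameter.
* **Undefined statistics** (SD of one value, precision with no
  positives, CV at mean zero, kappa with degenerate expectation) are
  reported as missing values with flags, never silently as 0.

## Segmentation post-processing

Deep segmentation models for this task emit binary masks; turning them
into instances is a fixed pipeline: connected-component labeling
(`label_components()`), then removal of objects smaller than 7 um^2
(`filter_small()`), which cannot be complete nuclei at this
magnification. Components are labeled in raster-scan order of their
first pixel, so labelings are deterministic. Two open choices are
exposed as configuration with the following defaults:

* **Connectivity**: 8-neighbor, because 4-connectivity splits nuclei
  whose thin diagonal boundaries survive thresholding; both are
  available.
* **Border instances**: kept. The border-exclusion rule belongs to the
  manual grid protocol (where a cut-off nucleus would be measured
  incompletely by a human); for algorithmic morphometry over the full
  ROI the bias from dropping all border nuclei exceeds the bias from
  measuring the truncated ones. `border_policy = "drop"` reverses this.

`baseline_segment()` is a deterministic classical segmenter (Otsu
threshold, distance-transform watershed, labeling, filtering) for
end-to-end demonstrations on rendered synthetic images. It is a
demonstration baseline, not a learned model, and its accuracy on real
stained tissue should be expected to be far below a trained network's.

## Manual sampling emulators

Two protocols from diagnostic practice are emulated so their
statistical behavior can be studied against complete morphometry.

**Grid protocol (>= 100 nuclei).** A 5 x 6 grid is overlaid; whole
fields are annotated completely until 100 nuclei are reached, central
fields first. Within a field every instance intersecting it counts
(once), but instances cut off at the outer image border are excluded.
The field order in the original protocol description is given only as a
center-out meander, so the package freezes one reproducible
realization: fields ranked by Chebyshev distance from the grid center,
serpentine row order within each ring, outer ring last
(`meander_order()`). The exact order used by any human rater is
unknowable; what matters statistically is "central first, border
last", which any such meander satisfies.

**Stratified protocol (12 nuclei).** Nuclei are sorted by area, split
into terciles at ranks `floor(n/3)` and `floor(2n/3)` (ties broken by
id), and 4 nuclei are drawn per tercile. Human raters choose
"representative" nuclei; the package replaces that unobservable
behavior with a seeded uniform draw, plus an explicit bias model
(`simulate_rater_measurement()`): an `area^tilt` selection weight
emulating the documented tendency to oversample large cells, and
multiplicative lognormal measurement noise emulating boundary-tracing
error. With both at zero the simulator reduces exactly to the plain
protocol.

## Statistical machinery

* **Accuracy**: pixel overlap by Dice; instance detection by greedy
  one-to-one IoU matching (default acceptance IoU >= 0.5 - the matching
  criterion is a parameter because published F1 values are
  criterion-dependent); parameter errors by RMSE over images.
* **Prognostic value**: ROC/AUC by the Mann-Whitney statistic with
  midrank tie handling (identical to the trapezoidal ROC area), with a
  seeded percentile bootstrap over cases (default 2000 resamples;
  resamples that lose an outcome class are dropped). Dichotomization
  scans 201 cutoffs spanning the marker range in 0.5% steps and picks
  the *highest* cutoff whose sensitivity equals the target;
  sensitivity matching is done on true-positive *counts* (e.g. 10 of
  13), never on floating-point percentages. A case is positive when its
  value is >= the cutoff.
* **Outcome conventions**: for classification, deaths not attributed
  to the tumor count as negatives; for survival they are censored at
  death, and survivors at end of follow-up. Twelve-month variants
  (tumor-specific and overall mortality) remove the bias of variable
  follow-up.
* **Survival**: Kaplan-Meier product-limit curves (median = first time
  the curve reaches 0.5) and univariate Cox regression with Breslow tie
  handling and Wald intervals, via the survival package. Fits where one
  group has no events are flagged unstable rather than suppressed.
* **Agreement**: weighted Cohen's kappa (linear weights by default for
  ordered 3-tier estimates, unweighted for binary calls - the weighting
  scheme is always reported because kappa values are scheme-dependent),
  Light's kappa as the mean over rater pairs, and ICC(A,1) - two-way
  random effects, absolute agreement, single measures - from the ANOVA
  mean squares with an F-based CI. Interpretation bands follow the
  conventional kappa and ICC scales.
* **Heterogeneity**: between-ROI CV and SD, the proportion of hotspot
  ROIs (>= threshold 1; the boundary is inclusive for consistency with
  the case-level positivity rule), the outcome distribution by exact
  hotspot proportion, and AUC as a function of the number of ROIs
  averaged.

## The synthetic cohort: what it emulates and what it does not

`generate_roi()` packs non-overlapping deformed ellipses into an image
by seeded dart-throwing (200 placement attempts per nucleus, shortfalls
reported, never silently padded; a one-pixel separation keeps instances
distinct under 8-connectivity). The area distribution is lognormal -
positive support and the right skew that real nuclear-area
distributions show; a gamma alternative sits behind a flag. The
defaults (mean 26.5, SD 8.6 um^2) place the median near 25 um^2 and the
90th percentile near 37.8 um^2, consistent with the reference
population behind the karyomegaly cutoffs. Eccentricity is Beta-drawn
and capped below 1; indentations are circular bites whose depth maps
monotonically to solidity.

`generate_cohort()` draws a latent per-case severity (the true
case-level area SD, lognormal with median 6.5 um^2), adds lognormal
between-ROI noise (SD of logs 0.15), and links outcome to severity
through an exponential survival time with log-hazard
`alpha + beta (severity - 6.5)`. The frozen defaults
(`alpha = -6.5`, `beta = 0.52`, censoring uniform on 12-45.3 months,
unrelated-death probability 11/96) were chosen once so that the
generating conditions match the kind of cohort this machinery is
designed for: about 13% tumor-related deaths in 96 cases and a
truth-ledger AUC near 0.9 for the area-SD score. `beta = 0` gives the
no-signal control. `generate_raters()` adds the rater layer: fixed
per-rater threshold offsets on a shared latent scale (driving
inter-rater disagreement that exceeds intrarater disagreement) and
multiplicative measurement noise.

What the generators do *not* emulate: stain and scanner variation,
touching/overlapping nuclei, non-neoplastic cells, segmentation error
structure of a real network, spatial correlation of nuclear features
within an ROI, and non-proportional hazards. Passing the package's
tests therefore demonstrates that the *statistical machinery* is
correct and that the pipeline recovers known generating parameters; it
does not certify segmentation accuracy or prognostic performance on
real tissue.

## Problem sizes used in the test suite

The suite works at deliberately moderate scale - ROIs of 300-455 nuclei
in 600 x 800 to 700 x 900 px images, cohorts of 96 cases, 20-50
replicates for Monte-Carlo checks, 2000 subjects for Cox recovery -
sizes at which the Monte-Carlo standard errors are comfortably inside
the asserted tolerances while a full run stays fast enough to be rerun
habitually.

## Known limitations

* Eccentricity from discrete moments is biased for very small regions
  (a handful of pixels); at typical nucleus sizes (> 100 px at
  0.25 um/px) the bias is negligible, as the analytic phantom tests
  show.
* The 200-interval threshold grid can skip a sensitivity value
  attainable only on a sub-grid interval; the selection function then
  reports the achievable sensitivities instead of silently moving the
  target.
* The bootstrap CI is a plain percentile interval; with 13 events in
  96 cases it is wide, which is faithful to the uncertainty rather
  than a defect.
* `baseline_segment()` requires EBImage and is intentionally simple;
  use it to exercise the pipeline, not to segment real slides.

## A worked example

```{r, eval = FALSE}
library(karyometry)
roi <- generate_roi(nucleus_population_spec(n_nuclei = 300, seed = 1),
                    image_shape = c(600, 800))
feats <- measure_instances(roi$mask)
roi_morphometry(feats)

res <- run_pipeline(list(seed = 1, microns_per_pixel = 0.25))
res$prognosis$auc
res$agreement$icc
```
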