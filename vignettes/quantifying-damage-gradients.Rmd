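---
title: "Quantifying colibactin-induced DNA-damage gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying colibactin-induced DNA-damage gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colidist)
```

## The measurement problem

Colibactin is a genotoxin encoded by the *pks* island of some *E. coli*
strains; it alkylates DNA and causes interstrand crosslinks in neighbouring
cells. Whether its delivery requires cell-cell contact can be probed with a
live transcriptional reporter: a *recA*-promoter (SOS response) YFP fusion in
target cells, constitutive CFP marking targets and constitutive mCherry
marking producers. Two imaging assays and one cytometry assay follow:

* **Lawn assay** — a producer colony sits on a lawn of reporter cells; the
  YFP intensity along a line from the colony centre into the lawn traces a
  decay curve.
* **Colony-pair assay** — producer and reporter colonies grow side by side,
  either touching (*contacting*) or separated by an edge-to-edge gap of at
  least 10 µm (*non-contacting*); the decay curve is read along the line
  through both colony centres.
* **Flow time course** — a pelleted 10:1 producer:reporter co-culture is
  sampled over time and the fraction of DNA-damage-positive reporter cells
  is counted.

The package implements the full measurement chain for all three, plus a
synthetic-data generator that renders scenes and event tables with known
ground truth, so each estimator can be validated against a recoverable
parameter without any microscope.

## The spatial metric: dist50

For one profile the procedure is:

1. **Smooth** the reporter intensity with a centred moving average of 20
   samples (`smooth_profile()`); near the ends the window truncates
   symmetrically, so constants and interior linear trends are preserved.
   Smoothing controls baseline noise in weak early-time profiles.
2. **Baseline** = mean of the 20 valid samples furthest from the producer
   (`estimate_baseline()`), computed on the smoothed curve by default
   (`baseline_on = "raw"` is a documented switch; the choice moves the
   result by far less than a sampling step on the synthetic scenes).
3. **YFP50** = baseline + (max − baseline) / 2 (`compute_yfp50()`), with the
   maximum taken from the smoothed curve.
4. **dist50** = distance of the first downward crossing of YFP50, scanning
   outward from the peak with linear interpolation between the bracketing
   samples (`compute_dist50()`). First crossing, not last: noisy tails can
   re-cross, and the first crossing is the conservative range estimate.

Profiles are aligned (`align_profile()`) before analysis: at the smoothed
YFP peak in the lawn assay, and at the producer-colony edge in the
colony-pair assay, where the edge is the half-maximum crossing of the
mCherry channel (`detect_producer_edge()`) standing in for manual edge
marks.

**Non-contacting colonies** never reach the full induced response, so their
own half-maximum is meaningless. Instead the YFP50 of contacting colonies —
averaged across all replicates, on the baseline-subtracted scale so it
transfers between colonies with different background expression — is carried
over as a reference, and the first valid crossing of that reference is
reported (`infer_dist50_noncontacting()`). Samples between the two colonies
are masked (`mask_gap()`) and a crossing that falls inside the masked gap is
flagged rather than extrapolated. The inference is only defined while the
profile maximum still exceeds the reference, i.e. for gaps comfortably below
λ·ln 2; larger gaps return a `reference above profile` flag.

Two safeguards gate degenerate input: a profile whose amplitude
(max − baseline) does not exceed `response_floor_k` (default 3) times the
raw tail SD is flagged `no response` instead of yielding a spurious dist50,
and a profile that never falls below YFP50 is flagged `no crossing`.

Because YFP50 is defined relative to baseline and maximum, dist50 is
invariant under affine intensity transforms — gain and offset drifts of the
microscope do not move it.

## The synthetic scenes

`scene_ground_truth()` fixes the generative model: toxin level `A` inside a
producer footprint and `A·exp(−(r−R)/λ)` beyond its edge — secretion with
first-order loss collapsed to a radial exponential. The radial exponential
was chosen over the 2-D Bessel-K₀ steady state for analytic tractability
(the half-max distance is exactly λ·ln 2 at zero baseline); λ keeps its
interpretation as a gradient decay length either way. Fields from several
colonies combine by maximum (switchable to sum), which keeps the
single-colony closed form exact near each colony. Rendering
(`render_scene()`, `render_colony_pair()`) adds the reporter response
(`b + g·T`), constitutive tags, zero-mean Gaussian noise, clipping at zero
and 16-bit quantization — enough to stress the smoothing and baseline logic
without modelling optics or camera physics (no PSF, no shot noise, no
colony growth; scenes are static snapshots).

Defaults are one set of plausible plate conditions, fixed once: 5 µm pixels
(the pixel calibration is mandatory, since magnification alone does not fix
µm/pixel), a 250 µm lawn-assay colony (200 µm in the pair assay), amplitude
× gain = 10⁴ intensity units over a baseline of 500, camera noise SD 50. In
the colony-pair simulation each colony draws its own decay length with an
8% log-normal CV — the colony-to-colony biological variability that makes
replicate means genuinely vary, so the replicate-level Welch test operates
at a realistic variance rather than at machine precision.

What passing tests on these scenes do **not** show: robustness to uneven
lawns, flat-field artefacts, colony autofluorescence structure, or manual
line-placement error. The generator emulates the geometry and noise of the
assays, not every nuisance of real plates.

## Flow cytometry

`sample_flow_events()` draws a labelled log-normal mixture: reporter
responders and non-responders, producers (10:1 producer:reporter by
default), low-scatter debris, doublets and PI-positive lysed cells. FSC-H
is drawn first and FSC-A follows it with a tight (0.02 log10 SD) ratio, so
doublets — which double FSC-A — are sharply separated in the FSC-H/FSC-A
ratio, as they are on a well-tuned instrument. Fluorescence spreads default
to 0.06 log10 units (≈14% CV, a tight, fixed and gated population); the
responder shift defaults to six such SDs.

Analysis mirrors the standard hierarchy: a scatter rectangle removes debris,
an FSC-H/FSC-A ratio band removes doublets (`apply_gates()`, with membership
always nested in the parent gate), two-colour classification assigns
reporter/producer by CFP and mCherry cutoffs (`classify_populations()`;
double-positive and double-negative events stay unclassified), and
positivity uses the conservative rule: cutoff = mean + 3 sample SDs of the
t = 0 reporter intensities (`compute_cutoff()`), strictly-greater
comparison so ties count negative, one cutoff reused for every time point
(`timecourse()`). Gate bounds are data-driven, not hard-coded: a
deterministic two-means split of the log10 intensities
(`intensity_split()`, initialized at the extremes) finds the valley between
two separated populations. That requires the reference sample to actually
contain both populations — on unimodal data the split is meaningless, which
is why the lysis assay sets its PE cutoff from pooled unstained and
heat-killed controls, never from the sample itself.

## Replicate statistics

Group comparisons use the two-tailed Welch unequal-variance t-test with
fractional Welch–Satterthwaite degrees of freedom (`welch_ttest()`), applied
to biological-replicate means (the per-replicate mean dist50, or
per-culture lysis percentages); the all-zero-variance corner returns p = 1
for equal means by convention. CFU back-calculation
(`cfu_per_ml()`) maps the 1:1 serial scheme to factor 2^k and pools plates
by raw-count weights (inverse-variance on the relative scale under Poisson
counting). Colony purity uses the exact one-sided Clopper–Pearson bound;
with zero producer colonies observed it reduces to `1 − 0.05^(1/n)`, the
exact rule of three.

## Numerical choices

* Off-grid sampling is bilinear (`extract_cross_section()`), the standard
  smooth choice, testable in closed form on a linear ramp; the sampling step
  defaults to one pixel equivalent so "samples" and "pixels" coincide.
* The smoothing window is counted in samples; its truncated-centred
  semantics multiply an exponential by a factor ≈ 1 + s²·step²/(2λ²)
  (s² the window's index variance), a sub-micrometre dist50 perturbation at
  1 µm sampling that grows with the step — estimates made at different
  sampling steps are comparable only within about half a window.
* Peak ties break toward the smallest distance; the crossing scan requires
  a strict drop below the level; alignment is idempotent and masking never
  alters intensities.
* Replicate averaging (`average_decays()`) resamples linearly onto the
  intersection of the profiles' ranges and flags distances supported by
  fewer than `min_n` profiles.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic data
at sizes chosen to make every stochastic check statistically comfortable
while staying quick on a laptop: single-colony scenes of 600×600 px (5 µm
pixels) for the lawn analyses, 3 replicates × 10 pairs per contact class
for the equivalence comparison, 10⁵-event tables for recovery checks and
10⁶ draws for the 3-SD calibration. The equivalence p-value is a true null
hypothesis test on three replicate means per group: its p is uniform by
construction, so individual simulated runs can and occasionally will dip
below 0.05 without indicating a defect.

## A worked run

```{r}
lawn <- run_lawn_assay(n_colonies = 3, decay_length = 100, step = 1,
                       seed = 11)
lawn$results[, c("scene_id", "baseline", "max_signal", "dist50_um")]
```

With λ = 100 µm the noise-free half-max distance is λ·ln 2 ≈ 69.3 µm; the
noisy estimates above sit within a micrometre of it.

```{r}
pairs <- run_colony_assay(n_replicates = 3, pairs_per_replicate = 10,
                          gap = 50, seed = 12)
pairs$group_summary
pairs$ttest
```

The contacting and non-contacting estimators agree to a few micrometres and
the Welch test does not reject equality — the contact-independence pattern,
reproduced in kind on data where it is true by construction.

## Known limitations

* No parametric decay fits (exponential or Hill): the metric is
  deliberately nonparametric, so no rate constants are estimated.
* No colony segmentation, registration, flat-field correction or spectral
  compensation; inputs are assumed registered single-field images and
  pre-scaled event tables.
* The non-contacting estimator is undefined when the gap exceeds the
  distance at which the profile falls below the contacting reference.
* `intensity_split()` assumes two separated populations; it will cut a
  unimodal population in half without warning.
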