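---
title: "Methods: variance-component PTV margins from cine portal imaging"
author: "dibhmargin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variance-component PTV margins from cine portal imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dibhmargin)
```

## The problem

During deep inspiration breath-hold (DIBH) irradiation of left-sided breast
cancer, the patient holds a deep breath to pull the heart away from the chest
wall while the beam is on. The residual motion and setup variation of the
chest wall determines how much the clinical target volume (CTV) must be
expanded into a planning target volume (PTV). `dibhmargin` implements the
full analysis chain for one measurement direction in the beam's-eye-view
plane:

1. **Tracking** — locate the chest-wall edge in every frame of a cine portal
   (EPID) image stream, relative to the reference position from the planning
   DRR, and convert it to a signed error in mm at the isocenter plane.
2. **Decomposition** — fit a nested random-effect model by REML to split the
   error variance into inter-patient, inter-fraction and intra-fraction
   components.
3. **Margin** — convert the components into effective systematic and random
   errors for `N` fractions and apply the van Herk margin recipe.

A synthetic-data module generates error traces, respiration-monitor traces
and portal-image-like frame stacks with known ground truth so that every
stage is testable without clinical data.

## The nested random-effect model

Each frame `k` of fraction `f` of patient `p` yields one signed error (mm):

    y[p, f, k] = M + a[p] + b[p, f] + e[p, f, k]

with independent `a ~ N(0, Sigma_pt^2)`, `b ~ N(0, sigma_fr^2)`,
`e ~ N(0, sigma_intra^2)`. Fractions are nested in patients: a fraction label
is only meaningful within its patient. The two tangential fields of a
fraction share the fraction effect — field is a provenance label, not a
variance level. `M` is the overall mean error; a value compatible with zero
indicates no systematic setup offset.

`varcomp()` maximizes the *restricted* likelihood, which removes the fixed
degrees of freedom consumed by `M` and therefore remains unbiased where
naive moment estimators are not, in particular on unbalanced data (frame
counts differ per fraction because breath-hold durations differ). REML is
also what the clinical analysis this package mirrors used.

### Numerical strategy

The restricted likelihood is evaluated from per-fraction sufficient
statistics (`n`, `sum y`, `sum y^2` per patient-fraction cell), reducing a
fit on hundreds of thousands of frames to arithmetic over a few hundred
cells: the covariance matrix of a patient is a fraction-block matrix plus a
rank-one patient term, and both the determinant and the quadratic forms have
closed forms in those statistics. Optimization is over log-variances
(enforcing positivity) with Nelder-Mead, a BFGS polish and coordinate-wise
Brent sweeps; the last step matters because the likelihood can be very flat
along a small component, and the package's tests require agreement with a
closed-form ANOVA oracle to 1e-6 on balanced designs. Starting values are
method-of-moments estimates truncated at a small positive floor.

**Boundary handling.** If a variance collapses toward zero (below `1e-7`
times the total variance, configurable via `control$boundary_tol`), the
model is refit with that component pinned to exactly zero and the better
restricted likelihood is kept; the component is reported as a boundary
estimate and its interval becomes one-sided. Data with literally zero
variance short-circuit to the exact limit (`M = y`, all SDs 0).

**Identifiability.** At least 2 patients, at least one patient with 2 or
more fractions, and at least one fraction with 2 or more frames are
required; violations raise explicit validation errors rather than returning
meaningless estimates.

### Confidence intervals

The clinical source names only "REML" for its intervals, so the CI
construction was a genuinely open choice. The package uses:

* **profile restricted likelihood** for the three SDs (default): the
  interval is the set of values whose profiled `-2 log RL` lies within
  `qchisq(level, 1)` of the minimum. This matches the convention of the
  mixed-model tooling ecosystem the source analysis used. Intervals are
  bounded below by 0, and a profile that never rises above the cutoff on
  the left is reported as `lower-at-zero`.
* **Wald** for the overall mean, `M +/- z * sqrt(1 / (1' V^-1 1))`. At the
  study design this reproduces the reported interval for `M` to the printed
  precision.
* a **parametric bootstrap** (percentile) as an option in
  `confint(..., method = "bootstrap")` for users who distrust the
  asymptotics at small patient counts.

With 25 patients the interval for `Sigma_pt` is much wider than those for
`sigma_fr` and `sigma_intra` — patients are the scarce replication unit —
and the package's tests assert exactly that qualitative ordering. Profile
intervals for variance components can undercover by a few percent at very
small patient counts (8 patients in the coverage test); the acceptance band
of 95% +/- 5% reflects that.

## Effective errors and the PTV margin

With a finite number of fractions `N`, inter-fraction variation does not
average away completely: its residual mean acts systematically. The
re-apportionment is

    Sigma_eff^2 = Sigma_pt^2 + sigma_fr^2 / N
    sigma_eff^2 = (1 - 1/N) * sigma_fr^2 + sigma_intra^2

and the margin is `2.5 * Sigma_eff + 0.7 * sigma_eff` (coefficients chosen
so that 90% of patients receive at least 95% of the prescription to the
CTV). The coefficients are arguments, not constants, so other recipes can
be explored. The margin is one-dimensional — along the measurement
direction in the beam's-eye-view plane — and the report says so explicitly
rather than implying an isotropic 3-D expansion.

At the component values 0.82 / 1.19 / 1.63 mm and `N = 16` this chain gives
`Sigma_eff = 0.872`, `sigma_eff = 1.996` and a margin of `3.578` mm. A
two-decimal report computed from *unrounded* REML estimates can print
3.59 mm; the package reports full precision and rounds only for display.

```{r margin}
margin_report(c(sigma_pt = 0.82, sigma_fr = 1.19, sigma_intra = 1.63),
              n_fractions = 16)
```

## Edge tracking

`detect_edge()` is a Canny-style detector restricted to a region of
interest (ROI) placed at isocenter level: Gaussian smoothing (default
`sigma = 1.5` px), central-difference gradients, non-maximum suppression
quantized to four directions, and hysteresis thresholding with thresholds
expressed as fractions of the maximum ROI gradient magnitude (defaults 0.2
and 0.5 — scale-free, so the same defaults work across contrast settings).
A frame with no surviving edge pixels returns a `no-edge` flag, never an
exception; `extract_trace()` excludes such frames from the error trace,
counts them in a quality report, and warns at stack level if more than half
the frames fail (threshold configurable).

When several candidate edges survive (e.g. a rib near the chest wall), the
candidate with the largest integrated gradient magnitude wins; near-ties
are broken toward the previous frame's position, else toward the reference
— a deliberate continuity prior for cine streams.

**Sub-pixel refinement** fits a parabola to the row-averaged gradient
magnitude profile around the winning column. The clinical accuracy
criterion is only "less than 1 pixel" on a static phantom; the parabolic
scheme achieves ~0.02 px SD on the synthetic phantom at default noise, so
the criterion is met with a wide margin.

**Geometry and conventions.** Pixel indices are 0-based with positions at
pixel centers (recorded in the on-disk sidecar). A detector displacement in
pixels maps to the isocenter plane as `px * pitch * 100 / SID` (distances
in cm, pitch in mm). Displacement toward deeper inspiration is positive;
`deep_direction = -1` flips the convention for fields oriented the other
way. For tilted fields the error is measured perpendicular to the field's
long axis; the implementation resamples the ROI along that direction
(bilinear interpolation) instead of rotating whole frames, which avoids
interpolating the full image. The printed clinical geometry contains an
internal inconsistency (an isocenter pixel "area" that cannot be reconciled
with the stated detector size, pixel count and SID), so geometry here is
always explicit configuration: detector pitch, SID and ROI travel with
every stack and the scaling formula is trusted over any printed constant.

## The synthetic-data generator

The generator's defaults are the stated study conditions, not tuning knobs:
25 patients x 16 fractions x 2 tangential fields; truth
`M = 0.30`, `Sigma_pt = 0.82`, `sigma_fr = 1.19`, `sigma_intra = 1.63` mm;
breath-holds of `20.4 +/- 1.7` s; abdominal amplitude 1.36 mm.

* **Frame counts.** The clinical source never states the cine frame rate.
  The package draws each field's frame count as
  `round(duration * rate)` summed over 2 breath-holds per field at 9.5 Hz —
  a plausible cine EPID rate chosen once so that the default design
  extrapolates to the study's analysed total of ~309,609 frames. Fixed
  counts (`frames_per_field`) are available for balanced designs.
* **Respiration traces** are breath-hold plateaus: a slow sinusoidal ripple
  with a weak second harmonic and small jitter, affinely rescaled so the
  realized amplitude (max minus min of position) is exact. Only the
  amplitude statistic is constrained by the source; the waveform shape is
  the package's own documented choice. Gating thresholds bracket the
  plateau with a 1 mm guard band.
* **Frames** contain a single oriented step edge rendered analytically as a
  blurred step (`pnorm` profile, blur floor 0.35 px so a "sharp" step is
  still resolvable at sub-pixel positions) plus additive white Gaussian
  detector noise (default contrast 8000 counts, noise SD 400, blur 1.5 px,
  16-bit range). Tests render small frames with the detector size scaled in
  proportion so the clinical pixel pitch (0.336 mm/px) is preserved —
  pixel-denominated results transfer unchanged, at a fraction of the cost.
* **Not modelled:** truncation of large excursions by beam-hold gating,
  within-breath-hold autocorrelation of frames, rib/heart confounders in
  the image, detector artefacts. A green round-trip test therefore
  establishes the tracker's behaviour on clean step edges with white noise,
  not on clinical anatomy; the intra-fraction interval width in particular
  would be optimistic if frames were strongly autocorrelated.

No TIFF codec exists in the supported R stack, so the package includes a
minimal uncompressed 16-bit multi-page TIFF reader/writer (verified against
an independent Python TIFF reader in development); stacks travel with a JSON
sidecar holding the geometry.

## Design decisions and limitations

* Field labels are carried but never modelled: the nested structure is
  patient then fraction then residual, and pooling the medial/lateral
  fields is implicit.
* Frames with undetectable edges are excluded and reported; the clinical
  source does not say how such frames were handled, so
  exclusion-with-reporting is this package's choice.
* The margin applies to one direction in the beam's-eye-view plane;
  3-D/rotational errors are out of scope.
* Dosimetric validation of the margin (coverage via dose recalculation) is
  out of scope.
* Simulation-based quantities in the test suite use fixed seeds and
  tolerances derived from closed-form sampling variances (3 standard
  errors), never tuned bands.
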