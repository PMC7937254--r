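# dibhmargin

Variance-component PTV margins from cine portal imaging during deep
inspiration breath-hold (DIBH) breast radiotherapy.

## What it does, and for whom

During DIBH irradiation of left-sided breast cancer the patient holds a deep
breath while the beam is on, pulling the heart away from the chest wall. How
well the chest wall actually holds still — across patients, across treatment
fractions, and within a breath-hold — determines the margin by which the
clinical target volume (CTV) must be expanded into the planning target
volume (PTV). This package is for medical physicists and radiotherapy
researchers who have (or want to simulate) per-frame chest-wall positions
from cine EPID streams and need a margin that does not overestimate the
systematic error the way the classic per-patient-mean recipe does.

The chain is:

1. **Edge tracking** (`detect_edge()`, `extract_trace()`): a Canny-style
   detector (Gaussian smoothing, gradient, non-maximum suppression,
   hysteresis) finds the chest-wall edge in each cine frame within an ROI at
   isocenter level, with parabolic sub-pixel refinement. Positions are
   converted to mm at the isocenter plane (`px * pitch * 100 / SID`) and
   differenced against the DRR reference position; deep inspiration is
   positive.
2. **Variance components** (`varcomp()`): REML fit of the nested
   random-effect model

       y[p,f,k] = M + a[p] + b[p,f] + e[p,f,k],
       a ~ N(0, Sigma_pt^2),  b ~ N(0, sigma_fr^2),  e ~ N(0, sigma_intra^2)

   giving the inter-patient, inter-fraction and intra-fraction SDs with
   profile-likelihood CIs (Wald for the overall mean M). Unbalanced designs
   are supported; the likelihood is evaluated from per-fraction sufficient
   statistics, so 300k frames fit in under a second.
3. **Margin** (`effective_errors()`, `ptv_margin()`, `margin_report()`):
   for N fractions,

       Sigma_eff^2 = Sigma_pt^2 + sigma_fr^2 / N
       sigma_eff^2 = (1 - 1/N) sigma_fr^2 + sigma_intra^2
       margin      = 2.5 Sigma_eff + 0.7 sigma_eff   (van Herk criterion)

   reported for one direction in the beam's-eye-view plane.

A synthetic-data module (`simulation_spec()`, `simulate_errors()`,
`simulate_rpm_trace()`, `render_frames()`) generates error traces,
respiration traces and portal-image-like frame stacks with known ground
truth, so the whole pipeline is testable offline. Stacks are written as
multi-page 16-bit TIFF plus a JSON geometry sidecar; traces as tidy CSV
(`patient_id, fraction, field, frame, time_s, error_mm`).

## Worked example

Simulate a study-scale data set (25 patients x 16 fractions x 200 frames)
at ground truth M = 0.30, Sigma_pt = 0.82, sigma_fr = 1.19,
sigma_intra = 1.63 mm, fit it, and compute the margin:

```r
library(dibhmargin)
d <- simulate_errors(simulation_spec(n_patients = 25, n_fractions = 16,
                                     frames_per_field = 100, seed = 1))
fit <- varcomp(error_mm ~ patient_id/fraction, d)
fit
#> Nested variance-component fit (REML)
#>   call: varcomp(formula = error_mm ~ patient_id/fraction, data = d)
#>   80000 observations, 25 patients, 400 patient:fraction cells
#>   overall mean M                     0.474 mm  [0.170, 0.778]
#>   inter-patient SD (Sigma_pt)        0.719 mm  [0.523, 1.019]
#>   inter-fraction SD (sigma_fr)       1.160 mm  [1.080, 1.249]
#>   intra-fraction SD (sigma_intra)    1.635 mm  [1.627, 1.643]
#>   (95% CIs: profile for SDs, Wald for M)

margin_report(fit, n_fractions = 16)
#> PTV margin from breath-hold variance components (all values mm)
#> Breath-hold error components
#>   Inter-patient (Sigma_pt)         0.72  (0.52 to 1.02)
#>   Inter-fraction (sigma_fr)        1.16  (1.08 to 1.25)
#>   Intra-fraction (sigma_intra)     1.63  (1.63 to 1.64)
#>   Overall mean (M)                 0.47  (0.17 to 0.78)
#> Effective errors at N = 16 fractions
#>   Effective systematic (Sigma_eff)   0.78
#>   Effective random (sigma_eff)     1.98
#> PTV margin                         3.33   (= 2.5 Sigma_eff + 0.7 sigma_eff)
#> Scope: one direction in the beam's-eye-view plane (not isotropic 3-D)
```

Reading the output: the estimated SDs land near the simulation truth (each
within its sampling spread — with only 25 patients, Sigma_pt is the noisy
one); the 95% interval for Sigma_pt is visibly the widest, since patients
are the scarce replication unit. The effective errors re-apportion the
inter-fraction SD between systematic and random roles for N = 16 fractions,
and the final line is the one-dimensional PTV margin in mm.

The image path works the same way from rendered frames:

```r
img <- synthetic_image_spec(frame_shape = c(256, 256),
                            detector_size_cm = 43 * 256 / 1280)  # 0.336 mm/px
stack <- render_frames(img, per_frame_offsets_mm = c(-0.5, 0, 0.8), seed = 1)
extract_trace(stack)$error_mm        # recovers the offsets to ~0.005 mm
```

A file-based pipeline (`cmd_simulate()`, `cmd_track()`, `cmd_fit()`,
`cmd_margin()`, `cmd_pipeline()`) chains these stages through CSV/TIFF/JSON
on disk, configured by a single JSON file; `inst/cli/dibh-pipeline.R` is a
thin Rscript wrapper exposing the same five subcommands from a shell.

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline numbers from
scratch against the installed package: the effective systematic and random
errors and the PTV margin from the component SDs 0.82 / 1.19 / 1.63 mm at
N = 16; the REML recovery of all three SDs on a freshly simulated
25 x 16 x 200-frame data set; and the static-phantom stability (SD in
detector pixels) of the edge detector over a 100-frame stack. Run it as:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The `--seed` flag drives every random draw; the output is a small JSON map
of named values.
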