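# eegtemplates

Template-based EEG source localization for functionally defined visual
areas.

## The problem

EEG has excellent temporal resolution but the scalp signal mixes the
activity of many cortical areas, and attributing it to brain sources
normally requires an individual head model built from each participant's
MRI/fMRI scans — expensive, slow, and impossible for already-collected
data.  The template approach sidesteps this: the expected scalp
topography of each functionally defined region of interest (ROI) is
averaged across many individuals' forward models ahead of time.  Those
across-participant average topographies — *EEG templates* — can then be
fitted to any group-averaged EEG recording, without any scans for the
new participants.

`eegtemplates` implements the full workflow for 18 visual ROIs (V1, V2v,
V2d, V3v, V3d, V4, V3A, LOC and MT, each per hemisphere):

* **Montages** — SFP-style electrode file I/O, a dense idealized
  10-05-style master montage, least-squares affine alignment on the 19
  classic 10-20 anchor electrodes, average/label re-referencing, and
  fitting templates to arbitrary montages (`customize_templates()`).
* **Synthetic head-model population** — per-participant lead fields from
  the analytic three-concentric-sphere model (brain/skull/scalp
  conductivities 0.33/0.025/0.33 S/m), with ROI caps near the occipital
  pole, mirrored across hemispheres, and von Mises–Fisher jitter of
  anatomy between participants.  Everything downstream is testable
  without any real MRI data.
* **Templates** — per-participant ROI topographies, cross-participant
  averaging, CSV (+ JSON sidecar) template files, and the 1/N sampling
  variability analysis.
* **Inverse solution** — Tikhonov (ridge) regularization computed along
  a λ-grid from one SVD of the design, with the coefficients `B(λ)`
  given by filter factors `d_i²/(d_i² + λ²)`; λ selected by the L-curve
  corner (analytic curvature), generalized cross-validation, a
  truth-informed optimal selector for simulations, or fixed.  One shared
  λ across all time samples; regularization is applied to the *group
  average*, not per participant.  The three individual-model comparison
  methods (whole-brain, ROI-subset, ROI-oracle) are included.
* **Simulation battery** — seeded ERP-like waveforms (baseline −45–0 ms,
  response 0–45 ms, peak amplitude uniform in 1–10), the SNR definition
  `SNR = (RMS(signal+noise)/RMS(noise))² − 1`, calibrated white or
  lead-field-correlated noise, participants drawn with replacement,
  interfering non-visual sources, and crosstalk matrices.
* **Evaluation** — two-class Hand–Till AUC (ties ½), relative energy,
  normalized MSE, bootstrap group inference (percentile CIs over
  participant resamples) and condition permutation tests.
* **Experiments** — factor grids over SNR ∈ {0.1, 1, 10, 200, 10000},
  group size ∈ {2, 8, 20, 50}, montage size ∈ {32, 64, 128, 256} and
  number of simultaneously active bilateral ROIs, plus interference and
  partial-V1 drivers.

## Worked example

```r
library(eegtemplates)

# a 20-participant synthetic population on a 32-electrode montage
mon <- montage_subsets(master_montage(), 32)[["32"]]
cfg <- population_config(n_sources = 500, montage = mon)
pop <- make_population(20, cfg, seed = 1)

templates <- build_templates(pop)
#> <eeg_templates> 32 electrodes x 18 ROIs (averaged over 20 participants, reference: average)

# simulate a bilateral V1 + MT response at a realistic SNR of 10
active <- c("V1-L", "V1-R", "MT-L", "MT-R")
ds <- simulate_group(pop, sim_config(active, snr = 10,
                                     n_participants = 20, seed = 2))
#> <simulated_dataset> 20 participants, 32 electrodes x 91 samples; active: V1-L, V1-R, MT-L, MT-R; SNR 10

# template method: ridge fit of the group average, L-curve selection
fit <- fit_templates(templates, ds$group_avg, selector = "lcurve")
#> <eeg_fit> method template (lcurve selector, lambda 145.4): 18 ROIs x 91 samples

evaluate_fit(fit, ds$truth)
#> <metrics_report> AUC 0.834 | relative energy 0.652 | normalized MSE 0.035 (active: V1-L, V1-R, MT-L, MT-R)
```

The AUC says how well absolute recovered activity separates the four
truly active ROIs from the fourteen silent ones during the response
interval (1 = perfect, 0.5 = chance); relative energy is the fraction of
recovered (per-time-normalized) energy landing inside the active set;
normalized MSE compares the unit-normalized recovered and true ROI
activity profiles.  With 50 participants and 128 electrodes (the
package defaults at study scale) the same regime reaches a mean AUC above
0.9 over 30 simulations.

A command-line interface covering fitting, template customization,
simulation, evaluation and bootstrap inference is in
`inst/cli/eegtemplates.R`; see `?cli_main`.

## Vignette

`vignettes/template-source-localization.Rmd` documents the model, its
assumptions, the synthetic-population design, the numerical choices in
the regularization path, and what the synthetic results do and do not
imply about real recordings.
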