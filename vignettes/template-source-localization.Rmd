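---
title: "Template-based EEG source localization: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based EEG source localization: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegtemplates)
```

## The model

Scalp EEG is, to an excellent approximation, a linear superposition of
cortical dipole sources: a participant's *lead field* $L$ maps source
amplitudes to electrode voltages.  For a functionally defined region of
interest (ROI) $r$, the scalp pattern of unit activation is the sum of
the lead-field columns of the sources inside the ROI; averaging that
pattern over many participants gives the **EEG template** $T_{\cdot r}$.
Given templates for $p$ ROIs and a group-averaged recording
$Y \in \mathbb{R}^{E \times S}$ ($E$ electrodes, $S$ samples), the ROI
contributions $B \in \mathbb{R}^{p \times S}$ solve a regularized least
squares problem

$$\hat B(\lambda) \;=\; \arg\min_B \;\lVert Y - T B\rVert_F^2
  \;+\; \lambda^2 \lVert B \rVert_F^2 .$$

Although only 18 sources are fitted from 32–300 electrodes (a formally
well-posed problem), the template matrix is badly conditioned — nearby
visual areas project almost identical patterns to the scalp — so at
realistic noise levels the unregularized solution amplifies noise and
regularization is essential.

**Convention.**  The penalty weight enters squared, so the SVD filter
factors are $d_i^2/(d_i^2+\lambda^2)$ and $\lambda$ has the units of a
singular value of the design.  Texts that write the penalty as
$\mu\lVert B\rVert^2$ have $\mu = \lambda^2$.

### Key assumptions

* Sources are fixed-orientation dipoles; ROI activation means all of an
  ROI's sources active with a common unit moment ("full ROI
  activation").
* The across-participant average topography represents the group; the
  method is built for group-level analyses, not individuals.
* The recording and the templates share the montage and the reference
  (the package applies/verifies the average reference in the target
  electrode space).
* Noise is zero-mean and, for the selectors' assumptions, roughly
  homogeneous across the group average; no pre-whitening is performed.

### Why regularize the average, not the individuals

Regularization is nonlinear: selecting $\lambda$ on each participant and
averaging the fits is not the same as fitting the (much cleaner) group
average once.  Per-participant shrinkage scales inversely with noise, so
noisy participants are shrunk harder and quiet participants dominate the
average.  The template method therefore fits the group average with a
single $\lambda$; the package's test suite includes a heterogeneous-noise
fixture on which the two pipelines measurably disagree.

## Choosing the regularization weight

`ridge_path()` computes, from one SVD, the full path of pooled residual
norms, solution norms, effective degrees of freedom, GCV values, and the
analytic curvature of the log–log L-curve.

* **Grid** — 200 logarithmically spaced $\lambda$ spanning
  $[10^{-6}\sigma_{\max},\,10\,\sigma_{\max}]$ of the design: filter
  factors are all $\approx 1$ at the bottom and all $\approx 0$ at the
  top, so the grid brackets both limits.
* **Multi-sample pooling** — one shared $\lambda$ across samples;
  residual/solution norms pool as root-sum-of-squares.  This is the
  simplest pooling consistent with treating an ERP's time samples
  jointly; complex (frequency-domain) data is handled by stacking real
  and imaginary parts as extra samples, keeping the solver real.
* **GCV** — $\mathrm{GCV}(\lambda) = \mathrm{RSS}(\lambda) /
  (E - \sum_i f_i(\lambda))^2$ with the filter-factor trace as effective
  degrees of freedom.  GCV assumes independent residuals across
  electrodes; template residuals are spatially correlated, which can
  bias GCV toward under-smoothing, so GCV is the default only for the
  individual-model methods (where it behaves well) and the L-curve for
  the template method.
* **L-curve** — the corner is the global maximum of the signed curvature
  of $(\log \lVert r \rVert, \log \lVert B \rVert)$, computed
  analytically from the SVD quantities (no finite differences); ties
  break toward more regularization.  A degenerate monotone path falls
  back to the maximum-curvature endpoint with a warning.  Note the
  corner is invariant to rescaling the data: scaling $Y$ scales both
  norms equally and only translates the log–log curve.
* **Optimal selector** — in simulations the true coefficients are known,
  so `optimal_select()` scans the grid for the MSE-minimizing $\lambda$;
  it bounds what any data-driven selector could achieve on that grid.
* **Degenerate inputs** — all-zero data yields the zero fit at the top
  of the grid; flat GCV warns and takes the largest $\lambda$.

## The synthetic population

The package ships no human data.  `make_population()` generates
per-participant forward models from the closed-form three-concentric-
sphere dipole solution (Legendre series, truncated at 120 harmonics
where the next 120 terms change nothing at 8 digits; an analytic
homogeneous-limit oracle pins the implementation).  Default radii are
80/86/92 mm and conductivities 0.33/0.025/0.33 S/m for brain, skull and
scalp.  Sources sit on a cortical sphere at 0.85 of the brain radius
with outward-normal orientations.

The 18 visual ROIs are spherical caps (12° angular radius, ≈ a fifth of
the cortical sphere jointly, before overlap) around canonical directions
near the occipital pole, mirrored across the sagittal plane.  The cap
layout is a deliberate caricature of visual cortex chosen to reproduce
the structure that makes the problem interesting:

* the ventral trio V2v/V3v/V4 sits 11–15° apart, so their templates
  correlate above 0.95 and form the "hard to separate" regime;
* V1 lies near the pole with ~20° between hemispheres;
* dorsal areas (V2d/V3d/V3A) sit above, LOC/MT lateral and anterior;
* eight non-visual caps (frontal, orbitofrontal, temporal,
  parahippocampal, bilateral) provide interfering sources that the
  templates do not model.

Between-participant variability enters through von Mises–Fisher jitter
of every cap centroid (concentration 200, ≈ 4° angular sd), vMF jitter
of each source orientation around the surface normal (concentration 50),
and a common lognormal jitter of the shell radii (2% sd).  All
randomness flows from one integer seed through a documented splitting
scheme (`child_seed()`), so any participant can be regenerated
independently and bitwise.

**What the generator does not emulate**: cortical folding (the source
surface is a sphere, so there is no sulcal orientation flipping and no
paradoxical lateralization), skull anisotropy and thickness variation,
heterogeneous ROI sizes, digitization error in electrode positions, and
physiological noise (alpha rhythms, muscle, line noise — noise is
Gaussian, white or lead-field-correlated).  Consequently, passing
simulations demonstrate the correctness and statistical behaviour of the
*procedure* — calibration of SNR, selector behaviour, leakage structure,
bootstrap coverage — not the anatomical accuracy of any particular
template set for real heads.

## The simulation battery

ERP-like sources are zero on a −45–0 ms baseline and follow a seeded
asymmetric raised-cosine bump over 0–45 ms (1 kHz sampling → 91
samples), with peak amplitude uniform in [1, 10]; one waveform is shared
by all active ROIs of a simulation and all participants.  SNR is defined
as $(\mathrm{RMS}(s+n)/\mathrm{RMS}(n))^2 - 1$ over electrodes and time;
noise is scaled so the target is met in expectation (calibration is
verified to 2% in the tests).  Correlated noise is white noise in source
space projected through the participant's own lead field.  Participants
are drawn from the population with replacement.  An interferer is a
non-visual cap with its own waveform scaled to half the visual peak, so
the instantaneous strength ratio varies over time.

Recovery is scored at the time points where at least one true source is
active: during a silent baseline the active/inactive classes carry no
signal and any recovered activity is noise, so including those samples
would cap the AUC of even a perfect method near 0.75.  The per-time
breakdowns retain all samples.

## Statistical inference

`bootstrap_significance()` resamples participants with replacement,
refits the templates on each resampled average (500 replicates by
default), and flags an ROI active wherever the percentile 95% interval
excludes zero — per cell, no multiple-comparison correction (a
Bonferroni flag exists, off by default).  On null data the false-flag
rate sits near the nominal 5% (slightly above with few participants, as
percentile intervals run anticonservative).  For paired condition
contrasts, `permutation_test_conditions()` swaps condition labels within
participants and uses the per-ROI maximum absolute difference as the
statistic.

## Numerical choices and tie-breaks

* Series solves for the shell gains are row/column equilibrated (the two
  radial basis functions span ~14 orders of magnitude at harmonic 120)
  and memoized per geometry ratio.
* Nearest-position electrode matching uses a 10 mm threshold after
  anchor-based affine alignment and fails loudly beyond it; ties take
  the smallest template index.  Re-referencing happens after
  subsetting, because the average-reference projector depends on the
  electrode set.
* ROI source pooling uses the sum of per-source coefficients (consistent
  with forward pooling of unit dipoles); mean pooling is available.
* V1 subdivides at the median source depth (ties ventral); subdivided
  labels score at the parent V1.
* Empty ROI topography is a zero vector with a warning, not an error.
* Desk-scale defaults: 1000 sources/participant and populations of
  10–50 keep a full population build under a minute and the entire grid
  reproduction in minutes on one CPU; full-scale source counts are
  config-reachable (`population_config(n_sources = ...)`).

## Known limitations

* Templates are un-normalized by design: large ROIs (V1) legitimately
  produce stronger patterns, which means comparing *amounts* of activity
  across ROIs is unreliable — asking whether an ROI is active (AUC-style
  questions, bootstrap flags) is the supported use.
* The spherical geometry makes left/right homologue templates more
  similar than real anatomy would; crosstalk between hemispheres is
  therefore, if anything, overstated.
* The sampling-variability analysis estimates the grand mean from a
  large but finite reference sample (2000 surrogates), which flattens
  the 1/N curve slightly at the largest N.
* GCV can select near-zero regularization when its independence
  assumption is badly violated; the L-curve default for template fits is
  the robust choice.
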