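---
title: "Decoding working-memory load from whole-head fNIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding working-memory load from whole-head fNIRS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsload)
```

## The experimental model

`nirsload` analyzes (and simulates) a speed-regulation n-back paradigm:
a driver passes a speed sign every 20 s and must drive at the speed
shown *n* signs earlier, with the n-back level (0–4) varied in blocks of
ten trials. A session is 2 repetitions × 5 levels × 10 trials = 100
trials, block order pseudorandomized under the constraint that the same
level never occurs in consecutive blocks, sign speeds drawn in
randomized order from the nine-value grid 60–140 km/h. The first *n*
trials of a block have no n-back target yet; the participant drives at
the block's first sign speed, and the generator encodes exactly that
rule. Each block is preceded by a 5 s level announcement that belongs to
no trial.

The induced working-memory load is therefore a known step trace over the
session, and decoding quality is summarized by the Pearson correlation
`r_mvr` between this induced trace and the cross-validated prediction,
evaluated sample by sample.

## Forward model (what the generator emulates)

Ground-truth HbR on channel *c* is

```
hbr_c(t) = -L_c * A * (level ⊛ h)(t) + artifacts_c(t) + noise_c(t)
```

where `L_c ∈ [0,1]` is the loading map (default: 1 on the bilateral
inferior-frontal and temporo-occipital channel groups, 0.3 on the
forehead channels, 0 elsewhere), `A` the response amplitude per level
unit, and `h` a canonical double-gamma HRF (peak 6 s, undershoot 16 s,
ratio 1/6) normalized to unit sum so that a sustained level-*L* block
drives a steady-state response of `L·A`. The sign convention is the
physiologically standard one — activation *lowers* HbR — and every
decoder is sign-agnostic because linear weights absorb the sign. HbO is
the sign-flipped counterpart scaled by `hbo_ratio` (default 2) with
independent artifact/noise draws.

Raw two-wavelength intensities follow the forward modified Beer–Lambert
relation `I = I0 · 10^-ΔOD` with
`ΔOD(λ) = (ε_HbO(λ)·ΔHbO + ε_HbR(λ)·ΔHbR) · d · DPF(λ)`, so the
analysis-side inversion is its exact left inverse (the round trip is
checked to ≤10⁻⁹ relative error in the tests). Bad channels are modeled
by adding intensity-domain noise targeting a ~35% coefficient of
variation, which the 20% CV screen must reject.

Default amplitudes (mol/l; 1e-6 = 1 µM) were chosen once as
representative of single-trial fNIRS, where physiological artifacts
rival or exceed the response: response 0.1 µM per level unit, cardiac
0.15 µM at ~1.1 Hz, respiration 0.1 µM at ~0.3 Hz, Mayer waves 0.15 µM
at ~0.1 Hz, drift 0.25 µM below 0.01 Hz, white noise SD 0.2 µM. The
cardiac frequency exceeds the 0.978 Hz Nyquist rate of the 1.955 Hz
system, so it is generated on an 8× oversampled grid and decimated by
sample selection — it aliases exactly as real acquisition would.

**What the generator does not emulate.** Channel noise is white and
spatially independent, whereas real systemic physiology is correlated
across channels and non-stationary; there is no motion-spike modeling
beyond bad-channel variance inflation, no photon-transport optics, and
no workload contribution from the concurrent driving itself. The
practical consequence is that whole-head decoding of synthetic
recordings is *easier* than of real ones (spatial pooling averages
independent noise very effectively), so passing decoding tests
demonstrates correctness of the machinery, not field performance; the
published whole-head mean correlation on human data was far below what
the simulator yields at default settings, and the frontal-restriction
comparison in the tests relies on the direction of the effect, not its
published magnitude.

## Preprocessing

* **Optical density** uses the whole-session mean intensity as the
  per-channel reference (the baseline is otherwise unspecified in this
  paradigm, which has no rest periods); a known baseline can be supplied
  instead, and with the forward model's emitted `I0` the inversion is
  exact rather than exact-up-to-a-constant.
* **Beer–Lambert constants**: ε₇₆₀ = [1486.59, 3843.71],
  ε₈₅₀ = [2526.39, 1798.64] M⁻¹cm⁻¹ (Gratzer spectrum), DPFs 7.25 and
  6.38. The source phrasing attaches the two DPFs to the chromophores,
  but a differential path-length factor is physically a per-wavelength
  quantity, so the package binds 7.25→760 nm and 6.38→850 nm; both are
  configurable.
* **Filtering**: the 0.1 Hz low-pass is a type-I (odd, symmetric) FIR
  designed by closed-form least squares against an ideal response with a
  0.05–0.15 Hz transition band at fs = 1.955 Hz, default 77 taps, DC
  gain normalized to 1. Edges are reflect-padded and the symmetric
  filter is applied centered, so the output is delay-compensated; edge
  samples are additionally covered by the ±3 s trial guard.
* **Channel QC**: CV is computed per wavelength on unfiltered raw
  intensity over the whole recording; a channel is rejected when
  *either* wavelength exceeds 20%. A zero-mean channel gets infinite CV
  and is rejected, not errored.
* **Sample sets**: each retained sample is labeled with its trial's
  level across the whole trial (the 3 s speed-adjustment transitions are
  handled by exclusion, not relabeling); samples within ±3 s of any sign
  passage, samples outside every trial (announcements, tail), and — by
  default — all samples of incorrect trials are excluded, each with a
  bookkept reason. Units are mol/l internally; mmol/l is a reporting
  convention at I/O boundaries.

## Decoding

PCA-truncation denoising (eigen-decomposition of the training
covariance, first *k* components kept, back-projection into channel
space) is followed by lasso regression, both inside a nested
cross-validation:

* **Fold granularity is the trial.** Instantaneous samples within a
  trial are strongly autocorrelated; sample-level folds would let
  near-duplicate neighbors straddle the train/test split and inflate
  generalization estimates. Assigning whole trials to folds is a
  deliberate strengthening over leaving the construction unspecified.
* **Hyperparameters** (k, λ) are selected per outer fold by an inner
  10-fold CV on the training trials only, maximizing the Pearson
  correlation of pooled inner-validation predictions; k and λ are
  searched jointly on a grid. The k grid is
  {1, 2, 3, 5, 8, 12, 17, 25, 35, 50, all}; the λ grid holds 50
  log-spaced values from the training λ_max down to 10⁻³·λ_max
  (standard regularization-path practice). Ties prefer the smallest k,
  then the largest λ — the most parsimonious model.
* **Numerical conventions**: features are standardized with
  training-fold statistics inside glmnet (coefficients returned on the
  original scale); each principal component's largest-magnitude loading
  is made positive, a pure reproducibility convention; predictions are
  not post-smoothed before correlating. The single-feature lasso is
  solved by the exact coordinate soft-threshold formula because glmnet
  requires at least two columns; tests pin both routes to their closed
  forms (OLS at λ = 0, soft-threshold for p = 1).
* The peripheral comparison decoder applies the identical machinery to
  the two-dimensional trial-wise (heart rate, RMSSD) feature space with
  k ∈ {1, 2}.

## Mapping

Per-channel univariate Pearson correlations between HbR samples and the
induced level double as single-predictor regressions (identical up to
the slope's sign, which the signed r carries). The group map weights
each participant's channel map by their multivariate decoding
correlation and requires positive weights: the weighted-mean formula is
undefined for mixed-sign weights, and in the motivating data all
per-participant correlations were positive. Per-channel p-values are
unadjusted two-sided by default (no multiplicity correction was applied
in the original analysis); Benjamini–Hochberg is available by option.

## Behavioral and cardiac statistics

Trial parameters follow the task's operational definitions: time in the
±5 km/h target band excludes the 3 s post-sign transition; reaction time
is the time from the sign passage until the speed enters the band *and
stays inside it* until trial end, computed on correct trials only; lane
deviation omits lane-change phases, detected as samples whose absolute
lane offset exceeds a configurable 1.75 m threshold; heart rate and
RMSSD are computed per ~20 s trial from the RR intervals it covers.
Outlier screening removes, per participant and parameter, trials more
than 3 SDs from the participant mean.

The trend test is a maximum-likelihood linear mixed model
`parameter ~ level` with random intercepts for participant, trial
number and target speed (each encoded as a grouping factor with one
intercept per distinct value), a likelihood-ratio χ² against the
level-free model, Satterthwaite denominator df and t from lmerTest, and
`r = √(t²/(t²+df))` signed like the slope. When the full random
structure cannot be fitted, grouping factors are dropped (target speed
first) with a warning, and a residual-df fallback is labeled in the
output.

**Generator parameters for the behavioral arm.** Baselines are the
0-back condition means (e.g. heart rate 73.8 bpm, RMSSD 39.5 ms, time in
range 92.3%) and slopes the published per-level effects (+0.89 bpm,
−1.24 ms, +0.23 s, −6.6 percentage points). Between/within SD splits
decompose the published totals where feasible (heart rate 12 + 2.2 bpm;
RMSSD 16 + 5.8 ms ≈ the printed 17 ms total). Participant intercepts are
drawn from a *truncated* normal so that every per-level mean stays a few
residual SDs inside the parameter's physical bounds (RMSSD ≥ 0, time in
range ≤ 100%): truncating the intercept distribution leaves the
fixed-effect slope unbiased, whereas clamping generated values at the
bounds would attenuate it. Time-in-range uses small SDs (1.0 between,
1.5 residual) because its 0-back mean sits near the 100% ceiling and the
printed per-level SDs for this parameter are internally inconsistent.
Per-level correctness probabilities (0.99, 0.97, 0.93, 0.88, 0.83)
decline with level; the resulting ~8% incorrect-trial rate is an
emergent default, not a constraint.

## Problem sizes used by the tests

Module tests run on 30-trial sessions (5 levels × 3 trials × 2
repetitions) with reduced hyperparameter grids; the slope-recovery
checks use 20 replicates of 12 participants × 100 trials; decoding
property checks use the full 100-trial session for the
permutation-null and frontal-comparison tests and 30-trial sessions
elsewhere; the type-I-error check of the trend test uses 120 null
simulations of 6 participants. These sizes were chosen to make
Monte-Carlo error small relative to the asserted margins while keeping
the default suite fast.

## Known limitations

* The montage is a synthesized stand-in honoring the published
  constraints (78 channels, frontal + parieto-temporo-occipital
  coverage with a somatomotor gap, mean 3.5 cm separations < 4 cm,
  12-channel forehead subset); the true emitter–detector pairing is not
  public.
* HbO-based decoding is generated but not analyzed (the motivating
  analysis used HbR only, as HbO showed drifts under the no-rest
  paradigm); no short-separation regression, wavelet motion correction
  or spline detrending; no temporal integration windows or nonlinear
  link functions.
* Response amplitudes per level in concentration units are unpublished;
  they are free generator parameters, and all decoding-performance
  statements in the tests are therefore relative (recovery, ordering,
  null behavior), not absolute claims about real recordings.
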