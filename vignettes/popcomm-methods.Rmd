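---
title: "Models and methods in popcomm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in popcomm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

popcomm studies a single scientific question with a family of related
models: how much of a neuron's sound-evoked response, at successive
stations of the ascending auditory pathway (inferior colliculus IC, medial
geniculate body MGB, primary auditory cortex A1), can be captured by a
linear function of the stimulus, and how much more becomes capturable when
the responses of other neurons — which have already passed through the
pathway's nonlinearities — are used as predictors instead. This vignette
documents the models, the estimators, the synthetic data generator used to
validate everything, and the design decisions taken where the methods left
choices open.

## Stimulus representation

Dynamic random chords (DRCs) are sequences of 25 ms chords; each chord
contains all 25 grid frequencies (1–64 kHz, quarter-octave spacing), each
at an independently drawn uniform level: 30–50 dB SPL in the low-contrast
condition, 20–60 dB SPL in high contrast, mean 40 dB SPL in both. The
package works entirely at the level of this chord-by-frequency dB matrix
(the cochleagram); waveforms, onset ramps and speaker calibration are
hardware concerns with no bearing on the analyses. Levels are drawn
independently across chords and frequencies, so the spectrogram is
uncorrelated at the analysis resolution and regression estimates are free
of stimulus-correlation bias. Repeats of the same ("frozen") chord
sequence provide trial-to-trial variability; trials are concatenated with
explicit boundary indices rather than simulated inter-trial gaps.

## The linear-nonlinear pipeline

Every trial-averaged model is the same two-stage pipeline, differing only
in its inputs.

**Linear stage.** The input matrix (cochleagram, or source-population
PSTHs) is tensorized: an extra lag dimension holds the input `h` bins away
at each time. STRFs use 13 history steps (0 to −12, 325 regressors); PCMs
use 8 history and 5 future steps per source unit. Negative offsets are
past samples; offsets are kept sorted ascending. Future lags exist so that
a PCM predicting a *short*-latency target from *long*-latency sources is
not handicapped by latency differences — important for judging descending
(A1 → IC) models fairly. Lag windows are zero-padded at every trial
boundary *and* at every cross-validation segment boundary, so the test
segment never leaks into training rows through the lags (a canary test
asserts that corrupting test-segment responses changes no fitted
parameter). Weights minimize mean-square error against the PSTH subject to
an L2 penalty; the solution is computed in closed form from an SVD of the
centered training design, which also lets one decomposition be shared by
every unit fitted on the same design — this is what makes population-scale
fitting cheap.

**Penalty selection.** The grid is logarithmic, 1e-4 to 1e4 in 17 steps.
The validation slice is the last 20% of the training bins (contiguous, so
it respects the temporal structure); the model is refitted on all training
bins at the selected penalty. The stimulus is divided into 16 equal
contiguous segments (15 in the silencing analyses); the last segment is
the default held-out test set, and a full fold sweep is available.

**Output nonlinearity.** A four-parameter logistic
`y = a + b/(1 + exp(-(z - c)/d))` is fitted to the linear output by
gradient descent on MSE (initialization `a = min(y)`, `b = range(y)`,
`c = median(z)`, `d = sd(z)/4`; adaptive step size, iteration cap 1000,
early stop at relative MSE change 1e-8; descent runs on standardized `z`
for conditioning). If descent cannot match the best affine map of `z`, an
affine-equivalent parameterization (very large `d`, so the curve is linear
over the data range) is substituted and flagged — the fit therefore never
loses to a plain linear readout.

**Evaluation.** Performance is the normalized correlation coefficient
`CC_norm = CC_abs / CC_max` on the test segment, where
`CC_max = sqrt(SP / Var(PSTH))` and the signal power `SP` is the unbiased
trial-to-trial estimator `SP = (N Var(PSTH) - mean_d Var(y_d)) / (N - 1)`
(population-variance convention, so `SP + NP/N = Var(PSTH)` holds
exactly). The estimator variant is validated by calibration rather than
formula matching: predicting simulated Poisson units with their own
generative rate yields median CC_norm = 1 within ±0.05 at 64 trials.
Units are included when their noise ratio `NR = NP/SP` is below 200;
`CC_norm` is reported unclipped, but population medians exclude units with
`CC_max < 0.05` (configurable floor) to avoid division blow-ups, and
Pearson correlations of constant sequences are defined as 0. For
silencing comparisons, `CC_max` is computed separately per condition so
reliability changes do not masquerade as model changes.

**Model variants.** PCM source populations contain all qualifying units
from *other* penetrations (different electrode insertions), because units
recorded simultaneously share trial-to-trial noise that would inflate
apparent communication. Source PSTHs enter raw (no standardization by
default; a flag exists, recorded in the training record, since ridge
shrinkage is scale-sensitive). The two-stage model fits STRFs to every IC
unit, predicts their responses, and fits a PCM from those *modeled*
responses; substituting perfect stage-1 responses makes it identical to
the direct PCM, which is asserted in a test. A PCM-based stage-1 variant
is available behind a flag. NRFs are single-hidden-layer logistic networks
(2–16 hidden units) trained on MSE with nnet; both the hidden-layer size
and the weight-decay strength are selected on the validation slice —
decay selection is essential, as an unregularized 325-input network badly
underfits this data regime.

## Single-trial Poisson GLM with spike coupling

At 5 ms resolution, a unit's spike count is modeled as Poisson with log
rate equal to a sum of: the sound-level history of the most recent 125 ms
(25 lags; frequency-resolved by default, or summed over frequency), the
unit's own spike history convolved with 7 basis functions spanning 100 ms,
and each same-penetration partner's spikes convolved with 12 basis
functions spanning 250 ms. Bases are one-hot deltas at 5 and 10 ms
followed by log-spaced raised cosines
`B_j(tau) = 0.5 (1 + cos(pi * clip((log(tau+1) - phi_j)/w, -1, 1)))` with
peaks ending at 150 ms (coupling) / 50 ms (history) and width equal to the
log-domain peak spacing, so adjacent functions cross at half height. All
spike regressors start at a one-bin lag — nothing at lag zero or in the
future — so coupling terms are strictly causal by construction. Fits use
glmnet's penalized Poisson regression (ridge, `alpha = 0`, by default;
configurable), training on 5 concatenated single trials with the penalty
chosen by Poisson deviance on the last training trial, and evaluating
plain Pearson correlation on 2 held-out trials (single-trial variability
is the object of interest here, so no reliability normalization).
Time-domain filters are reconstructed by multiplying each basis function
by its fitted coefficient and summing; projection onto the basis is the
exact left inverse of reconstruction. Filter change across conditions is
summarized as one minus the Pearson correlation of the reconstructed
filters, with a refit-jitter null available from split-seed refits;
excitatory/inhibitory mass is integrated separately over fast (< 10 ms)
and slow (≥ 10 ms) lags.

## The synthetic population generator

Nothing in the package requires recorded data: a hierarchical generator
produces populations whose statistical structure matches what the analyses
assume, with known ground truth.

* **IC-like units** are LN in ground truth: a gammatone-like kernel
  (Gaussian frequency tuning whose best frequencies tile the grid,
  biphasic temporal profile) drives a threshold-linear output; thresholds
  sit at the 30th–55th percentile of each unit's drive, so rectification
  is substantial but the units remain LN — real midbrain units are well,
  though not perfectly, captured by LN fits.
* **MGB- and A1-like units** pool 3 random source units with positive
  weights through progressively harder rectifiers (65th / 75th percentile
  thresholds) and progressively longer latencies (1/2/3 bins for
  IC/MGB/A1). Rectification makes the composite map non-invertible, which
  is the mechanism by which linear predictability decays along the
  pathway and descending (A1 → IC) models fail.
* **Rates, not spikes, feed downstream**, so within-penetration noise
  correlations arise only through shared stimulus drive — except in the
  coupled simulator, where correlations are injected explicitly through
  ground-truth coupling filters and spikes are drawn sequentially from the
  conditional intensity (the exact generative twin of the GLM). A
  runaway-excitation guard aborts with a diagnostic if the realized mean
  rate explodes.
* **Silencing** is modeled as a gain factor (default 0.7) on MGB-like
  rates plus a scale factor (default 0.5) on coupling filters, leaving
  linear tuning untouched — the downstream signature of removing
  corticofugal input. The active and silenced conditions share the
  stimulus, units and ground-truth rates but draw *independent* trial
  noise (a `session` offset on the spike streams), because the two
  conditions are distinct blocks of trials; reusing one noise stream
  would artificially correlate the paired per-unit scores and distort
  the paired tests.
* All randomness flows from one master seed through documented stream
  splitting, so every scenario is exactly reproducible.

Default scenario sizes are 60 IC / 30 MGB / 30 A1 units, 6,000 chords and
10 trials for the hierarchy scenario; 5 units, 6,000 chords and 7 trials
(5 train + 2 test) for the coupled scenario. Tests use smaller instances
of the same scenarios where the property under test does not need the full
scale.

**What passing tests show, and what they do not.** The generator
reproduces hierarchical nonlinearity, Poisson variability, latency
gradients, penetration structure, coupling-induced noise correlations and
a silencing manipulation; it does not emulate non-Poisson dispersion,
adaptation or other history dependence in the trial-averaged pathway,
across-area noise correlations, or anesthesia state. Orderings confirmed
on synthetic data therefore validate the *machinery* (estimators,
cross-validation discipline, model classes, statistics), not the
biological effect sizes; quantitative medians here are not comparable to
recorded-data values.

## Design decisions and numerical choices

* Lag sign convention: negative = past, stated once and used everywhere.
* Zero-padding (not truncation) at sequence, trial and segment joins.
* Segment remainder bins go to the final segment.
* Wilcoxon signed-rank drops zero differences; an all-zero comparison
  returns p = 1. Mann-Whitney U serves unpaired contrasts. Bootstrap 95%
  CIs are percentile intervals of resampled medians (10,000 resamples by
  default, seeded). Both are calibration-tested (null rejection rate at
  alpha = 0.05 within [0.02, 0.09]; CI coverage within [0.92, 0.98]).
* Best frequency is read from a 10x cubic-spline interpolation of the
  positive-part tuning curve; because splines overshoot, the peak is
  refined locally around the raw argmax, which also implements the
  documented tie-break toward the lower frequency.
* The GLM's stimulus block is frequency-resolved by default as the more
  general model; the coupled-scenario analyses use the summed-over-
  frequency variant, which is well-specified there (the generator's
  stimulus drive is a filtered total level) and an order of magnitude
  smaller.
* An NRF "interaction" test unit is gain-modulated (a linear driver whose
  gain follows a second band) rather than purely multiplicative: a pure
  product has no linear signal component, and gradient-trained networks
  cannot find it from spectrally random stimuli — consistent with the
  general observation that random chords sample such interactions poorly.
* Serialization uses plain-text CSV + JSON containers for cochleagrams and
  recordings; models expose broom-style `tidy()`/`glance()` and ggplot2
  `autoplot()` methods instead of bespoke formats.

## Known limitations

The ridge path assumes the design fits in memory (fine up to a few
thousand source units at these durations). The coupled simulator's
sequential loop is pure R and is the slowest generator component. The
logistic output stage is fitted after, not jointly with, the linear stage,
as is standard for this model family; units whose optimal readout is
non-monotone are outside the model class by construction. `CC_norm` can
exceed 1 in finite samples when `CC_max` is underestimated; medians over
units are the intended population summary.
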