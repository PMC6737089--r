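---
title: "Methods: neuronal-avalanche statistics from calcium-imaging rasters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neuronal-avalanche statistics from calcium-imaging rasters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avalanchr)
```

## The problem

Two-photon calcium imaging of cortical populations yields, after spike
deconvolution, a *spike-probability raster*: a neurons x frames matrix of
continuous per-frame spike likelihoods λ at a fixed frame rate (30 Hz here,
Δt ≈ 33 ms). Population activity in such recordings — in auditory cortex,
both in the absence of sound and during tone presentation — organizes into
*neuronal ensembles*: maximal runs of contiguous frames in which at least
one neuron is active, bounded by silent frames. When the network operates
near a critical point, ensemble **size** (active neuron-frames per run)
and **duration** (frames per run) follow power laws — the signature of
neuronal avalanches — and this structure is destroyed by shuffling each
neuron's activity in time. This package implements the full chain from raw
fluorescence to those statistics, together with seeded synthetic
generators that stand in for imaging data.

## Pipeline stages and their parameters

**ΔF/F** (`compute_dff`). F0(t) is the mean of the samples below the 50th
percentile of the preceding 10-s window (300 frames); ΔF/F = (F − F0)/F0.
Two reading choices were open: "points less than the 50th percentile" is
taken as *strictly below* the window median, with a fallback to the window
mean when that set is empty (constant windows), so F0 stays defined for
flat traces; and the causal window uses the partial available history for
the first 300 frames (frame 1 uses itself) rather than discarding them, so
trace and raster lengths match. ΔF/F is exactly invariant under positive
rescaling of F; an additive offset c changes it by the factor F0/(F0+c) —
the test suite asserts both relations.

**Neuropil correction** (`neuropil_correct`). Pointwise
(ΔF/F)soma − α·(ΔF/F)neuropil with α = 0.9 by default.

**Responsiveness** (`responsive_neurons`). One-way ANOVA per neuron with
one pooled pre-stimulus baseline group (per-trial mean over the 1 s before
onset) plus one group per frequency x level condition (per-trial mean over
the 1-s stimulus window); criterion p < 0.01. The grouping granularity was
an open choice; per-condition groups are the finest design consistent with
"baseline vs all sound presentation periods", and label permutation on
noise traces reproduces a false-positive rate ≈ the criterion.

**Binarization threshold** (`optimize_lambda_thr`). λ_thr is chosen to
maximize the number of extracted ensembles; too low a threshold fuses
everything into few giant ensembles, too high erases activity. The
candidate grid default is 40 quantiles of the nonzero λ values, which
adapts to any λ scale (the source data give no grid). Ties go to the
smallest maximizing threshold (retains more activity); the full
threshold-vs-count curve is always reported and no unimodality is assumed.
Whether the threshold should be optimized jointly over ongoing + evoked
frames or separately is not determined by the source description; the
default is jointly over the whole session.

**Ensembles** (`extract_ensembles`). Sizes count each neuron once per
active frame (binary activity per frame; multiple inferred spikes within a
frame are not multiply counted). An ensemble truncated by the end of the
recording is kept but flagged. Every active neuron-frame belongs to
exactly one ensemble, so sizes partition total activity — an exact
invariant the tests enforce against a naive frame-walking oracle.

**Shuffle null** (`shuffle_raster`). Each neuron's λ values are permuted
in time independently (for sparse rasters this is equivalent to placing
each neuron's nonzero values on uniformly drawn distinct frames), the
permutation is applied *before* thresholding, per-neuron active-frame
counts are preserved exactly, and among 10 repeats the shuffle yielding
the most ensembles is used.

**Evoked classification** (`classify_evoked`). An ensemble is evoked iff
its *initiation frame* lies in a 1-s stimulus window; it keeps the label
if it outlasts the stimulus, and an ensemble already running at onset
stays ongoing. An ensemble spanning two stimuli is assigned to the trial
containing its start frame.

## Model selection and slope estimation

Sizes and durations are integer counts, so discrete likelihoods are used
throughout (the continuous-vs-discrete choice was open). The power law is
zeta-normalized, P(s) = s^α / Z(α, x_min) with α < −1 estimated by
numerical likelihood maximization; the exponential alternative is the
geometric distribution with its closed-form MLE. LLR = loglik_pl −
loglik_exp (positive favors the power law), with a Vuong-style normalized
two-sided significance. `fit_alpha_ks` estimates the slope independently
by minimizing the Kolmogorov–Smirnov distance between the empirical CDF
and the discrete power-law CDF over the grid α ∈ [−4, −1.01] step 0.01,
which covers every slope the analysis is expected to produce. x_min is
fixed at 1 — the minimum observable size — rather than estimated, because
the analysis fits whole distributions; it is configurable for sensitivity
analysis. Exponent recovery is verified at α ∈ {−1.5, −2, −2.5, −3} (and
at the published values −2.23, −2.47, −1.93) to within ±0.05 over 20
seeds of 10^5 samples, with the KS and MLE routes agreeing within 0.02.

## Scaling collapse

`collapse_scan` rescales each sound level's log-binned size distribution
to (x = s·L^b, y = P(s)·s^|α|) and scans b over −0.5..0.5 in steps of
0.001 for the best overlay; b ≈ 0 means avalanche statistics are
level-invariant. "The error between the distributions" needed a concrete
definition; the one implemented — isolated in this single function so
alternatives can be swapped — is the mean over level pairs of the
precision-weighted mean squared difference of interpolated log-densities
over the common support, with each pair's mean offset removed. The offset
removal is forced by the algebra: a pure rescaling s → s·L^b multiplies
the (unnormalized) transformed density by L^(b(|α|−1)), a vertical shift
that a horizontal-only scan cannot absorb, so curve *shape* is what must
collapse. The precision weights (harmonic mean of the two interpolated bin
counts) keep one-count tail bins from drowning the well-estimated head of
the distribution. With these choices the scan recovers a constructed
s·L^0.2 rescaling to ±0.005 and returns |b| ≤ 0.01 on i.i.d. samples;
ties in the error landscape break toward b = 0.

## Ensemble receptive fields

Single-neuron RFs are mean ΔF/F per frequency x level over the 1-s
stimulus window and 5 repeats. Best frequency is the center of mass of
the RF, computed in log2 frequency with negative responses rectified to
zero (axis and rectification were open; the log axis matches the
octave-spaced stimuli, and a signed mode is provided). The ensemble RF is
the member-RF average weighted by frames active; IQR_BF is the
interquartile range of member BFs in octaves, each member counted once,
unweighted. Bandwidth — no formula was given — defaults to the half-max
log2 span around the peak at the level row containing the global peak,
with linearly interpolated crossings; an RF supported on a single
frequency reports 0 with a point-support flag. The definition sits behind
one configurable function.

## Synthetic data: what it emulates and what it does not

No imaging data are deposited, so the generators define the study
conditions:

* `make_stimulus_protocol` reproduces the tone design exactly: 3–48 kHz,
  2 tones/octave (9 frequencies) x 40/60/80 dB x 5 repeats of 1-s tones
  with 4–6 s ISI = 135 trials (75 for the 1-tone/octave variant).
* `simulate_branching_raster` is the canonical avalanche model — Poisson
  external drive, each active neuron activating Poisson(σ) uniformly
  chosen neurons in the next frame; σ = 1 is critical. The generating
  model was not described in the source; the branching process is the
  standard choice in the criticality literature.
* `sample_powerlaw_ensembles` draws from the truncated discrete power law
  by exact inverse-CDF (not rejection) for bit-reproducibility.
* `synth_tuned_population` gives each neuron a log-uniform BF and
  Gaussian-in-log2-frequency evoked gain — the simplest model matching
  heterogeneous tuning maps.
* `synth_session` composes the two: critical cascades plus extra drive
  during stimuli routed to tuned neurons, with level-dependent gain
  (0.05/0.1/0.2 extra events per stimulus frame by default — a modest
  elevation over the 0.02 ongoing drive, so a stimulus window contains
  several avalanches rather than one merged response).
* `synth_fluorescence` builds soma traces as baseline x (1 + exponential
  transients + contamination x shared neuropil signal) + noise, so that
  neuropil correction with α equal to the contamination constructively
  inverts the corruption.

All generators draw from one explicit seed per call and never touch the
global RNG state. Known gaps between synthetic and real data: λ estimates
carry no deconvolution noise model (the uniform jitter option is a
convenience for threshold-search tests, not a claim about deconvolution
output statistics); the branching session's per-neuron ongoing rate
(~0.1–0.2 spikes/s at the default drive) is well below the ~1.8 spikes/s
of cortical recordings, because matching both that rate and clearly
silence-separated avalanches at 30 Hz binning is not possible in the
bare branching model — rate-sensitive checks therefore use Bernoulli
rasters generated at the target rate; and compound-RF bandwidth *grows*
with ensemble size in the synthetic session (members have narrow,
widely spaced tuning), whereas the invariance claim is exercised in its
testable core — identically tuned members give exactly the single-member
bandwidth. Passing tests on synthetic data validate the machinery and its
calibration, not biological conclusions.

## Problem sizes and numerical choices

The test suite and the acceptance script use 10^5-sample slope
recoveries (20 seeds per exponent), a 512-neuron x 2x10^5-frame critical
raster (10 seeds) for the shuffle-control property, and 10^3 random
rasters for the oracle-equivalence checks; the analysis scripts use a
256 x 6x10^4 ongoing raster and a 160-neuron, 135-trial session. Degenerate
inputs are handled explicitly: all-equal samples are flagged with LLR
undefined; zero-ensemble rasters return the lowest threshold candidate
with a flag; a single level degenerates the collapse scan (b = 0,
flagged); neurons with fewer than 3 spikes have undefined CV_ISI;
zero-variance neurons are excluded (and flagged) from correlation
matrices.

## Orchestration

`run_pipeline(config)` chains the stages from a single config (list or
YAML) in which every constant above is a field, validates it with
`validate_config`, and emits a machine-readable report; identical
config + seed gives an identical report. The numbered scripts under
`analysis/` run the same stages as a narrated workflow and write their
tables under `results/`.
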