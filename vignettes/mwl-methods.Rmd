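---
title: "Detecting pilot mental workload from few-channel EEG: methods"
author: "mwldetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pilot mental workload from few-channel EEG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwldetect)
```

## The problem

A pilot's mental workload (MWL) rises and falls with the demands of the
flight: landing is the most taxing segment of an airfield traffic
pattern, take-off intermediate, and straight-and-level cruise the
least. Sustained excess workload degrades reaction time and decision
quality, so a system that reads a graded workload state
(low / middle / high) from the pilot's EEG in near real time is of
direct operational interest. Consumer-grade wireless headsets make this
practical: five semi-dry electrodes (AF3/AF4 frontal, T7/T8 temporal,
Pz posterior midline; 10--20 system) sampled at 128 Hz.

`mwldetect` implements the full analysis as a reusable, tested
pipeline. Because study-grade cockpit EEG is not publicly available,
the package ships a first-class synthetic-data generator whose defaults
encode the statistical structure the analysis assumes; every downstream
stage is developed and verified against it.

## Signal model of the generator

Each phase of the synthetic recording is, per channel,

* a 1/f^a Gaussian background (default RMS 10 uV, a = 1), synthesized
  in the frequency domain with random phases;
* one band-limited Gaussian oscillation per frequency band (delta 1--3,
  theta 4--7, alpha 8--11, beta1 12--20, beta2 21--29, gamma 30--40 Hz),
  with RMS taken from a (workload level x brain region x band) gain
  table; and
* on frontal channels only, Poisson-timed half-second raised-cosine
  transients (default 150 uV peak, 4 per minute) that mimic ocular
  artifacts and give the rejection stage something real to reject.

Oscillations are band-limited Gaussian noise rather than pure tones:
the random per-bin amplitudes give periodogram estimates realistic
variance, whereas a sinusoid would make every band-power test
degenerate. Synthesizing directly in the frequency domain (random
Gaussian spectrum supported on the band) keeps essentially all of an
oscillation's power inside its band, which a time-domain band-pass
filter with a finite transition would not.

The default gain table plants one distinctive rhythm per workload
level at 20 uV RMS (twice the background RMS, the contrast at which
the class structure is comfortably recoverable) over a 2 uV baseline
in every cell: strong occipital alpha at low workload (relaxed
wakefulness), frontal theta plus temporal low-beta at middle workload
(working-memory engagement), and frontal delta plus temporal high-beta
at high workload. These choices echo the qualitative band-power
patterns reported for simulated-flight workload; they are a synthetic
stand-in, not a reproduction of any participant's data. Phase durations
default to 60 s each, giving 59 windows per phase.

What the generator deliberately does **not** model: volume conduction
and realistic inter-channel correlation, non-stationarity within a
phase, electrode drift, line noise, or the difference between a
simulator and a real cockpit. A pipeline that passes on this synthetic
data has demonstrated *mechanical and statistical correctness*, not
field performance; the headline accuracies obtainable here say nothing
quantitative about real recordings.

## Survey model and labeling

The NASA-TLX instrument scores six subscales (mental, physical,
temporal, effort, frustration, performance) on 0--100 with
pairwise-comparison weights (15 comparisons, tallies summing to 15).
The generator draws subscale ratings from truncated normals at
phase-specific means; the printed dispersions of the reference survey
are given as "mean +/- value" without stating SD or SE, so the config
exposes both interpretations, defaulting to SE of a 21-participant mean
(per-participant SD = value x sqrt(21)).

The standard weighted score sum(r_i w_i)/15 stays on 0--100, yet
phase-level summaries of the reference survey exceed 100
(145.53 / 105.6 / 65.6 for landing / take-off / cruise), so whatever
aggregation produced them is not the standard one. Rather than silently
redefine the instrument, `tlxWeightedScore()` keeps the standard
aggregator as default and offers the plain weighted sum as an
alternative, and `simulateTLXScores()` can draw weighted scores
directly at the phase-level means for labeling studies.

Labels follow the phase ranking of mean weighted scores: highest ->
high, middle -> middle, lowest -> low, applied to every epoch of the
phase. Phase differences are tested with one-way ANOVA plus pairwise
Welch t-tests against a Bonferroni-corrected threshold (0.05/3,
reported to three decimals as 0.017). Welch's form is used because
equal variances across phases are not guaranteed; a tie in phase means
aborts with a request for an explicit map rather than guessing.

## Preprocessing

* **Low-pass filtering.** The 0--40 Hz passband is realized as a
  zero-phase Hamming-window FIR low-pass (129 taps, -6 dB at
  cut + 4 Hz), applied forward and backward with reflected end padding.
  The realized template leaves 38 Hz attenuated by well under 1 dB and
  attenuates 50 Hz by far more than 20 dB; applying the filter twice
  changes the RMS of EEG-like input by well under 0.1%. There is no
  lower transition to implement at DC; an optional 0.5 Hz high-pass is
  exposed for drift removal and off by default.
* **Bad channels.** A channel is dropped if its variance falls below a
  flat-line floor or any sample exceeds a clipping bound (default
  500 uV); removals are logged, and removing every channel is an error.
* **Windowing.** 2-s windows with 50% overlap, aligned to each phase's
  start, half-open sample intervals, trailing partials discarded; a
  window must lie entirely inside one phase, so labels stay pure. An
  integer n-second phase yields n - 1 windows.
* **Epoch rejection.** Ocular-artifact handling by independent-
  component analysis requires a manual, map-guided component choice
  that cannot be reproduced from a text description; the package
  instead rejects epochs whose peak-to-peak amplitude on any channel
  exceeds 150 uV, which removes the simulated frontal transients by
  construction.

## The 90-feature set

Per channel and 2-s epoch (18 features; 90 for five channels), named
`<channel>-<feature>`:

* **Band powers (6).** One-sided periodogram of the rectangular-
  windowed epoch, |FFT|^2 / (fs N), doubled off DC/Nyquist, summed
  times the bin width over the closed band interval. Bins in the
  printed gaps between bands (e.g. 3.5 Hz) belong to no band, matching
  the band table literally. Summed over all bins this convention
  returns exactly the signal's mean square (Parseval), which the tests
  assert to 1e-9. A Hann taper is available behind a flag; the default
  is rectangular because the reference analysis applies the FFT
  directly to each window.
* **Time-domain (10).** Mean, variance, SD, peak-to-peak, skewness,
  excess kurtosis, RMS, zero crossings (strict sign changes, exact
  zeros inheriting the previous sign), Hjorth mobility
  sqrt(var(dx)/var(x)) and complexity mobility(dx)/mobility(x). The
  standard Hjorth definitions are dimensionally frequency-like even
  though feature tables sometimes list uV/Hz; the standard form is
  implemented. Zero-variance inputs return 0 for the scale-free
  statistics with a degenerate flag instead of NaN, so downstream
  selection never sees missing values.
* **Entropies (2).** Sample entropy (template pairs, self-matches
  excluded) and approximate entropy (self-matches included), Chebyshev
  distance, with the field-standard m = 2 and r = 0.2 x epoch SD.
  When no (m+1)-length matches exist, sample entropy returns its
  maximum attainable value ln((N-m)(N-m-1)) - ln 2 with a flag rather
  than infinity. Both implementations are verified against a literal
  O(n^2) nested-loop oracle on every tested input.

## Feature selection

Two routes, mirroring the two philosophies:

* **Statistical screen.** Shapiro--Wilk normality per feature first
  (EEG features essentially never pass; constant features are flagged
  and treated as non-normal), then the tie-corrected Kruskal--Wallis H
  across the three workload classes with chi-squared (df 2) p-values,
  and selected sets at alpha 0.05 and 0.01 (the stricter set always
  nests in the looser). z-scoring standardizes the selected features;
  by default statistics are fitted on training rows only
  (leakage-safe), with a global mode available to match analyses that
  standardize the whole table at once.
* **Wrapper search (SFFS).** Sequential forward floating selection
  around a cross-validated estimator (default KNN k = 1, 10-fold
  stratified CV, accuracy criterion): greedy inclusion, then
  conditional exclusion whenever removing a feature strictly improves
  the best criterion known at the smaller size. A full-state history
  skips exclusions that would revisit a previous subset, preventing
  cycles; ties break toward the lowest column index so runs are
  deterministic. By construction the floating search never reports a
  worse criterion than plain forward selection at any size it reaches,
  and on small problems it attains the exhaustive-search optimum per
  size, which the tests check on a six-feature problem. Band-power and
  calculative features can be searched as separate pools.

## Classification and evaluation

Six classifier kinds: SVM with linear, RBF and polynomial kernels
(one-vs-rest on top of binary machines, since the margin formulation is
binary), KNN with k = 1 and Euclidean distance, random forest with 500
trees (bootstrap resamples of training size, sqrt(p) features per
split), and a Bayesian neural network. Evaluation is stratified 10-fold
cross-validation with per-fold z-scoring, reporting accuracy and
macro-averaged one-vs-rest precision, recall and F1 as mean +/- SD over
folds. Macro averaging is used because it reproduces the characteristic
pattern of precision exceeding accuracy for conservative classifiers on
imbalanced classes, which micro averaging cannot (it forces precision =
accuracy). One published metric definition derives F1 from accuracy
instead of precision; the standard precision-based F1 is the default
and the accuracy-based variant sits behind a flag.

The Bayesian network is a 3-layer ReLU perceptron
(inputs -> 200 -> 200 -> classes) with dropout after each hidden
activation, trained by full-batch Adam (lr 1e-3, plateau halving) on
cross-entropy plus 0.05 x the KL penalty of the weights against a
N(0, 0.1) prior -- the Monte-Carlo-dropout variational approximation,
in which the KL term reduces to scaled weight decay and the posterior
predictive is approximated by averaging the softmax outputs of
stochastic forward passes (default 50). It is implemented directly in
matrix arithmetic. The desk-scale default of 500 epochs keeps training
in seconds; the configuration accepts larger budgets (the reference
setting is 10,000 epochs) when fidelity matters more than time.

The region-by-band harness re-runs the KNN evaluation on every
(frontal / temporal / occipital / all) x (six bands / mix) subset of the
band-power columns, reproducing the comparison-table layout used to
ask which region and band carry the workload signal.

## Numerical and design choices

* Fold assignment, simulation draws and network initialization all
  derive from explicit integer seeds; a single pipeline seed fans out
  as `seed * 1000 + stage offset`, so one number reproduces a run.
* Degenerate inputs (constant channels, zero-variance features, tied
  phase means, all-rejected epochs) fail loudly or are flagged, never
  silently imputed.
* Problem sizes in the shipped tests and acceptance script -- 10
  virtual participants, 3 x 60 s phases, 20-seed retention sweeps,
  1000-draw null calibrations -- were chosen as the smallest sizes at
  which the statistical assertions are stable; the vignette's numbers
  and the README example come from those runs.

## Known limitations

* Synthetic EEG only: no claim of transfer to real recordings is made
  or testable here (see the generator's non-goals above).
* The EDF container is not read or written; recordings exchange as
  long-format CSV. Annotations follow the same CSV convention.
* ICA-based artifact removal is out of scope (manual component
  selection); amplitude-based rejection stands in.
* The SVM one-vs-rest wrapper refits one binary machine per class and
  is the slowest of the classical classifiers here.
* The exhaustive-optimum property of SFFS is verified on small
  problems; on large correlated feature sets the search remains a
  heuristic, as all sequential searches are.
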