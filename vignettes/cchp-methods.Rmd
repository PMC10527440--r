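---
title: "Channel selection by correlation of Hjorth parameters: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel selection by correlation of Hjorth parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Mental-stress classification from EEG works best with many electrodes, but
every extra electrode costs setup time, comfort and computation, which rules
out dense caps for wearable use. The CCHP method (correlation coefficient of
Hjorth parameters) addresses this by finding, across a panel of subjects, a
small set of channels that (a) respond to the stress/calm contrast and (b)
are not redundant with one another — and by ranking them so a device designer
can trade channel count against accuracy deliberately.

This package implements that pipeline end to end: labelling, Hjorth
summarisation, per-subject selection, cross-subject aggregation,
multi-domain feature extraction, and classifier-based evaluation, plus a
synthetic generator that makes every stage testable without access to gated
EEG corpora.

## Labelling trials

Trials carry valence and arousal self-ratings on the 1–9 SAM scale.
`label_trial()` maps them to classes with strict inequalities:

* stress: valence < 3 and arousal > 5;
* calm: 4 < valence < 6 and arousal < 4;
* anything else, including ratings exactly on a bound, is `unlabeled` and
  dropped.

The gap between the two regions is intentional — it excludes ambiguous
affective states rather than forcing them into a class. Subjects left
without at least one trial of each class cannot support a within-subject
contrast and are excluded (`filter_subjects()`), mirroring the upstream
study design in which a quarter of the panel drops out at this step.

A note on durations: trials arrive as 63 s recordings whose first 3 s are a
pre-stimulus baseline; trimming leaves 7680 samples at 128 Hz. Downstream
feature extraction divides each trial into 16 equal parts of 480 samples.
480 samples at 128 Hz is 3.75 s, although such windows are conventionally
described as "4 s"; the implementation follows the sample counts, because
sample counts (not durations) drive all the arithmetic that matters.

## Hjorth parameters and normalisation

Each (trial, channel) pair is summarised by the three time-domain Hjorth
parameters:

* activity `= var(x)` — signal power;
* mobility `= sqrt(var(dx)/var(x))` — a mean-frequency proxy;
* complexity `= mobility(dx)/mobility(x)` — a bandwidth proxy, 1 in the
  pure-sine limit.

Two conventions are fixed deliberately. The derivative is the plain first
difference without sampling-rate scaling: mobility and complexity are
ratios in which an `fs` factor cancels, and activity never sees the
derivative, so results are comparable across sampling rates. Variances use
the N−1 denominator, matching the covariance definition used by the
correlation stage. (The moment *features* of the classification stage use
population 1/T moments instead — their printed definitions differ, and each
formula is kept as printed rather than harmonised.)

Before any correlation is computed, each (channel, parameter) column is
Z-scored across the subject's labelled trials, both classes pooled
(`zscore_table()`). Pooled rather than per-class normalisation is the
default because selection is a per-subject procedure and the class contrast
must survive normalisation; a `per_class` flag exists for sensitivity
analysis. Normalisation happens once, before all correlation computations,
following the pipeline's narrative order.

## The selection core

For one subject, with z-scored Hjorth tables:

* **Channel–channel redundancy** (`pair_channel_corr()`): for channels S, K
  within one class, the entry aggregates the three parameters,
  `(cov(A_S,A_K)+cov(M_S,M_K)+cov(C_S,C_K)) /
  (sd(A_S)sd(A_K)+sd(M_S)sd(M_K)+sd(C_S)sd(C_K))`, across the class's
  trials. The stress and calm matrices are averaged elementwise
  (`pooled_pair_corr()`). By Cauchy–Schwarz every entry lies in [−1, 1].

* **Channel–class relevance** (`channel_class_corr()`): the default mode is
  the point-biserial correlation — for each channel and parameter, the
  Pearson correlation between the feature across all labelled trials and
  the binary class indicator — averaged in absolute value over the three
  parameters. Absolute values are taken so that channels anti-correlated
  with the class still count as relevant. The printed sum-of-covariances
  form of this statistic divides by a *sum* of standard deviations and
  needs the two classes paired trial by trial, which is undefined for
  unequal class sizes and unbounded in scale; it is nevertheless available
  as `mode = "paired"` (classes paired by sorted rank, truncated to the
  smaller class) for reproduction experiments. Both modes are labelled
  interpretations in the report.

* **Merit** (`merit_score()`): a k-channel subset with mean relevance
  `r_cf` and mean absolute pooled inter-correlation `r_ff` scores
  `k·r_cf / (k + k(k+1)·k·r_ff)` in the default `"literal"` mode — the
  formula exactly as printed — or the classical correlation-feature-
  selection (CFS) merit `k·r_cf / sqrt(k + k(k−1)·r_ff)` as `mode = "cfs"`.
  `r_ff` averages absolute pooled correlations: without the absolute value
  an anti-correlated pair could drive the literal denominator through
  zero. For k = 1 there are no pairs and `r_ff` is defined as 0, so both
  modes reduce to `r_cf`.

  The two modes behave differently under growth. The literal denominator
  grows at least linearly in k while the mean relevance cannot rise once
  the best channel is taken, so greedy search under the literal merit
  typically stops at one channel per subject; the CFS merit rewards adding
  an uncorrelated, relevant channel and yields multi-channel subsets. Both
  are deterministic, and every report names the mode used. The default
  remains the printed formula; the cross-subject aggregation below makes
  the method work either way.

* **Per-subject search** (`select_subject_channels()`): best-first greedy
  forward selection with patience 0 — add the merit-maximising channel,
  stop when no addition improves the merit. Ties are broken by higher
  relevance score, then channel name, making the search fully
  deterministic. A `topk` strategy (k highest-relevance channels) is the
  simple alternative.

* **Aggregation** (`aggregate_occurrences()`, `rank_and_threshold()`):
  channels are counted across subjects' significant sets, ranked by
  descending occurrence, ties broken by descending mean relevance across
  subjects and then name, thresholded at `f_thr` occurrences and capped at
  `n_max`. The threshold is not stated numerically in the source study
  (only its outcome, an 8-channel set, is); the default here is
  `f_thr = ceiling(0.5 · n_subjects)` — a channel must matter for at least
  half the panel — with `n_max = 8` mirroring the headline configuration.
  When nothing clears the threshold the operation warns and returns an
  empty set; the pipeline then falls back to the top of the occurrence
  ranking so downstream stages remain meaningful.

Selection operates on whole trials by default. Whether selection should use
whole 60 s trials or 4 s segments is genuinely open; whole trials give the
Hjorth estimates maximal stability and keep the trial count equal to the
rating count, so they are the default, with `use_segments = TRUE` exposing
the segment-level variant.

## Features

`extract_features()` emits exactly 20 features per channel per 480-sample
segment:

* time domain: line length, peak-to-peak amplitude, kurtosis and skewness
  (population moments, no excess-kurtosis shift), and the three Hjorth
  parameters (delegated to the same functions the selection stage uses);
* frequency domain: relative powers of theta (4–8 Hz), low alpha (8–12),
  high alpha (12–15), low beta (15–20) and high beta (20–30), as
  percentages of total 4–45 Hz Welch power. The denominator is the full
  4–45 Hz band of the preprocessed data rather than the union of the five
  bands — an interpretation, flagged as such — so the five shares sum to
  at most 100;
* time–frequency: six db4 wavelet energies, Welch spectral entropy over
  4–45 Hz (natural log; base 2 available), and the Katz fractal dimension
  with the standard step-count form `D = log10(n)/(log10(d/L)+log10(n))`.

Welch parameters are not dictated by the source material; the default is
128-sample Hamming windows with 50% overlap, giving 1 Hz resolution — enough
to resolve the 4 Hz lower band edge — and six averaged windows per segment.
An on-bin tone under a Hamming taper still spreads over three bins with
weights `(0.23, 0.54, 0.23)` squared, so a pure sine's spectral entropy is
about 0.76 nats rather than 0; the tests account for this.

A 6-level db4 decomposition yields seven coefficient sets; the six detail
levels D1–D6 are used and the approximation is excluded, because at 128 Hz
the approximation band lies below 1 Hz, which the 4–45 Hz preprocessing
already removed. `set = "d2_a6"` swaps D1 for the approximation energy
instead. The transform uses periodization rather than symmetric extension:
periodization keeps the analysis orthogonal, so level energies sum exactly
to the signal energy (Parseval), which the tests verify to 1e−8 at dyadic
lengths. The one caveat is odd-length levels: 480 samples reach length 15
at the sixth level, which is extended by duplicating the final coefficient
(the usual periodization convention), mildly breaking exactness at that
level only.

## Classification

Three classifiers with fixed defaults: RBF-SVM (C = 1, tolerance 1e−3,
gamma = 1/(n_features · mean feature variance) — gamma is not specified in
the source, so the common "scale" heuristic is recorded in every report),
KNN (k = 10, Euclidean), and LDA with an eigen solve and no shrinkage
(what "regularized LDA, shrinkage = none" denotes). Evaluation is
subject-wise, stratified 10-fold cross-validation: stratification is used
because per-subject class counts are small and imbalanced under the
labelling rule; fold assignment is seeded and reported. Feature columns are
standardised with training-fold statistics only — without this, RBF-SVM and
KNN distances are dominated by the activity and energy features, whose
scales are orders of magnitude above the rest; `scale = FALSE` restores the
literal reading. Metrics (precision, recall, accuracy; stress positive) are
computed from confusion counts pooled across folds — whether the source
study pooled or macro-averaged folds is not stated, and pooling is the
flagged default. A zero-denominator metric is reported as undefined, never
silently 0. `channel_sweep()` evaluates accuracy over ranked channel-set
sizes, defaulting to the sizes 1, 5, 8, 9, 15, 19, 32.

## The synthetic generator

`simulate_dataset()` emulates the study's data shape: per subject, 40
trials of 60 s at 128 Hz across 32 montage-named channels, balanced
stress/calm labels, and a planted channel subset shared across subjects
(the cross-subject commonality the selection stage exists to find).
Backgrounds are synthesised in the frequency domain — complex-Gaussian bins
under a 1/f amplitude envelope restricted to 4–45 Hz, inverse-transformed —
for exact band control and speed; the expected per-trial standard deviation
is 1, with natural trial-to-trial fluctuation retained. Effects are
calibrated in across-trial standard-deviation units so effect sizes are
comparable across kinds: `bandpower_shift` adds a 15–30 Hz narrowband
component of amplitude `effect` × background sd to stress trials on planted
channels; `mobility_shift` tilts the planted channels' spectral envelope
upward by the tilt (found by root-solving the envelope's expected discrete
mobility) that raises mobility by `effect` × its across-trial null sd. A
`mixing` parameter can add a shared component across channels to emulate
volume conduction; it defaults to 0.

What the generator does *not* emulate: event-related potentials, eye blinks
and electrode drift, non-stationarity within trials, realistic inter-subject
variability, or spatially structured correlation between neighbouring
electrodes. Passing tests therefore demonstrate that the machinery
recovers planted, well-calibrated effects under clean conditions — not that
it will rank the same channels on any real cortex.

## Problem sizes and numerical choices

The simulation studies in the test suite and the acceptance script use 10
subjects × 16 channels with 3 planted channels at effect 2 and 20
trials per class. Recovery-rate estimates run many independent master
seeds and use 20 s trials: shorter trials give noisier Hjorth estimates,
i.e. a strictly harder recovery problem than the full 60 s shape, while
keeping many-seed studies tractable. Shape and classification checks use
the full 63 s/128 Hz trial geometry. Further fixed choices: ties in
selection break by relevance then name; degenerate inputs (constant
signals, zero-variance features, empty classes) raise classed errors
rather than producing silent zeros; all randomness flows from explicit
seeds, with per-subject seeds derived deterministically from the master
seed.

## Known limitations

* The literal merit's singleton bias (above) means per-subject subsets are
  usually small; multi-channel per-subject subsets require `merit = "cfs"`
  or `strategy = "topk"`.
* The paired channel–class mode is one reading of an ambiguous formula and
  should be treated as such.
* EDF support covers continuous, single-rate recordings only (no EDF+
  annotations, BDF or GDF).
* No artifact handling: inputs are assumed preprocessed (band-passed,
  ocular artifacts removed), as in the upstream dataset.
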