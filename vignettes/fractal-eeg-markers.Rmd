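---
title: "Fractal complexity markers in motor-imagery EEG: methods and validation"
author: "fractalEEG authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal complexity markers in motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractalEEG)
```

## The scientific problem

Central neuropathic pain (CNP) after spinal cord injury is associated with
changes in cortical activity that are visible in the EEG. Beyond the
well-studied oscillatory markers (band power shifts, slowed alpha),
non-linear *complexity* measures capture a partly independent aspect of the
signal. This package implements an analysis chain built around the Higuchi
fractal dimension (HFD) of short EEG windows recorded during motor imagery:
feature extraction, electrode-wise group statistics, and transferable
single/few-channel classification, together with a synthetic-data module
that makes the whole chain testable against exact ground truth.

## The Higuchi fractal dimension

For a timeseries $S(t)$, $t = 0, \dots, N-1$, and an interval size $k$, the
curve length at phase $m \in \{0, \dots, k-1\}$ is

$$
L_m(k) \;=\; \frac{1}{k} \left[ \sum_{i=1}^{n_m}
  \lvert S(m+ik) - S(m+(i-1)k) \rvert \right] \frac{N-1}{n_m\,k},
\qquad n_m = \left\lfloor \frac{N-1-m}{k} \right\rfloor ,
$$

and the curve length is the phase average $L(k) = \frac{1}{k} \sum_m
L_m(k)$. For a statistically self-similar signal $L(k) \propto k^{-D}$, so
the fractal dimension $D$ is estimated as the negated slope of the
least-squares fit of $\log L(k)$ on $\log k$. Natural logarithms are used;
the slope does not depend on the base. For timeseries $D \in [1, 2]$:
a noiseless ramp attains exactly 1 and uncorrelated noise approaches 2.

Published formulations of the estimator mix 0- and 1-based indexing. The
convention above is pinned by two exact identities that the test suite
asserts: a ramp of length $N$ has $L(k) = (N-1)/k$ for every $k$ (so
$D = 1$ exactly), and the 10-sample ramp gives $L(2) = 4.5$ and
$L(3) = 3.0$.

Two numerical notes:

* The interval grid defaults to all integers $2..k_{\max}$ with
  $k_{\max} = 7$, a small-$k_{\max}$ setting repeatedly reported to be
  accurate on EEG. With $k_{\max}$ this small, an "exponentially spaced"
  grid is indistinguishable from the full integer grid, so the full grid is
  the default and `hfdConfig(kGrid = ...)` exposes the choice.
* The estimator carries a small upward bias on pure white noise (the
  log of an average exceeds the average of logs asymmetrically across
  $k$), so individual white-noise windows scatter around 2 with a standard
  deviation of about 0.03 at $N = 500$ and can exceed 2 slightly; the
  *mean* over many windows stays within $[1.90, 2.00]$ at this window
  length. A constant window has zero curve length; the estimator refuses
  it, and the feature extractor records such windows as missing and
  reports their count.

## Windowing

HFD is most effective on short windows, so each 5-s trial is analysed in
2-s windows with 50% overlap, at offsets 0, 1, 2 and 3 s from trial onset.
Window sample counts are `round(length * rate)` and starts are
`round(offset * rate)`, which is exact for both 250 Hz (500-sample
windows) and 256 Hz (512-sample windows) cohorts. A feature table row is
produced per (participant, trial, task, channel, offset).

## The synthetic cohorts

The two study layouts are emulated, not reproduced: the package ships
presets for a three-group, 61-channel, 250 Hz cohort and a two-group,
48-channel, 256 Hz cohort, both with 10 participants per group, 60 trials
per task and three motor-imagery tasks.

Signals are fractional Brownian motion (fBm) paths synthesised exactly by
circulant embedding of the fractional-Gaussian-noise covariance. fBm is
chosen because its fractal dimension is known in closed form, $D = 2 - H$,
which turns estimator validation and downstream parameter recovery into
assertable tests: the Hurst exponent of each trial/channel is

$$
H = \mathrm{clip}\bigl(H_0 + u_p + \Delta H_g(\text{channel}),\;
  0.05,\; 0.95\bigr),
$$

with $H_0$ the baseline (default 0.25, i.e. baseline $D \approx 1.75$,
mid-way through the 1.5–2.0 range typically estimated from motor-imagery
EEG, leaving headroom for effects of either sign), $u_p \sim
\mathcal N(0, 0.03^2)$ a per-participant random effect shared across all
of that participant's channels and trials, and $\Delta H_g$ the per-group,
per-channel planted effect. A negative $\Delta H$ raises the affected
group's complexity. The participant random effect matters: it induces the
within-participant correlation of classification errors that real cohorts
show, which is exactly why all cross-validation in this package is grouped
by participant.

What the generator does *not* emulate: oscillatory rhythms and their
task-related (de)synchronisation, artifacts, volume conduction between
channels (channels are independent given the participant effect), and
non-stationarity within a trial. Passing tests therefore demonstrate that
the pipeline recovers complexity differences of known size under realistic
noise and clustering — not that any specific clinical effect exists.

## Group statistics

Features are aggregated into group means per (group, task, offset,
channel). Because HFD features are not normally distributed, group
differences are tested by bootstrap: $M$ resamples of each group's
features (each group at its own size; 600 in the canonical
60-trials-by-10-participants design) yield a distribution of group-mean
differences, and with $\mathrm{ECDF}(0)$ its empirical CDF at zero, the
null $\mu_a = \mu_b$ is rejected at level $p$ when $\mathrm{ECDF}(0) \le
p/2$ or $\ge 1 - p/2$. Electrode-wise multiplicity is Bonferroni-corrected
with factor $1/n_{\text{channels}}$ (0.05/61 $\approx 8.2\times 10^{-4}$
per channel on the 61-channel montage). $M$ defaults to $10^6$ to mirror
the full-scale analysis; the validation suite uses $10^4$, which makes the
ECDF granular to $10^{-4}$ — ample for the decision thresholds involved.

Two design points deserve emphasis:

* The rule as stated reads the percentile of zero off the *un-recentred*
  resampled difference distribution. A textbook alternative recentres the
  distribution under the null first; both are implemented
  (`recentre = TRUE`), the un-recentred rule being the default because it
  is the procedure as specified. Under the null the two agree closely.
* The bootstrap resamples *trials*, treating the 600 features per group as
  exchangeable. Under participant-level random effects this is
  anticonservative for group-level inference: a chance imbalance in
  participant offsets shifts every channel of the group and the
  trial-level test will flag it. This is a faithful property of the
  procedure, visible in the package's own parameter-recovery runs (null
  channels are sometimes flagged alongside planted ones, all shifted by
  the same participant-mean imbalance). Calibration of the test itself is
  verified on exchangeable nulls, where its empirical type-I error is
  within Monte-Carlo range of nominal.

The per-channel results (observed difference, ECDF(0), uncorrected and
corrected flags) are exactly antisymmetric in the group order and
deterministic given the seed: each channel draws its own sub-seed by
alphabetical channel rank, so row order, pair order and channel subsets do
not change results.

## Classification

Per-trial feature vectors are HFD values at a channel subset for one task
and window offset. The classifier is a linear $\nu$-SVC ($\nu \in (0,1]$
upper-bounds the margin-error fraction and lower-bounds the
support-vector fraction); the solver is libsvm via e1071, while channel
selection, nesting, voting and transfer logic are implemented here.
Features are z-scored with statistics fitted on training folds only
(margin classifiers are scale-sensitive; the raw feature scale is
arbitrary).

A practical property of the $\nu$ parameterisation worth knowing: when
$\nu$ is smaller than the *unavoidable* margin-error fraction of the
training set, the dual becomes degenerate and solvers return a collapsed
(sometimes sign-inverted) rule. On a single weakly informative channel
with heavily overlapping classes this can happen for $\nu \lesssim 0.2$.
The grid search handles this naturally — degenerate fits score badly in
inner cross-validation and are never selected, and infeasible fits are
treated as failed grid points — but reduced single-value grids should use
mid-range $\nu$; the package's own validation studies use $\nu = 0.3$.

*Greedy forward channel selection* starts from the empty set, evaluates
every candidate channel joined to the selected set by inner
cross-validation accuracy, adds the best, and halts when no candidate
*strictly* improves accuracy. Strict improvement is required because a
halting rule that tolerates ties can grow the set indefinitely on
plateaus; ties among candidates go to the channel listed first (montage
order), making selection deterministic.

*Nested leave-one-subject-out evaluation*: the outer loop holds out each
participant once; within an outer fold, a grid over $(\nu,
\text{offset})$ is searched with the channel subset re-optimised by the
greedy procedure at every grid point, scored by inner
leave-one-participant-out accuracy. Leave-one-participant-out is used for
the inner loop (the fold structure is otherwise open) because errors are
participant-correlated, so trial-level inner folds would leak. The winning
configuration is refit on all training participants and applied to the
held-out participant. Reported are the mean and standard deviation of
per-participant trial accuracies, pooled sensitivity and specificity
(positive class defaulting to the alphabetically first group), the
winning configuration per fold with its modal value across folds, and the
percentage of participants whose majority vote over trials is correct —
an exact tie counts as incorrect, the conservative reading of majority
voting.

*Transfer*: channels and offset are frozen to values learned on a source
cohort and only $\nu$ is re-optimised per outer fold on the target cohort,
mirroring the use of a diagnostic configuration as a prognostic
classifier.

## Validation studies and their sizes

All validation runs are seeded and sized for a desk machine; the sizes
below are the package's own choices and are asserted in
`tests/testthat/test-acceptance.R` and recomputed by
`scripts/acceptance.R`.

* **Estimator exactness** — ramp identities ($L(2)=4.5$, $L(3)=3.0$,
  $D=1$) to $10^{-9}$; vectorised curve length against a naive double-loop
  transcription on 50 random signals to $10^{-12}$ relative.
* **Upper range** — mean HFD of 100 white-noise windows ($N=500$) within
  $[1.90, 2.00]$.
* **Bootstrap calibration** — 500 exchangeable-null repetitions
  ($n = 600$ per group, $M = 10^4$): empirical rejection rate within
  $[0.03, 0.07]$ at nominal 0.05.
* **Parameter recovery** — 20 seeded replications of a two-group,
  10-per-group, 60-trial cohort on a 6-electrode montage with
  $\Delta H = -0.15$ planted at FCz and CPz: the corrected-significant set
  contains both planted channels in at least 95% of runs; nested LOSO on a
  4-channel pool ($\nu$ grid $\{0.3\}$, offsets $\{0, 2\}$) reaches
  accuracy $\ge 0.9$ with a planted channel selected first in every fold,
  the first pick agreeing with an exhaustive single-channel oracle.
* **Chance calibration** — 100 participant-level label permutations of a
  zero-effect single-electrode cohort (10 per group, 60 trials), nested
  LOSO at a singleton grid: mean accuracy within $[0.45, 0.55]$, the 50%
  chance level of balanced two-class prediction.
* **Structural counts** — the canonical design yields exactly 600
  features per (group, channel, offset, task) and four 2-s windows per
  5-s trial at either sampling rate.

The montage tables shipped in `inst/extdata` are standard extended 10-10
label sets (61 and 48 channels) with conventional flat head-circle
coordinates, synthesised from the 10-10 geometry; they serve labelling,
subset selection and topography rendering.

## Known limitations

* The generator's channels are conditionally independent; spatial
  correlation (volume conduction) is not modelled, so channel-selection
  behaviour under strongly correlated neighbours is untested.
* The trial-level bootstrap inherits the anticonservativeness under
  participant clustering discussed above; it quantifies feature-level,
  not participant-level, evidence.
* Only the linear kernel and two-class problems are supported; the
  three-task design is handled as separate pairwise problems.
* EDF import covers continuous uniform-rate recordings (the common case),
  not the discontinuous EDF+D variant.
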