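# fractalEEG

Non-linear complexity markers for motor-imagery EEG, built around the
Higuchi fractal dimension (HFD). The package is aimed at researchers
studying EEG biomarkers of central neuropathic pain after spinal cord
injury — and, more generally, at anyone who wants a tested, seeded
implementation of windowed HFD features, electrode-wise bootstrap group
statistics, and transferable few-channel classification under
leave-one-subject-out cross-validation.

## What it computes

**Higuchi fractal dimension.** For a windowed signal `S(t)`,
`t = 0..N-1`, curve lengths

    L_m(k) = (1/k) [ Σ_{i=1..n_m} |S(m+ik) − S(m+(i−1)k)| ] (N−1)/(n_m k),
    n_m = ⌊(N−1−m)/k⌋,   L(k) = (1/k) Σ_{m=0..k−1} L_m(k)

scale as `L(k) ∝ k^(−D)`; `D` is the negated slope of the least-squares
fit of `log L(k)` on `log k` over `k = 2..7`. For timeseries
`D ∈ [1, 2]`: a ramp gives exactly 1, white noise approaches 2, and
fractional Brownian motion with Hurst exponent `H` has `D = 2 − H`.
Features are extracted from four 2-s windows (50% overlap) of each 5-s
trial, per electrode and motor-imagery task.

**Group statistics.** Differences in group-mean HFD are tested per
electrode by bootstrap: `M` resamples of each group's features yield a
distribution of mean differences, and `H0: μa = μb` is rejected at level
`p` when the distribution's ECDF at 0 falls outside `[p/2, 1 − p/2]`,
with electrode-wise Bonferroni correction (factor `1/n_channels`).

**Classification.** Linear ν-SVC on per-trial HFD vectors with greedy
forward channel selection, nested leave-one-subject-out cross-validation
(grid search over ν and window offset with channel re-selection per grid
point, inner leave-one-participant-out scoring), majority-vote
participant-level predictions, and transfer evaluation with channels and
offset frozen from a source cohort.

**Synthetic cohorts.** A seeded generator emulates the study layouts
(three-group 61-channel 250 Hz; two-group 48-channel 256 Hz) with
fractional Brownian motion signals, per-participant Hurst random effects
and per-channel planted group effects — giving the entire chain exact
ground truth (`D = 2 − H`) to validate against.

## Worked example

```r
library(fractalEEG)

# a reduced two-group cohort: 4 participants per group, 12 trials,
# complexity raised at FCz in the group that later develops pain
montage <- subsetMontage(standardMontage("48"), c("F3", "FCz", "CPz", "Oz"))
cfg <- synthConfig(groups = c("sPDP", "sPNP"), participantsPerGroup = 4,
                   trialsPerTask = 12, tasks = "RH", samplingRate = 256,
                   montage = montage,
                   groupEffect = list(sPDP = c(FCz = -0.15)), seed = 42)
dataset <- generateDataset(cfg)
dataset
#> EpochsDataset
#>   8 participants x 12 trials x 1 tasks x 4 channels x 1280 samples
#>   sampling rate: 256 Hz
#>   groups: sPDP (n=4), sPNP (n=4)
#>   tasks: RH

features <- extractFeatures(dataset)
head(features, 3)
#>   group participant trial task channel offset      hfd
#> 1  sPDP      sPDP01     1   RH      F3      0 1.793921
#> 2  sPDP      sPDP01     1   RH      F3      1 1.797108
#> 3  sPDP      sPDP01     1   RH      F3      2 1.708093

comparison <- compareGroups(features, c("sPDP", "sPNP"), task = "RH",
                            windowOffset = 2, M = 10000, seed = 1)
comparison[, c("channel", "difference", "ecdfAtZero",
               "significantUncorrected", "significantCorrected")]
#>   channel   difference ecdfAtZero significantUncorrected significantCorrected
#> 1     CPz -0.014706158     0.9393                  FALSE                FALSE
#> 2      F3 -0.009665845     0.8264                  FALSE                FALSE
#> 3     FCz  0.137586546     0.0000                   TRUE                 TRUE
#> 4      Oz  0.012562148     0.0863                  FALSE                FALSE

report <- nestedLosoEvaluate(features, "RH",
                             classifierConfig(nuGrid = c(0.3, 0.5),
                                              offsetGrid = c(0, 2)))
report
#> EvalReport: task RH (positive class sPDP)
#>   accuracy 0.97 +/- 0.06 | sensitivity 0.96 | specificity 0.98 | participants correct 100%
#>   modal config: offset 0 s, nu 0.3, channels FCz
```

Reading the output: the planted complexity increase at FCz appears as a
positive mean HFD difference of about 0.14 (the planted Hurst shift of
−0.15, attenuated only by estimator noise) with ECDF(0) = 0, significant
before and after Bonferroni correction; the other channels stay
non-significant. The nested evaluation selects FCz in every outer fold
and classifies held-out participants' trials at 97% mean accuracy, with
every participant correct by majority vote — chance level is 50%.

`runPipeline(defaultRunConfig("demo"), "out/")` runs the same stages from
one declarative configuration and writes CSV/JSON artifacts stamped with
the configuration hash. A command-line wrapper with `simulate`,
`features`, `compare`, `classify`, `transfer` and `run` subcommands is
installed at `system.file("cli", "fractaleeg.R", package = "fractalEEG")`.

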