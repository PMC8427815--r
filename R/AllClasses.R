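#' @import methods
NULL

## ---------------------------------------------------------------------------
## ChannelMontage
## ---------------------------------------------------------------------------

#' Electrode montage
#'
#' An S4 container for an EEG electrode montage: channel labels in the
#' extended international 10-10 nomenclature together with flat 2-D scalp
#' coordinates on the unit head circle (vertex at the origin, nasion towards
#' positive y, right ear towards positive x; unitless).
#'
#' @slot labels character vector of unique channel labels.
#' @slot positions numeric matrix with one row per channel and columns
#'   `x`, `y`; every position lies within the unit head circle.
#'
#' @seealso [standardMontage()], [subsetMontage()]
#' @export
setClass("ChannelMontage",
  representation(labels = "character", positions = "matrix"))

setValidity("ChannelMontage", function(object) {
  lab <- object@labels
  pos <- object@positions
  if (length(lab) == 0L) return("montage must contain at least one channel")
  if (anyDuplicated(lab)) return("channel labels must be unique")
  if (any(!nzchar(lab))) return("channel labels must be non-empty")
  if (!is.numeric(pos) || ncol(pos) != 2L)
    return("positions must be a numeric matrix with columns x, y")
  if (nrow(pos) != length(lab))
    return("positions must have one row per channel label")
  if (anyNA(pos)) return("positions must not contain NA")
  r <- sqrt(rowSums(pos^2))
  if (any(r > 1 + 1e-6))
    return(sprintf("position of channel '%s' lies outside the unit head circle",
                   lab[which.max(r)]))
  TRUE
})

## ---------------------------------------------------------------------------
## SynthConfig
## ---------------------------------------------------------------------------

#' Synthetic dataset configuration
#'
#' Parameters of the synthetic EEG epoch generator. Signals are fractional
#' Brownian motion (fBm) paths whose Hurst exponent is
#' `baseHurst + participant offset + group effect(channel)`, clipped to
#' `[0.05, 0.95]`; the theoretical fractal dimension of an fBm path is
#' `D = 2 - H`, which provides ground truth for validating the Higuchi
#' estimator and everything downstream.
#'
#' @slot groups character vector of group labels.
#' @slot participantsPerGroup integer, participants per group.
#' @slot trialsPerTask integer, repetitions per motor-imagery task.
#' @slot tasks character vector of task labels.
#' @slot samplingRate sampling rate in Hz.
#' @slot trialDuration trial length in seconds.
#' @slot montage a [ChannelMontage-class].
#' @slot baseHurst baseline Hurst exponent, in (0, 1).
#' @slot groupEffect named list: per group, a named numeric vector of
#'   Hurst-exponent shifts by channel (channels not listed get 0).
#' @slot participantSd standard deviation of the per-participant Gaussian
#'   Hurst offset (shared across that participant's channels and trials).
#' @slot seed integer seed; identical configurations generate bit-identical
#'   datasets.
#'
#' @seealso [synthConfig()], [generateDataset()]
#' @export
setClass("SynthConfig",
  representation(groups = "character", participantsPerGroup = "integer",
                 trialsPerTask = "integer", tasks = "character",
                 samplingRate = "numeric", trialDuration = "numeric",
                 montage = "ChannelMontage", baseHurst = "numeric",
                 groupEffect = "list", participantSd = "numeric",
                 seed = "integer"))

setValidity("SynthConfig", function(object) {
  if (length(object@groups) < 1L || anyDuplicated(object@groups))
    return("groups must be a non-empty vector of unique labels")
  if (object@participantsPerGroup < 1L)
    return("participantsPerGroup must be >= 1")
  if (object@trialsPerTask < 1L) return("trialsPerTask must be >= 1")
  if (length(object@tasks) < 1L || anyDuplicated(object@tasks))
    return("tasks must be a non-empty vector of unique labels")
  if (object@samplingRate <= 0) return("samplingRate must be positive")
  if (object@trialDuration <= 0) return("trialDuration must be positive")
  ns <- object@samplingRate * object@trialDuration
  if (abs(ns - round(ns)) > 1e-8)
    return("trialDuration x samplingRate must be an integer sample count")
  if (object@baseHurst <= 0 || object@baseHurst >= 1)
    return("baseHurst must lie in (0, 1)")
  if (object@participantSd < 0) return("participantSd must be >= 0")
  ge <- object@groupEffect
  if (length(ge)) {
    if (is.null(names(ge)) || !all(names(ge) %in% object@groups))
      return(sprintf("groupEffect refers to unknown group(s): %s",
                     paste(setdiff(names(ge), object@groups), collapse = ", ")))
    for (g in names(ge)) {
      eff <- ge[[g]]
      if (!is.numeric(eff) || is.null(names(eff)))
        return("each groupEffect entry must be a named numeric vector")
      bad <- setdiff(names(eff), object@montage@labels)
      if (length(bad))
        return(sprintf("groupEffect for group '%s' names unknown channel(s): %s",
                       g, paste(bad, collapse = ", ")))
    }
  }
  TRUE
})

## ---------------------------------------------------------------------------
## EpochsDataset
## ---------------------------------------------------------------------------

#' Labelled EEG epoch tensor
#'
#' An S4 container for a set of epoched multichannel EEG trials, indexed
#' `(participant, trial, task, channel, sample)`, together with the sampling
#' rate, electrode montage, participant-to-group assignment and provenance.
#'
#' @slot data 5-dimensional numeric array
#'   `(participant, trial, task, channel, sample)` with complete dimnames on
#'   the first four dimensions and no missing samples.
#' @slot samplingRate sampling rate in Hz.
#' @slot montage a [ChannelMontage-class]; its labels match the channel
#'   dimension.
#' @slot groupOf named character vector mapping every participant id to a
#'   group label.
#' @slot provenance list describing how the data came to be (generator
#'   configuration or import descriptor).
#'
#' @seealso [generateDataset()], [readDataset()], [extractFeatures()]
#' @export
setClass("EpochsDataset",
  representation(data = "array", samplingRate = "numeric",
                 montage = "ChannelMontage", groupOf = "character",
                 provenance = "list"))

setValidity("EpochsDataset", function(object) {
  d <- object@data
  if (length(dim(d)) != 5L)
    return("data must be a 5-d array (participant, trial, task, channel, sample)")
  dn <- dimnames(d)
  if (is.null(dn) || any(vapply(dn[1:4], is.null, logical(1))))
    return("data must carry dimnames for participant, trial, task and channel")
  if (!identical(dn[[4]], object@montage@labels))
    return("channel dimnames must match the montage labels")
  if (anyNA(d)) return("data must not contain missing samples")
  p <- dn[[1]]
  if (!all(p %in% names(object@groupOf)))
    return("groupOf must cover every participant")
  if (object@samplingRate <= 0) return("samplingRate must be positive")
  ns <- dim(d)[5]
  dur <- object@provenance$trialDuration
  if (!is.null(dur) && abs(ns - dur * object@samplingRate) > 1e-6)
    return("per-trial sample count must equal trialDuration x samplingRate")
  TRUE
})

## ---------------------------------------------------------------------------
## HfdConfig
## ---------------------------------------------------------------------------

#' Higuchi estimator and windowing configuration
#'
#' @slot kMax largest interval size considered by the Higuchi estimator.
#' @slot kGrid integer vector of interval sizes used in the log-log fit
#'   (default all integers `2..kMax`).
#' @slot windowLength analysis window length in seconds.
#' @slot windowOffsets window start offsets in seconds from trial onset.
#'
#' @seealso [hfdConfig()], [higuchiFd()], [extractFeatures()]
#' @export
setClass("HfdConfig",
  representation(kMax = "integer", kGrid = "integer",
                 windowLength = "numeric", windowOffsets = "numeric"))

setValidity("HfdConfig", function(object) {
  kg <- object@kGrid
  if (length(kg) < 2L) return("kGrid must contain at least two interval sizes")
  if (min(kg) < 2L) return("kGrid values must be >= 2")
  if (max(kg) > object@kMax) return("kGrid values must not exceed kMax")
  if (anyDuplicated(kg)) return("kGrid values must be unique")
  if (object@windowLength <= 0) return("windowLength must be positive")
  if (any(object@windowOffsets < 0)) return("windowOffsets must be >= 0")
  if (anyDuplicated(object@windowOffsets))
    return("windowOffsets must be unique")
  TRUE
})

## ---------------------------------------------------------------------------
## Group comparison results
## ---------------------------------------------------------------------------

#' Group mean HFD map
#'
#' Mean Higuchi fractal dimension for one group and task, aggregated over
#' all trials and participants of the group, arranged as a
#' window-offset-by-channel matrix.
#'
#' @slot group group label.
#' @slot task task label.
#' @slot means numeric matrix, rows = window offsets (seconds, as names),
#'   columns = channels.
#' @slot nMissing number of missing feature rows excluded from the means.
#'
#' @seealso [groupMeanMap()]
#' @export
setClass("GroupMeanMap",
  representation(group = "character", task = "character",
                 means = "matrix", nMissing = "integer"))

#' Bootstrap group-difference test result
#'
#' Result of the two-tailed bootstrap test of equal group means. `M`
#' with-replacement resamples of each group (of that group's own size) yield
#' a distribution of mean differences; the empirical CDF of that
#' distribution evaluated at zero decides the test: the null is rejected at
#' level `p` when `ECDF(0) <= p/2` or `ECDF(0) >= 1 - p/2`. The corrected
#' decision applies the Bonferroni-adjusted level
#' `p * bonferroniFactor`.
#'
#' @slot channel channel label the test refers to (may be `NA`).
#' @slot observedDiff observed difference in group means (a minus b).
#' @slot M number of bootstrap replicates.
#' @slot ecdfAtZero fraction of replicate differences `<= 0`.
#' @slot propGeZero fraction of replicate differences `>= 0` (retained so
#'   that swapping the group order flips the result exactly).
#' @slot pNominal nominal two-tailed level.
#' @slot bonferroniFactor multiplicative correction factor (1/n channels).
#' @slot significantUncorrected rejection at the nominal level.
#' @slot significantCorrected rejection at the corrected level.
#' @slot seed integer seed used for resampling.
#'
#' @seealso [bootstrapTest()], [compareGroups()]
#' @export
setClass("BootstrapTestResult",
  representation(channel = "character", observedDiff = "numeric",
                 M = "numeric", ecdfAtZero = "numeric",
                 propGeZero = "numeric", pNominal = "numeric",
                 bonferroniFactor = "numeric",
                 significantUncorrected = "logical",
                 significantCorrected = "logical", seed = "integer"))

setValidity("BootstrapTestResult", function(object) {
  if (object@ecdfAtZero < 0 || object@ecdfAtZero > 1)
    return("ecdfAtZero must lie in [0, 1]")
  if (object@bonferroniFactor <= 0 || object@bonferroniFactor > 1)
    return("bonferroniFactor must lie in (0, 1]")
  if (object@significantCorrected && !object@significantUncorrected)
    return("a corrected-significant result must also be nominally significant")
  TRUE
})

## ---------------------------------------------------------------------------
## Classification
## ---------------------------------------------------------------------------

#' Classifier configuration
#'
#' Hyper-parameter grids and numerical settings for nu-SVC classification of
#' per-trial HFD feature vectors.
#'
#' @slot nuGrid candidate values of the nu-SVC parameter, each in (0, 1].
#'   nu upper-bounds the fraction of margin errors and lower-bounds the
#'   fraction of support vectors.
#' @slot offsetGrid candidate window offsets (seconds).
#' @slot kernel kernel name; only `"linear"` is supported.
#' @slot standardize logical; z-score features using training-fold
#'   statistics only.
#' @slot tolerance termination tolerance passed to the libsvm solver.
#'
#' @seealso [classifierConfig()], [nestedLosoEvaluate()]
#' @export
setClass("ClassifierConfig",
  representation(nuGrid = "numeric", offsetGrid = "numeric",
                 kernel = "character", standardize = "logical",
                 tolerance = "numeric"))

setValidity("ClassifierConfig", function(object) {
  if (length(object@nuGrid) == 0L) return("nuGrid must be non-empty")
  if (any(object@nuGrid <= 0 | object@nuGrid > 1))
    return("all nu values must lie in (0, 1]")
  if (length(object@offsetGrid) == 0L) return("offsetGrid must be non-empty")
  if (!identical(object@kernel, "linear"))
    return("only the linear kernel is supported")
  if (object@tolerance <= 0) return("tolerance must be positive")
  TRUE
})

#' Greedy channel selection result
#'
#' @slot channels selected channel labels, in order of selection.
#' @slot trace inner cross-validation accuracy after each addition;
#'   strictly increasing under the strict-improvement halting rule.
#' @slot haltReason why selection stopped: `"no_improvement"` or
#'   `"exhausted"`.
#'
#' @seealso [greedySelect()]
#' @export
setClass("ChannelSelection",
  representation(channels = "character", trace = "numeric",
                 haltReason = "character"))

setValidity("ChannelSelection", function(object) {
  if (anyDuplicated(object@channels)) return("selected channels must be unique")
  if (length(object@trace) != length(object@channels))
    return("trace must have one entry per selected channel")
  if (length(object@trace) > 1L && any(diff(object@trace) <= 0))
    return("accuracy trace must be strictly increasing")
  TRUE
})

#' Classifier evaluation report
#'
#' Held-out performance of the nested leave-one-subject-out evaluation (or
#' of a transfer evaluation): per-trial accuracy summarised across held-out
#' participants, pooled sensitivity and specificity, the percentage of
#' participants whose majority-vote prediction is correct, the winning
#' hyper-parameters per outer fold, and all per-trial predictions.
#'
#' @slot task task label evaluated.
#' @slot positiveClass group treated as positive for sensitivity.
#' @slot accuracyMean mean of per-participant trial accuracies.
#' @slot accuracySd standard deviation of per-participant trial accuracies.
#' @slot sensitivity pooled true-positive rate.
#' @slot specificity pooled true-negative rate.
#' @slot participantsCorrect percentage of participants correctly classified
#'   by majority vote over their trials (ties count as incorrect).
#' @slot folds data.frame with one row per outer fold: held-out participant,
#'   winning offset, nu, selected channels, inner accuracy, held-out trial
#'   accuracy.
#' @slot predictions data.frame of per-trial predictions (participant,
#'   trial, truth, predicted).
#' @slot modalConfig list with the modal winning configuration across folds
#'   (offset, nu, channels).
#'
#' @seealso [nestedLosoEvaluate()], [transferEvaluate()]
#' @export
setClass("EvalReport",
  representation(task = "character", positiveClass = "character",
                 accuracyMean = "numeric", accuracySd = "numeric",
                 sensitivity = "numeric", specificity = "numeric",
                 participantsCorrect = "numeric", folds = "data.frame",
                 predictions = "data.frame", modalConfig = "list"))

setValidity("EvalReport", function(object) {
  rates <- c(object@accuracyMean, object@sensitivity, object@specificity)
  rates <- rates[!is.na(rates)]
  if (any(rates < 0 | rates > 1))
    return("accuracy, sensitivity and specificity must lie in [0, 1]")
  if (!is.na(object@participantsCorrect) &&
      (object@participantsCorrect < 0 || object@participantsCorrect > 100))
    return("participantsCorrect must be a percentage in [0, 100]")
  TRUE
})
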