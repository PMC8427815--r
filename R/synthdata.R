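#' Create a synthetic dataset configuration
#'
#' The generator emulates the structure of cue-based motor-imagery EEG
#' studies: groups of participants, each recorded over repeated trials of
#' several imagery tasks at many electrodes. Every trial/channel signal is
#' a fractional Brownian motion path whose Hurst exponent is
#' `baseHurst + participant offset + groupEffect[[group]][channel]`, clipped
#' to `[0.05, 0.95]`. Group differences in signal complexity are therefore
#' planted at chosen channels with known magnitude, and participant-level
#' random effects induce the within-participant correlation of
#' classification errors seen in real cohorts.
#'
#' @param groups group labels.
#' @param participantsPerGroup participants per group.
#' @param trialsPerTask trials per task and participant.
#' @param tasks task labels (default left hand, right hand, legs).
#' @param samplingRate sampling rate in Hz.
#' @param trialDuration trial length in seconds; `samplingRate *
#'   trialDuration` must be an integer.
#' @param montage a [ChannelMontage-class].
#' @param baseHurst baseline Hurst exponent. The default 0.25 puts the
#'   baseline fractal dimension near 1.75, mid-way through the range
#'   typically estimated from motor-imagery EEG, leaving headroom for group
#'   effects of either sign.
#' @param groupEffect named list mapping group labels to named numeric
#'   vectors of per-channel Hurst shifts.
#' @param participantSd standard deviation of the per-participant Hurst
#'   offset.
#' @param seed integer seed.
#' @return a [SynthConfig-class].
#' @examples
#' cfg <- synthConfig(groups = c("sPDP", "sPNP"), participantsPerGroup = 2,
#'                    trialsPerTask = 3, tasks = "RH", samplingRate = 50,
#'                    montage = ChannelMontage(c("FCz", "CPz")),
#'                    groupEffect = list(sPDP = c(FCz = -0.15)))
#' @export
synthConfig <- function(groups = c("G1", "G2"), participantsPerGroup = 10,
                        trialsPerTask = 60, tasks = c("LH", "RH", "L"),
                        samplingRate = 250, trialDuration = 5,
                        montage = standardMontage("61"), baseHurst = 0.25,
                        groupEffect = list(), participantSd = 0.03,
                        seed = 1) {
  new("SynthConfig", groups = as.character(groups),
      participantsPerGroup = as.integer(participantsPerGroup),
      trialsPerTask = as.integer(trialsPerTask), tasks = as.character(tasks),
      samplingRate = samplingRate, trialDuration = trialDuration,
      montage = montage, baseHurst = baseHurst,
      groupEffect = lapply(groupEffect, function(e) {
        v <- as.numeric(e); names(v) <- names(e); v
      }),
      participantSd = participantSd, seed = as.integer(seed))
}

#' Preset configurations mirroring the two cohort layouts
#'
#' `"dataset1"`: three groups (AB, cPWP, cPNP) of 10 participants, 61
#' channels at 250 Hz. `"dataset2"`: two groups (sPDP, sPNP) of 10
#' participants, 48 channels at 256 Hz. Both use 60 trials per task of the
#' three motor-imagery tasks (LH, RH, L) and 5-s trials.
#'
#' @param preset `"dataset1"` or `"dataset2"`.
#' @param ... overrides passed on to [synthConfig()].
#' @return a [SynthConfig-class].
#' @examples
#' datasetPreset("dataset2", participantsPerGroup = 2, trialsPerTask = 3)
#' @export
datasetPreset <- function(preset = c("dataset1", "dataset2"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    dataset1 = list(groups = c("AB", "cPWP", "cPNP"), samplingRate = 250,
                    montage = standardMontage("61")),
    dataset2 = list(groups = c("sPDP", "sPNP"), samplingRate = 256,
                    montage = standardMontage("48")))
  args <- utils::modifyList(base, list(...))
  do.call(synthConfig, args)
}

#' Generate a synthetic EEG epoch dataset
#'
#' Deterministic given the configuration (including its seed): the same
#' [SynthConfig-class] always produces a bit-identical
#' [EpochsDataset-class].
#'
#' @param config a [SynthConfig-class].
#' @return an [EpochsDataset-class] whose data array is indexed
#'   `(participant, trial, task, channel, sample)`.
#' @examples
#' cfg <- synthConfig(participantsPerGroup = 2, trialsPerTask = 2,
#'                    tasks = "RH", samplingRate = 50,
#'                    montage = ChannelMontage(c("FCz", "CPz")))
#' ds <- generateDataset(cfg)
#' dim(epochsData(ds))
#' @export
generateDataset <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  nG <- length(config@groups)
  nP <- config@participantsPerGroup
  nT <- config@trialsPerTask
  nTask <- length(config@tasks)
  chans <- config@montage@labels
  nC <- length(chans)
  nS <- as.integer(round(config@samplingRate * config@trialDuration))

  pid <- as.vector(vapply(config@groups, function(g)
    sprintf("%s%02d", g, seq_len(nP)), character(nP)))
  grp <- rep(config@groups, each = nP)
  names(grp) <- pid

  # per (group, channel) Hurst shift
  shift <- matrix(0, nG, nC, dimnames = list(config@groups, chans))
  for (g in names(config@groupEffect)) {
    eff <- config@groupEffect[[g]]
    shift[g, names(eff)] <- eff
  }

  data <- array(NA_real_,
                dim = c(nG * nP, nT, nTask, nC, nS),
                dimnames = list(pid, sprintf("t%02d", seq_len(nT)),
                                config@tasks, chans, NULL))
  evCache <- new.env(parent = emptyenv())
  withSeed(config@seed, {
    pOffset <- stats::rnorm(nG * nP, 0, config@participantSd)
    for (p in seq_along(pid)) {
      for (ci in seq_len(nC)) {
        h <- clipHurst(config@baseHurst + pOffset[p] + shift[grp[p], ci])
        key <- sprintf("%.15g", h)
        ev <- evCache[[key]]
        if (is.null(ev)) {
          ev <- fgnEigenvalues(nS, h)
          evCache[[key]] <- ev
        }
        for (ti in seq_len(nTask)) {
          paths <- fbmPathsFromStream(nS, ev, nT)   # nS x nT
          data[p, , ti, ci, ] <- t(paths)
        }
      }
    }
  })
  new("EpochsDataset", data = data, samplingRate = config@samplingRate,
      montage = config@montage, groupOf = grp,
      provenance = list(kind = "synthetic",
                        trialDuration = config@trialDuration,
                        config = synthConfigAsList(config)))
}

# Plain-list rendering of a SynthConfig (for provenance / JSON metadata).
synthConfigAsList <- function(config) {
  list(groups = config@groups,
       participantsPerGroup = config@participantsPerGroup,
       trialsPerTask = config@trialsPerTask, tasks = config@tasks,
       samplingRate = config@samplingRate,
       trialDuration = config@trialDuration,
       montage = list(labels = config@montage@labels,
                      x = unname(config@montage@positions[, 1]),
                      y = unname(config@montage@positions[, 2])),
       baseHurst = config@baseHurst,
       groupEffect = lapply(config@groupEffect, as.list),
       participantSd = config@participantSd, seed = config@seed)
}

#' Permute group labels across participants
#'
#' Randomly reassigns the existing multiset of group labels to the
#' participants of a feature table (labels permuted at the participant
#' level, so all trials of a participant move together). Used for
#' permutation-based chance-level calibration of the classification
#' pipeline.
#'
#' @param features a feature table (see [extractFeatures()]).
#' @param seed integer seed.
#' @return the feature table with its `group` column rewritten.
#' @export
permuteGroupLabels <- function(features, seed) {
  pid <- unique(features$participant)
  g <- features$group[match(pid, features$participant)]
  newg <- withSeed(seed, sample(g))
  names(newg) <- pid
  features$group <- unname(newg[features$participant])
  features
}
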