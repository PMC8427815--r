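#' @include AllClasses.R
NULL

#' Accessors for fractalEEG S4 classes
#'
#' Small accessor generics: `channelNames()` and `channelPositions()` for
#' montages and datasets, `nChannels()` for the channel count,
#' `samplingRate()`, `groupOf()`, `taskLabels()`, `participantIds()` and
#' `epochsData()` for [EpochsDataset-class] objects, `meanMatrix()` for
#' [GroupMeanMap-class], and `selectedChannels()` / `accuracyTrace()` for
#' [ChannelSelection-class].
#'
#' @param x the object.
#' @return the corresponding slot content (see each class's documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("channelPositions", function(x) standardGeneric("channelPositions"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("montage", function(x) standardGeneric("montage"))
#' @rdname accessors
#' @export
setGeneric("groupOf", function(x) standardGeneric("groupOf"))
#' @rdname accessors
#' @export
setGeneric("taskLabels", function(x) standardGeneric("taskLabels"))
#' @rdname accessors
#' @export
setGeneric("participantIds", function(x) standardGeneric("participantIds"))
#' @rdname accessors
#' @export
setGeneric("epochsData", function(x) standardGeneric("epochsData"))
#' @rdname accessors
#' @export
setGeneric("meanMatrix", function(x) standardGeneric("meanMatrix"))
#' @rdname accessors
#' @export
setGeneric("selectedChannels", function(x) standardGeneric("selectedChannels"))
#' @rdname accessors
#' @export
setGeneric("accuracyTrace", function(x) standardGeneric("accuracyTrace"))

#' @rdname accessors
#' @export
setMethod("channelNames", "ChannelMontage", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("channelPositions", "ChannelMontage", function(x) {
  p <- x@positions
  dimnames(p) <- list(x@labels, c("x", "y"))
  p
})
#' @rdname accessors
#' @export
setMethod("nChannels", "ChannelMontage", function(x) length(x@labels))

#' @rdname accessors
#' @export
setMethod("channelNames", "EpochsDataset", function(x) x@montage@labels)
#' @rdname accessors
#' @export
setMethod("nChannels", "EpochsDataset", function(x) length(x@montage@labels))
#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochsDataset", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("montage", "EpochsDataset", function(x) x@montage)
#' @rdname accessors
#' @export
setMethod("groupOf", "EpochsDataset", function(x) x@groupOf)
#' @rdname accessors
#' @export
setMethod("taskLabels", "EpochsDataset", function(x) dimnames(x@data)[[3]])
#' @rdname accessors
#' @export
setMethod("participantIds", "EpochsDataset", function(x) dimnames(x@data)[[1]])
#' @rdname accessors
#' @export
setMethod("epochsData", "EpochsDataset", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("meanMatrix", "GroupMeanMap", function(x) x@means)
#' @rdname accessors
#' @export
setMethod("selectedChannels", "ChannelSelection", function(x) x@channels)
#' @rdname accessors
#' @export
setMethod("accuracyTrace", "ChannelSelection", function(x) x@trace)

## show methods -------------------------------------------------------------

setMethod("show", "ChannelMontage", function(object) {
  cat(sprintf("ChannelMontage with %d channels\n", length(object@labels)))
  cat("  ", paste(utils::head(object@labels, 10), collapse = " "),
      if (length(object@labels) > 10) "...\n" else "\n")
})

setMethod("show", "EpochsDataset", function(object) {
  d <- dim(object@data)
  cat("EpochsDataset\n")
  cat(sprintf("  %d participants x %d trials x %d tasks x %d channels x %d samples\n",
              d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  sampling rate: %g Hz\n", object@samplingRate))
  tab <- table(object@groupOf[participantIds(object)])
  cat("  groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  cat("  tasks:", paste(taskLabels(object), collapse = ", "), "\n")
})

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig\n")
  cat(sprintf("  groups: %s; %d participants/group; %d trials/task; tasks: %s\n",
              paste(object@groups, collapse = ", "),
              object@participantsPerGroup, object@trialsPerTask,
              paste(object@tasks, collapse = ", ")))
  cat(sprintf("  %g Hz, %g s trials, %d channels; baseHurst %.2f, participantSd %.3f, seed %d\n",
              object@samplingRate, object@trialDuration,
              length(object@montage@labels), object@baseHurst,
              object@participantSd, object@seed))
  if (length(object@groupEffect)) {
    for (g in names(object@groupEffect)) {
      eff <- object@groupEffect[[g]]
      cat(sprintf("  effect[%s]: %s\n", g,
                  paste(sprintf("%s=%+.3g", names(eff), eff), collapse = ", ")))
    }
  }
})

setMethod("show", "GroupMeanMap", function(object) {
  cat(sprintf("GroupMeanMap: group %s, task %s (%d offsets x %d channels)\n",
              object@group, object@task, nrow(object@means), ncol(object@means)))
  print(round(object@means[, seq_len(min(6L, ncol(object@means))), drop = FALSE], 3))
  if (ncol(object@means) > 6L) cat("  ...\n")
})

setMethod("show", "BootstrapTestResult", function(object) {
  cat(sprintf("BootstrapTestResult%s\n",
              if (!is.na(object@channel)) paste0(" [", object@channel, "]") else ""))
  cat(sprintf("  observed diff %+.4g, ECDF(0) = %.4g (M = %g)\n",
              object@observedDiff, object@ecdfAtZero, object@M))
  cat(sprintf("  significant: uncorrected %s, corrected %s (p = %g, factor = %g)\n",
              object@significantUncorrected, object@significantCorrected,
              object@pNominal, object@bonferroniFactor))
})

setMethod("show", "ChannelSelection", function(object) {
  cat("ChannelSelection:", paste(object@channels, collapse = " > "), "\n")
  cat("  trace:", paste(sprintf("%.3f", object@trace), collapse = " "),
      sprintf(" (halt: %s)\n", object@haltReason))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: task %s (positive class %s)\n",
              object@task, object@positiveClass))
  cat(sprintf("  accuracy %.2f +/- %.2f | sensitivity %.2f | specificity %.2f | participants correct %.0f%%\n",
              object@accuracyMean, object@accuracySd, object@sensitivity,
              object@specificity, object@participantsCorrect))
  mc <- object@modalConfig
  cat(sprintf("  modal config: offset %g s, nu %g, channels %s\n",
              mc$offset, mc$nu, paste(mc$channels, collapse = ", ")))
})
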