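#' Classifier configuration
#'
#' @param nuGrid candidate nu-SVC values; the default lattice 0.05 to 0.95
#'   in steps of 0.025 covers the values that win in practice.
#' @param offsetGrid candidate window offsets (seconds).
#' @param kernel only `"linear"`.
#' @param standardize z-score features with training-fold statistics.
#' @param tolerance libsvm termination tolerance. The default 0.01 is
#'   looser than the solver's own 0.001; on feature-scale data it changes
#'   no predictions while roughly halving fit time.
#' @return a [ClassifierConfig-class].
#' @export
classifierConfig <- function(nuGrid = seq(0.05, 0.95, by = 0.025),
                             offsetGrid = c(0, 1, 2, 3), kernel = "linear",
                             standardize = TRUE, tolerance = 0.01) {
  new("ClassifierConfig", nuGrid = nuGrid, offsetGrid = offsetGrid,
      kernel = kernel, standardize = standardize, tolerance = tolerance)
}

#' Per-trial design matrix for one task and offset
#'
#' Pivots a feature table into one row per trial with one column per
#' requested channel (in the requested order), plus group labels and
#' participant ids. Trials with a missing feature in any requested channel
#' are dropped with a message.
#'
#' @param features a feature table ([extractFeatures()]).
#' @param task task label.
#' @param channels channel labels, defining column order.
#' @param offset window offset in seconds.
#' @return list with elements `x` (matrix), `y` (character group labels),
#'   `participant`, `trial`.
#' @export
trialVectors <- function(features, task, channels, offset) {
  w <- wideFeatures(features, task, offset, channels)
  if (w$nDropped > 0L)
    message(sprintf("trialVectors: %d trial(s) dropped for missing features",
                    w$nDropped))
  w[c("x", "y", "participant", "trial")]
}

# Internal pivot used across the classification module (silent).
wideFeatures <- function(features, task, offset, channels) {
  missingCh <- setdiff(channels, unique(features$channel))
  if (length(missingCh))
    stop(sprintf("channel(s) absent from the feature table: %s",
                 paste(missingCh, collapse = ", ")), call. = FALSE)
  sel <- features$task == task & features$offset == offset &
    features$channel %in% channels
  ft <- features[sel, ]
  if (!nrow(ft))
    stop(sprintf("no features for task '%s' at offset %g", task, offset),
         call. = FALSE)
  dt <- data.table::as.data.table(ft)
  wide <- as.data.frame(data.table::dcast(dt,
    group + participant + trial ~ channel, value.var = "hfd"))
  x <- as.matrix(wide[, channels, drop = FALSE])
  keep <- stats::complete.cases(x)
  list(x = x[keep, , drop = FALSE], y = wide$group[keep],
       participant = wide$participant[keep], trial = wide$trial[keep],
       nDropped = sum(!keep))
}

# Fit a linear nu-SVC on (xtr, ytr) and predict xte. Standardisation uses
# training statistics only (zero-variance columns get unit scale). Returns
# NULL when the solver rejects nu as infeasible for this class balance.
fitPredictNuSvc <- function(xtr, ytr, xte, nu, config) {
  ytr <- factor(ytr)
  if (config@standardize) {
    ctr <- colMeans(xtr)
    sds <- apply(xtr, 2L, stats::sd)
    sds[sds == 0 | is.na(sds)] <- 1
    xtr <- scale(xtr, center = ctr, scale = sds)
    xte <- scale(xte, center = ctr, scale = sds)
  }
  fit <- tryCatch(
    e1071::svm(xtr, ytr, type = "nu-classification", kernel = "linear",
               nu = nu, scale = FALSE, tolerance = config@tolerance),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  as.character(stats::predict(fit, xte))
}

# Leave-one-participant-out accuracy of a nu-SVC on the given design
# matrix; pooled over all predicted trials. NA when any fold is unfittable.
innerLopoAccuracy <- function(x, y, pid, nu, config) {
  ids <- unique(pid)
  correct <- 0L
  for (hold in ids) {
    te <- pid == hold
    pred <- fitPredictNuSvc(x[!te, , drop = FALSE], y[!te],
                            x[te, , drop = FALSE], nu, config)
    if (is.null(pred)) return(NA_real_)
    correct <- correct + sum(pred == y[te])
  }
  correct / length(y)
}

# Greedy forward channel selection on a prepared design matrix.
greedyCore <- function(x, y, pid, nu, config) {
  y <- factor(y)
  if (nlevels(y) < 2L)
    stop("training set contains a single class", call. = FALSE)
  pool <- colnames(x)
  selected <- character(0)
  trace <- numeric(0)
  best <- -Inf
  halt <- "exhausted"
  while (length(pool)) {
    accs <- vapply(pool, function(ch)
      innerLopoAccuracy(x[, c(selected, ch), drop = FALSE], y, pid, nu,
                        config), numeric(1))
    if (all(is.na(accs))) {
      if (!length(selected))
        stop("nu infeasible for every candidate channel", call. = FALSE)
      halt <- "no_improvement"
      break
    }
    accs[is.na(accs)] <- -Inf
    i <- which.max(accs)          # ties: first in montage order wins
    if (accs[i] <= best) { halt <- "no_improvement"; break }
    best <- accs[i]
    selected <- c(selected, pool[i])
    trace <- c(trace, best)
    pool <- pool[-i]
  }
  list(channels = selected, trace = trace, haltReason = halt,
       accuracy = best)
}

#' Greedy forward channel selection
#'
#' Wrapper selection of EEG channels for a nu-SVC: starting from the empty
#' set, each iteration evaluates the inner leave-one-participant-out
#' cross-validation accuracy of every remaining channel joined to the
#' selected set and adds the best performer; ties are broken in favour of
#' the channel listed first (montage order). Selection halts when no
#' candidate strictly improves the accuracy.
#'
#' @param features a feature table ([extractFeatures()]).
#' @param task task label.
#' @param offset window offset in seconds.
#' @param nu nu-SVC parameter.
#' @param channels candidate channel pool, in montage order (default: the
#'   channels of the feature table in order of appearance).
#' @param config a [ClassifierConfig-class] (grids are ignored here).
#' @return a [ChannelSelection-class].
#' @export
greedySelect <- function(features, task, offset, nu,
                         channels = unique(features$channel),
                         config = classifierConfig()) {
  w <- wideFeatures(features, task, offset, channels)
  ids <- unique(w$participant)
  perClass <- table(w$y[match(ids, w$participant)])
  if (length(perClass) < 2L || any(perClass < 2L))
    stop("need at least two participants per class", call. = FALSE)
  g <- greedyCore(w$x, w$y, w$participant, nu, config)
  new("ChannelSelection", channels = g$channels, trace = g$trace,
      haltReason = g$haltReason)
}

#' Majority-vote participant-level predictions
#'
#' Aggregates per-trial predictions into one prediction per participant:
#' the class most frequently predicted across that participant's trials.
#' An exact tie yields no vote and counts as incorrect (conservative).
#'
#' @param predictions `data.frame` with columns `participant`, `truth`,
#'   `predicted`.
#' @return list with `votes` (a `data.frame` of participant, truth, vote,
#'   correct) and `percentCorrect`.
#' @examples
#' p <- data.frame(participant = rep("s1", 60), truth = "a",
#'                 predicted = rep(c("a", "b"), c(40, 20)))
#' majorityVote(p)$percentCorrect  # 100
#' @export
majorityVote <- function(predictions) {
  stopifnot(all(c("participant", "truth", "predicted") %in%
                  names(predictions)))
  ids <- unique(predictions$participant)
  votes <- data.frame(participant = ids, truth = NA_character_,
                      vote = NA_character_, correct = FALSE,
                      stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    rows <- predictions$participant == ids[i]
    votes$truth[i] <- predictions$truth[rows][1]
    tab <- table(predictions$predicted[rows])
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) votes$vote[i] <- top
    votes$correct[i] <- !is.na(votes$vote[i]) &&
      votes$vote[i] == votes$truth[i]
  }
  list(votes = votes, percentCorrect = 100 * mean(votes$correct))
}

# Assemble an EvalReport from accumulated per-fold results.
buildEvalReport <- function(task, positiveClass, folds, predictions) {
  perPart <- tapply(predictions$predicted == predictions$truth,
                    predictions$participant, mean)
  isPos <- predictions$truth == positiveClass
  sens <- if (any(isPos)) mean(predictions$predicted[isPos] == positiveClass)
          else NA_real_
  spec <- if (any(!isPos)) mean(predictions$predicted[!isPos] != positiveClass)
          else NA_real_
  mv <- majorityVote(predictions)
  cfgKey <- sprintf("%g|%g|%s", folds$offset, folds$nu, folds$channels)
  modal <- folds[match(names(which.max(table(cfgKey))), cfgKey), ]
  new("EvalReport", task = task, positiveClass = positiveClass,
      accuracyMean = mean(perPart), accuracySd = stats::sd(perPart),
      sensitivity = sens, specificity = spec,
      participantsCorrect = mv$percentCorrect, folds = folds,
      predictions = predictions,
      modalConfig = list(offset = modal$offset, nu = modal$nu,
                         channels = strsplit(modal$channels, ",")[[1]]))
}

#' Nested leave-one-subject-out evaluation
#'
#' The transferability estimate of the classification pipeline. The outer
#' loop holds out each participant once. Within each outer fold, a grid
#' search over `(offset, nu)` is run on the training participants: for
#' every grid point the channel subset is re-optimised by [greedySelect]'s
#' procedure under inner leave-one-participant-out cross-validation, and
#' the grid point (with its selected channels) achieving the highest inner
#' accuracy wins (ties: earlier grid point). A classifier with the winning
#' configuration is then trained on all training participants and applied
#' to the held-out participant's trials. Standardisation statistics are
#' always fitted on the training side only, so no information from the
#' held-out participant leaks into training.
#'
#' @param features a feature table ([extractFeatures()]) containing exactly
#'   two groups.
#' @param task task label to evaluate.
#' @param config a [ClassifierConfig-class].
#' @param channels candidate channel pool (default: all channels of the
#'   table, in order of appearance).
#' @param positiveClass group treated as positive for sensitivity
#'   (default: alphabetically first).
#' @return an [EvalReport-class].
#' @export
nestedLosoEvaluate <- function(features, task, config = classifierConfig(),
                               channels = unique(features$channel),
                               positiveClass = NULL) {
  groups <- sort(unique(features$group))
  if (length(groups) != 2L)
    stop("feature table must contain exactly two groups", call. = FALSE)
  if (is.null(positiveClass)) positiveClass <- groups[1]
  if (length(config@nuGrid) == 0L || length(config@offsetGrid) == 0L)
    stop("hyper-parameter grids must be non-empty", call. = FALSE)

  wides <- lapply(config@offsetGrid, function(o)
    wideFeatures(features, task, o, channels))
  ids <- unique(wides[[1]]$participant)
  perClass <- table(wides[[1]]$y[match(ids, wides[[1]]$participant)])
  if (length(perClass) < 2L || any(perClass < 2L))
    stop("need at least two participants per class", call. = FALSE)

  folds <- vector("list", length(ids))
  preds <- vector("list", length(ids))
  for (f in seq_along(ids)) {
    hold <- ids[f]
    best <- list(acc = -Inf)
    for (oi in seq_along(config@offsetGrid)) {
      w <- wides[[oi]]
      tr <- w$participant != hold
      for (nu in config@nuGrid) {
        g <- tryCatch(
          greedyCore(w$x[tr, , drop = FALSE], w$y[tr], w$participant[tr],
                     nu, config),
          error = function(e) NULL)
        if (is.null(g) || !is.finite(g$accuracy)) next
        if (g$accuracy > best$acc)
          best <- list(acc = g$accuracy, oi = oi, nu = nu,
                       channels = g$channels)
      }
    }
    if (!is.finite(best$acc))
      stop(sprintf("no feasible grid point for held-out participant '%s'",
                   hold), call. = FALSE)
    w <- wides[[best$oi]]
    tr <- w$participant != hold
    pred <- fitPredictNuSvc(w$x[tr, best$channels, drop = FALSE], w$y[tr],
                            w$x[!tr, best$channels, drop = FALSE], best$nu,
                            config)
    folds[[f]] <- data.frame(heldOut = hold,
                             offset = config@offsetGrid[best$oi],
                             nu = best$nu,
                             channels = paste(best$channels, collapse = ","),
                             innerAccuracy = best$acc,
                             trialAccuracy = mean(pred == w$y[!tr]),
                             stringsAsFactors = FALSE)
    preds[[f]] <- data.frame(participant = hold, trial = w$trial[!tr],
                             truth = w$y[!tr], predicted = pred,
                             stringsAsFactors = FALSE)
  }
  buildEvalReport(task, positiveClass, do.call(rbind, folds),
                  do.call(rbind, preds))
}

#' Transfer evaluation with frozen channels and offset
#'
#' Evaluates a classifier on a target cohort using the channel subset and
#' window offset learned on a source cohort: within each outer
#' leave-one-subject-out fold only nu is re-optimised by inner
#' leave-one-participant-out cross-validation, the features being fixed to
#' `sourceChannels` at `sourceOffset`.
#'
#' @param features target cohort feature table (two groups).
#' @param task task label.
#' @param sourceChannels channels learned on the source cohort; must exist
#'   in the target feature table.
#' @param sourceOffset window offset (seconds) learned on the source
#'   cohort.
#' @param config a [ClassifierConfig-class]; only `nuGrid` is searched.
#' @param positiveClass see [nestedLosoEvaluate()].
#' @return an [EvalReport-class].
#' @export
transferEvaluate <- function(features, task, sourceChannels, sourceOffset,
                             config = classifierConfig(),
                             positiveClass = NULL) {
  groups <- sort(unique(features$group))
  if (length(groups) != 2L)
    stop("feature table must contain exactly two groups", call. = FALSE)
  if (is.null(positiveClass)) positiveClass <- groups[1]
  w <- wideFeatures(features, task, sourceOffset, sourceChannels)
  ids <- unique(w$participant)
  folds <- vector("list", length(ids))
  preds <- vector("list", length(ids))
  for (f in seq_along(ids)) {
    hold <- ids[f]
    tr <- w$participant != hold
    accs <- vapply(config@nuGrid, function(nu)
      innerLopoAccuracy(w$x[tr, , drop = FALSE], w$y[tr],
                        w$participant[tr], nu, config), numeric(1))
    if (all(is.na(accs)))
      stop(sprintf("nu infeasible for held-out participant '%s'", hold),
           call. = FALSE)
    accs[is.na(accs)] <- -Inf
    nu <- config@nuGrid[which.max(accs)]
    pred <- fitPredictNuSvc(w$x[tr, , drop = FALSE], w$y[tr],
                            w$x[!tr, , drop = FALSE], nu, config)
    folds[[f]] <- data.frame(heldOut = hold, offset = sourceOffset, nu = nu,
                             channels = paste(sourceChannels, collapse = ","),
                             innerAccuracy = max(accs),
                             trialAccuracy = mean(pred == w$y[!tr]),
                             stringsAsFactors = FALSE)
    preds[[f]] <- data.frame(participant = hold, trial = w$trial[!tr],
                             truth = w$y[!tr], predicted = pred,
                             stringsAsFactors = FALSE)
  }
  buildEvalReport(task, positiveClass, do.call(rbind, folds),
                  do.call(rbind, preds))
}

#' Render an evaluation report as a plain list
#'
#' Convenience for JSON export of an [EvalReport-class].
#'
#' @param report an [EvalReport-class].
#' @return a nested list mirroring the report's slots.
#' @export
evalReportAsList <- function(report) {
  list(task = report@task, positiveClass = report@positiveClass,
       accuracyMean = report@accuracyMean, accuracySd = report@accuracySd,
       sensitivity = report@sensitivity, specificity = report@specificity,
       participantsCorrect = report@participantsCorrect,
       modalConfig = report@modalConfig,
       folds = report@folds, predictions = report@predictions)
}
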