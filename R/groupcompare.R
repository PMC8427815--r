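#' Group mean HFD map
#'
#' Aggregates a feature table into the mean HFD of one group and task per
#' window offset and channel (the mean over all trials and participants of
#' the group). Missing features are excluded and counted.
#'
#' @param features a feature table ([extractFeatures()]).
#' @param group group label.
#' @param task task label.
#' @return a [GroupMeanMap-class] whose matrix has one row per window
#'   offset and one column per channel (channels in alphabetical order, so
#'   the map does not depend on feature-table row order).
#' @export
groupMeanMap <- function(features, group, task) {
  sel <- features$group == group & features$task == task
  if (!any(sel))
    stop(sprintf("no rows for group '%s', task '%s'", group, task),
         call. = FALSE)
  ft <- features[sel, ]
  chans <- sort(unique(features$channel))
  offs <- sort(unique(ft$offset))
  nMissing <- sum(is.na(ft$hfd))
  means <- tapply(ft$hfd, list(factor(ft$offset, levels = offs),
                               factor(ft$channel, levels = chans)),
                  mean, na.rm = TRUE)
  means <- matrix(as.numeric(means), length(offs), length(chans),
                  dimnames = list(as.character(offs), chans))
  if (nMissing > 0L)
    message(sprintf("groupMeanMap: %d missing feature(s) excluded", nMissing))
  new("GroupMeanMap", group = group, task = task, means = means,
      nMissing = as.integer(nMissing))
}

# Bootstrap replicate counts: resample na values of a and nb values of b
# with replacement M times; count replicate mean differences <= 0 and >= 0.
# Indices are drawn as floor(runif * n) + 1, a discrete-uniform draw that is
# considerably faster than sample.int at these volumes.
bootstrapCounts <- function(a, b, M) {
  na <- length(a); nb <- length(b)
  cntLe <- 0; cntGe <- 0; done <- 0
  chunk <- max(1L, floor(4e6 / (na + nb)))
  while (done < M) {
    m <- min(chunk, M - done)
    ma <- .colMeans(a[floor(stats::runif(na * m) * na) + 1L], na, m)
    mb <- .colMeans(b[floor(stats::runif(nb * m) * nb) + 1L], nb, m)
    d <- ma - mb
    cntLe <- cntLe + sum(d <= 0)
    cntGe <- cntGe + sum(d >= 0)
    done <- done + m
  }
  c(le = cntLe, ge = cntGe)
}

#' Bootstrap test of equal group means
#'
#' Two-tailed bootstrap test of `H0: mu_a - mu_b = 0`. `M` synthetic
#' feature sets are drawn by resampling each group with replacement (each
#' group at its own size; 600 in the canonical 60-trials-by-10-participants
#' design) and the difference of their means computed. The empirical CDF of
#' these `M` differences evaluated at 0 drives the decision: `H0` is
#' rejected at level `p` when `ECDF(0) <= p/2` or `ECDF(0) >= 1 - p/2`; the
#' corrected decision uses the Bonferroni-adjusted level
#' `p * bonferroniFactor`.
#'
#' The test as stated reads the percentile of zero off the un-recentred
#' resampled difference distribution. `recentre = TRUE` switches to the
#' textbook variant that recentres the resampled distribution under the
#' null before comparing (equivalently, evaluates the ECDF at twice the
#' observed difference); it is not the default.
#'
#' @param a,b numeric feature vectors for the two groups.
#' @param M number of bootstrap replicates (>= 100; 1e6 mirrors the
#'   full-scale analysis, smaller values suit interactive use).
#' @param pNominal nominal two-tailed level.
#' @param bonferroniFactor multiplicative correction (1/n channels when
#'   testing each channel of a montage).
#' @param seed integer seed; results are deterministic given the seed.
#' @param recentre use the recentred decision rule (see Details).
#' @param channel optional channel label carried into the result.
#' @return a [BootstrapTestResult-class].
#' @examples
#' a <- rnorm(600, 1.9, 0.05); b <- rnorm(600, 1.8, 0.05)
#' bootstrapTest(a, b, M = 1000, seed = 1)
#' @export
bootstrapTest <- function(a, b, M = 1e6, pNominal = 0.05,
                          bonferroniFactor = 1, seed = 1, recentre = FALSE,
                          channel = NA_character_) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must contain non-missing features", call. = FALSE)
  if (M < 100) stop("M must be >= 100", call. = FALSE)
  dObs <- mean(a) - mean(b)
  cnt <- withSeed(seed, {
    if (recentre) bootstrapCountsAt(a, b, M, 2 * dObs)
    else bootstrapCounts(a, b, M)
  })
  ecdf0 <- unname(cnt["le"]) / M
  pc <- pNominal * bonferroniFactor
  sigU <- ecdf0 <= pNominal / 2 || ecdf0 >= 1 - pNominal / 2
  sigC <- ecdf0 <= pc / 2 || ecdf0 >= 1 - pc / 2
  new("BootstrapTestResult", channel = channel, observedDiff = dObs,
      M = M, ecdfAtZero = ecdf0, propGeZero = unname(cnt["ge"]) / M,
      pNominal = pNominal, bonferroniFactor = bonferroniFactor,
      significantUncorrected = sigU, significantCorrected = sigC,
      seed = as.integer(seed))
}

# Recentred variant: counts of replicate differences <= tau and >= tau,
# where tau = 2 * observed difference (ECDF of the null-centred
# distribution evaluated at the observed difference).
bootstrapCountsAt <- function(a, b, M, tau) {
  na <- length(a); nb <- length(b)
  cntLe <- 0; cntGe <- 0; done <- 0
  chunk <- max(1L, floor(4e6 / (na + nb)))
  while (done < M) {
    m <- min(chunk, M - done)
    ma <- .colMeans(a[floor(stats::runif(na * m) * na) + 1L], na, m)
    mb <- .colMeans(b[floor(stats::runif(nb * m) * nb) + 1L], nb, m)
    d <- ma - mb
    cntLe <- cntLe + sum(d <= tau)
    cntGe <- cntGe + sum(d >= tau)
    done <- done + m
  }
  c(le = cntLe, ge = cntGe)
}

#' Channel-wise bootstrap comparison of two groups
#'
#' Runs the bootstrap mean-difference test at every channel for one task
#' and window offset, with per-channel Bonferroni factor `1/n_channels`
#' (0.05/61 gives the corrected per-channel threshold of about 8.2e-4 on a
#' 61-channel montage). The observed differences form the red/blue
#' topography; the uncorrected and corrected flags mark the grey and black
#' electrodes of the usual rendering.
#'
#' Results are exactly antisymmetric in the pair order: swapping the pair
#' negates the differences and leaves both significance flags unchanged
#' (the resampling is performed once in a canonical group order).
#'
#' @param features a feature table ([extractFeatures()]).
#' @param pair character vector of two group labels (a, b); differences are
#'   reported as mean(a) - mean(b).
#' @param task task label.
#' @param windowOffset window offset in seconds.
#' @param M,pNominal,seed,recentre see [bootstrapTest()]. Each channel uses
#'   the sub-seed `seed + i - 1` with `i` its rank in alphabetical channel
#'   order, so results do not depend on row order or pair order.
#' @return a `data.frame` with one row per channel: `channel, task, offset,
#'   groupA, groupB, nA, nB, difference, ecdfAtZero, pNominal,
#'   bonferroniFactor, significantUncorrected, significantCorrected, seed`.
#' @export
compareGroups <- function(features, pair, task, windowOffset, M = 1e6,
                          pNominal = 0.05, seed = 1, recentre = FALSE) {
  stopifnot(length(pair) == 2L)
  for (g in pair)
    if (!any(features$group == g))
      stop(sprintf("group '%s' not present in the feature table", g),
           call. = FALSE)
  sel <- features$task == task & features$offset == windowOffset &
    features$group %in% pair
  ft <- features[sel, ]
  if (!nrow(ft))
    stop(sprintf("no features for task '%s' at offset %g", task,
                 windowOffset), call. = FALSE)
  chans <- sort(unique(features$channel))   # stable channel -> sub-seed map
  factor <- 1 / length(chans)
  canon <- sort(pair)
  flip <- !identical(as.character(pair), canon)
  rows <- vector("list", length(chans))
  for (i in seq_along(chans)) {
    va <- ft$hfd[ft$channel == chans[i] & ft$group == canon[1]]
    vb <- ft$hfd[ft$channel == chans[i] & ft$group == canon[2]]
    r <- bootstrapTest(va, vb, M = M, pNominal = pNominal,
                       bonferroniFactor = factor, seed = seed + i - 1,
                       recentre = recentre, channel = chans[i])
    diff <- r@observedDiff
    ecdf0 <- r@ecdfAtZero
    if (flip) {
      diff <- -diff
      ecdf0 <- r@propGeZero   # ECDF(0) of the negated replicate distribution
    }
    rows[[i]] <- data.frame(channel = chans[i], task = task,
                            offset = windowOffset, groupA = pair[1],
                            groupB = pair[2],
                            nA = length(stats::na.omit(if (flip) vb else va)),
                            nB = length(stats::na.omit(if (flip) va else vb)),
                            difference = diff, ecdfAtZero = ecdf0,
                            pNominal = pNominal, bonferroniFactor = factor,
                            significantUncorrected = r@significantUncorrected,
                            significantCorrected = r@significantCorrected,
                            seed = r@seed, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "M") <- M
  out
}

#' Plot a difference topography
#'
#' Minimal scalp rendering of a channel-wise comparison: electrodes at
#' their montage positions, coloured by the observed mean difference (red
#' positive, blue negative), ringed in grey when nominally significant and
#' in black when significant after Bonferroni correction.
#'
#' @param comparison result of [compareGroups()].
#' @param montage the [ChannelMontage-class] the features came from.
#' @param labels draw channel labels.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the comparison.
#' @export
plotTopography <- function(comparison, montage, labels = FALSE, ...) {
  pos <- channelPositions(montage)[comparison$channel, , drop = FALSE]
  d <- comparison$difference
  scale <- max(abs(d), 1e-12)
  cols <- grDevices::rgb(pmax(d, 0) / scale, 0, pmax(-d, 0) / scale)
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("%s - %s (%s, offset %g s)",
                                comparison$groupA[1], comparison$groupB[1],
                                comparison$task[1], comparison$offset[1]),
                 ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th))
  ring <- ifelse(comparison$significantCorrected, "black",
                 ifelse(comparison$significantUncorrected, "grey50", NA))
  graphics::points(pos[, 1], pos[, 2], pch = 21, bg = cols, col = ring,
                   cex = 1.6, lwd = 2)
  if (labels)
    graphics::text(pos[, 1], pos[, 2] + 0.06, comparison$channel, cex = 0.6)
  invisible(comparison)
}
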