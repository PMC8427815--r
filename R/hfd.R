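#' Higuchi estimator configuration
#'
#' @param kMax largest interval size (default 7, a value repeatedly found
#'   to give accurate fractal-dimension estimates on EEG).
#' @param kGrid interval sizes used for the log-log fit; default all
#'   integers `2..kMax`.
#' @param windowLength analysis window length in seconds (default 2, short
#'   windows being where the estimator is most effective on EEG).
#' @param windowOffsets window start offsets in seconds (default 0..3,
#'   i.e. four 50%-overlapping 2-s windows of a 5-s trial).
#' @return an [HfdConfig-class].
#' @export
hfdConfig <- function(kMax = 7, kGrid = seq(2L, kMax), windowLength = 2,
                      windowOffsets = c(0, 1, 2, 3)) {
  new("HfdConfig", kMax = as.integer(kMax), kGrid = as.integer(kGrid),
      windowLength = windowLength, windowOffsets = windowOffsets)
}

#' Higuchi curve length
#'
#' Length of the reconstructed curve of a timeseries at interval size `k`.
#' With a 0-based time index `t = 0..N-1`, for each phase `m = 0..k-1` the
#' subsampled curve `S(m), S(m+k), S(m+2k), ...` contributes
#' \deqn{L_m(k) = \frac{1}{k}\left[\sum_{i=1}^{n_m} |S(m+ik) - S(m+(i-1)k)|\right]
#'   \frac{N-1}{n_m k}, \quad n_m = \lfloor (N-1-m)/k \rfloor,}
#' and the curve length is the average \eqn{L(k) = \frac{1}{k}\sum_m
#' L_m(k)}. For a statistically self-similar signal \eqn{L(k) \propto
#' k^{-D}}; a linear ramp gives exactly \eqn{L(k) = (N-1)/k}.
#'
#' @param signal numeric vector of length N.
#' @param k integer interval size, `2 <= k <= N/2`.
#' @return the curve length L(k); 0 for a constant signal.
#' @examples
#' curveLength(0:9, 2)  # (N-1)/k = 4.5 for a ramp
#' @export
curveLength <- function(signal, k) {
  k <- as.integer(k)
  n <- length(signal)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (n < 2L * k)
    stop(sprintf("window of %d samples is too short for k = %d", n, k),
         call. = FALSE)
  drop(curveLengthMatrix(matrix(signal, ncol = 1L), k))
}

# Curve lengths at interval k for every column of a window matrix
# (samples x windows). Vectorised over windows: the m-phase loop runs k
# times regardless of how many windows are processed.
curveLengthMatrix <- function(x, k) {
  n <- nrow(x)
  total <- 0
  for (m in 0:(k - 1L)) {
    nm <- (n - 1L - m) %/% k
    idx <- m + (0:nm) * k + 1L
    d <- abs(x[idx[-1L], , drop = FALSE] - x[idx[-length(idx)], , drop = FALSE])
    total <- total + .colSums(d, nm, ncol(x)) * (n - 1) / (nm * k) / k
  }
  total / k
}

# HFD for every column of a window matrix; degenerate (constant) windows
# yield NA. Returns the negated slope of the least-squares fit of log L(k)
# on log k (natural logs; the slope is base-invariant).
higuchiFdMatrix <- function(x, kGrid) {
  n <- nrow(x)
  if (n < 2L * max(kGrid))
    stop(sprintf("window of %d samples is too short for k = %d", n,
                 max(kGrid)), call. = FALSE)
  L <- vapply(kGrid, function(k) curveLengthMatrix(x, k), numeric(ncol(x)))
  L <- matrix(L, nrow = ncol(x))          # windows x k
  bad <- rowSums(L <= 0) > 0
  lk <- log(kGrid)
  lkc <- lk - mean(lk)
  slope <- (log(L) %*% lkc) / sum(lkc^2)
  out <- -drop(slope)
  out[bad] <- NA_real_
  out
}

#' Higuchi fractal dimension
#'
#' Estimates the fractal dimension D of a timeseries as the negated slope
#' of the least-squares fit of `log L(k)` on `log k` over the configured
#' interval grid. For timeseries D lies in `[1, 2]`: a smooth ramp attains
#' exactly 1, uncorrelated noise approaches 2, and a fractional Brownian
#' motion path with Hurst exponent H has theoretical dimension `2 - H`.
#' The estimate is invariant under affine transforms of the signal.
#'
#' @param signal numeric vector, at least twice as long as the largest k.
#' @param config an [HfdConfig-class] (only its `kGrid` is used here).
#' @return the estimated fractal dimension.
#' @examples
#' higuchiFd(seq_len(100))             # exactly 1
#' higuchiFd(generateFbm(500, 0.5, 1)) # about 1.5
#' @export
higuchiFd <- function(signal, config = hfdConfig()) {
  stopifnot(is(config, "HfdConfig"))
  d <- higuchiFdMatrix(matrix(signal, ncol = 1L), config@kGrid)
  if (is.na(d))
    stop("degenerate (constant) signal: curve length is zero", call. = FALSE)
  d
}

#' Extract analysis windows from a trial signal
#'
#' Cuts the configured windows out of one trial: one window per offset,
#' each of `round(windowLength * samplingRate)` samples starting at
#' `round(offset * samplingRate)`. With the defaults on a 5-s trial this
#' yields four 2-s windows with 50% overlap.
#'
#' @param trialSignal numeric vector of one trial at one channel.
#' @param samplingRate sampling rate in Hz.
#' @param config an [HfdConfig-class].
#' @return named list of numeric vectors, one per offset.
#' @examples
#' w <- extractWindows(rnorm(1250), 250)
#' lengths(w)  # 500 500 500 500
#' @export
extractWindows <- function(trialSignal, samplingRate, config = hfdConfig()) {
  stopifnot(is(config, "HfdConfig"))
  n <- length(trialSignal)
  len <- as.integer(round(config@windowLength * samplingRate))
  out <- vector("list", length(config@windowOffsets))
  names(out) <- sprintf("offset%g", config@windowOffsets)
  for (i in seq_along(config@windowOffsets)) {
    off <- config@windowOffsets[i]
    start <- as.integer(round(off * samplingRate)) + 1L
    if (start + len - 1L > n)
      stop(sprintf("window at offset %g s (%d samples from sample %d) exceeds the trial length of %d samples",
                   off, len, start, n), call. = FALSE)
    out[[i]] <- trialSignal[start:(start + len - 1L)]
  }
  out
}

#' Extract the windowed HFD feature table from a dataset
#'
#' Computes one Higuchi fractal dimension per participant, trial, task,
#' channel and window offset. Degenerate (constant) windows are recorded as
#' missing (`NA`) and their count reported via a message, so the row count
#' always equals `participants x trials x tasks x channels x offsets`.
#'
#' @param dataset an [EpochsDataset-class].
#' @param config an [HfdConfig-class].
#' @return a `data.frame` with columns `group, participant, trial, task,
#'   channel, offset, hfd`, ordered by group, participant, trial, task,
#'   channel (montage order) and offset.
#' @examples
#' cfg <- synthConfig(participantsPerGroup = 2, trialsPerTask = 2,
#'                    tasks = "RH", samplingRate = 50,
#'                    montage = ChannelMontage(c("FCz", "CPz")))
#' ft <- extractFeatures(generateDataset(cfg))
#' nrow(ft)  # 4 x 2 x 1 x 2 x 4
#' @export
extractFeatures <- function(dataset, config = hfdConfig()) {
  stopifnot(is(dataset, "EpochsDataset"), is(config, "HfdConfig"))
  d <- dataset@data
  dn <- dimnames(d)
  nP <- dim(d)[1]; nT <- dim(d)[2]; nTask <- dim(d)[3]; nC <- dim(d)[4]
  nS <- dim(d)[5]
  offs <- config@windowOffsets
  nW <- length(offs)
  rate <- dataset@samplingRate
  len <- as.integer(round(config@windowLength * rate))
  starts <- as.integer(round(offs * rate)) + 1L
  bad <- starts + len - 1L > nS
  if (any(bad))
    stop(sprintf("window at offset %g s exceeds the %g-s trial",
                 offs[which(bad)[1]], nS / rate), call. = FALSE)

  rowsPer <- nT * nW
  total <- nP * nTask * nC * rowsPer
  hfd <- numeric(total)
  participant <- character(total); task <- character(total)
  channel <- character(total); trial <- integer(total); offset <- numeric(total)
  pos <- 0L
  for (p in seq_len(nP)) {
    for (ti in seq_len(nTask)) {
      for (ci in seq_len(nC)) {
        sig <- matrix(d[p, , ti, ci, ], nT, nS)   # trials x samples
        # window matrix: len x (trials * offsets), offset-major blocks
        wm <- matrix(NA_real_, len, nT * nW)
        for (w in seq_len(nW))
          wm[, ((w - 1L) * nT + 1L):(w * nT)] <-
            t(sig[, starts[w]:(starts[w] + len - 1L), drop = FALSE])
        vals <- higuchiFdMatrix(wm, config@kGrid)
        idx <- pos + seq_len(rowsPer)
        hfd[idx] <- vals
        participant[idx] <- dn[[1]][p]
        task[idx] <- dn[[3]][ti]
        channel[idx] <- dn[[4]][ci]
        trial[idx] <- rep(seq_len(nT), nW)
        offset[idx] <- rep(offs, each = nT)
        pos <- pos + rowsPer
      }
    }
  }
  ft <- data.frame(group = unname(dataset@groupOf[participant]),
                   participant = participant, trial = trial, task = task,
                   channel = channel, offset = offset, hfd = hfd,
                   stringsAsFactors = FALSE)
  nMissing <- sum(is.na(ft$hfd))
  if (nMissing > 0L)
    message(sprintf("extractFeatures: %d degenerate window(s) recorded as missing",
                    nMissing))
  chOrder <- match(ft$channel, dn[[4]])
  ft <- ft[order(ft$group, ft$participant, ft$trial, ft$task, chOrder,
                 ft$offset), ]
  rownames(ft) <- NULL
  ft
}
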