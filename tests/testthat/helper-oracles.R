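# Independent oracles and fixture builders, deliberately written as plain
# (slow) transcriptions so they cannot share bugs with the package's
# vectorised implementations.

# Direct double-loop transcription of the curve-length definition:
# 0-based t, phases m = 0..k-1, n_m = floor((N-1-m)/k),
# L_m(k) = (1/k) * sum_i |S[m+ik] - S[m+(i-1)k]| * (N-1)/(n_m k),
# L(k) = (1/k) * sum_m L_m(k).
naiveCurveLength <- function(s, k) {
  n <- length(s)
  total <- 0
  for (m in 0:(k - 1)) {
    nm <- floor((n - 1 - m) / k)
    acc <- 0
    for (i in seq_len(nm))
      acc <- acc + abs(s[m + i * k + 1] - s[m + (i - 1) * k + 1])
    total <- total + (1 / k) * acc * (n - 1) / (nm * k)
  }
  total / k
}

naiveHfd <- function(s, kGrid = 2:7) {
  L <- vapply(kGrid, function(k) naiveCurveLength(s, k), numeric(1))
  -unname(coef(lm(log(L) ~ log(kGrid)))[2])
}

# Synthetic per-trial feature table built directly from Gaussians (no EEG
# generation): hfd = base + groupEffect[channel] + participant offset +
# trial noise. Cheap fixture for classification logic tests.
gaussFeatureTable <- function(nPerGroup = 4, trials = 10,
                              channels = c("ch1", "ch2", "ch3"),
                              groups = c("A", "B"),
                              effect = c(ch2 = 0.2), base = 1.8,
                              participantSd = 0.02, trialSd = 0.05,
                              offsets = 2, task = "RH", seed = 1) {
  set.seed(seed)
  rows <- list()
  for (gi in seq_along(groups)) {
    for (p in seq_len(nPerGroup)) {
      pid <- sprintf("%s%02d", groups[gi], p)
      pOff <- rnorm(1, 0, participantSd)
      for (ch in channels) {
        eff <- if (gi == 1 && ch %in% names(effect)) effect[[ch]] else 0
        for (off in offsets) {
          rows[[length(rows) + 1]] <- data.frame(
            group = groups[gi], participant = pid, trial = seq_len(trials),
            task = task, channel = ch, offset = off,
            hfd = base + eff + pOff + rnorm(trials, 0, trialSd),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

# Exhaustive single-channel oracle: inner leave-one-participant-out
# accuracy of a standardized linear nu-SVC for every channel, computed with
# a plain loop straight on e1071.
oracleSingleChannelAccuracies <- function(features, task, offset, nu,
                                          channels) {
  sel <- features$task == task & features$offset == offset
  ft <- features[sel, ]
  sapply(channels, function(ch) {
    f1 <- ft[ft$channel == ch, ]
    ids <- unique(f1$participant)
    correct <- 0
    for (hold in ids) {
      tr <- f1[f1$participant != hold, ]
      te <- f1[f1$participant == hold, ]
      mu <- mean(tr$hfd); sdv <- sd(tr$hfd); if (sdv == 0) sdv <- 1
      fit <- e1071::svm(matrix((tr$hfd - mu) / sdv, ncol = 1),
                        factor(tr$group), type = "nu-classification",
                        kernel = "linear", nu = nu, scale = FALSE,
                        tolerance = 0.01)
      pred <- predict(fit, matrix((te$hfd - mu) / sdv, ncol = 1))
      correct <- correct + sum(as.character(pred) == te$group)
    }
    correct / nrow(f1)
  })
}

# Minimal EDF writer for import tests: continuous recording, 16-bit
# little-endian samples, 1-s data records.
writeTinyEdf <- function(path, signals, rate) {
  pad <- function(x, n) formatC(as.character(x), width = n, flag = "-")
  ns <- length(signals)
  nRec <- length(signals[[1]]) %/% rate
  physMin <- -250; physMax <- 250
  digMin <- -32768; digMax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("synthetic subject", 80),
                pad("synthetic recording", 80), pad("01.01.26", 8),
                pad("00.00.00", 8), pad(256 * (1 + ns), 8), pad("", 44),
                pad(nRec, 8), pad(1, 8), pad(ns, 4))
  sig <- paste0(paste(vapply(names(signals), pad, character(1), 16),
                      collapse = ""),
                paste(rep(pad("", 80), ns), collapse = ""),
                paste(rep(pad("uV", 8), ns), collapse = ""),
                paste(rep(pad(physMin, 8), ns), collapse = ""),
                paste(rep(pad(physMax, 8), ns), collapse = ""),
                paste(rep(pad(digMin, 8), ns), collapse = ""),
                paste(rep(pad(digMax, 8), ns), collapse = ""),
                paste(rep(pad("", 80), ns), collapse = ""),
                paste(rep(pad(rate, 8), ns), collapse = ""),
                paste(rep(pad("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  gain <- (digMax - digMin) / (physMax - physMin)
  for (r in seq_len(nRec)) {
    for (i in seq_len(ns)) {
      seg <- signals[[i]][((r - 1) * rate + 1):(r * rate)]
      dig <- as.integer(round((seg - physMin) * gain + digMin))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

# Small synthetic epoch dataset shared by several tests.
tinyDataset <- function(nPerGroup = 2, trials = 3, tasks = "RH",
                        channels = c("FCz", "CPz"), rate = 50,
                        effect = list(), seed = 7, participantSd = 0.03) {
  cfg <- synthConfig(groups = c("sPDP", "sPNP"),
                     participantsPerGroup = nPerGroup,
                     trialsPerTask = trials, tasks = tasks,
                     samplingRate = rate,
                     montage = subsetMontage(standardMontage("48"), channels),
                     groupEffect = effect, participantSd = participantSd,
                     seed = seed)
  generateDataset(cfg)
}
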