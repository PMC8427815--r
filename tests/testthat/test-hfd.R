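test_that("curve length matches the hand-evaluated ramp values", {
  ramp <- 0:9
  expect_equal(curveLength(ramp, 2), 4.5, tolerance = 1e-12)
  expect_equal(curveLength(ramp, 3), 3.0, tolerance = 1e-12)
  # L(k) = (N-1)/k holds for ramps of any length
  for (n in c(20, 57, 200))
    for (k in 2:7)
      expect_equal(curveLength(seq_len(n), k), (n - 1) / k,
                   tolerance = 1e-12)
})

test_that("curve length input contracts", {
  expect_equal(curveLength(rep(3.2, 50), 4), 0)   # constant signal
  expect_error(curveLength(1:10, 6), "too short")
  expect_error(curveLength(1:10, 1), "k must be")
})

test_that("vectorised curve length equals the naive loop transcription", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(60:200, 1)
    s <- cumsum(rnorm(n))
    for (k in 2:7) {
      expect_equal(curveLength(s, k), naiveCurveLength(s, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("a linear ramp attains the lower bound D = 1 exactly", {
  for (n in c(20, 100, 500))
    expect_equal(higuchiFd(seq_len(n)), 1, tolerance = 1e-9)
})

test_that("HFD estimates agree with an independent least-squares fit", {
  set.seed(7)
  for (i in 1:10) {
    s <- cumsum(rnorm(300))
    expect_equal(higuchiFd(s), naiveHfd(s), tolerance = 1e-10)
  }
})

test_that("HFD is invariant under affine transforms", {
  set.seed(8)
  s <- cumsum(rnorm(400))
  expect_equal(higuchiFd(3 * s + 7), higuchiFd(s), tolerance = 1e-9)
  expect_equal(higuchiFd(-0.2 * s), higuchiFd(s), tolerance = 1e-9)
})

test_that("constant signals raise a degenerate-signal error", {
  expect_error(higuchiFd(rep(1, 100)), "degenerate")
})

test_that("mean estimated D decreases strictly in the Hurst exponent", {
  hGrid <- c(0.2, 0.4, 0.6, 0.8)
  meanD <- vapply(hGrid, function(h)
    mean(vapply(1:100, function(s)
      higuchiFd(generateFbm(500, h, seed = 1000 * h + s)), numeric(1))),
    numeric(1))
  expect_true(all(diff(meanD) < 0))
  # estimates track the theoretical D = 2 - H within estimator bias
  expect_equal(meanD, 2 - hGrid, tolerance = 0.08)
})

test_that("estimates on the generator's signal battery stay within [0.95, 2.05]", {
  # ramps and fBm over the full admissible Hurst range (the signals the
  # feature pipeline analyses); individual pure-noise draws scatter around
  # 2 and are pinned separately through their mean
  hGrid <- c(0.05, seq(0.1, 0.9, by = 0.1), 0.95)
  battery <- c(lapply(c(50, 500), seq_len),
               unlist(lapply(hGrid, function(h)
                 lapply(1:3, function(s)
                   generateFbm(500, h, seed = round(100 * h) + s))),
                 recursive = FALSE))
  d <- vapply(battery, higuchiFd, numeric(1))
  expect_true(all(d >= 0.95 & d <= 2.05))
})

test_that("window extraction matches both cohort sampling rates", {
  w250 <- extractWindows(rnorm(1250), 250)
  expect_length(w250, 4)
  expect_true(all(lengths(w250) == 500))
  # 50% overlap: starts at samples 0, 250, 500, 750 (0-based)
  x <- seq_len(1250)
  w <- extractWindows(x, 250)
  expect_equal(vapply(w, `[`, numeric(1), 1), c(1, 251, 501, 751),
               ignore_attr = TRUE)
  w256 <- extractWindows(rnorm(1280), 256)
  expect_true(all(lengths(w256) == 512))
  # a 3-s trial cannot host a 2-s window at 3-s offset
  expect_error(extractWindows(rnorm(3 * 250), 250,
                              hfdConfig(windowOffsets = c(0, 3))),
               "offset 3")
})

test_that("feature extraction yields one row per design cell", {
  ds <- tinyDataset(nPerGroup = 1, trials = 1, channels = c("FCz", "CPz"),
                    rate = 50)
  ft <- extractFeatures(ds)
  expect_equal(nrow(ft), 2 * 1 * 1 * 2 * 4)   # 8 rows for the toy design
  expect_identical(names(ft), c("group", "participant", "trial", "task",
                                "channel", "offset", "hfd"))
  expect_true(all(is.finite(ft$hfd)))
  expect_true(all(ft$hfd >= 0.95 & ft$hfd <= 2.05))

  ds2 <- tinyDataset(nPerGroup = 2, trials = 3, tasks = c("LH", "RH"),
                     channels = c("FCz", "CPz", "Oz"), rate = 50)
  ft2 <- extractFeatures(ds2)
  expect_equal(nrow(ft2), 4 * 3 * 2 * 3 * 4)
})

test_that("feature extraction is deterministic across regeneration", {
  f1 <- extractFeatures(tinyDataset(seed = 13))
  f2 <- extractFeatures(tinyDataset(seed = 13))
  expect_identical(f1, f2)
})

test_that("degenerate windows are recorded as missing, with a message", {
  ds <- tinyDataset(nPerGroup = 1, trials = 2, channels = c("FCz", "CPz"),
                    rate = 50)
  d <- epochsData(ds)
  d[, , , "CPz", ] <- 5   # flat channel
  flat <- new("EpochsDataset", data = d, samplingRate = samplingRate(ds),
              montage = montage(ds), groupOf = groupOf(ds),
              provenance = ds@provenance)
  expect_message(ft <- extractFeatures(flat), "degenerate")
  expect_equal(nrow(ft), 2 * 2 * 2 * 4)   # row count unchanged
  expect_true(all(is.na(ft$hfd[ft$channel == "CPz"])))
  expect_true(all(is.finite(ft$hfd[ft$channel == "FCz"])))
})

test_that("feature table CSV round trip preserves the table", {
  ft <- extractFeatures(tinyDataset())
  f <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(ft, f)
  ft2 <- readFeatureTable(f)
  expect_equal(ft, ft2, ignore_attr = TRUE)
})

test_that("hfd configuration validation", {
  expect_error(hfdConfig(kGrid = 1:7), "kGrid")
  expect_error(hfdConfig(kMax = 7, kGrid = 2:9), "kMax")
  expect_error(hfdConfig(windowOffsets = c(0, 0)), "unique")
  expect_error(hfdConfig(windowLength = -1), "windowLength")
})
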