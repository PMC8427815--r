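test_that("generated datasets have the configured shape and groups", {
  ds <- tinyDataset(nPerGroup = 2, trials = 3, tasks = c("LH", "RH"),
                    channels = c("FCz", "CPz", "Oz"), rate = 50)
  expect_s4_class(ds, "EpochsDataset")
  expect_equal(dim(epochsData(ds)), c(4, 3, 2, 3, 250))
  expect_equal(sum(groupOf(ds) == "sPDP"), 2)
  expect_equal(sum(groupOf(ds) == "sPNP"), 2)
  expect_identical(taskLabels(ds), c("LH", "RH"))
  expect_false(anyNA(epochsData(ds)))
})

test_that("cohort presets encode the two recording layouts", {
  c1 <- datasetPreset("dataset1")
  c2 <- datasetPreset("dataset2")
  # implied full tensor shapes: 3x10 and 2x10 participants, 60 trials,
  # 3 tasks, 61/48 channels, 5 s at 250/256 Hz
  expect_identical(c1@groups, c("AB", "cPWP", "cPNP"))
  expect_equal(c1@samplingRate * c1@trialDuration, 1250)
  expect_equal(nChannels(c1@montage), 61)
  expect_equal(c1@participantsPerGroup, 10L)
  expect_equal(c1@trialsPerTask, 60L)
  expect_identical(c2@groups, c("sPDP", "sPNP"))
  expect_equal(c2@samplingRate * c2@trialDuration, 1280)
  expect_equal(nChannels(c2@montage), 48)
  expect_length(c2@tasks, 3)
})

test_that("identical configurations generate bit-identical datasets", {
  d1 <- tinyDataset(seed = 11)
  d2 <- tinyDataset(seed = 11)
  expect_identical(epochsData(d1), epochsData(d2))
  d3 <- tinyDataset(seed = 12)
  expect_false(identical(epochsData(d1), epochsData(d3)))
})

test_that("configuration validation rejects inconsistent inputs", {
  m <- subsetMontage(standardMontage("48"), c("FCz", "CPz"))
  expect_error(synthConfig(montage = m,
                           groupEffect = list(G1 = c(Oz = -0.1))), "Oz")
  expect_error(synthConfig(montage = m,
                           groupEffect = list(G9 = c(FCz = -0.1))), "G9")
  expect_error(synthConfig(montage = m, samplingRate = 250,
                           trialDuration = 5.0001), "integer sample count")
  expect_error(synthConfig(montage = m, baseHurst = 1.2), "baseHurst")
  expect_error(synthConfig(montage = m, trialsPerTask = 0), "trialsPerTask")
})

test_that("a planted complexity deficit raises HFD at the affected channels", {
  # group effect dH = -0.15 at FCz only; CPz and Oz untouched
  ds <- tinyDataset(nPerGroup = 4, trials = 10,
                    channels = c("FCz", "CPz", "Oz"), rate = 125,
                    effect = list(sPDP = c(FCz = -0.15)),
                    participantSd = 0.01, seed = 21)
  ft <- extractFeatures(ds, hfdConfig(windowOffsets = 2))
  gm <- function(g, ch) mean(ft$hfd[ft$group == g & ft$channel == ch])
  dFCz <- gm("sPDP", "FCz") - gm("sPNP", "FCz")
  dCPz <- abs(gm("sPDP", "CPz") - gm("sPNP", "CPz"))
  dOz <- abs(gm("sPDP", "Oz") - gm("sPNP", "Oz"))
  expect_gt(dFCz, dCPz)
  expect_gt(dFCz, dOz)
  expect_gt(dFCz, 0.08)   # clip-free effect of 0.15 on D = 2 - H, noisily
})

test_that("group mean HFD difference grows monotonically with the planted effect", {
  diffs <- vapply(c(0, 0.05, 0.1, 0.15), function(dh) {
    eff <- if (dh > 0) list(sPDP = c(FCz = -dh)) else list()
    ds <- tinyDataset(nPerGroup = 4, trials = 10, channels = c("FCz", "CPz"),
                      rate = 125, effect = eff, participantSd = 0.01,
                      seed = 31)
    ft <- extractFeatures(ds, hfdConfig(windowOffsets = 2))
    abs(mean(ft$hfd[ft$group == "sPDP" & ft$channel == "FCz"]) -
          mean(ft$hfd[ft$group == "sPNP" & ft$channel == "FCz"]))
  }, numeric(1))
  expect_true(all(diff(diffs) > 0))
})

test_that("with zero effect and no participant heterogeneity the bootstrap stays quiet", {
  ds <- tinyDataset(nPerGroup = 4, trials = 15,
                    channels = c("FCz", "CPz", "Oz"), rate = 125,
                    effect = list(), participantSd = 0, seed = 41)
  ft <- extractFeatures(ds, hfdConfig(windowOffsets = 2))
  cmp <- compareGroups(ft, c("sPDP", "sPNP"), "RH", 2, M = 2000, seed = 1)
  expect_false(any(cmp$significantCorrected))
})

test_that("dataset directory round trip is bit-exact", {
  ds <- tinyDataset(seed = 51)
  dir <- withr::local_tempdir()
  writeDataset(ds, dir, overwrite = TRUE)
  ds2 <- readDataset(dir)
  expect_identical(epochsData(ds), epochsData(ds2))
  expect_identical(groupOf(ds), groupOf(ds2))
  expect_identical(samplingRate(ds), samplingRate(ds2))
  expect_identical(channelNames(ds), channelNames(ds2))
})

test_that("malformed dataset metadata produces errors naming the field", {
  ds <- tinyDataset(seed = 51)
  dir <- withr::local_tempdir()
  writeDataset(ds, dir, overwrite = TRUE)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  broken <- meta; broken$groupOf <- broken$groupOf[-1]
  jsonlite::write_json(broken, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE)
  expect_error(readDataset(dir), "groupOf")
  broken <- meta; broken$montage$labels <- NULL
  jsonlite::write_json(broken, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE)
  expect_error(readDataset(dir), "montage")
  expect_error(readDataset(withr::local_tempdir()), "metadata.json")
})

test_that("EDF import takes the rate from the header and maps channel subsets", {
  rate <- 100
  t <- seq_len(rate * 12)
  sig <- list(FCz = sin(t / 7) * 40, CPz = cos(t / 11) * 40,
              Oz = sin(t / 23) * 40)
  f1 <- withr::local_tempfile(fileext = ".edf")
  f2 <- withr::local_tempfile(fileext = ".edf")
  writeTinyEdf(f1, sig, rate)
  writeTinyEdf(f2, lapply(sig, rev), rate)
  ds <- importEdf(c(f1, f2), groups = c("sPDP", "sPNP"),
                  channels = c("CPz", "FCz"), trialDuration = 5)
  expect_equal(samplingRate(ds), rate)
  expect_equal(dim(epochsData(ds)), c(2, 2, 1, 2, 500))
  expect_identical(channelNames(ds), c("CPz", "FCz"))
  # amplitudes survive the 16-bit round trip to ~quantisation accuracy
  expect_equal(as.numeric(epochsData(ds)[1, 1, 1, "CPz", ]),
               sig$CPz[1:500], tolerance = 1e-3)
  expect_error(importEdf(f1, groups = "sPDP", channels = "P3"), "P3")
})
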