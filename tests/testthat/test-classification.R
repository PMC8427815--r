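test_that("trial vectors have one row per trial and ordered columns", {
  ft <- gaussFeatureTable(nPerGroup = 10, trials = 60,
                          channels = c("ch1", "ch2"), seed = 2)
  tv <- trialVectors(ft, "RH", c("ch1", "ch2"), 2)
  expect_equal(dim(tv$x), c(1200, 2))
  expect_identical(colnames(tv$x), c("ch1", "ch2"))
  expect_equal(length(tv$y), 1200)
  expect_equal(sort(unique(tv$y)), c("A", "B"))

  tv1 <- trialVectors(ft, "RH", "ch2", 2)
  expect_equal(ncol(tv1$x), 1)

  rev <- trialVectors(ft, "RH", c("ch2", "ch1"), 2)
  expect_identical(rev$x[, "ch1"], tv$x[, "ch1"])
  expect_identical(colnames(rev$x), c("ch2", "ch1"))
})

test_that("trials with missing features are dropped with a message", {
  ft <- gaussFeatureTable(nPerGroup = 2, trials = 5, seed = 3)
  ft$hfd[ft$participant == "A01" & ft$trial == 1 & ft$channel == "ch1"] <- NA
  expect_message(tv <- trialVectors(ft, "RH", c("ch1", "ch2"), 2),
                 "dropped")
  expect_equal(nrow(tv$x), 4 * 5 - 1)
  expect_error(trialVectors(ft, "RH", "nope", 2), "nope")
  expect_error(trialVectors(ft, "LH", "ch1", 2), "no features")
})

test_that("greedy selection finds the informative channel first and agrees with the exhaustive oracle", {
  ft <- gaussFeatureTable(nPerGroup = 4, trials = 15,
                          channels = c("ch1", "ch2", "ch3"),
                          effect = c(ch2 = 0.25), trialSd = 0.05, seed = 4)
  sel <- greedySelect(ft, "RH", 2, nu = 0.3)
  expect_s4_class(sel, "ChannelSelection")
  expect_identical(selectedChannels(sel)[1], "ch2")
  oracle <- oracleSingleChannelAccuracies(ft, "RH", 2, 0.3,
                                          c("ch1", "ch2", "ch3"))
  expect_identical(names(which.max(oracle)), selectedChannels(sel)[1])
  expect_equal(unname(accuracyTrace(sel)[1]), unname(max(oracle)),
               tolerance = 1e-12)
  if (length(accuracyTrace(sel)) > 1)
    expect_true(all(diff(accuracyTrace(sel)) > 0))
})

test_that("all-noise channels halt selection after a single pick", {
  ft <- gaussFeatureTable(nPerGroup = 4, trials = 15, effect = numeric(0),
                          seed = 5)
  sel <- greedySelect(ft, "RH", 2, nu = 0.3)
  expect_lte(length(selectedChannels(sel)), 2)
  expect_lt(accuracyTrace(sel)[1], 0.7)   # near-chance first pick
})

test_that("bit-identical informative channels tie-break by montage order", {
  ft <- gaussFeatureTable(nPerGroup = 4, trials = 15,
                          channels = c("ch1", "ch2"),
                          effect = c(ch2 = 0.25), seed = 6)
  dup <- ft[ft$channel == "ch2", ]
  dup$channel <- "ch2b"
  ft2 <- rbind(ft, dup)
  sel <- greedySelect(ft2, "RH", 2, nu = 0.3,
                      channels = c("ch2", "ch2b", "ch1"))
  expect_identical(selectedChannels(sel)[1], "ch2")
  sel2 <- greedySelect(ft2, "RH", 2, nu = 0.3,
                       channels = c("ch2b", "ch2", "ch1"))
  expect_identical(selectedChannels(sel2)[1], "ch2b")
})

test_that("degenerate training sets are rejected", {
  ft <- gaussFeatureTable(nPerGroup = 4, trials = 10, seed = 7)
  single <- ft[ft$group == "A", ]
  expect_error(greedySelect(single, "RH", 2, nu = 0.3), "class")
})

test_that("majority voting follows the modal class with conservative ties", {
  p <- data.frame(participant = rep("s1", 60), truth = "a",
                  predicted = rep(c("a", "b"), c(40, 20)))
  expect_equal(majorityVote(p)$percentCorrect, 100)

  tie <- data.frame(participant = rep("s1", 60), truth = "a",
                    predicted = rep(c("a", "b"), c(30, 30)))
  mv <- majorityVote(tie)
  expect_true(is.na(mv$votes$vote[1]))
  expect_equal(mv$percentCorrect, 0)

  nine <- data.frame(
    participant = rep(sprintf("s%02d", 1:10), each = 3),
    truth = "a",
    predicted = c(rep("a", 27), rep("b", 3)))
  expect_equal(majorityVote(nine)$percentCorrect, 90)

  # 31 of 60 trials correct is a correct participant
  maj <- data.frame(participant = rep("s1", 60), truth = "a",
                    predicted = rep(c("a", "b"), c(31, 29)))
  expect_equal(majorityVote(maj)$percentCorrect, 100)
})

test_that("well-separated groups reach near-perfect nested LOSO accuracy", {
  ft <- gaussFeatureTable(nPerGroup = 3, trials = 12,
                          channels = c("ch1", "ch2", "ch3"),
                          effect = c(ch2 = 0.25), participantSd = 0.01,
                          trialSd = 0.04, offsets = c(0, 2), seed = 8)
  cfg <- classifierConfig(nuGrid = c(0.1, 0.3), offsetGrid = c(0, 2))
  rep <- nestedLosoEvaluate(ft, "RH", cfg)
  expect_s4_class(rep, "EvalReport")
  expect_gte(rep@accuracyMean, 0.95)
  expect_equal(rep@participantsCorrect, 100)
  expect_true(all(vapply(strsplit(rep@folds$channels, ","),
                         function(ch) ch[1] == "ch2", logical(1))))
  expect_equal(nrow(rep@folds), 6)
  expect_equal(nrow(rep@predictions), 6 * 12)
})

test_that("nested evaluation is deterministic", {
  ft <- gaussFeatureTable(nPerGroup = 3, trials = 8, seed = 9)
  cfg <- classifierConfig(nuGrid = 0.3, offsetGrid = 2)
  r1 <- nestedLosoEvaluate(ft, "RH", cfg)
  r2 <- nestedLosoEvaluate(ft, "RH", cfg)
  expect_identical(r1@predictions, r2@predictions)
  expect_identical(r1@folds, r2@folds)
})

test_that("held-out participants do not influence their own fold's model selection", {
  ft <- gaussFeatureTable(nPerGroup = 3, trials = 10,
                          channels = c("ch1", "ch2"),
                          effect = c(ch2 = 0.2), seed = 10)
  cfg <- classifierConfig(nuGrid = c(0.1, 0.3), offsetGrid = 2)
  clean <- nestedLosoEvaluate(ft, "RH", cfg)
  # wreck one participant's features; the model selected when that
  # participant is held out must be unchanged
  corrupted <- ft
  wreck <- corrupted$participant == "A01"
  corrupted$hfd[wreck] <- corrupted$hfd[wreck] + 1000
  dirty <- nestedLosoEvaluate(corrupted, "RH", cfg)
  cleanFold <- clean@folds[clean@folds$heldOut == "A01",
                           c("offset", "nu", "channels", "innerAccuracy")]
  dirtyFold <- dirty@folds[dirty@folds$heldOut == "A01",
                           c("offset", "nu", "channels", "innerAccuracy")]
  expect_identical(cleanFold, dirtyFold)
})

test_that("label permutation drives accuracy towards chance", {
  ft <- gaussFeatureTable(nPerGroup = 3, trials = 10,
                          channels = c("ch1", "ch2"),
                          effect = c(ch2 = 0.25), seed = 11)
  cfg <- classifierConfig(nuGrid = 0.3, offsetGrid = 2)
  accs <- vapply(1:5, function(s) {
    perm <- permuteGroupLabels(ft, seed = s)
    nestedLosoEvaluate(perm, "RH", cfg)@accuracyMean
  }, numeric(1))
  expect_gt(mean(accs), 0.25)
  expect_lt(mean(accs), 0.75)
})

test_that("permuting labels preserves group sizes and moves whole participants", {
  ft <- gaussFeatureTable(nPerGroup = 3, trials = 5, seed = 12)
  perm <- permuteGroupLabels(ft, seed = 1)
  expect_equal(table(perm$group), table(ft$group))
  byPart <- tapply(perm$group, perm$participant,
                   function(g) length(unique(g)))
  expect_true(all(byPart == 1))
  expect_identical(permuteGroupLabels(ft, seed = 1),
                   permuteGroupLabels(ft, seed = 1))
})

test_that("identity transfer reproduces the restricted nested evaluation", {
  ft <- gaussFeatureTable(nPerGroup = 3, trials = 10,
                          channels = c("ch1", "ch2"),
                          effect = c(ch2 = 0.2), seed = 13)
  cfg <- classifierConfig(nuGrid = c(0.1, 0.3), offsetGrid = 2)
  native <- nestedLosoEvaluate(ft, "RH", cfg, channels = "ch2")
  transfer <- transferEvaluate(ft, "RH", "ch2", 2, cfg)
  expect_identical(native@predictions, transfer@predictions)
  expect_equal(native@accuracyMean, transfer@accuracyMean)
})

test_that("transferring an uninformative channel yields chance accuracy", {
  ft <- gaussFeatureTable(nPerGroup = 4, trials = 12,
                          channels = c("ch1", "ch2"),
                          effect = c(ch2 = 0.3), participantSd = 0,
                          seed = 14)
  cfg <- classifierConfig(nuGrid = c(0.1, 0.3), offsetGrid = 2)
  rep <- transferEvaluate(ft, "RH", "ch1", 2, cfg)
  expect_gt(rep@accuracyMean, 0.2)
  expect_lt(rep@accuracyMean, 0.8)
  good <- transferEvaluate(ft, "RH", "ch2", 2, cfg)
  expect_gt(good@accuracyMean, 0.9)
})

test_that("classifier configuration validation", {
  expect_error(classifierConfig(nuGrid = c(0.5, 1.2)), "nu")
  expect_error(classifierConfig(nuGrid = numeric(0)), "non-empty")
  expect_error(classifierConfig(kernel = "rbf"), "linear")
  ft <- gaussFeatureTable(seed = 15)
  expect_error(nestedLosoEvaluate(ft[ft$group == "A", ], "RH",
                                  classifierConfig(nuGrid = 0.3,
                                                   offsetGrid = 2)),
               "two groups")
})
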