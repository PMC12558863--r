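test_that("noiseless hard-edged scenario reproduces the two-level template", {
  sc <- groupScenario("g", 1, c(19, 30), sotMeanH = 23, sotSdH = 0,
                      sleepDurationMeanH = 8, sleepDurationSdH = 0,
                      transitionWidthH = 0, noiseSd = 0, dayJitterSdH = 0,
                      missingRate = 0)
  rec <- generateSubject(sc, 11)$recording
  v <- activityValues(rec)
  expect_equal(nrow(v), 7L)
  # every day identical
  for (d in 2:7) expect_identical(v[d, ], v[1, ])
  # night level on [23:00, 07:00), day level elsewhere
  night <- c(1:420, 1381:1440)      # minutes covering [0,7) and [23,24)
  expect_true(all(v[1, night] == 2))
  expect_true(all(v[1, -night] == 15))
})

test_that("subject generation is seed-deterministic", {
  sc <- groupScenario("g", 1, c(19, 30), sotMeanH = 23)
  a <- generateSubject(sc, 7)
  b <- generateSubject(sc, 7)
  expect_identical(activityValues(a$recording), activityValues(b$recording))
  expect_identical(a$truth, b$truth)
  c <- generateSubject(sc, 8)
  expect_false(identical(activityValues(a$recording),
                         activityValues(c$recording)))
})

test_that("cohorts conserve counts, unique ids, and rhythmic flags", {
  scen <- list(groupScenario("a", 5, c(19, 30), sotMeanH = 23),
               groupScenario("b", 7, c(31, 50), sotMeanH = 22.5))
  coh <- generateCohort(scen, masterSeed = 3)
  expect_length(coh$recordings, 12L)
  expect_equal(nrow(coh$truth), 12L)
  expect_false(anyDuplicated(coh$truth$subject_id) > 0)
  expect_equal(unname(table(coh$truth$group)[c("a", "b")]),
               c(5L, 7L), ignore_attr = TRUE)

  # duplicate labels rejected
  expect_error(generateCohort(list(scen[[1]], scen[[1]]), 1), "duplicate")

  allArr <- generateCohort(list(
    groupScenario("x", 6, c(19, 30), sotMeanH = 23,
                  arrhythmicFraction = 1)), 5)
  expect_true(all(!allArr$truth$rhythmic))
  allRhy <- generateCohort(list(
    groupScenario("x", 6, c(19, 30), sotMeanH = 23,
                  arrhythmicFraction = 0)), 5)
  expect_true(all(allRhy$truth$rhythmic))
})

test_that("cohort generation is byte-identical under a fixed master seed", {
  scen <- list(groupScenario("a", 3, c(19, 30), sotMeanH = 23))
  c1 <- generateCohort(scen, 99)
  c2 <- generateCohort(scen, 99)
  expect_identical(lapply(c1$recordings, activityValues),
                   lapply(c2$recordings, activityValues))
  expect_identical(c1$truth, c2$truth)
})

test_that("invalid scenarios raise errors naming the offending field", {
  expect_error(groupScenario("g", 0, c(19, 30), sotMeanH = 23), "nSubjects")
  expect_error(groupScenario("g", 2, c(19, 30), sotMeanH = 23,
                             nightLevelMean = 20), "nightLevelMean")
  expect_error(groupScenario("g", 2, c(19, 30), sotMeanH = 23,
                             missingRate = 1.5), "missingRate")
  expect_error(groupScenario("g", 2, c(19, 30), sotMeanH = 23,
                             nDays = 9), "nDays")
})

test_that("emitted values are nonnegative and missing minutes are NA", {
  sc <- groupScenario("g", 1, c(19, 30), sotMeanH = 23, noiseSd = 5,
                      missingRate = 0.1)
  v <- activityValues(generateSubject(sc, 21)$recording)
  expect_true(all(v >= 0, na.rm = TRUE))
  expect_gt(mean(is.na(v)), 0.05)
  expect_lt(mean(is.na(v)), 0.15)
})

test_that("a noiseless rhythmic subject round-trips through the fitter", {
  sc <- groupScenario("g", 1, c(19, 30), sotMeanH = 22, sotSdH = 0,
                      sleepDurationMeanH = 8, sleepDurationSdH = 0,
                      noiseSd = 0, dayJitterSdH = 0, missingRate = 0)
  sub <- generateSubject(sc, 13)
  prof <- colMeans(matrix(minuteProfile(buildAverageDay(sub$recording)),
                          nrow = 6))
  fit <- fitPiecewise(prof, stepH = 0.1)
  expect_equal(sleepOnset(fit), 22, tolerance = 1e-8)
  expect_equal(wakeTime(fit), 6, tolerance = 1e-8)
})

test_that("scenario files round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "groups:",
    "  - label: young",
    "    n_subjects: 4",
    "    age_range: [19, 30]",
    "    sot_mean_h: 23.5",
    "    noise_sd: 0.5",
    "  - label: old",
    "    n_subjects: 3",
    "    age_range: [71, 80]",
    "    sot_mean_h: 21.5",
    "    arrhythmic_fraction: 0.25"), path)
  scen <- readScenarioFile(path)
  expect_length(scen, 2L)
  expect_equal(scen[[1]]@label, "young")
  expect_equal(scen[[1]]@nSubjects, 4L)
  expect_equal(scen[[1]]@noiseSd, 0.5)
  expect_equal(scen[[2]]@arrhythmicFraction, 0.25)
  # omitted keys fall back to defaults
  expect_equal(scen[[2]]@nDays, 7L)
})
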