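test_that("hourly concatenation interpolates interior gaps and trims ends", {
  hm <- matrix(runif(7 * 24), 7, 24)
  expect_length(concatenateHourly(hm), 168L)

  hm2 <- matrix(5, 3, 24)
  hm2[1, 10] <- 4; hm2[1, 12] <- 6; hm2[1, 11] <- NA
  s <- concatenateHourly(hm2)
  expect_equal(s[11], 5)

  hm3 <- matrix(1, 3, 24)
  hm3[1, 1:5] <- NA; hm3[3, 20:24] <- NA
  expect_length(concatenateHourly(hm3), 72L - 10L)

  hm4 <- matrix(NA_real_, 7, 24)
  hm4[1, ] <- 1
  expect_error(concatenateHourly(hm4), "insufficient data")
})

test_that("the sample ACF is normalized and tracks a 24-h cosine", {
  set.seed(1)
  x <- runif(100)
  a <- activityAcf(x)
  expect_equal(unname(a[1]), 1)
  expect_true(all(abs(a) <= 1 + 1e-12))

  t <- 0:167
  a <- activityAcf(cos(2 * pi * t / 24))
  expect_gt(a["24"], 0.8)
  expect_gt(a["24"], a["23"])
  expect_gt(a["24"], a["25"])

  # white noise: correlations at positive lags stay near the O(1/sqrt(n))
  # sampling band
  set.seed(5)
  w <- abs(activityAcf(rnorm(168))[as.character(1:48)])
  expect_gte(mean(w < 0.2), 0.95)
  expect_true(all(w < 0.3))

  expect_error(activityAcf(rep(3, 100)), "constant signal")
})

test_that("ACF smoothing is a centered moving average with shrunken ends", {
  x <- runif(50)
  expect_identical(smoothAcf(x, 1L), x)
  expect_equal(smoothAcf(rep(2, 30), 5L), rep(2, 30))
  set.seed(9)
  x <- rnorm(40)
  expect_equal(smoothAcf(x, 7L), naiveMovingAverage(x, 7))
  expect_error(smoothAcf(x, 4L), "odd")
})

test_that("peak detection finds circadian-spaced ACF maxima", {
  t <- 0:167
  sm <- smoothAcf(activityAcf(cos(2 * pi * t / 24)))
  peaks <- detectPeaks(sm)
  expect_gte(length(peaks), 5L)
  expect_true(all(vapply(peaks, function(p)
    min(abs(p - seq(24, 168, by = 24))) <= 1, logical(1))))

  expect_length(detectPeaks(exp(-(0:100) / 10)), 0L)

  # of two candidate maxima 6 h apart only the higher is retained
  s <- rep(0, 41)
  s[21] <- 0.5; s[27] <- 0.4
  s[20] <- s[22] <- 0.2; s[26] <- s[28] <- 0.15
  expect_identical(detectPeaks(s, minSeparationH = 12), 20L)
  # spaced beyond the separation both survive
  s2 <- rep(0, 61)
  s2[21] <- 0.5; s2[41] <- 0.4
  expect_identical(detectPeaks(s2, minSeparationH = 12), c(20L, 40L))
})

test_that("the chi-square consistency test matches its closed form", {
  exact <- periodicityTest(rep(24, 6))
  expect_equal(exact$chi2Stat, 0)
  expect_equal(exact$pValue, 1)
  expect_true(exact$accepted)

  off <- periodicityTest(rep(30, 3))
  expect_equal(off$chi2Stat, 4.5)
  expect_equal(off$pValue, pchisq(4.5, df = 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(off$pValue, 0.2123, tolerance = 1e-3)
  # p exceeds 0.01 yet the mean-interval gate still rejects a 30-h rhythm
  expect_false(off$accepted)

  expect_false(periodicityTest(numeric(0))$accepted)

  # p decreases monotonically as intervals deviate further from 24 h
  ps <- vapply(seq(24, 30, by = 0.5), function(iv)
    periodicityTest(rep(iv, 5))$pValue, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("screening accepts rhythmic and rejects arrhythmic or flat subjects", {
  acc <- screenSubject(flatRecording())
  expect_true(isAccepted(acc))
  expect_equal(acc@reason, "ok")
  expect_equal(acc@chi2Stat, 0, tolerance = 1e-9)

  arr <- screenSubject(periodicRecording(29))
  expect_false(isAccepted(arr))

  flat <- screenSubject(makeRecording(matrix(5, 7, 1440)))
  expect_false(isAccepted(flat))
  expect_equal(flat@reason, "constant signal")

  tiny <- makeRecording(matrix(c(runif(1440), rep(NA, 1440)), 2,
                               byrow = TRUE))
  expect_false(isAccepted(screenSubject(tiny)))
})

test_that("acceptance is invariant to affine rescaling of the activity", {
  for (seed in 1:5) {
    sc <- groupScenario("g", 1, c(19, 30), sotMeanH = 23,
                        arrhythmicFraction = ifelse(seed %% 2 == 0, 1, 0))
    rec <- generateSubject(sc, seed)$recording
    v <- activityValues(rec)
    scaled <- makeRecording(2.7 * v + 3.1, subjectId = subjectId(rec))
    expect_identical(isAccepted(screenSubject(rec)),
                     isAccepted(screenSubject(scaled)))
  }
})
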