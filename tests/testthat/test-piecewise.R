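test_that("a clean two-level step profile is fitted exactly", {
  fit <- fitPiecewise(c(rep(2, 8), rep(14, 16)))
  expect_equal(sleepOnset(fit), 0)
  expect_equal(wakeTime(fit), 8)
  expect_equal(sleepLevel(fit), 2)
  expect_equal(wakeLevel(fit), 14)
  expect_equal(fit@sse, 0)
  expect_false(fit@degenerate)
})

test_that("a constant profile yields the canonical degenerate fit", {
  fit <- fitPiecewise(rep(7, 24))
  expect_true(fit@degenerate)
  expect_equal(fit@alpha, 7)
  expect_equal(fit@beta, 7)
  expect_equal(fit@sse, 0)
  expect_equal(fit@b1H, 0)
  expect_equal(fit@b2H, 12)
})

test_that("the fitter equals the brute-force minimizer on random profiles", {
  set.seed(20)
  for (rep in 1:50) {
    n <- sample(4:48, 1)
    x <- if (rep %% 3 == 0) {
      # piecewise-ish profile with noise: realistic near-tie structure
      s <- sample(n, 1); l <- sample(n - 1, 1)
      base <- rep(10, n)
      base[((s - 1 + seq_len(l) - 1) %% n) + 1] <- 2
      base + rnorm(n, sd = 0.5)
    } else {
      runif(n, 0, 20)
    }
    fit <- fitPiecewise(x)
    oracle <- bruteforcePiecewise(x)
    expect_equal(fit@b1H, oracle$b1)
    expect_equal(fit@b2H, oracle$b2)
    expect_equal(fit@alpha, oracle$alpha, tolerance = 1e-12)
    expect_equal(fit@beta, oracle$beta, tolerance = 1e-12)
    expect_equal(fit@sse, oracle$sse, tolerance = 1e-9)
  }
})

test_that("templates sampled from printed parameters round-trip exactly", {
  fit <- fitPiecewise(piecewiseTemplate(21.71, 6.92, 3.72, 15.71, 0.01),
                      stepH = 0.01)
  expect_equal(sleepOnset(fit), 21.71, tolerance = 1e-9)
  expect_equal(wakeTime(fit), 6.92, tolerance = 1e-9)
  expect_equal(sleepLevel(fit), 3.72, tolerance = 1e-9)
  expect_equal(wakeLevel(fit), 15.71, tolerance = 1e-9)
  expect_equal(fit@sse, 0, tolerance = 1e-9)
})

test_that("the derivative stencils are exact on low-degree polynomials", {
  expect_equal(activityDerivative(rep(4, 24)), rep(0, 24))

  t <- 0:23
  expect_equal(activityDerivative(t)[3:22], rep(1, 20))

  set.seed(12)
  co <- rnorm(5)
  f <- co[1] + co[2] * t + co[3] * t^2 + co[4] * t^3 + co[5] * t^4
  fp <- co[2] + 2 * co[3] * t + 3 * co[4] * t^2 + 4 * co[5] * t^3
  expect_equal(activityDerivative(f)[3:22], fp[3:22], tolerance = 1e-9)

  # cosine: interior error bounded by the 4th-order truncation term
  g <- cos(2 * pi * t / 24)
  gp <- -(2 * pi / 24) * sin(2 * pi * t / 24)
  bound <- (2 * pi / 24)^5 / 30
  expect_lt(max(abs(activityDerivative(g)[3:22] - gp[3:22])), bound * 1.01)

  expect_error(activityDerivative(c(1, 2, NA, 4, 5)), "finite")
})

test_that("fitted levels and times obey scale and shift equivariance", {
  set.seed(14)
  prof <- c(rep(3, 7), rep(12, 17)) + runif(24)
  fit <- fitPiecewise(prof)
  for (c in c(0.5, 2, 10)) {
    fs <- fitPiecewise(c * prof)
    expect_equal(sleepOnset(fs), sleepOnset(fit))
    expect_equal(wakeTime(fs), wakeTime(fit))
    expect_equal(fs@alpha, c * fit@alpha)
    expect_equal(fs@beta, c * fit@beta)
    expect_equal(fs@sse, c^2 * fit@sse, tolerance = 1e-9)
  }
  for (s in c(1, 5, 11)) {
    rot <- c(prof[(24 - s + 1):24], prof[1:(24 - s)])
    fr <- fitPiecewise(rot)
    expect_equal(fr@sse, fit@sse, tolerance = 1e-9)
    expect_equal(sleepOnset(fr), (sleepOnset(fit) + s) %% 24)
    expect_equal(wakeTime(fr), (wakeTime(fit) + s) %% 24)
  }
})

test_that("marker scale equivariance holds", {
  set.seed(15)
  t <- 0:23
  prof <- 10 + 5 * cos(2 * pi * (t - 14) / 24) + runif(24, 0, 0.5)
  m1 <- computeMarkers(prof)
  m3 <- computeMarkers(3 * prof)
  expect_equal(m3@windingDownPeriodH, m1@windingDownPeriodH)
  expect_equal(m3@windingDownActivity, 3 * m1@windingDownActivity)
  expect_equal(m3@overallActivity, 3 * m1@overallActivity)
  expect_equal(m3@ttaH, m1@ttaH)
})

test_that("winding-down and overall activity follow their definitions", {
  const <- computeMarkers(rep(5, 24))
  expect_equal(const@windingDownPeriodH, 0)
  expect_equal(const@windingDownActivity, 0)
  expect_equal(const@overallActivity, 120)
  expect_true(is.na(const@ttaH))

  t <- 0:23
  prof <- 10 + 5 * cos(2 * pi * (t - 14) / 24)
  deriv <- activityDerivative(prof)
  wd <- windingDown(prof, deriv)
  expect_lte(abs(wd[["periodH"]] - 12), 1)
  # matches the direct rectangle-rule evaluation over the negative set
  expect_equal(wd[["activity"]], sum(prof[deriv < 0]))
  expect_lte(wd[["activity"]], overallActivity(prof))

  expect_equal(overallActivity(runif(24, 1, 2) * 0), 0)
  set.seed(16)
  x <- runif(24, 0, 9)
  expect_equal(overallActivity(x), sum(x))
})

test_that("time to alertness matches analytic and dense-grid references", {
  t <- 0:23
  prof <- 10 + 5 * cos(2 * pi * (t - 14) / 24)   # trough at 02:00
  deriv <- activityDerivative(prof)
  tta <- timeToAlertness(prof, deriv)
  expect_equal(tta, 6, tolerance = 0.25)

  expect_true(is.na(timeToAlertness(rep(2, 24), activityDerivative(rep(2, 24)))))

  # two-harmonic profile against a dense evaluation of the analytic derivative
  f <- function(u) 10 + 4 * cos(2 * pi * (u - 15) / 24) +
    1.5 * cos(4 * pi * (u - 15) / 24 + 1)
  fp <- function(u) -4 * (2 * pi / 24) * sin(2 * pi * (u - 15) / 24) -
    1.5 * (4 * pi / 24) * sin(4 * pi * (u - 15) / 24 + 1)
  dense <- seq(0, 24, by = 1e-4)
  dv <- fp(dense)
  tPeak <- dense[which.max(dv)]
  before <- which(dv <= 0 & c(dv[-1], dv[1]) > 0 & dense < tPeak)
  tZero <- dense[max(before)]
  ref <- (tPeak - tZero) %% 24
  got <- timeToAlertness(f(t), activityDerivative(f(t)))
  expect_equal(got, ref, tolerance = 0.25)
})
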