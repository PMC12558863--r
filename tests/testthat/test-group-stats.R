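test_that("the weighted CDF steps by normalized weights", {
  F1 <- weightedCdf(5)
  expect_equal(F1(4.999), 0)
  expect_equal(F1(5), 1)

  F <- weightedCdf(c(1, 2), c(3, 1))
  expect_equal(F(1.5), 0.75)
  expect_equal(F(2), 1)

  # equals the empirical CDF of the weight-expanded sample
  set.seed(21)
  v <- round(runif(12, 0, 10), 1)
  w <- sample(1:5, 12, replace = TRUE)
  Fw <- weightedCdf(v, w)
  Fe <- ecdf(rep(v, times = w))
  at <- seq(-1, 11, by = 0.05)
  expect_equal(Fw(at), Fe(at))

  expect_error(weightedCdf(c(1, 2), c(1, 0)), "positive")
})

test_that("the 1-Wasserstein distance has its metric properties", {
  set.seed(22)
  x <- runif(15, 0, 10)
  expect_equal(wassersteinDistance(x, x), 0)
  expect_equal(wassersteinDistance(3, 5), 2)

  # translation identity on weighted fixtures
  for (i in 1:100) {
    v <- rnorm(sample(2:20, 1))
    w <- runif(length(v), 0.2, 3)
    s <- runif(1, -5, 5)
    expect_equal(wassersteinDistance(v, v + s, w, w), abs(s),
                 tolerance = 1e-9)
  }

  # symmetry and triangle inequality
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(8, 1); c <- rnorm(8, 2)
    ab <- wassersteinDistance(a, b)
    expect_equal(ab, wassersteinDistance(b, a), tolerance = 1e-12)
    expect_lte(ab,
               wassersteinDistance(a, c) + wassersteinDistance(c, b) + 1e-12)
  }
})

test_that("the permutation test saturates on identical samples and is seeded", {
  v <- c(1, 2, 3, 4)
  same <- wassersteinPermutationTest(v, v, nPermutations = 500, seed = 3)
  expect_gte(same$pValue, 0.99)

  set.seed(23)
  a <- rnorm(20, 0, 0.01)
  b <- rnorm(20, 10, 0.01)
  apart <- wassersteinPermutationTest(a, b, nPermutations = 10000, seed = 4)
  expect_lte(apart$pValue, 0.001)

  r1 <- wassersteinPermutationTest(a, b, nPermutations = 300, seed = 9)
  r2 <- wassersteinPermutationTest(a, b, nPermutations = 300, seed = 9)
  expect_identical(r1$pValue, r2$pValue)

  # common rescaling of both samples leaves the p-value unchanged
  r3 <- wassersteinPermutationTest(5 * a, 5 * b, nPermutations = 300,
                                   seed = 9)
  expect_identical(r1$pValue, r3$pValue)

  expect_false(is.na(wassersteinPermutationTest(a, b, nPermutations = 50,
                                                seed = 1)$warning))
})

test_that("permutation p-values are roughly uniform under the null", {
  set.seed(24)
  ps <- vapply(1:120, function(i) {
    pool <- rnorm(24)
    wassersteinPermutationTest(pool[1:12], pool[13:24],
                               nPermutations = 400, seed = i)$pValue
  }, numeric(1))
  ks <- max(abs(sort(ps) - (seq_along(ps) / length(ps))))
  expect_lt(ks, 0.15)
})

test_that("the TtA-on-wake regression matches closed-form OLS", {
  # an exact line makes summary.lm warn about a perfect fit; that is the point
  exact <- suppressWarnings(regressTtaOnWake(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(exact$slope, 1)
  expect_equal(exact$intercept, 0)
  expect_equal(exact$rSquared, 1)

  set.seed(25)
  x <- runif(12, 5, 9)
  y <- 0.8 * x - 2 + rnorm(12, sd = 0.3)
  got <- regressTtaOnWake(x, y)
  ref <- naiveOls(x, y)
  expect_equal(got$slope, ref$slope, tolerance = 1e-10)
  expect_equal(got$intercept, ref$intercept, tolerance = 1e-10)
  expect_equal(got$rSquared, ref$r2, tolerance = 1e-10)
  expect_equal(got$nPoints, 12L)
  expect_true(got$pValue > 0 && got$pValue < 1)

  expect_error(regressTtaOnWake(rep(3, 5), 1:5), "zero variance")
  expect_error(regressTtaOnWake(c(1, 2), c(1, 2)), "at least 3")
})

test_that("clock helpers wrap, unwrap and average circularly", {
  expect_equal(wrapClock(25.5), 1.5)
  expect_equal(unwrapClock(c(23.8, 0.2), center = 24), c(23.8, 24.2))
  expect_equal(circularMeanHours(c(23.5, 0.5)), 0)
  expect_equal(circularDiffHours(0.5, 23.5), 1)
  expect_equal(circularDiffHours(23.5, 0.5), -1)
})
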