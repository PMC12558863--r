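#' Weighted empirical CDF
#'
#' Right-continuous step CDF that jumps by `weight / sum(weights)` at each
#' sorted value; for integer weights it equals the ordinary empirical CDF of
#' the weight-expanded sample. Used to compare marker distributions in which
#' each cluster contributes its population count as weight.
#'
#' @param values Numeric marker values.
#' @param weights Positive weights, same length (default: equal weights).
#' @return A right-continuous step function (class `stepfun`); evaluate it
#'   at `x` to get the cumulative fraction at or below `x`.
#' @examples
#' F <- weightedCdf(c(1, 2), c(3, 1))
#' F(1.5)  # 0.75
#' @export
weightedCdf <- function(values, weights = rep(1, length(values))) {
  stopIfNot(length(values) >= 1L, "sample must be nonempty")
  stopIfNot(length(values) == length(weights),
            "values and weights must have equal length")
  stopIfNot(all(weights > 0), "weights must be positive")
  o <- order(values)
  v <- values[o]
  w <- weights[o]
  cw <- cumsum(w) / sum(w)
  last <- !duplicated(v, fromLast = TRUE)      # merge exact ties
  xs <- v[last]
  cw <- cw[last]
  cw[length(cw)] <- 1                          # exact top
  stats::stepfun(xs, c(0, cw), right = FALSE)
}

#' 1-Wasserstein distance between weighted samples
#'
#' The exact area between the two weighted step CDFs,
#' `integral |F_a(x) - F_b(x)| dx` over the pooled support. For point
#' masses at `u` and `v` this is `|u - v|`; translating a sample by `s`
#' moves the distance by exactly `|s|`.
#'
#' @param valuesA,valuesB Numeric samples.
#' @param weightsA,weightsB Positive weights (default equal).
#' @return Nonnegative distance in the units of the values.
#' @examples
#' wassersteinDistance(3, 5)  # 2
#' @export
wassersteinDistance <- function(valuesA, valuesB,
                                weightsA = rep(1, length(valuesA)),
                                weightsB = rep(1, length(valuesB))) {
  stopIfNot(length(valuesA) >= 1L && length(valuesB) >= 1L,
            "both samples must be nonempty")
  fa <- weightedCdf(valuesA, weightsA)
  fb <- weightedCdf(valuesB, weightsB)
  xs <- sort(unique(c(valuesA, valuesB)))
  if (length(xs) == 1L) return(0)
  widths <- diff(xs)
  left <- xs[-length(xs)]
  sum(widths * abs(fa(left) - fb(left)))
}

#' Permutation test on the Wasserstein distance
#'
#' Builds the null distribution by randomly reassigning the pooled
#' (value, weight) pairs to the two groups, preserving group sizes, and
#' recomputing the weighted 1-Wasserstein distance. The p-value uses the
#' add-one estimator `(1 + #{null >= observed}) / (1 + nPermutations)`;
#' ties count as exceedances. Deterministic given `seed`.
#'
#' @param valuesA,valuesB Numeric samples.
#' @param weightsA,weightsB Positive weights (default equal).
#' @param nPermutations Number of permutations (default 10000); fewer than
#'   100 records a warning in the result.
#' @param seed Integer seed.
#' @param labels Length-2 character vector naming the groups.
#' @return List with `groupA`, `groupB`, `w1Distance`, `pValue`,
#'   `nPermutations`, `seed`, and `warning` (`NA` or a message).
#' @export
wassersteinPermutationTest <- function(valuesA, valuesB,
                                       weightsA = rep(1, length(valuesA)),
                                       weightsB = rep(1, length(valuesB)),
                                       nPermutations = 10000L, seed = 1L,
                                       labels = c("A", "B")) {
  stopIfNot(length(valuesA) + length(valuesB) >= 2L,
            "need at least two observations in total")
  observed <- wassersteinDistance(valuesA, valuesB, weightsA, weightsB)
  vals <- c(valuesA, valuesB)
  wts <- c(weightsA, weightsB)
  nA <- length(valuesA)
  n <- length(vals)
  set.seed(as.integer(seed))
  exceed <- 0L
  for (i in seq_len(nPermutations)) {
    idx <- sample.int(n, nA)
    w1 <- wassersteinDistance(vals[idx], vals[-idx], wts[idx], wts[-idx])
    if (w1 >= observed - 1e-12) exceed <- exceed + 1L
  }
  warn <- if (nPermutations < 100L)
    sprintf("only %d permutations; p-value is coarse", nPermutations)
  else NA_character_
  list(groupA = labels[1L], groupB = labels[2L], w1Distance = observed,
       pValue = (1 + exceed) / (1 + nPermutations),
       nPermutations = as.integer(nPermutations), seed = as.integer(seed),
       warning = warn)
}

#' Regress time to alertness on wake time
#'
#' Ordinary least squares of cluster-level time-to-alertness on wake time
#' within one age group (one point per cluster, unweighted). Reports the
#' slope, intercept, R-squared and the two-sided p-value of the slope from
#' the t distribution with n - 2 degrees of freedom.
#'
#' @param wakeH Wake times (clock hours, already unwrapped onto a linear
#'   scale if they straddle midnight).
#' @param ttaH Times to alertness (h); `NA` pairs are dropped.
#' @return List with `slope`, `intercept`, `rSquared`, `pValue`, `nPoints`.
#' @export
regressTtaOnWake <- function(wakeH, ttaH) {
  keep <- is.finite(wakeH) & is.finite(ttaH)
  wakeH <- wakeH[keep]
  ttaH <- ttaH[keep]
  stopIfNot(length(wakeH) >= 3L, "need at least 3 (wake, TtA) points")
  stopIfNot(stats::var(wakeH) > 0, "zero variance in wake time")
  fit <- stats::lm(ttaH ~ wakeH)
  sm <- summary(fit)
  co <- stats::coef(sm)
  list(slope = unname(co["wakeH", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       rSquared = sm$r.squared,
       pValue = unname(co["wakeH", "Pr(>|t|)"]),
       nPoints = length(wakeH))
}
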