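# Independent oracles and fixture builders shared across tests. These are
# deliberately naive re-implementations (loops, direct formulas) so they
# stay independent of the production code paths they check.

makeRecording <- function(values, subjectId = "s1", ageYears = 25L) {
  new("SubjectRecording", subjectId = subjectId,
      ageYears = as.integer(ageYears), values = values)
}

# A flat-template recording: `nightLevel` on [sotH, sotH + durH), `dayLevel`
# elsewhere, identical days.
flatRecording <- function(sotH = 23, durH = 8, nightLevel = 2,
                          dayLevel = 15, nDays = 7, subjectId = "s1") {
  clock <- (0:1439) / 60
  x <- (clock - sotH) %% 24
  day <- ifelse(x < durH, nightLevel, dayLevel)
  makeRecording(matrix(rep(day, nDays), nrow = nDays, byrow = TRUE),
                subjectId = subjectId)
}

# A recording whose template repeats with an arbitrary period (hours).
periodicRecording <- function(periodH, sotH = 23, durH = 8, nightLevel = 2,
                              dayLevel = 15, nDays = 7, subjectId = "s1") {
  vals <- matrix(NA_real_, nDays, 1440)
  clock <- (0:1439) / 60
  for (d in seq_len(nDays)) {
    u <- ((d - 1) * 24 + clock) * 24 / periodH
    vals[d, ] <- dailyTemplate(u, sotH, durH, nightLevel, dayLevel,
                               transitionWidthH = 0)
  }
  makeRecording(vals, subjectId = subjectId)
}

# Exhaustive brute-force two-level piecewise-constant fit: direct means and
# residuals for every (start, length), same deterministic scan order and
# tie tolerance as the production fitter.
bruteforcePiecewise <- function(x, stepH = 24 / length(x)) {
  n <- length(x)
  best <- list(sse = Inf)
  for (l in seq_len(n - 1L)) {
    for (s in seq_len(n)) {
      idx <- ((s - 1L + 0:(l - 1L)) %% n) + 1L
      alpha <- mean(x[idx])
      beta <- mean(x[-idx])
      sse <- sum((x[idx] - alpha)^2) + sum((x[-idx] - beta)^2)
      if (sse < best$sse - 1e-12) {
        best <- list(s = s, l = l, alpha = alpha, beta = beta, sse = sse,
                     b1 = (s - 1L) * stepH,
                     b2 = ((s - 1L + l) %% n) * stepH)
      }
    }
  }
  best
}

# Brute-force minute-of-day mean over present values.
naiveAverageDay <- function(values) {
  vapply(seq_len(ncol(values)), function(t) {
    v <- values[, t]
    mean(v[!is.na(v)])
  }, numeric(1))
}

# Brute-force hourly groupby mean.
naiveHourlyMatrix <- function(values) {
  out <- matrix(NA_real_, nrow(values), 24)
  for (d in seq_len(nrow(values))) {
    for (tau in 1:24) {
      v <- values[d, ((tau - 1) * 60 + 1):(tau * 60)]
      if (any(!is.na(v))) out[d, tau] <- mean(v, na.rm = TRUE)
    }
  }
  out
}

naiveMovingAverage <- function(x, window) {
  half <- (window - 1) / 2
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    w <- x[max(1, i - half):min(length(x), i + half)]
    out[i] <- mean(w)
  }
  out
}

# Closed-form simple OLS via the normal equations.
naiveOls <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

# The three well-separated hourly chronotype templates used in clustering
# recovery checks.
threeTemplates <- function() {
  tmpl <- function(sot, dur, a, b) {
    x <- (0:23 - sot) %% 24
    ifelse(x < dur, a, b)
  }
  list(tmpl(23, 8, 2, 15), tmpl(21, 9, 2, 12), tmpl(1, 7, 3, 18))
}
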