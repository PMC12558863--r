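#' Concatenate an hourly matrix into one series
#'
#' Days are concatenated in order into a single hourly series of length
#' `nDays * 24`. Interior missing cells are filled by linear interpolation
#' between their nearest present neighbours; leading and trailing missing
#' cells are dropped (never extrapolated).
#'
#' @param hourlyMatrix `nDays x 24` matrix from [buildHourlyMatrix()].
#' @param minUsableHours Minimum number of present hourly values (default
#'   48, i.e. two days); fewer raises an "insufficient data" error.
#' @return Numeric series without missing values.
#' @export
concatenateHourly <- function(hourlyMatrix, minUsableHours = 48L) {
  series <- as.vector(t(hourlyMatrix))
  stopIfNot(sum(!is.na(series)) >= minUsableHours,
            "insufficient data: fewer than %d usable hours", minUsableHours)
  series <- interpolateInterior(series)
  ok <- which(!is.na(series))
  series[ok[1L]:ok[length(ok)]]
}

#' Sample autocorrelation at hourly lags
#'
#' Standard sample ACF (mean-corrected, normalized so that lag 0 equals 1)
#' of an hourly activity series, for lags up to `maxLag` hours (capped at
#' series length minus one).
#'
#' @param series Numeric series (no missing values).
#' @param maxLag Maximum lag in hours (default 168 = 7 days).
#' @return Numeric vector of ACF values named by lag `0..maxLag`.
#' @export
activityAcf <- function(series, maxLag = 168L) {
  stopIfNot(length(series) >= 2L, "series must have at least two values")
  stopIfNot(stats::var(series) > 0, "constant signal")
  lagMax <- min(maxLag, length(series) - 1L)
  a <- as.numeric(stats::acf(series, lag.max = lagMax, plot = FALSE,
                             demean = TRUE)$acf)
  names(a) <- 0:lagMax
  a
}

#' Smooth an ACF by a centered moving average
#'
#' @param acfValues Numeric vector (e.g. from [activityAcf()]).
#' @param window Odd window width; 1 is the identity. Ends use shrunken
#'   (asymmetric) windows so length is preserved.
#' @return Smoothed vector, same length and names.
#' @export
smoothAcf <- function(acfValues, window = 3L) {
  out <- movingAverage(as.numeric(acfValues), as.integer(window))
  names(out) <- names(acfValues)
  out
}

# Topographic prominence of peak i in series s: height above the higher of
# the two saddle minima separating it from taller terrain (or the series
# ends).
peakProminence <- function(s, i) {
  n <- length(s)
  leftMin <- s[i]
  j <- i - 1L
  while (j >= 1L && s[j] <= s[i]) {
    leftMin <- min(leftMin, s[j])
    j <- j - 1L
  }
  rightMin <- s[i]
  j <- i + 1L
  while (j <= n && s[j] <= s[i]) {
    rightMin <- min(rightMin, s[j])
    j <- j + 1L
  }
  s[i] - max(leftMin, rightMin)
}

#' Detect peaks in a smoothed ACF
#'
#' Finds local maxima of the smoothed ACF at lags 1 and above (lag 0 is
#' never a candidate), keeps those with topographic prominence at least
#' `minProminence`, and enforces a minimum spacing by greedily retaining
#' higher peaks first.
#'
#' @param smoothed Smoothed ACF values at lags `0..L` (from [smoothAcf()]).
#' @param minSeparationH Minimum spacing between retained peaks (h).
#' @param minProminence Minimum prominence on the ACF scale.
#' @return Strictly increasing integer vector of peak lags (h); may be
#'   empty.
#' @export
detectPeaks <- function(smoothed, minSeparationH = 12L,
                        minProminence = 0.05) {
  s <- as.numeric(smoothed)
  n <- length(s)
  if (n < 3L) return(integer(0))
  lag <- seq_len(n) - 1L
  cand <- integer(0)
  for (i in 3:n) {          # index i is lag i-1; lag 0 excluded
    isMax <- if (i < n) s[i] > s[i - 1L] && s[i] >= s[i + 1L]
             else s[i] > s[i - 1L]
    if (isMax && peakProminence(s, i) >= minProminence)
      cand <- c(cand, i)
  }
  if (length(cand) == 0L) return(integer(0))
  kept <- integer(0)
  for (i in cand[order(-s[cand], lag[cand])]) {
    if (all(abs(lag[i] - lag[kept]) >= minSeparationH))
      kept <- c(kept, i)
  }
  sort(lag[kept])
}

#' Chi-square consistency test of inter-peak intervals against 24 h
#'
#' Tests whether the spacings between successive ACF peaks are consistent
#' with a 24-hour rhythm. The statistic is
#' `sum((interval - expectedH)^2 / expectedH)` compared against the
#' chi-square upper tail with df = number of intervals. Following the
#' screening convention, the rhythm is *accepted* when the p-value exceeds
#' the threshold (a consistency test, not a significance test). Because the
#' statistic alone is weak against grossly non-24-h periods, an additional
#' gate requires the mean interval to lie within `maxMeanDeviationH` of
#' `expectedH`.
#'
#' @param intervals Numeric inter-peak intervals (h).
#' @param expectedH Expected period (default 24 h).
#' @param threshold Acceptance threshold on the p-value (default 0.01).
#' @param maxMeanDeviationH Maximum allowed deviation of the mean interval
#'   from `expectedH` (default 2 h).
#' @return List with `chi2Stat`, `pValue`, `accepted`, `reason`.
#' @examples
#' periodicityTest(rep(24, 6))   # chi2 = 0, p = 1, accepted
#' periodicityTest(rep(30, 3))   # chi2 = 4.5, p ~ 0.21, but gated out
#' @export
periodicityTest <- function(intervals, expectedH = 24,
                            threshold = 0.01, maxMeanDeviationH = 2) {
  if (length(intervals) == 0L)
    return(list(chi2Stat = NA_real_, pValue = NA_real_, accepted = FALSE,
                reason = "no recurring peaks"))
  chi2 <- sum((intervals - expectedH)^2 / expectedH)
  p <- stats::pchisq(chi2, df = length(intervals), lower.tail = FALSE)
  meanDev <- abs(mean(intervals) - expectedH)
  accepted <- (p > threshold) && (meanDev <= maxMeanDeviationH)
  reason <- if (accepted) "ok" else "periodicity inconsistent with 24 h"
  list(chi2Stat = chi2, pValue = p, accepted = accepted, reason = reason)
}

#' Screen a subject for robust 24-hour periodicity
#'
#' Composes the screening pipeline: hourly matrix, concatenation with
#' interior interpolation, sample ACF to `maxLag` hours, moving-average
#' smoothing, peak detection, and the chi-square consistency test of the
#' inter-peak intervals. Component failures (too little data, a constant
#' signal, no recurring peaks) become structured rejections, not errors.
#'
#' @param rec A [SubjectRecording-class].
#' @param threshold p-value acceptance threshold (accept when p > it).
#' @param smoothWindow Odd ACF smoothing window (h).
#' @param minSeparationH,minProminence Peak-detection constraints.
#' @param expectedH Expected period (h).
#' @param maxMeanDeviationH Gate on the mean inter-peak interval (h).
#' @param maxLag Maximum ACF lag (h).
#' @param minUsableHours Minimum present hours (default 48).
#' @return A [PeriodicityAssessment-class].
#' @export
screenSubject <- function(rec, threshold = 0.01, smoothWindow = 3L,
                          minSeparationH = 12L, minProminence = 0.05,
                          expectedH = 24, maxMeanDeviationH = 2,
                          maxLag = 168L, minUsableHours = 48L) {
  reject <- function(reason, acf = numeric(0), smoothed = numeric(0),
                     peaks = integer(0), intervals = numeric(0),
                     chi2 = NA_real_, p = NA_real_) {
    new("PeriodicityAssessment", subjectId = subjectId(rec), acf = acf,
        smoothedAcf = smoothed, peakLags = as.integer(peaks),
        intervals = as.numeric(intervals), chi2Stat = chi2, pValue = p,
        accepted = FALSE, threshold = threshold, reason = reason)
  }
  series <- tryCatch(
    concatenateHourly(buildHourlyMatrix(rec), minUsableHours),
    error = function(e) e)
  if (inherits(series, "error")) return(reject("insufficient data"))
  a <- tryCatch(activityAcf(series, maxLag), error = function(e) e)
  if (inherits(a, "error")) return(reject("constant signal"))
  sm <- smoothAcf(a, smoothWindow)
  peaks <- detectPeaks(sm, minSeparationH, minProminence)
  if (length(peaks) < 2L)
    return(reject("no recurring peaks", a, sm, peaks))
  intervals <- diff(peaks)
  tst <- periodicityTest(intervals, expectedH, threshold, maxMeanDeviationH)
  new("PeriodicityAssessment", subjectId = subjectId(rec), acf = a,
      smoothedAcf = sm, peakLags = as.integer(peaks),
      intervals = as.numeric(intervals), chi2Stat = tst$chi2Stat,
      pValue = tst$pValue, accepted = tst$accepted, threshold = threshold,
      reason = tst$reason)
}

#' Summarize screening results as a table
#'
#' @param assessments List of [PeriodicityAssessment-class].
#' @return data.frame with one row per subject: `subject_id`, `n_peaks`,
#'   `mean_interval_h`, `chi2`, `p_value`, `accepted`, `reason`.
#' @export
screeningReport <- function(assessments) {
  do.call(rbind, lapply(assessments, function(a) data.frame(
    subject_id = a@subjectId,
    n_peaks = length(a@peakLags),
    mean_interval_h = if (length(a@intervals)) mean(a@intervals) else NA_real_,
    chi2 = a@chi2Stat,
    p_value = a@pValue,
    accepted = a@accepted,
    reason = a@reason,
    stringsAsFactors = FALSE)))
}
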