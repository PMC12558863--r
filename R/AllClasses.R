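#' @import methods
NULL

MINUTES_PER_DAY <- 1440L
HOURS_PER_DAY <- 24L

#' Scenario describing one synthetic cohort group
#'
#' A `GroupScenario` bundles the generative parameters for one group of
#' synthetic subjects: how many subjects, their age range, the distribution of
#' sleep onset and sleep duration across subjects, the two activity levels of
#' the diurnal template (nocturnal and diurnal), the width of the
#' morning/evening transitions, measurement noise, day-to-day phase jitter,
#' the probability that a minute is missing, and the fraction of subjects
#' whose template runs at a non-24-hour period (arrhythmic subjects).
#'
#' @slot label Group label (unique within a cohort).
#' @slot nSubjects Number of subjects to generate.
#' @slot ageRange Inclusive integer age range, `c(min, max)` in years.
#' @slot sotMeanH,sotSdH Mean and SD of subject sleep-onset clock hour.
#' @slot sleepDurationMeanH,sleepDurationSdH Mean and SD of sleep duration (h).
#' @slot nightLevelMean,dayLevelMean Nocturnal and diurnal activity levels
#'   (arbitrary MIMS-like units); the night level must be below the day level.
#' @slot transitionWidthH Width of the logistic morning/evening ramps (h);
#'   0 gives hard two-level steps.
#' @slot noiseSd SD of additive minute noise (truncated at zero).
#' @slot dayJitterSdH SD of the per-day phase jitter (h).
#' @slot missingRate Probability that any minute is missing.
#' @slot arrhythmicFraction Probability that a subject is arrhythmic, in which
#'   case the template period is drawn uniformly from 26--32 h.
#' @slot nDays Number of recorded days (at most 7).
#'
#' @seealso [groupScenario()], [generateSubject()], [generateCohort()]
#' @export
setClass("GroupScenario",
  representation(
    label = "character",
    nSubjects = "integer",
    ageRange = "numeric",
    sotMeanH = "numeric",
    sotSdH = "numeric",
    sleepDurationMeanH = "numeric",
    sleepDurationSdH = "numeric",
    nightLevelMean = "numeric",
    dayLevelMean = "numeric",
    transitionWidthH = "numeric",
    noiseSd = "numeric",
    dayJitterSdH = "numeric",
    missingRate = "numeric",
    arrhythmicFraction = "numeric",
    nDays = "integer"
  )
)

setValidity("GroupScenario", function(object) {
  bad <- function(field, why) sprintf("invalid '%s': %s", field, why)
  if (length(object@label) != 1L || !nzchar(object@label))
    return(bad("label", "must be a non-empty string"))
  if (length(object@nSubjects) != 1L || is.na(object@nSubjects) ||
      object@nSubjects < 1L)
    return(bad("nSubjects", "must be >= 1"))
  if (length(object@ageRange) != 2L || any(is.na(object@ageRange)) ||
      object@ageRange[1L] > object@ageRange[2L])
    return(bad("ageRange", "must be c(min, max) with min <= max"))
  if (!(object@sleepDurationMeanH > 0 && object@sleepDurationMeanH < 24))
    return(bad("sleepDurationMeanH", "must lie strictly between 0 and 24"))
  if (!(object@nightLevelMean < object@dayLevelMean))
    return(bad("nightLevelMean", "must be below dayLevelMean"))
  if (object@nightLevelMean < 0)
    return(bad("nightLevelMean", "must be >= 0"))
  for (field in c("sotSdH", "sleepDurationSdH", "transitionWidthH",
                  "noiseSd", "dayJitterSdH")) {
    v <- slot(object, field)
    if (length(v) != 1L || is.na(v) || v < 0)
      return(bad(field, "must be a nonnegative number"))
  }
  for (field in c("missingRate", "arrhythmicFraction")) {
    v <- slot(object, field)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      return(bad(field, "must be a fraction in [0, 1]"))
  }
  if (length(object@nDays) != 1L || is.na(object@nDays) ||
      object@nDays < 1L || object@nDays > 7L)
    return(bad("nDays", "must be an integer in 1..7"))
  TRUE
})

#' A subject's minute-level activity recording
#'
#' Holds up to seven days of per-minute nonnegative activity values for one
#' subject as an `nDays x 1440` matrix; `NA` cells mark missing minutes
#' (distinct from zero activity, which is a legitimate value). Minute column
#' `m` covers clock time `[(m-1)/60, m/60)` hours.
#'
#' @slot subjectId Subject identifier.
#' @slot ageYears Age in whole years (`NA` if unknown).
#' @slot values `nDays x 1440` numeric matrix, `NA` = missing minute.
#'
#' @seealso [readMinuteTable()], [buildAverageDay()], [screenSubject()]
#' @export
setClass("SubjectRecording",
  representation(
    subjectId = "character",
    ageYears = "integer",
    values = "matrix"
  )
)

setValidity("SubjectRecording", function(object) {
  if (length(object@subjectId) != 1L || !nzchar(object@subjectId))
    return("subjectId must be a non-empty string")
  if (!is.numeric(object@values))
    return("values must be a numeric matrix")
  if (ncol(object@values) != MINUTES_PER_DAY)
    return(sprintf("values must have %d minute columns", MINUTES_PER_DAY))
  if (nrow(object@values) < 1L)
    return("values must contain at least one day")
  if (any(object@values < 0, na.rm = TRUE))
    return("activity values must be nonnegative")
  TRUE
})

#' Average-day representation of a recording
#'
#' The per-minute average day `Y_t` (each minute-of-day averaged over the days
#' on which it was observed) and its hourly compression `y_pa` (consecutive
#' 60-minute block means of `Y_t`).
#'
#' @slot minuteProfile Numeric vector of length 1440 (`Y_t`).
#' @slot hourlyProfile Numeric vector of length 24 (`y_pa`).
#' @slot nDaysUsed Number of days in the source recording.
#'
#' @seealso [buildAverageDay()]
#' @export
setClass("AverageDay",
  representation(
    minuteProfile = "numeric",
    hourlyProfile = "numeric",
    nDaysUsed = "integer"
  )
)

setValidity("AverageDay", function(object) {
  if (length(object@minuteProfile) != MINUTES_PER_DAY)
    return("minuteProfile must have 1440 values")
  if (length(object@hourlyProfile) != HOURS_PER_DAY)
    return("hourlyProfile must have 24 values")
  if (any(!is.finite(object@minuteProfile)) ||
      any(object@minuteProfile < 0))
    return("minuteProfile must be finite and nonnegative")
  blocks <- colMeans(matrix(object@minuteProfile, nrow = 60L))
  if (max(abs(blocks - object@hourlyProfile)) > 1e-8)
    return("hourlyProfile must equal the 60-minute block means of minuteProfile")
  TRUE
})

#' Outcome of the 24-hour periodicity screen for one subject
#'
#' Records the hourly-lag autocorrelation function of the concatenated hourly
#' series, its smoothed version, the detected peak lags, the inter-peak
#' intervals, the chi-square consistency statistic against a 24-h spacing with
#' its upper-tail p-value, and the accept/reject decision (a subject is
#' accepted when at least two peaks are found, the p-value *exceeds* the
#' threshold, and the mean inter-peak interval lies close to 24 h).
#'
#' @slot subjectId Subject identifier.
#' @slot acf Sample ACF at integer hourly lags `0..maxLag`.
#' @slot smoothedAcf Centered moving-average smoothed ACF (same length).
#' @slot peakLags Increasing integer lags (h) of detected ACF peaks.
#' @slot intervals Successive differences of `peakLags` (h).
#' @slot chi2Stat Chi-square statistic `sum((interval - 24)^2 / 24)`.
#' @slot pValue Upper-tail chi-square probability, df = number of intervals.
#' @slot accepted Whether the subject passed the screen.
#' @slot threshold Acceptance threshold on the p-value (accept when p > it).
#' @slot reason `"ok"` when accepted, otherwise a short rejection reason.
#'
#' @seealso [screenSubject()], [periodicityTest()]
#' @export
setClass("PeriodicityAssessment",
  representation(
    subjectId = "character",
    acf = "numeric",
    smoothedAcf = "numeric",
    peakLags = "integer",
    intervals = "numeric",
    chi2Stat = "numeric",
    pValue = "numeric",
    accepted = "logical",
    threshold = "numeric",
    reason = "character"
  )
)

setValidity("PeriodicityAssessment", function(object) {
  if (length(object@peakLags) > 1L && any(diff(object@peakLags) <= 0))
    return("peakLags must be strictly increasing")
  if (length(object@intervals) != max(0L, length(object@peakLags) - 1L))
    return("intervals must be the successive differences of peakLags")
  if (length(object@chi2Stat) == 1L && !is.na(object@chi2Stat) &&
      object@chi2Stat < 0)
    return("chi2Stat must be nonnegative")
  TRUE
})

#' Two-level piecewise-constant fit of a daily activity profile
#'
#' The fitted model takes a value `alpha` on the half-open clock window
#' `[b1, b2)` (wrapping midnight when `b2 <= b1`) and `beta` on its
#' complement. Independently of the raw window labels, `sotH`/`wtH` name the
#' start and end of the *lower*-level segment, the sleep-onset and wake-time
#' proxies.
#'
#' @slot b1H,b2H Fitted window boundaries in clock hours, window `[b1, b2)`.
#' @slot alpha In-window level; `beta` the complement level (a.u.).
#' @slot beta See `alpha`.
#' @slot sse Residual sum of squares of the fit.
#' @slot sotH,wtH Start and end (clock hours) of the lower-level segment.
#' @slot degenerate `TRUE` for an all-constant profile (canonical window
#'   `[0, 12)`, `alpha == beta`, `sse == 0`).
#' @slot stepH Sampling step of the fitted grid (h).
#'
#' @seealso [fitPiecewise()], [piecewiseTemplate()]
#' @export
setClass("PiecewiseFit",
  representation(
    b1H = "numeric",
    b2H = "numeric",
    alpha = "numeric",
    beta = "numeric",
    sse = "numeric",
    sotH = "numeric",
    wtH = "numeric",
    degenerate = "logical",
    stepH = "numeric"
  )
)

setValidity("PiecewiseFit", function(object) {
  if (object@sse < -1e-9) return("sse must be nonnegative")
  inClock <- function(x) x >= 0 && x < 24
  for (field in c("b1H", "b2H", "sotH", "wtH"))
    if (!inClock(slot(object, field)))
      return(sprintf("%s must lie in [0, 24)", field))
  TRUE
})

#' Derivative-based markers of one daily activity profile
#'
#' @slot windingDownPeriodH Total hours with negative activity derivative.
#' @slot windingDownActivity Activity integrated over the winding-down hours
#'   (a.u. h).
#' @slot overallActivity Activity integrated over the whole day (a.u. h).
#' @slot ttaH Time to alertness (h): from the morning inactive-to-active zero
#'   crossing of the derivative to the derivative's maximum; `NA` when the
#'   profile never increases.
#'
#' @seealso [computeMarkers()], [timeToAlertness()]
#' @export
setClass("MarkerSet",
  representation(
    windingDownPeriodH = "numeric",
    windingDownActivity = "numeric",
    overallActivity = "numeric",
    ttaH = "numeric"
  )
)

setValidity("MarkerSet", function(object) {
  if (object@windingDownPeriodH < 0 || object@windingDownPeriodH > 24)
    return("windingDownPeriodH must lie in [0, 24]")
  if (object@windingDownActivity < 0)
    return("windingDownActivity must be nonnegative")
  if (object@windingDownActivity > object@overallActivity + 1e-9)
    return("windingDownActivity cannot exceed overallActivity")
  TRUE
})

#' K-means clustering of hourly average-day profiles
#'
#' @slot k Number of clusters.
#' @slot centers `k x 24` matrix of cluster-center hourly profiles.
#' @slot labels Named integer vector, subject id -> cluster index (1..k).
#' @slot clusterCounts Integer vector of cluster sizes.
#' @slot wcssByK Named numeric vector: within-cluster sum of squares for each
#'   k explored when selecting the number of clusters (may be empty when k
#'   was fixed by the caller).
#' @slot seed Seed used for the k-means restarts.
#'
#' @seealso [clusterProfiles()], [wcssCurve()], [selectK()]
#' @export
setClass("ClusteringResult",
  representation(
    k = "integer",
    centers = "matrix",
    labels = "integer",
    clusterCounts = "integer",
    wcssByK = "numeric",
    seed = "integer"
  )
)

setValidity("ClusteringResult", function(object) {
  if (nrow(object@centers) != object@k)
    return("centers must have one row per cluster")
  if (length(object@clusterCounts) != object@k)
    return("clusterCounts must have one entry per cluster")
  if (any(object@clusterCounts < 1L))
    return("every cluster must be non-empty")
  if (sum(object@clusterCounts) != length(object@labels))
    return("cluster counts must sum to the number of clustered subjects")
  if (is.null(names(object@labels)))
    return("labels must be named by subject id")
  TRUE
})
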