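#' Accessors for actiphen S4 objects
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `subjectId()` and `activityValues()` for [SubjectRecording-class],
#' `minuteProfile()`/`hourlyProfile()` for [AverageDay-class],
#' `isAccepted()` for [PeriodicityAssessment-class], `sleepOnset()` and
#' `wakeTime()` for [PiecewiseFit-class], and `clusterCenters()` /
#' `clusterLabels()` for [ClusteringResult-class].
#'
#' @param x An actiphen S4 object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setMethod("subjectId", "SubjectRecording", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("subjectId", "PeriodicityAssessment", function(x) x@subjectId)

#' @rdname accessors
#' @export
setGeneric("ageYears", function(x) standardGeneric("ageYears"))
#' @rdname accessors
#' @export
setMethod("ageYears", "SubjectRecording", function(x) x@ageYears)

#' @rdname accessors
#' @export
setGeneric("activityValues", function(x) standardGeneric("activityValues"))
#' @rdname accessors
#' @export
setMethod("activityValues", "SubjectRecording", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("minuteProfile", function(x) standardGeneric("minuteProfile"))
#' @rdname accessors
#' @export
setMethod("minuteProfile", "AverageDay", function(x) x@minuteProfile)

#' @rdname accessors
#' @export
setGeneric("hourlyProfile", function(x) standardGeneric("hourlyProfile"))
#' @rdname accessors
#' @export
setMethod("hourlyProfile", "AverageDay", function(x) x@hourlyProfile)

#' @rdname accessors
#' @export
setGeneric("isAccepted", function(x) standardGeneric("isAccepted"))
#' @rdname accessors
#' @export
setMethod("isAccepted", "PeriodicityAssessment", function(x) x@accepted)

#' @rdname accessors
#' @export
setGeneric("sleepOnset", function(x) standardGeneric("sleepOnset"))
#' @rdname accessors
#' @export
setMethod("sleepOnset", "PiecewiseFit", function(x) x@sotH)

#' @rdname accessors
#' @export
setGeneric("wakeTime", function(x) standardGeneric("wakeTime"))
#' @rdname accessors
#' @export
setMethod("wakeTime", "PiecewiseFit", function(x) x@wtH)

#' @rdname accessors
#' @export
setGeneric("clusterCenters", function(x) standardGeneric("clusterCenters"))
#' @rdname accessors
#' @export
setMethod("clusterCenters", "ClusteringResult", function(x) x@centers)

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusteringResult", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("markerValues", function(x) standardGeneric("markerValues"))
#' @rdname accessors
#' @export
setMethod("markerValues", "MarkerSet", function(x) {
  c(windingDownPeriodH = x@windingDownPeriodH,
    windingDownActivity = x@windingDownActivity,
    overallActivity = x@overallActivity,
    ttaH = x@ttaH)
})

setMethod("show", "SubjectRecording", function(object) {
  v <- object@values
  cat(sprintf(
    "SubjectRecording '%s': %d day(s) x 1440 min, age %s, %.1f%% missing\n",
    object@subjectId, nrow(v),
    ifelse(is.na(object@ageYears), "NA", object@ageYears),
    100 * mean(is.na(v))))
})

setMethod("show", "AverageDay", function(object) {
  cat(sprintf(
    "AverageDay over %d day(s); minute mean %.2f, hourly range [%.2f, %.2f]\n",
    object@nDaysUsed, mean(object@minuteProfile),
    min(object@hourlyProfile), max(object@hourlyProfile)))
})

setMethod("show", "PeriodicityAssessment", function(object) {
  cat(sprintf(
    "PeriodicityAssessment '%s': %s (%s); %d peak(s), chi2 = %.3g, p = %.3g\n",
    object@subjectId, if (isTRUE(object@accepted)) "accepted" else "rejected",
    object@reason, length(object@peakLags), object@chi2Stat, object@pValue))
})

setMethod("show", "PiecewiseFit", function(object) {
  cat(sprintf(
    paste0("PiecewiseFit: window [%.2f, %.2f) h, alpha = %.3g, beta = %.3g, ",
           "SOT = %.2f, WT = %.2f, SSE = %.4g%s\n"),
    object@b1H, object@b2H, object@alpha, object@beta,
    object@sotH, object@wtH, object@sse,
    if (isTRUE(object@degenerate)) " (degenerate)" else ""))
})

setMethod("show", "MarkerSet", function(object) {
  cat(sprintf(
    paste0("MarkerSet: winding-down %.2f h / %.3g a.u.h, ",
           "overall %.3g a.u.h, TtA %s h\n"),
    object@windingDownPeriodH, object@windingDownActivity,
    object@overallActivity,
    ifelse(is.na(object@ttaH), "undefined", sprintf("%.2f", object@ttaH))))
})

setMethod("show", "ClusteringResult", function(object) {
  cat(sprintf("ClusteringResult: k = %d, sizes [%s], seed %d\n",
              object@k, paste(object@clusterCounts, collapse = ", "),
              object@seed))
})

setMethod("show", "GroupScenario", function(object) {
  cat(sprintf(
    paste0("GroupScenario '%s': %d subject(s), ages %d-%d, SOT %.1f+/-%.1f h, ",
           "sleep %.1f+/-%.1f h, levels %.1f/%.1f, %d day(s)\n"),
    object@label, object@nSubjects, object@ageRange[1L], object@ageRange[2L],
    object@sotMeanH, object@sotSdH, object@sleepDurationMeanH,
    object@sleepDurationSdH, object@nightLevelMean, object@dayLevelMean,
    object@nDays))
})
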