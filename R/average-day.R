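#' Collapse a recording into its average day
#'
#' Treats the recorded days as replicates: minute `t` of the average day,
#' `Y_t`, is the mean of the present (non-missing) values at that
#' minute-of-day across days; missing values are excluded from both the
#' numerator and the denominator. The hourly profile `y_pa` is the sequence
#' of consecutive 60-minute block means of `Y_t`. Day-to-day variation is
#' deliberately discarded.
#'
#' @param rec A [SubjectRecording-class].
#' @param minDaysPerMinute Minimum number of present days required at every
#'   minute-of-day (default 1); minutes covered by fewer days raise an error
#'   naming the first offending minute.
#' @return An [AverageDay-class].
#' @examples
#' v <- matrix(rep(c(1, 3), each = 1440), nrow = 2, byrow = TRUE)
#' rec <- new("SubjectRecording", subjectId = "s", ageYears = 25L, values = v)
#' minuteProfile(buildAverageDay(rec))[1]  # 2
#' @export
buildAverageDay <- function(rec, minDaysPerMinute = 1L) {
  validObject(rec)
  v <- activityValues(rec)
  nPresent <- colSums(!is.na(v))
  short <- which(nPresent < minDaysPerMinute)
  stopIfNot(length(short) == 0L,
            "minute-of-day %d has fewer than %d present value(s) across days",
            if (length(short)) short[1L] else 0L, minDaysPerMinute)
  Yt <- colMeans(v, na.rm = TRUE)
  ypa <- colMeans(matrix(Yt, nrow = 60L))
  new("AverageDay", minuteProfile = as.numeric(Yt),
      hourlyProfile = as.numeric(ypa), nDaysUsed = nrow(v))
}

#' Hourly day-by-hour activity matrix
#'
#' Cell `[d, tau]` is the mean of the present minutes in hour `tau` of day
#' `d`; a cell is `NA` only when all 60 minutes of that hour are missing.
#'
#' @param rec A [SubjectRecording-class].
#' @return `nDays x 24` numeric matrix.
#' @export
buildHourlyMatrix <- function(rec) {
  validObject(rec)
  v <- activityValues(rec)
  hm <- matrix(NA_real_, nrow = nrow(v), ncol = HOURS_PER_DAY)
  for (tau in seq_len(HOURS_PER_DAY)) {
    cols <- ((tau - 1L) * 60L + 1L):(tau * 60L)
    block <- v[, cols, drop = FALSE]
    m <- rowMeans(block, na.rm = TRUE)
    m[rowSums(!is.na(block)) == 0L] <- NA_real_
    hm[, tau] <- m
  }
  hm
}
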