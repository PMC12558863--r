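#' Read a minute-level activity table
#'
#' Reads a long-format CSV with one row per recorded minute, in the dialect
#' of the NHANES per-minute physical-activity files: default columns `SEQN`
#' (subject), `day` (1-based day index, at most 7), `minute` (1-based minute
#' of day, 1..1440) and `PAXMTSM` (nonnegative per-minute MIMS activity; an
#' empty field marks a missing minute). Minutes absent from the file are
#' marked missing -- never silently zero.
#'
#' @param path CSV file path.
#' @param columnMap Named list mapping roles `subject`, `day`, `minute`,
#'   `activity` to column names.
#' @param ages Optional data.frame with columns `SEQN` (or `subject_id`) and
#'   `age_years`, attaching ages to the returned recordings.
#' @return List of [SubjectRecording-class], ordered by subject id.
#' @seealso [writeMinuteTable()], [readAgeTable()]
#' @export
readMinuteTable <- function(path,
                            columnMap = list(subject = "SEQN", day = "day",
                                             minute = "minute",
                                             activity = "PAXMTSM"),
                            ages = NULL) {
  stopIfNot(file.exists(path), "minute table not found: %s", path)
  dt <- data.table::fread(path, colClasses = list(
    character = columnMap$subject))
  for (role in c("subject", "day", "minute", "activity"))
    stopIfNot(columnMap[[role]] %in% names(dt),
              "column '%s' (role '%s') not found in %s",
              columnMap[[role]], role, path)
  subj <- as.character(dt[[columnMap$subject]])
  day <- as.integer(dt[[columnMap$day]])
  minute <- as.integer(dt[[columnMap$minute]])
  act <- as.numeric(dt[[columnMap$activity]])

  stopIfNot(all(day >= 1L), "day index must be 1-based")
  stopIfNot(all(day <= 7L), "day index exceeds 7")
  stopIfNot(all(minute >= 1L & minute <= MINUTES_PER_DAY),
            "minute index must lie in 1..1440")
  stopIfNot(!any(act < 0, na.rm = TRUE),
            "negative activity values are not allowed")
  key <- paste(subj, day, minute)
  stopIfNot(!anyDuplicated(key),
            "duplicate (subject, day, minute) rows, e.g. %s",
            key[anyDuplicated(key)])

  ageOf <- NULL
  if (!is.null(ages)) {
    idCol <- intersect(c("SEQN", "subject_id"), names(ages))[1]
    stopIfNot(!is.na(idCol), "ages must have a SEQN or subject_id column")
    ageOf <- stats::setNames(as.integer(ages$age_years),
                             as.character(ages[[idCol]]))
  }

  out <- lapply(sort(unique(subj)), function(id) {
    sel <- subj == id
    nDays <- max(day[sel])
    vals <- matrix(NA_real_, nrow = nDays, ncol = MINUTES_PER_DAY)
    vals[cbind(day[sel], minute[sel])] <- act[sel]
    age <- if (!is.null(ageOf) && id %in% names(ageOf)) ageOf[[id]]
           else NA_integer_
    new("SubjectRecording", subjectId = id, ageYears = as.integer(age),
        values = vals)
  })
  out
}

#' Write recordings as a long-format minute CSV
#'
#' One row per *present* minute (missing minutes are omitted), in
#' deterministic (subject, day, minute) order, so identical input always
#' yields byte-identical files.
#'
#' @param recordings List of [SubjectRecording-class].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeMinuteTable <- function(recordings, path) {
  rows <- lapply(recordings, function(rec) {
    v <- activityValues(rec)
    present <- which(!is.na(v), arr.ind = TRUE)
    if (nrow(present) == 0L) return(NULL)
    data.table::data.table(
      SEQN = subjectId(rec),
      day = as.integer(present[, 1L]),
      minute = as.integer(present[, 2L]),
      # 17 significant digits so doubles survive the text round trip
      PAXMTSM = sprintf("%.17g", v[present]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    dt <- data.table::data.table(SEQN = character(), day = integer(),
                                 minute = integer(), PAXMTSM = character())
  } else {
    dt <- data.table::rbindlist(rows)
    data.table::setorder(dt, SEQN, day, minute)
  }
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a subject age table
#'
#' @param path CSV with columns `SEQN` and `age_years`.
#' @return data.frame with character `SEQN` and integer `age_years`.
#' @export
readAgeTable <- function(path) {
  stopIfNot(file.exists(path), "age table not found: %s", path)
  dt <- data.table::fread(path, colClasses = list(character = "SEQN"))
  stopIfNot(all(c("SEQN", "age_years") %in% names(dt)),
            "age table must have columns SEQN and age_years")
  data.frame(SEQN = as.character(dt$SEQN),
             age_years = as.integer(dt$age_years),
             stringsAsFactors = FALSE)
}

#' Adult age-group definitions
#'
#' The default partition used throughout the package: 19--30, 31--50, 51--70
#' and 71--80 years, with inclusive bounds on both ends. Subjects outside all
#' groups (for instance, under 19) are excluded from analysis.
#'
#' @param labels Optional labels; defaults to `"min-max"`.
#' @param bounds Two-column integer matrix of inclusive `(min, max)` rows.
#' @return data.frame with columns `label`, `min_years`, `max_years`.
#' @examples
#' ageGroups()
#' @export
ageGroups <- function(bounds = cbind(c(19L, 31L, 51L, 71L),
                                     c(30L, 50L, 70L, 80L)),
                      labels = sprintf("%d-%d", bounds[, 1L], bounds[, 2L])) {
  data.frame(label = labels, min_years = as.integer(bounds[, 1L]),
             max_years = as.integer(bounds[, 2L]), stringsAsFactors = FALSE)
}

#' Assign subjects to age groups
#'
#' Each subject with a known age falls into at most one group (groups must
#' not overlap); subjects outside all groups are excluded and reported.
#'
#' @param recordings List of [SubjectRecording-class] with ages set.
#' @param groups Age-group table from [ageGroups()].
#' @return List with `assignments` (named list: group label -> character
#'   vector of subject ids) and `excluded` (ids outside all groups).
#' @examples
#' # an 80-year-old falls in "71-80" (inclusive upper bound)
#' @export
assignAgeGroups <- function(recordings, groups = ageGroups()) {
  stopIfNot(nrow(groups) >= 1L, "at least one age group is required")
  if (nrow(groups) > 1L) {
    o <- order(groups$min_years)
    g <- groups[o, ]
    overlap <- any(g$min_years[-1L] <= g$max_years[-nrow(g)])
    stopIfNot(!overlap, "age groups overlap")
  }
  stopIfNot(all(groups$min_years <= groups$max_years),
            "age group bounds must satisfy min <= max")

  ids <- vapply(recordings, subjectId, character(1))
  ages <- vapply(recordings, ageYears, integer(1))
  stopIfNot(!anyNA(ages), "every subject needs age_years; missing for %s",
            paste(utils::head(ids[is.na(ages)], 3L), collapse = ", "))

  assignments <- stats::setNames(
    lapply(seq_len(nrow(groups)), function(i)
      ids[ages >= groups$min_years[i] & ages <= groups$max_years[i]]),
    groups$label)
  inAny <- Reduce(`|`, lapply(seq_len(nrow(groups)), function(i)
    ages >= groups$min_years[i] & ages <= groups$max_years[i]))
  list(assignments = assignments, excluded = ids[!inAny])
}
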