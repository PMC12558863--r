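#' Construct a synthetic-cohort group scenario
#'
#' Builds a validated [GroupScenario-class]. Defaults describe a realistic
#' MIMS-like regime: a diurnal level of 15 a.u. against a nocturnal level of
#' 2 a.u., one-hour logistic transitions, minute noise at 10% of the diurnal
#' level, a quarter-hour of day-to-day phase jitter, 2% missing minutes, and
#' seven recorded days.
#'
#' @param label Group label (unique within a cohort).
#' @param nSubjects Number of subjects.
#' @param ageRange Inclusive integer age range `c(min, max)` in years.
#' @param sotMeanH,sotSdH Across-subject mean/SD of sleep-onset clock hour.
#' @param sleepDurationMeanH,sleepDurationSdH Across-subject mean/SD of sleep
#'   duration (h).
#' @param nightLevelMean,dayLevelMean Template activity levels (a.u.).
#' @param transitionWidthH Logistic ramp width (h); 0 for hard steps.
#' @param noiseSd SD of additive minute noise, truncated at zero (a.u.).
#' @param dayJitterSdH SD of per-day phase jitter (h).
#' @param missingRate Per-minute missingness probability.
#' @param arrhythmicFraction Probability a subject is arrhythmic (template
#'   period drawn uniformly from 26--32 h instead of 24 h).
#' @param nDays Recorded days, at most 7.
#' @return A [GroupScenario-class] object.
#' @examples
#' groupScenario("young", 5, c(19, 30), sotMeanH = 23.5)
#' @export
groupScenario <- function(label, nSubjects, ageRange, sotMeanH,
                          sotSdH = 0.5,
                          sleepDurationMeanH = 8,
                          sleepDurationSdH = 0.5,
                          nightLevelMean = 2,
                          dayLevelMean = 15,
                          transitionWidthH = 1,
                          noiseSd = 1.5,
                          dayJitterSdH = 0.25,
                          missingRate = 0.02,
                          arrhythmicFraction = 0,
                          nDays = 7) {
  new("GroupScenario",
      label = as.character(label),
      nSubjects = as.integer(nSubjects),
      ageRange = as.numeric(ageRange),
      sotMeanH = as.numeric(sotMeanH),
      sotSdH = as.numeric(sotSdH),
      sleepDurationMeanH = as.numeric(sleepDurationMeanH),
      sleepDurationSdH = as.numeric(sleepDurationSdH),
      nightLevelMean = as.numeric(nightLevelMean),
      dayLevelMean = as.numeric(dayLevelMean),
      transitionWidthH = as.numeric(transitionWidthH),
      noiseSd = as.numeric(noiseSd),
      dayJitterSdH = as.numeric(dayJitterSdH),
      missingRate = as.numeric(missingRate),
      arrhythmicFraction = as.numeric(arrhythmicFraction),
      nDays = as.integer(nDays))
}

#' Two-level daily activity template
#'
#' Evaluates the smooth two-level diurnal template at pseudo-clock hours `u`:
#' the nocturnal level inside the sleep window starting at `sotH` and lasting
#' `durationH` hours (wrapping midnight), the diurnal level outside it, with
#' logistic ramps of nominal width `transitionWidthH` at both boundaries
#' (logistic scale = width / 4, so the central slope spans the nominal
#' width). `transitionWidthH = 0` gives the hard half-open window
#' `[sotH, sotH + durationH)`.
#'
#' @param u Pseudo-clock hours (any real values; reduced mod 24).
#' @param sotH Sleep-onset clock hour.
#' @param durationH Sleep duration (h), in (0, 24).
#' @param nightLevel,dayLevel Template levels (a.u.).
#' @param transitionWidthH Ramp width (h).
#' @return Numeric vector of template activity values.
#' @export
dailyTemplate <- function(u, sotH, durationH, nightLevel, dayLevel,
                          transitionWidthH = 1) {
  x <- (u - sotH) %% 24
  if (transitionWidthH <= 0) {
    w <- as.numeric(x < durationH)
  } else {
    s <- transitionWidthH / 4
    bump <- function(z) stats::plogis(z / s) - stats::plogis((z - durationH) / s)
    # sum over adjacent periods so the window is smooth across the wrap
    w <- bump(x) + bump(x - 24) + bump(x + 24)
  }
  dayLevel + (nightLevel - dayLevel) * w
}

#' Generate one synthetic subject
#'
#' Draws a subject from a scenario: subject-level sleep-onset hour and sleep
#' duration from the scenario's normal distributions, an arrhythmic flag with
#' probability `arrhythmicFraction` (arrhythmic subjects get a template
#' period drawn uniformly from 26--32 h, traversed continuously across days),
#' per-day phase jitter, additive truncated-at-zero minute noise, and
#' independent per-minute missingness. Activity for minute `m` is the
#' template evaluated at the minute's start time.
#'
#' @param scenario A [GroupScenario-class].
#' @param subjectSeed Integer seed; identical seeds reproduce the subject.
#' @param subjectId Subject identifier (default derived from label and seed).
#' @return A list with elements `recording` ([SubjectRecording-class]) and
#'   `truth` (one-row data.frame: `subject_id`, `true_sot_h`, `true_wt_h`,
#'   `true_night_level`, `true_day_level`, `rhythmic`).
#' @examples
#' sc <- groupScenario("g", 1, c(19, 30), sotMeanH = 23, noiseSd = 0,
#'                     dayJitterSdH = 0, missingRate = 0)
#' sub <- generateSubject(sc, subjectSeed = 1)
#' sub$truth
#' @export
generateSubject <- function(scenario, subjectSeed,
                            subjectId = sprintf("%s_s%d", scenario@label,
                                                subjectSeed)) {
  validObject(scenario)
  set.seed(as.integer(subjectSeed))

  age <- sample(seq(scenario@ageRange[1L], scenario@ageRange[2L]), 1L)
  rhythmic <- stats::runif(1) >= scenario@arrhythmicFraction
  period <- if (rhythmic) 24 else stats::runif(1, 26, 32)
  sot <- wrapClock(stats::rnorm(1, scenario@sotMeanH, scenario@sotSdH))
  dur <- min(23, max(1, stats::rnorm(1, scenario@sleepDurationMeanH,
                                     scenario@sleepDurationSdH)))
  nDays <- scenario@nDays
  jitter <- if (scenario@dayJitterSdH > 0)
    stats::rnorm(nDays, 0, scenario@dayJitterSdH) else numeric(nDays)

  clock <- (seq_len(MINUTES_PER_DAY) - 1) / 60
  vals <- matrix(NA_real_, nrow = nDays, ncol = MINUTES_PER_DAY)
  for (d in seq_len(nDays)) {
    tAbs <- (d - 1) * 24 + clock
    u <- (tAbs * 24 / period) - jitter[d]
    vals[d, ] <- dailyTemplate(u, sot, dur, scenario@nightLevelMean,
                               scenario@dayLevelMean,
                               scenario@transitionWidthH)
  }
  if (scenario@noiseSd > 0)
    vals <- pmax(vals + stats::rnorm(length(vals), 0, scenario@noiseSd), 0)
  if (scenario@missingRate > 0)
    vals[stats::runif(length(vals)) < scenario@missingRate] <- NA_real_

  rec <- new("SubjectRecording", subjectId = as.character(subjectId),
             ageYears = as.integer(age), values = vals)
  truth <- data.frame(
    subject_id = subjectId,
    true_sot_h = sot,
    true_wt_h = wrapClock(sot + dur),
    true_night_level = scenario@nightLevelMean,
    true_day_level = scenario@dayLevelMean,
    rhythmic = rhythmic,
    stringsAsFactors = FALSE)
  list(recording = rec, truth = truth)
}

#' Generate a multi-group synthetic cohort
#'
#' Derives one seed per subject deterministically from `masterSeed` and calls
#' [generateSubject()] for each; subject ids are unique across scenarios
#' (`<label>_<index>`).
#'
#' @param scenarios List of [GroupScenario-class] objects with distinct
#'   labels.
#' @param masterSeed Integer master seed.
#' @return A list with `recordings` (list of [SubjectRecording-class]),
#'   `truth` (data.frame with one row per subject plus a `group` column), and
#'   `groups` (named character vector subject id -> group label).
#' @examples
#' coh <- generateCohort(list(
#'   groupScenario("a", 2, c(19, 30), sotMeanH = 23),
#'   groupScenario("b", 3, c(31, 50), sotMeanH = 22.5)), masterSeed = 1)
#' length(coh$recordings)
#' @export
generateCohort <- function(scenarios, masterSeed) {
  stopIfNot(length(scenarios) >= 1L, "at least one scenario is required")
  labels <- vapply(scenarios, function(s) s@label, character(1))
  stopIfNot(!anyDuplicated(labels), "duplicate scenario labels: %s",
            paste(unique(labels[duplicated(labels)]), collapse = ", "))
  for (s in scenarios) validObject(s)

  counts <- vapply(scenarios, function(s) s@nSubjects, integer(1))
  total <- sum(counts)
  set.seed(as.integer(masterSeed))
  seeds <- sample.int(.Machine$integer.max - 1L, total)

  recordings <- vector("list", total)
  truthRows <- vector("list", total)
  groupOf <- character(total)
  idx <- 0L
  for (g in seq_along(scenarios)) {
    sc <- scenarios[[g]]
    for (i in seq_len(sc@nSubjects)) {
      idx <- idx + 1L
      id <- sprintf("%s_%03d", sc@label, i)
      sub <- generateSubject(sc, seeds[idx], subjectId = id)
      recordings[[idx]] <- sub$recording
      truthRows[[idx]] <- cbind(sub$truth, group = sc@label,
                                stringsAsFactors = FALSE)
      groupOf[idx] <- sc@label
    }
  }
  truth <- do.call(rbind, truthRows)
  names(groupOf) <- truth$subject_id
  list(recordings = recordings, truth = truth, groups = groupOf)
}

#' Read a scenario file
#'
#' Scenario files are plain-text YAML: a top-level `groups` list, one block
#' per group, with keys `label`, `n_subjects`, `age_range`, `sot_mean_h`,
#' `sot_sd_h`, `sleep_duration_mean_h`, `sleep_duration_sd_h`,
#' `night_level_mean`, `day_level_mean`, `transition_width_h`, `noise_sd`,
#' `day_jitter_sd_h`, `missing_rate`, `arrhythmic_fraction`, `n_days`.
#' Omitted keys fall back to the [groupScenario()] defaults.
#'
#' @param path Path to the YAML scenario file.
#' @return List of [GroupScenario-class] objects.
#' @export
readScenarioFile <- function(path) {
  stopIfNot(file.exists(path), "scenario file not found: %s", path)
  doc <- yaml::read_yaml(path)
  blocks <- if (!is.null(doc$groups)) doc$groups else doc
  lapply(blocks, function(b) {
    args <- list(
      label = b$label, nSubjects = b$n_subjects, ageRange = b$age_range,
      sotMeanH = b$sot_mean_h, sotSdH = b$sot_sd_h,
      sleepDurationMeanH = b$sleep_duration_mean_h,
      sleepDurationSdH = b$sleep_duration_sd_h,
      nightLevelMean = b$night_level_mean, dayLevelMean = b$day_level_mean,
      transitionWidthH = b$transition_width_h, noiseSd = b$noise_sd,
      dayJitterSdH = b$day_jitter_sd_h, missingRate = b$missing_rate,
      arrhythmicFraction = b$arrhythmic_fraction, nDays = b$n_days)
    do.call(groupScenario, args[!vapply(args, is.null, logical(1))])
  })
}

#' Write a cohort ground-truth table
#'
#' @param truth Ground-truth data.frame from [generateCohort()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  data.table::fwrite(truth, path)
  invisible(path)
}
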