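#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated list,
#' so all screening, clustering, marker and comparison settings are auditable
#' in one place. Exactly one input source must be given: either a scenario
#' file / scenario list (synthetic cohort) or a minute CSV plus age CSV.
#'
#' @param scenarioFile Path to a YAML scenario file (see
#'   [readScenarioFile()]).
#' @param scenarios List of [GroupScenario-class] (alternative to
#'   `scenarioFile`).
#' @param minuteCsv,ageCsv Paths to a minute-level activity CSV and an age
#'   CSV (see [readMinuteTable()], [readAgeTable()]).
#' @param ageGroupTable Age-group definitions from [ageGroups()].
#' @param masterSeed Seed for cohort generation.
#' @param threshold,smoothWindow,minSeparationH,minProminence,maxMeanDeviationH
#'   Periodicity-screen settings (see [screenSubject()]).
#' @param kRange,nRestarts,clusterSeed,standardize Clustering settings.
#' @param subjectFitStepH Grid step (h) for per-subject piecewise fits
#'   (default 0.1 h).
#' @param periodicDerivative Use the periodic derivative variant.
#' @param nPermutations,statSeed Group-comparison settings.
#' @param outDir Output directory for report artifacts (`NULL`: no files).
#' @param figures Render figures (best-effort).
#' @return A validated configuration list of class `actiphenConfig`.
#' @export
pipelineConfig <- function(scenarioFile = NULL, scenarios = NULL,
                           minuteCsv = NULL, ageCsv = NULL,
                           ageGroupTable = ageGroups(), masterSeed = 1L,
                           threshold = 0.01, smoothWindow = 3L,
                           minSeparationH = 12L, minProminence = 0.05,
                           maxMeanDeviationH = 2, kRange = 2:12,
                           nRestarts = 10L, clusterSeed = 1L,
                           standardize = FALSE, subjectFitStepH = 0.1,
                           periodicDerivative = FALSE,
                           nPermutations = 10000L, statSeed = 1L,
                           outDir = NULL, figures = FALSE) {
  fromScenario <- !is.null(scenarioFile) || !is.null(scenarios)
  fromFiles <- !is.null(minuteCsv) || !is.null(ageCsv)
  stopIfNot(xor(fromScenario, fromFiles),
            "provide exactly one input source: scenarios or CSV paths")
  if (fromFiles)
    stopIfNot(!is.null(minuteCsv) && !is.null(ageCsv),
              "both minuteCsv and ageCsv are required")
  cfg <- list(scenarioFile = scenarioFile, scenarios = scenarios,
              minuteCsv = minuteCsv, ageCsv = ageCsv,
              ageGroupTable = ageGroupTable,
              masterSeed = as.integer(masterSeed),
              threshold = threshold, smoothWindow = as.integer(smoothWindow),
              minSeparationH = minSeparationH,
              minProminence = minProminence,
              maxMeanDeviationH = maxMeanDeviationH,
              kRange = as.integer(kRange), nRestarts = as.integer(nRestarts),
              clusterSeed = as.integer(clusterSeed),
              standardize = isTRUE(standardize),
              subjectFitStepH = subjectFitStepH,
              periodicDerivative = isTRUE(periodicDerivative),
              nPermutations = as.integer(nPermutations),
              statSeed = as.integer(statSeed),
              outDir = outDir, figures = isTRUE(figures))
  class(cfg) <- "actiphenConfig"
  cfg
}

# Average a 1440-point minute profile into uniform bins of stepH hours.
rebinProfile <- function(minuteProfile, stepH) {
  n <- round(24 / stepH)
  stopIfNot(abs(n * stepH - 24) < 1e-8 && 1440 %% n == 0,
            "subjectFitStepH must divide 24 h into a whole number of minutes")
  colMeans(matrix(minuteProfile, nrow = 1440 %/% n))
}

#' Run the end-to-end phenotyping pipeline
#'
#' Executes, independently for every age group: cohort loading or synthetic
#' generation, the 24-h periodicity screen, average-day compression,
#' k-means clustering of hourly profiles with curvature-based selection of
#' k, piecewise-constant fitting of cluster centers, derivative-based
#' markers, pairwise weighted Wasserstein comparisons of the marker
#' distributions between groups, and the per-group regression of time to
#' alertness on wake time. Fully deterministic given the configuration.
#'
#' Artifacts (CSV tables) are first written to a staging directory and moved
#' into `outDir` only when every stage has succeeded.
#'
#' @param config An `actiphenConfig` from [pipelineConfig()].
#' @return A report list of class `actiphenReport`: `cohortSummary`,
#'   `screening` (per-subject table), `subjectFits` (per accepted subject),
#'   `clustering` (per group [ClusteringResult-class]), `clusterTable`
#'   (Table-1-style per-cluster parameters and markers), `comparisons`,
#'   `regressions`, `provenance`.
#' @export
runPipeline <- function(config) {
  stopIfNot(inherits(config, "actiphenConfig"),
            "config must come from pipelineConfig()")

  # --- stage: input -------------------------------------------------------
  truth <- NULL
  if (!is.null(config$scenarioFile) || !is.null(config$scenarios)) {
    scenarios <- if (!is.null(config$scenarios)) config$scenarios
                 else readScenarioFile(config$scenarioFile)
    cohort <- generateCohort(scenarios, config$masterSeed)
    recordings <- cohort$recordings
    truth <- cohort$truth
  } else {
    agesTab <- readAgeTable(config$ageCsv)
    recordings <- readMinuteTable(config$minuteCsv, ages = agesTab)
  }
  names(recordings) <- vapply(recordings, subjectId, character(1))

  # --- stage: age groups --------------------------------------------------
  grp <- assignAgeGroups(recordings, config$ageGroupTable)
  retained <- unlist(grp$assignments, use.names = FALSE)

  # --- stage: periodicity screen -----------------------------------------
  assessments <- lapply(recordings[retained], function(rec)
    screenSubject(rec, threshold = config$threshold,
                  smoothWindow = config$smoothWindow,
                  minSeparationH = config$minSeparationH,
                  minProminence = config$minProminence,
                  maxMeanDeviationH = config$maxMeanDeviationH))
  screening <- screeningReport(assessments)
  accepted <- screening$subject_id[screening$accepted]

  # --- stage: average days and subject-level fits ------------------------
  averageDays <- lapply(recordings[accepted], buildAverageDay)
  subjectFits <- do.call(rbind, lapply(accepted, function(id) {
    prof <- rebinProfile(minuteProfile(averageDays[[id]]),
                         config$subjectFitStepH)
    fit <- fitPiecewise(prof, config$subjectFitStepH)
    data.frame(subject_id = id,
               group = groupLabelOf(id, grp$assignments),
               sot_h = sleepOnset(fit), wt_h = wakeTime(fit),
               sleep_level = sleepLevel(fit), wake_level = wakeLevel(fit),
               sse = fit@sse, degenerate = fit@degenerate,
               stringsAsFactors = FALSE)
  }))

  # --- stage: clustering per age group -----------------------------------
  clustering <- list()
  clusterRows <- list()
  for (label in names(grp$assignments)) {
    ids <- intersect(grp$assignments[[label]], accepted)
    if (length(ids) == 0L) next
    profiles <- do.call(rbind, lapply(averageDays[ids], hourlyProfile))
    rownames(profiles) <- ids
    kr <- config$kRange[config$kRange <= nrow(profiles)]
    res <- if (length(kr) >= 4L) {
      clusterProfiles(profiles, k = NULL, seed = config$clusterSeed,
                      nRestarts = config$nRestarts, kRange = kr,
                      standardize = config$standardize)
    } else {
      clusterProfiles(profiles, k = min(2L, nrow(profiles)),
                      seed = config$clusterSeed,
                      nRestarts = config$nRestarts,
                      standardize = config$standardize)
    }
    clustering[[label]] <- res

    for (j in seq_len(res@k)) {
      center <- clusterCenters(res)[j, ]
      fit <- fitPiecewise(center, stepH = 1)
      mk <- computeMarkers(center, stepH = 1,
                           periodic = config$periodicDerivative)
      clusterRows[[length(clusterRows) + 1L]] <- data.frame(
        group = label, cluster = j, count = res@clusterCounts[j],
        sot_h = sleepOnset(fit), wt_h = wakeTime(fit),
        alpha = fit@alpha, beta = fit@beta, sse = fit@sse,
        winding_down_period_h = mk@windingDownPeriodH,
        winding_down_activity = mk@windingDownActivity,
        overall_activity = mk@overallActivity,
        tta_h = mk@ttaH, stringsAsFactors = FALSE)
    }
  }
  clusterTable <- if (length(clusterRows)) do.call(rbind, clusterRows)
                  else NULL

  # --- stage: group comparisons ------------------------------------------
  comparisons <- NULL
  regressions <- NULL
  if (!is.null(clusterTable) && length(unique(clusterTable$group)) >= 1L) {
    markers <- c("winding_down_period_h", "winding_down_activity",
                 "overall_activity", "sot_h", "wt_h")
    gs <- unique(clusterTable$group)
    compRows <- list()
    if (length(gs) >= 2L) {
      pairs <- utils::combn(gs, 2L, simplify = FALSE)
      for (marker in markers) {
        for (pr in pairs) {
          ta <- clusterTable[clusterTable$group == pr[1L], ]
          tb <- clusterTable[clusterTable$group == pr[2L], ]
          va <- markerComparisonValues(ta, marker)
          vb <- markerComparisonValues(tb, marker)
          tst <- wassersteinPermutationTest(
            va, vb, ta$count, tb$count,
            nPermutations = config$nPermutations,
            seed = config$statSeed, labels = pr)
          compRows[[length(compRows) + 1L]] <- data.frame(
            marker = marker, group_a = pr[1L], group_b = pr[2L],
            w1 = tst$w1Distance, p_value = tst$pValue,
            n_permutations = tst$nPermutations, seed = tst$seed,
            stringsAsFactors = FALSE)
        }
      }
      comparisons <- do.call(rbind, compRows)
    }
    regRows <- list()
    for (g in gs) {
      tg <- clusterTable[clusterTable$group == g, ]
      ok <- is.finite(tg$tta_h)
      if (sum(ok) >= 3L && stats::var(tg$wt_h[ok]) > 0) {
        wake <- unwrapClock(tg$wt_h[ok],
                            center = circularMeanHours(tg$wt_h[ok]))
        r <- regressTtaOnWake(wake, tg$tta_h[ok])
        regRows[[length(regRows) + 1L]] <- data.frame(
          group = g, slope = r$slope, intercept = r$intercept,
          r2 = r$rSquared, p = r$pValue, n = r$nPoints,
          stringsAsFactors = FALSE)
      }
    }
    if (length(regRows)) regressions <- do.call(rbind, regRows)
  }

  nByReason <- table(screening$reason[!screening$accepted])
  report <- list(
    cohortSummary = list(
      nRead = length(recordings),
      nRetained = length(retained),
      nExcludedByAge = length(grp$excluded),
      nAccepted = length(accepted),
      nRejected = sum(!screening$accepted),
      rejectedByReason = as.list(nByReason),
      perGroup = vapply(grp$assignments, function(ids)
        length(intersect(ids, accepted)), integer(1))),
    screening = screening,
    subjectFits = subjectFits,
    truth = truth,
    clustering = clustering,
    clusterTable = clusterTable,
    comparisons = comparisons,
    regressions = regressions,
    provenance = list(config = config, packageVersion =
                        as.character(utils::packageVersion("actiphen"))))
  class(report) <- "actiphenReport"

  # --- stage: artifacts ---------------------------------------------------
  if (!is.null(config$outDir)) writeReport(report, config$outDir)
  if (isTRUE(config$figures) && !is.null(config$outDir))
    renderFigures(report, config$outDir)
  report
}

groupLabelOf <- function(id, assignments) {
  for (label in names(assignments))
    if (id %in% assignments[[label]]) return(label)
  NA_character_
}

# Marker values entering a group comparison; clock-valued markers (SOT/WT)
# are unwrapped around their pooled circular mean so distances are computed
# on a linear scale.
markerComparisonValues <- function(tab, marker) {
  v <- tab[[marker]]
  if (marker %in% c("sot_h", "wt_h"))
    v <- unwrapClock(v, center = circularMeanHours(v))
  v
}

#' Write report artifacts
#'
#' Writes the screening table, per-subject fits, cluster parameter table,
#' comparisons, regressions and a provenance echo as CSV/YAML files,
#' atomically: everything goes to a staging directory that replaces
#' `outDir`'s content only on success.
#'
#' @param report An `actiphenReport` from [runPipeline()].
#' @param outDir Output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeReport <- function(report, outDir) {
  staging <- file.path(tempfile("actiphen_stage_"))
  dir.create(staging, recursive = TRUE)
  put <- function(x, name) {
    if (!is.null(x)) data.table::fwrite(x, file.path(staging, name))
  }
  put(report$screening, "screening.csv")
  put(report$subjectFits, "subject_fits.csv")
  put(report$clusterTable, "cluster_parameters.csv")
  put(report$comparisons, "comparisons.csv")
  put(report$regressions, "regressions.csv")
  put(report$truth, "ground_truth.csv")
  summaryLines <- c(
    sprintf("subjects_read: %d", report$cohortSummary$nRead),
    sprintf("subjects_in_age_range: %d", report$cohortSummary$nRetained),
    sprintf("subjects_accepted: %d", report$cohortSummary$nAccepted),
    sprintf("subjects_rejected: %d", report$cohortSummary$nRejected),
    sprintf("package_version: %s", report$provenance$packageVersion))
  writeLines(summaryLines, file.path(staging, "summary.yaml"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  for (f in list.files(staging, full.names = TRUE))
    file.copy(f, file.path(outDir, basename(f)), overwrite = TRUE)
  unlink(staging, recursive = TRUE)
  invisible(outDir)
}

#' Print a pipeline report summary
#'
#' @param x An `actiphenReport`.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
print.actiphenReport <- function(x, ...) {
  s <- x$cohortSummary
  cat(sprintf(
    "actiphen pipeline report: %d read, %d in age range, %d accepted\n",
    s$nRead, s$nRetained, s$nAccepted))
  if (length(s$perGroup)) {
    cat("accepted per group:\n")
    for (g in names(s$perGroup))
      cat(sprintf("  %s: %d", g, s$perGroup[[g]]),
          if (!is.null(x$clustering[[g]]))
            sprintf(" (k = %d)\n", x$clustering[[g]]@k) else "\n")
  }
  invisible(x)
}
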