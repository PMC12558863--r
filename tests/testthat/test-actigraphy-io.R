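test_that("minute tables round-trip exactly, including the missing pattern", {
  sc <- groupScenario("g", 2, c(19, 30), sotMeanH = 23, missingRate = 0.05)
  coh <- generateCohort(list(sc), 17)
  path <- withr::local_tempfile(fileext = ".csv")
  writeMinuteTable(coh$recordings, path)
  back <- readMinuteTable(path)
  expect_length(back, 2L)
  for (i in 1:2) {
    orig <- coh$recordings[[i]]
    match <- back[[which(vapply(back, subjectId, character(1)) ==
                           subjectId(orig))]]
    expect_identical(activityValues(match), unname(activityValues(orig)))
  }
})

test_that("writes are deterministic and empty input gives a header-only file", {
  sc <- groupScenario("g", 1, c(19, 30), sotMeanH = 23, missingRate = 0.02)
  rec <- generateSubject(sc, 4)$recording
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeMinuteTable(list(rec), p1)
  writeMinuteTable(list(rec), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  p0 <- withr::local_tempfile(fileext = ".csv")
  writeMinuteTable(list(), p0)
  expect_length(readLines(p0), 1L)

  # one full day -> 1440 data rows
  one <- makeRecording(matrix(1, 1, 1440))
  pOne <- withr::local_tempfile(fileext = ".csv")
  writeMinuteTable(list(one), pOne)
  expect_length(readLines(pOne), 1441L)
})

test_that("absent minutes are flagged missing, never zero", {
  dt <- expand.grid(day = 1:2, minute = 1:1440)
  dt$SEQN <- "s1"
  dt$PAXMTSM <- 1
  dt <- dt[!(dt$day == 2 & dt$minute == 100), ]
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(dt[order(dt$day, dt$minute), ], path, row.names = FALSE)
  rec <- readMinuteTable(path)[[1]]
  v <- activityValues(rec)
  expect_true(is.na(v[2, 100]))
  expect_equal(sum(is.na(v)), 1L)
})

test_that("malformed minute tables are rejected", {
  base <- data.frame(SEQN = "s1", day = 1L, minute = 1:3, PAXMTSM = 1)
  path <- withr::local_tempfile(fileext = ".csv")

  dup <- rbind(base, base[1, ])
  write.csv(dup, path, row.names = FALSE)
  expect_error(readMinuteTable(path), "duplicate")

  neg <- base
  neg$PAXMTSM[2] <- -1
  write.csv(neg, path, row.names = FALSE)
  expect_error(readMinuteTable(path), "negative")

  late <- base
  late$day <- 8L
  write.csv(late, path, row.names = FALSE)
  expect_error(readMinuteTable(path), "day")
})

test_that("age-group assignment follows the inclusive adult partition", {
  recs <- list(makeRecording(matrix(1, 1, 1440), "a", 25L),
               makeRecording(matrix(1, 1, 1440), "b", 18L),
               makeRecording(matrix(1, 1, 1440), "c", 80L),
               makeRecording(matrix(1, 1, 1440), "d", 31L),
               makeRecording(matrix(1, 1, 1440), "e", 30L))
  out <- assignAgeGroups(recs)
  expect_setequal(out$assignments[["19-30"]], c("a", "e"))
  expect_identical(out$assignments[["71-80"]], "c")
  expect_identical(out$assignments[["31-50"]], "d")
  expect_identical(out$excluded, "b")
})

test_that("group assignment partitions the retained cohort", {
  set.seed(1)
  ages <- sample(10:90, 40, replace = TRUE)
  recs <- lapply(seq_along(ages), function(i)
    makeRecording(matrix(1, 1, 1440), sprintf("s%02d", i), ages[i]))
  out <- assignAgeGroups(recs)
  assigned <- unlist(out$assignments, use.names = FALSE)
  expect_false(anyDuplicated(assigned) > 0)
  expect_equal(sort(c(assigned, out$excluded)),
               sort(vapply(recs, subjectId, character(1))))
  expect_equal(length(assigned), sum(ages >= 19 & ages <= 80))
})

test_that("overlapping age groups are rejected", {
  groups <- data.frame(label = c("x", "y"), min_years = c(19L, 25L),
                       max_years = c(30L, 40L))
  recs <- list(makeRecording(matrix(1, 1, 1440), "a", 25L))
  expect_error(assignAgeGroups(recs, groups), "overlap")
})
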