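test_that("reader preserves record and event counts", {
  dir <- withr::local_tempdir()
  writeCohort(toyCohort(), dir)
  ch <- readCohort(dir)
  expect_equal(nRecords(ch), 3L)
  expect_equal(nrow(labEvents(ch)), 6L)
  expect_equal(sum(labEvents(ch)$record_id == "A"), 3L)
  expect_equal(sum(labEvents(ch)$record_id == "B"), 3L)
  # events sorted by day within record
  byRec <- split(labEvents(ch)$day, labEvents(ch)$record_id)
  expect_true(all(vapply(byRec, function(d) !is.unsorted(d), NA)))
})

test_that("demographics-only input yields records with empty event streams", {
  dir <- withr::local_tempdir()
  demo <- data.frame(record_id = c("X", "Y"), sex = "female",
                     race = "white", birth_day_offset = -10000)
  writeCohort(EHRCohort(demo), dir)
  ch <- readCohort(dir)
  expect_equal(nRecords(ch), 2L)
  expect_equal(nrow(labEvents(ch)), 0L)
  expect_equal(nrow(codeEvents(ch)), 0L)
  expect_equal(nrow(medEvents(ch)), 0L)
})

test_that("write/read round trip reproduces every field", {
  set.seed(42)
  gt <- tinyGroundTruth()
  sim <- simulateCohort(gt, simConfig(20, seed = 9))
  dir <- withr::local_tempdir()
  writeCohort(sim$cohort, dir)
  ch <- readCohort(dir)
  orig <- sim$cohort
  for (acc in list(labEvents, codeEvents, medEvents, demographics))
    expect_equal(acc(ch), acc(orig), ignore_attr = TRUE)
  expect_equal(indexDays(ch), indexDays(orig))
  expect_equal(recordSpans(ch), recordSpans(orig))
  expect_equal(recordLabels(ch), recordLabels(orig))
})

test_that("reader rejects malformed inputs", {
  dir <- withr::local_tempdir()
  writeCohort(toyCohort(), dir)
  # drop a required column
  labs <- read.csv(file.path(dir, "labs.csv"))
  write.csv(labs[, setdiff(names(labs), "value")],
            file.path(dir, "labs.csv"), row.names = FALSE)
  expect_error(readCohort(dir), "schema")
  labs$day[1] <- -5
  write.csv(labs, file.path(dir, "labs.csv"), row.names = FALSE)
  expect_error(readCohort(dir), "negative")
})

test_that("truncation keeps only pre-index events and is idempotent", {
  ch <- toyCohort()
  # record A: codes at 10, 200 with index 250 -> both kept; labs all kept
  tr <- truncateAtIndex(ch)
  expect_equal(unname(recordSpans(tr)), unname(indexDays(ch)))
  # B: lab at day 90 <= index 90 kept (boundary inclusive)
  expect_equal(sum(labEvents(tr)$record_id == "B"), 3L)
  # move index earlier and check filtering
  ch2 <- EHRCohort(demographics(ch), labs = labEvents(ch),
                   codes = codeEvents(ch), meds = medEvents(ch),
                   spans = recordSpans(ch),
                   index = setNames(c(100, 15, 120), c("A", "B", "C")))
  tr2 <- truncateAtIndex(ch2)
  expect_equal(labEvents(tr2)$day[labEvents(tr2)$record_id == "A"],
               c(0, 10, 50))
  expect_equal(labEvents(tr2)$day[labEvents(tr2)$record_id == "B"], 5)
  # demographics retained even when all events are dropped
  expect_equal(demographics(tr2), demographics(ch2))
  # idempotent
  expect_equal(truncateAtIndex(tr2), tr2)
  # precondition: index required
  ch3 <- EHRCohort(demographics(ch), spans = recordSpans(ch))
  expect_error(truncateAtIndex(ch3), "index")
})

mkLabelCohort <- function(relDays) {
  demo <- data.frame(record_id = "P", sex = "female", race = "white",
                     birth_day_offset = -10000)
  codes <- data.frame(record_id = "P", day = 100 + relDays,
                      code_id = "malig")
  EHRCohort(demo, codes = codes, index = c(P = 100),
            spans = c(P = 100 + max(relDays, 0)))
}

test_that("labeling window boundaries follow the inclusive [4, 1095] rule", {
  lab <- function(rel) as.character(
    assignLabels(mkLabelCohort(rel), "malig")[["P"]])
  expect_equal(lab(4), "positive")      # window opens on day 4
  expect_equal(lab(1095), "positive")   # closes on day 1095, inclusive
  expect_equal(lab(2), "excluded")      # same-period diagnosis -> excluded
  expect_equal(lab(1096), "negative")   # beyond the window
  # prior-cancer history dominates a within-window code
  expect_equal(lab(c(2, 10)), "excluded")
  # no malignancy code anywhere
  ch <- mkLabelCohort(10)
  expect_equal(as.character(assignLabels(ch, "othercode")[["P"]]),
               "negative")
})

test_that("labeling is invariant to event order and out-of-window events", {
  demo <- data.frame(record_id = c("P", "Q"), sex = "female",
                     race = "white", birth_day_offset = -10000)
  codes <- data.frame(record_id = c("P", "P", "Q"),
                      day = c(1300, 110, 2000), code_id = "malig")
  ch <- EHRCohort(demo, codes = codes,
                  index = c(P = 100, Q = 100), spans = c(P = 2000, Q = 2000))
  ch2 <- EHRCohort(demo, codes = codes[c(2, 1, 3), ],
                   index = c(P = 100, Q = 100),
                   spans = c(P = 2000, Q = 2000))
  l1 <- assignLabels(ch, "malig")
  expect_equal(l1, assignLabels(ch2, "malig"))
  expect_equal(as.character(l1[["P"]]), "positive")
  expect_equal(as.character(l1[["Q"]]), "negative")
  expect_error(assignLabels(ch, character()), "configuration")
})

test_that("cohort summary reports strata percentages and per-record IQIs", {
  sm <- cohortSummary(toyCohort())
  expect_equal(sm$n, 3L)
  male <- sm$strata[sm$strata$field == "sex" & sm$strata$level == "male", ]
  expect_equal(male$count, 2L)
  expect_equal(male$percent, 100 * 2 / 3, tolerance = 1e-12)
  # single-record cohort: median equals the record's value, IQI degenerate
  demo1 <- data.frame(record_id = "Z", sex = "male", race = "white",
                      birth_day_offset = -9000)
  codes1 <- data.frame(record_id = "Z", day = c(1, 2, 3), code_id = "c")
  one <- cohortSummary(EHRCohort(demo1, codes = codes1,
                                 spans = c(Z = 50)))
  row <- one$perRecord[one$perRecord$statistic == "n_billing_codes", ]
  expect_equal(row$median, 3)
  expect_equal(row$q25, 3)
  expect_equal(row$q75, 3)
  expect_error(cohortSummary(EHRCohort(demo1[0, ])), "empty")
})
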