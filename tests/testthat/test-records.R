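window <- observation_window("2005-04-01", "2008-05-31")

test_that("well-formed files parse into records and issues are flagged, not dropped", {
  path <- write_records_fixture(c(
    "P1,PF,placement,2005-06-01,2005-08-15,died,82,640.50",
    "P2,Palliative,home_care,2006-01-10,,,75,410",
    "P3,OMH,placement,2007-03-05,2007-02-01,home,68,590"))
  rec <- read_stay_records(path)
  expect_equal(nrow(rec), 3)
  expect_s3_class(rec, "stay_records")
  expect_equal(rec$invalid, c(FALSE, FALSE, TRUE))  # discharge < admission
  expect_match(attr(rec, "issues"), "row 3")
  expect_true(is.na(rec$discharge_date[2]))
  expect_equal(rec$weekly_cost[1], 640.5)
})

test_that("unparseable dates are flagged with a row-level log", {
  path <- write_records_fixture(c(
    "P1,PF,placement,not-a-date,2005-08-15,died,82,640",
    "P2,PF,placement,2005-06-01,15/08/2005,died,82,640"))
  rec <- read_stay_records(path)
  expect_true(all(rec$invalid))
  expect_length(attr(rec, "issues"), 2)
})

test_that("missing mandatory columns raise a schema error naming them", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,care_group,admission_date", "P1,PF,2005-06-01"),
             path)
  expect_error(read_stay_records(path), "care_type")
})

test_that("tab-delimited input is autodetected", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(paste("patient_id", "care_group", "care_type",
                     "admission_date", "discharge_date", "discharge_reason",
                     "age_at_admission", "weekly_cost", sep = "\t"),
               paste("P1", "PF", "placement", "2005-06-01", "2005-08-15",
                     "died", "82", "640", sep = "\t")), path)
  rec <- read_stay_records(path)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$care_type, "placement")
})

test_that("cleaning applies the window and missingness rules with a full tally", {
  path <- write_records_fixture(c(
    "A1,PF,placement,2005-06-01,2005-08-15,died,82,640",       # keep
    "A2,PF,,2005-06-01,2005-08-15,died,82,640",                # missing type
    "A3,OMH,,2006-06-01,,,75,500",                             # missing type
    "A4,PF,placement,2004-01-01,2005-03-01,home,70,600",       # pre-window
    "A5,PF,placement,2008-06-15,,,88,700",                     # post-window
    "A6,PF,placement,2006-01-01,2006-05-01,,80,600",           # no reason
    "A7,PF,placement,2006-01-01,,,80,600",                     # censored: ok
    "A8,PF,placement,2006-03-01,2006-02-01,died,80,600",       # reversed
    "A9,PF,home_care,2006-01-01,2006-04-01,home,77,300",       # keep
    "A10,Palliative,placement,2007-01-01,2007-02-01,died,69,550"))  # keep
  rec <- read_stay_records(path)
  cleaned <- clean_stay_records(rec, window)
  tally <- attr(cleaned, "exclusions")
  expect_equal(nrow(cleaned) + sum(tally), nrow(rec))
  expect_equal(unname(tally["missing_care_type"]), 2L)
  expect_equal(unname(tally["out_of_window"]), 2L)
  expect_equal(unname(tally["missing_discharge_reason"]), 1L)
  expect_equal(unname(tally["invalid"]), 1L)
  expect_equal(nrow(cleaned), 4)
  expect_true("A7" %in% cleaned$patient_id)  # censored stay kept, no reason
})

test_that("dual-care patients are split into independent records with distinct ids", {
  path <- write_records_fixture(c(
    "D1,PF,placement,2005-06-01,2006-01-01,home,82,640",
    "D1,PF,home_care,2006-02-01,,,82,320",
    "D2,PF,placement,2005-07-01,,,79,600"))
  cleaned <- clean_stay_records(read_stay_records(path), window)
  expect_equal(nrow(cleaned), 3)
  ids <- cleaned$patient_id
  expect_equal(length(unique(ids)), 3)
  expect_setequal(ids[grepl("^D1", ids)],
                  c("D1/placement", "D1/home_care"))
  expect_equal(attr(cleaned, "dual_care_ids"), "D1")
  expect_equal(ids[3], "D2")  # single-care ids untouched
})

test_that("cleaning is idempotent", {
  path <- write_records_fixture(c(
    "D1,PF,placement,2005-06-01,2006-01-01,home,82,640",
    "D1,PF,home_care,2006-02-01,,,82,320",
    "E9,OMH,,2006-06-01,,,75,500"))
  once <- clean_stay_records(read_stay_records(path), window)
  twice <- clean_stay_records(once, window)
  expect_equal(as.data.frame(twice), as.data.frame(once),
               ignore_attr = TRUE)
  expect_equal(sum(attr(twice, "exclusions")), 0L)
})

test_that("observations encode duration, censoring and truncation from dates", {
  path <- write_records_fixture(c(
    "B1,PF,placement,2004-04-01,,,82,640",                # pre-window, open
    "B2,PF,placement,2006-01-01,2006-01-31,died,75,600",  # in-window event
    "B3,PF,placement,2006-02-01,2006-02-01,died,70,580")) # zero-day stay
  cleaned <- clean_stay_records(read_stay_records(path), window)
  obs <- build_observations(cleaned, window)
  expect_equal(obs$truncation[1], 365)
  expect_false(obs$event[1])
  expect_equal(obs$duration[1],
               as.numeric(as.Date("2008-05-31") - as.Date("2004-04-01")))
  expect_equal(obs$duration[2], 30)
  expect_true(obs$event[2])
  expect_equal(obs$truncation[2], 0)
  expect_equal(obs$duration[3], 0.5)  # continuous likelihood needs t > 0
  expect_true(all(obs$duration > obs$truncation))
})

test_that("a projection-origin roster follows the admitted-before, discharged-after rule", {
  origin <- as.Date("2007-05-31")
  path <- write_records_fixture(c(
    "C1,PF,placement,2006-01-01,,,80,600",                # in care at origin
    "C2,PF,placement,2006-01-01,2007-05-30,died,81,610",  # discharged before
    "C3,PF,placement,2007-06-15,,,78,620",                # admitted after
    "C4,PF,placement,2005-05-01,2007-09-01,home,83,630")) # in care at origin
  cleaned <- clean_stay_records(read_stay_records(path), window)
  cohort <- standing_population(cleaned, origin, window = window)
  expect_setequal(cohort$patient_id, c("C1", "C4"))
  expect_equal(cohort$elapsed[cohort$patient_id == "C1"],
               as.numeric(origin - as.Date("2006-01-01")))
  expect_error(standing_population(cleaned, "2010-01-01", window = window),
               "outside")
})

test_that("window filtering does not depend on record order", {
  path <- write_records_fixture(c(
    "A1,PF,placement,2005-06-01,2005-08-15,died,82,640",
    "A4,PF,placement,2004-01-01,2005-03-01,home,70,600",
    "A5,PF,placement,2008-06-15,,,88,700",
    "A9,PF,home_care,2006-01-01,2006-04-01,home,77,300"))
  rec <- read_stay_records(path)
  c1 <- clean_stay_records(rec, window)
  c2 <- clean_stay_records(rec[rev(seq_len(nrow(rec))), ], window)
  expect_setequal(c1$patient_id, c2$patient_id)
  expect_equal(attr(c1, "exclusions"), attr(c2, "exclusions"))
})

test_that("written cleaned records round-trip through the reader", {
  path <- write_records_fixture(c(
    "R1,PF,placement,2005-06-01,2005-08-15,died,82,640.5",
    "R2,PF,home_care,2006-01-10,,,75,410"))
  cleaned <- clean_stay_records(read_stay_records(path), window)
  out <- tempfile(fileext = ".csv")
  tally <- tempfile(fileext = ".json")
  write_stay_records(cleaned, out, tally)
  back <- read_stay_records(out)
  expect_equal(back$patient_id, cleaned$patient_id)
  expect_equal(back$admission_date, cleaned$admission_date)
  expect_equal(back$discharge_date, cleaned$discharge_date)
  expect_equal(back$weekly_cost, cleaned$weekly_cost)
  expect_true(file.exists(tally))
})
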