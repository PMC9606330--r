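test_that("FAERS ASCII join attaches child rows to the case", {
  dir <- withr::local_tempdir()
  paths <- write_faers_fixture(
    dir,
    demo_rows = list(c("1001", "C1", "20200110", "20200105", "70", "MON",
                       "F", "MD", "US")),
    drug_rows = list(c("1001", "1", "PS", "AVASTIN"),
                     c("1001", "2", "C", "METFORMIN")),
    reac_rows = list(c("1001", "Hypertension"),
                     c("1001", "Nausea")),
    outc_rows = list(c("1001", "HO")),
    ther_rows = list(c("1001", "1", "20191201")))
  rs <- read_faers_ascii(paths, quarter = "2020Q1")
  expect_equal(n_reports(rs), 1L)
  expect_equal(nrow(rs$drugs), 2L)
  expect_equal(nrow(rs$reactions), 2L)
  expect_equal(rs$outcomes$outcome, "hospitalization")
  expect_equal(rs$reports$patient_sex, "female")
  expect_equal(rs$reports$reporter_type, "health_professional")
  expect_equal(rs$reports$country, "US")
  # age 70 months converts to years
  expect_equal(rs$reports$patient_age_years, 70 / 12, tolerance = 1e-12)
  # therapy start date joined by drug_seq onto the suspect row only
  expect_equal(rs$drugs$start_date[1], as.Date("2019-12-01"))
  expect_true(is.na(rs$drugs$start_date[2]))
  expect_equal(rs$drugs$role, c("primary_suspect", "concomitant"))
  expect_equal(rs$log$n_cases_in, rs$log$n_reports_out + rs$log$n_rejected)
})

test_that("empty REAC file yields empty reaction lists plus a counter", {
  dir <- withr::local_tempdir()
  paths <- write_faers_fixture(
    dir,
    demo_rows = list(c("1", "C1", "20200110", "", "", "", "M", "", "JP"),
                     c("2", "C2", "20200211", "", "", "", "F", "", "DE")),
    drug_rows = list(c("1", "1", "PS", "SUTENT"),
                     c("2", "1", "PS", "NEXAVAR")),
    reac_rows = list())
  expect_warning(rs <- read_faers_ascii(paths), "no reaction rows")
  expect_equal(nrow(rs$reactions), 0L)
  expect_equal(rs$log$n_empty_reactions, 2L)
})

test_that("missing mandatory column and duplicate header raise file errors", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "DRUG.txt")
  writeLines(c("primaryid$role_cod", "1$PS"), bad)
  demo <- file.path(dir, "DEMO.txt")
  writeLines(c("primaryid$rept_dt", "1$20200101"), demo)
  reac <- file.path(dir, "REAC.txt")
  writeLines(c("primaryid$pt", "1$Nausea"), reac)
  expect_error(read_faers_ascii(list(demo = demo, drug = bad, reac = reac)),
               "drugname")
  dup <- file.path(dir, "DEMO2.txt")
  writeLines(c("primaryid$sex$sex", "1$M$F"), dup)
  expect_error(read_faers_ascii(list(demo = dup, drug = bad, reac = reac)),
               "duplicate header")
})

test_that("age unit conversion covers all accepted codes and bounds", {
  expect_equal(convert_age_years(c(70, 7, 52.1775, 365.25, 8766, 3),
                                 c("MON", "DEC", "WK", "DY", "HR", "YR")),
               c(70 / 12, 70, 1, 1, 1, 3), tolerance = 1e-12)
  # unknown unit or out-of-range value becomes missing
  expect_true(is.na(convert_age_years(40, "FORTNIGHT")))
  expect_true(is.na(convert_age_years(130, "YR")))
  expect_true(is.na(convert_age_years(-1, "YR")))
})

test_that("interchange CSV round-trips generated records exactly", {
  cfg <- sim_config(n_reports = 50, seed = 11, dup_prob = 0.1,
                    version_prob = 0.1)
  rs <- generate_reports(cfg)$reports
  path <- withr::local_tempfile(fileext = ".csv")
  write_interchange_csv(rs, path)
  back <- read_interchange_csv(path)
  # child-table row order is canonical per report, not global: compare sorted
  canon <- function(df) {
    df <- df[do.call(order, df), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  for (tab in c("reports", "drugs", "reactions", "outcomes")) {
    expect_identical(canon(back[[tab]]), canon(rs[[tab]]),
                     label = paste("table", tab))
  }
})

test_that("interchange reader flags malformed dates and maps sex tokens", {
  df <- data.frame(
    uid = c("A", "B"), report_id = c("A", "B"), case_id = c("A", "B"),
    receipt_date = c("2020-01-01", "2020-01-02"),
    patient_age_years = c("55", ""),
    patient_sex = c("M", "female"),
    reporter_type = c("health_professional", "nonsense"),
    country = c("US", ""),
    event_date = c("2020-02-30", "2020-03-01"),
    report_year = c("2020", "2020"),
    drugs = c("AVASTIN~primary_suspect~2020-01-01", ""),
    ingredients = c("bevacizumab", ""), drug_classes = c("anti_VEGF_mAb", ""),
    reactions = c("Hypertension;Nausea", "Rash"),
    outcomes = c("death", ""), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  rs <- read_interchange_csv(path)
  expect_true(is.na(rs$reports$event_date[1]))     # 2020-02-30 is invalid
  expect_equal(rs$log$n_bad_dates, 1L)
  expect_equal(rs$reports$patient_sex, c("male", "female"))
  expect_equal(rs$reports$reporter_type[2], "unknown")
  expect_equal(rs$reports$country[2], "unknown")
  expect_equal(nrow(rs$reactions), 3L)
})
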