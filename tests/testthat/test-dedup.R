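test_that("keep_last_version retains the latest receipt per report id", {
  r <- rbind(mk_reports("A", receipt = "2020-01-01"),
             mk_reports("A", receipt = "2020-06-01"),
             mk_reports("B", receipt = "2020-03-01"))
  r$uid <- c("A", "A#v1", "B")
  rs <- report_set(r)
  out <- keep_last_version(rs)
  expect_equal(out$reports$report_id, c("A", "B"))
  expect_equal(out$reports$receipt_date[1], as.Date("2020-06-01"))
  expect_equal(out$log$n_versions_removed, 1L)
})

test_that("partial receipt dates compare by their earliest consistent date", {
  # 2020-01 expands to 2020-01-01 < 2020-01-15
  r <- rbind(mk_reports("A", receipt = "2020-01"),
             mk_reports("A", receipt = "2020-01-15"))
  r$uid <- c("A#old", "A#new")
  out <- keep_last_version(report_set(r))
  expect_equal(out$reports$uid, "A#new")
})

test_that("single report passes through keep_last_version unchanged", {
  rs <- report_set(mk_reports("X", receipt = "2019-05-05"))
  out <- keep_last_version(rs)
  expect_equal(out$reports$uid, "X")
})

test_that("six-field duplicates collapse to the smallest report id", {
  # two reports differing only in report_id -> one survivor
  r <- rbind(mk_reports("B2", receipt = "2020-02-02", sex = "male", age = 60),
             mk_reports("A1", receipt = "2020-02-02", sex = "male", age = 60))
  d <- rbind(mk_drugs("B2", "SUTENT"), mk_drugs("A1", "SUTENT"))
  p <- rbind(mk_reactions("B2", "Nausea"), mk_reactions("A1", "Nausea"))
  out <- drop_field_duplicates(report_set(r, d, p))
  expect_equal(out$reports$report_id, "A1")
  expect_equal(out$log$n_duplicates_removed, 1L)
})

test_that("an extra reaction PT breaks the duplicate key", {
  r <- rbind(mk_reports("A", receipt = "2020-02-02"),
             mk_reports("B", receipt = "2020-02-02"))
  p <- rbind(mk_reactions("A", c("Nausea", "Rash")),
             mk_reactions("B", "Nausea"))
  out <- drop_field_duplicates(report_set(r, reactions = p))
  expect_equal(sort(out$reports$report_id), c("A", "B"))
})

test_that("planted duplicate pairs are found among distinct reports", {
  # 6 reports, 2 planted duplicate pairs -> 4 survivors
  r <- rbind(mk_reports("R1", receipt = "2020-01-01", sex = "male", age = 50),
             mk_reports("R2", receipt = "2020-01-01", sex = "male", age = 50),
             mk_reports("R3", receipt = "2020-02-01", sex = "female", age = 61),
             mk_reports("R4", receipt = "2020-02-01", sex = "female", age = 61),
             mk_reports("R5", receipt = "2020-03-01", sex = "male", age = 50),
             mk_reports("R6", receipt = "2020-01-01", sex = "male", age = 70))
  d <- rbind(mk_drugs(c("R1", "R2"), "AVASTIN"),
             mk_drugs(c("R3", "R4"), "SUTENT"),
             mk_drugs(c("R5", "R6"), "AVASTIN"))
  p <- mk_reactions(paste0("R", 1:6),
                    c("Nausea", "Nausea", "Rash", "Rash", "Nausea", "Nausea"))
  out <- drop_field_duplicates(report_set(r, d, p))
  expect_equal(out$reports$report_id, c("R1", "R3", "R5", "R6"))
})

test_that("missing key fields compare equal to each other", {
  r <- rbind(mk_reports("A", receipt = "2020-02-02", age = NA),
             mk_reports("B", receipt = "2020-02-02", age = NA))
  out <- drop_field_duplicates(report_set(r))
  expect_equal(out$reports$report_id, "A")
})

test_that("dedup is idempotent and survivors are an unmutated subset", {
  for (seed in c(3, 17, 101)) {
    g <- generate_reports(sim_config(n_reports = 200, seed = seed,
                                     dup_prob = 0.15, version_prob = 0.15))
    once <- dedup_reports(g$reports)
    twice <- dedup_reports(once)
    expect_equal(twice$reports, once$reports)
    expect_equal(twice$drugs, once$drugs)
    # survivors are rows of the input, fields untouched
    idx <- match(once$reports$uid, g$reports$reports$uid)
    expect_false(anyNA(idx))
    cmp <- g$reports$reports[idx, , drop = FALSE]
    rownames(cmp) <- NULL
    expect_identical(once$reports, cmp)
  }
})

test_that("removing an unrelated report never changes other survivors", {
  g <- generate_reports(sim_config(n_reports = 120, seed = 5,
                                   dup_prob = 0.2, version_prob = 0))
  rs <- g$reports
  out_full <- dedup_reports(rs)
  # drop one non-duplicate report from the input entirely
  dup_uids <- c(g$truth$duplicate_pairs$original_uid,
                g$truth$duplicate_pairs$duplicate_uid)
  lone <- setdiff(rs$reports$uid, dup_uids)[1]
  rs_small <- subset_reports(rs, setdiff(rs$reports$uid, lone))
  out_small <- dedup_reports(rs_small)
  expect_setequal(out_small$reports$uid, setdiff(out_full$reports$uid, lone))
})
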