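# Oracle values in this file were computed independently (closed forms
# evaluated by hand / exhaustive enumeration) before the implementation ran.

test_that("the toy six-report table classifies into a=2,b=1,c=1,d=2", {
  rs <- mk_mapped_rs(
    drug_sets = list("X", "X", "W", "W", c("X", "W"), "W"),
    pt_sets = list("Y", "Z", "Y", "Z", c("Y", "Z"), "Z"))
  tab <- build_contingency(rs, "X", pt_predicate("Y"))
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(2, 1, 1, 2))
  expect_equal(tab$n_drug, 3); expect_equal(tab$n_event, 3)
  expect_equal(tab$n_total, 6)
  expect_equal(tab$n_expected, 1.5)
})

test_that("degenerate target specs land in the forced cells", {
  rs <- mk_mapped_rs(drug_sets = list("W", "W", "V"),
                     pt_sets = list("Y", "Z", "Y"))
  tab <- build_contingency(rs, "X", pt_predicate("Y"))
  expect_equal(c(tab$a, tab$b), c(0, 0))
  tab2 <- build_contingency(rs, "W", any_event_predicate())
  expect_equal(tab2$b, 0)
  expect_equal(tab2$c, 1)  # the single report without W
  expect_error(build_contingency(report_set(mk_reports(character(0))),
                                 "X", pt_predicate("Y")),
               "empty")
})

test_that("suspect-only role filter excludes concomitant exposure", {
  rs <- mk_mapped_rs(drug_sets = list("X", "X"), pt_sets = list("Y", "Y"),
                     roles = "concomitant")
  expect_equal(build_contingency(rs, "X", pt_predicate("Y"))$a, 0)
  expect_equal(build_contingency(rs, "X", pt_predicate("Y"),
                                 role = "all")$a, 2)
})

test_that("repeated drugs or PTs within one report count once", {
  rs <- mk_mapped_rs(drug_sets = list(c("X", "X")),
                     pt_sets = list(c("Y", "Y", "Y")))
  tab <- build_contingency(rs, "X", pt_predicate("Y"))
  expect_equal(c(tab$a, tab$n_total), c(1, 1))
})

test_that("shrunk ratio matches hand-evaluated closed forms", {
  tab <- contingency_table(3, 7, 30, 60)  # n_expected = 10*33/100 = 3.3
  expect_equal(shrunk_ratio(tab), 3.5 / 3.8, tolerance = 1e-12)
  # observed equal to expected gives exactly 1
  tab2 <- contingency_table(10, 10, 10, 10)
  expect_equal(shrunk_ratio(tab2), 1)
  # a = 0 stays defined through the shrinkage constant
  tab3 <- contingency_table(0, 0, 0, 5)
  expect_equal(shrunk_ratio(tab3), 1)  # 0.5/0.5
  expect_error(contingency_table(0, 0, 0, 0), "empty")
})

test_that("ic_stats reproduces the exact closed-form interval", {
  out <- ic_stats(3, 3.5 / 3.8)
  expect_equal(unname(out["ic"]), -0.1186444965, tolerance = 1e-9)
  expect_equal(unname(out["ic_low"]), -2.188010112, tolerance = 1e-8)
  expect_equal(unname(out["ic_high"]), 1.08784911, tolerance = 1e-8)
})

test_that("ic_stats reproduces printed per-agent statistics at 2 dp", {
  # treating each printed shrunk ROR as exact at the printed N
  rows <- list(
    list(n = 71, ror = 2.60, ic = 1.38, lo = 0.98, hi = 1.66),
    list(n = 104, ror = 1.42, ic = 0.51, lo = 0.18, hi = 0.74))
  for (r in rows) {
    out <- ic_stats(r$n, r$ror)
    expect_equal(round_half_away(unname(out["ic"]), 2), r$ic)
    expect_equal(round_half_away(unname(out["ic_low"]), 2), r$lo)
    expect_equal(round_half_away(unname(out["ic_high"]), 2), r$hi)
  }
})

test_that("ror_ci computes the classical log-scale interval", {
  tab <- contingency_table(3, 7, 30, 60)
  ci <- ror_ci(tab, point = "classical")
  expect_equal(ci$point, 180 / 210, tolerance = 1e-12)
  expect_equal(ci$low, 0.20681826, tolerance = 1e-7)
  expect_equal(ci$high, 3.552364658, tolerance = 1e-7)
  expect_true(ci$defined)
  # symmetric table: classical point (a/b)^2, CI symmetric in log space
  tab_s <- contingency_table(8, 2, 2, 8)
  ci_s <- ror_ci(tab_s, point = "classical")
  expect_equal(ci_s$point, (8 / 2)^2)
  expect_equal(log(ci_s$high) - log(ci_s$point),
               log(ci_s$point) - log(ci_s$low), tolerance = 1e-12)
})

test_that("a zero cell leaves the ROR bounds undefined, never substituted", {
  tab <- contingency_table(0, 10, 5, 100)
  ci <- ror_ci(tab)
  expect_false(ci$defined)
  expect_true(is.na(ci$low) && is.na(ci$high))
  # and the signal rule treats the undefined clause as unsatisfied
  est <- signal_estimate(tab)
  expect_false(est$is_signal)
})

test_that("the signal rule combines min reports with the OR of bounds", {
  cfg <- shrinkage_config()
  # published non-signal row: N=26, ROR025=0.89, IC025=-0.24
  expect_false(detect_signal(list(n_observed = 26, ror_ci_low = 0.89,
                                  ic_low = -0.24), cfg))
  # two reports never signal regardless of ratio
  expect_false(detect_signal(list(n_observed = 2, ror_ci_low = 50,
                                  ic_low = 5), cfg))
  # either clause suffices
  expect_true(detect_signal(list(n_observed = 1000, ror_ci_low = 0.99,
                                 ic_low = 0.01), cfg))
  expect_true(detect_signal(list(n_observed = 1000, ror_ci_low = 1.01,
                                 ic_low = -0.01), cfg))
  expect_false(detect_signal(list(n_observed = 1000, ror_ci_low = NA,
                                  ic_low = -0.01), cfg))
})

test_that("ic equals log2 of the shrunk ratio on every estimate row", {
  set.seed(8)
  for (i in 1:50) {
    cells <- stats::rpois(4, lambda = c(5, 50, 50, 500))
    tab <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    est <- signal_estimate(tab)
    expect_identical(est$ic, log2(est$ror_shrunk))
  }
})

test_that("shrinkage pulls the ratio toward 1", {
  set.seed(9)
  for (i in 1:100) {
    a <- stats::rpois(1, 4) + 1
    tab <- contingency_table(a, stats::rpois(1, 30) + 1,
                             stats::rpois(1, 30) + 1,
                             stats::rpois(1, 300) + 1)
    raw <- tab$a / tab$n_expected
    expect_lte(abs(log(shrunk_ratio(tab))), abs(log(raw)) + 1e-12)
  }
})

test_that("IC bounds bracket IC and their widths shrink with N", {
  ratio <- 2
  ns <- c(0, 1, 2, 3, 5, 10, 30, 100, 1000, 1e5)
  lows <- highs <- numeric(length(ns))
  for (i in seq_along(ns)) {
    out <- ic_stats(ns[i], ratio)
    expect_lt(out["ic_low"], out["ic"])
    expect_gt(out["ic_high"], out["ic"])
    lows[i] <- out["ic"] - out["ic_low"]
    highs[i] <- out["ic_high"] - out["ic"]
  }
  expect_true(all(diff(lows) < 0))
  expect_true(all(diff(highs) < 0))
})

test_that("build_contingency agrees with the brute-force classifier", {
  set.seed(123)
  pool_drugs <- c("X", "W", "V", NA)
  pool_pts <- c("P1", "P2", "P3", "P4")
  for (rep in 1:60) {
    n <- sample(1:20, 1)
    drug_sets <- replicate(n, sample(pool_drugs[!is.na(pool_drugs)],
                                     sample(0:2, 1)), simplify = FALSE)
    pt_sets <- replicate(n, sample(pool_pts, sample(1:3, 1)),
                         simplify = FALSE)
    roles <- sample(c("primary_suspect", "concomitant"), 1)
    rs <- mk_mapped_rs(drug_sets, pt_sets, roles = roles)
    for (role in c("suspect", "all")) {
      tab <- build_contingency(rs, "X", pt_predicate(c("P1", "P2")),
                               role = role)
      oracle <- brute_contingency(rs, "X",
                                  function(p) p %in% c("P1", "P2"),
                                  role = role)
      expect_equal(c(a = tab$a, b = tab$b, c = tab$c, d = tab$d), oracle)
    }
  }
})

test_that("run_panel matches single-cell computation and aggregates classes", {
  arch <- test_archive()
  defs <- test_smq_defs()
  g <- generate_reports(sim_config(
    n_reports = 3000, seed = 21,
    planted_lambda = data.frame(ingredient = "sunitinib",
                                pt = "Hypertension", lambda = 6)))
  mapped <- map_reactions(map_drugs(dedup_reports(g$reports), arch), defs)
  panel <- run_panel(mapped, list(
    list(name = "sunitinib-htn", drugs = "sunitinib",
         events = list(smq = 20000147)),
    list(name = "tki-any", drugs = "class:TKI", events = "any")),
    arch, defs)
  expect_equal(nrow(panel), 2L)
  direct <- signal_estimate(build_contingency(
    mapped, "sunitinib", smq_predicate(20000147)))
  expect_equal(panel$ror_shrunk[1], direct$ror_shrunk)
  expect_equal(panel$ic_low[1], direct$ic_low)
  # class spec aggregates all TKI ingredients into one exposure set
  tki_tab <- build_contingency(mapped, class_members(arch, "TKI"),
                               any_event_predicate())
  expect_equal(panel$n_observed[2], tki_tab$a)
  expect_error(run_panel(mapped, list(
    list(name = "bad", drugs = "nosuchdrug", events = "any")), arch, defs),
    "nosuchdrug")
  expect_error(run_panel(mapped, list(
    list(name = "bad", drugs = "sunitinib", events = list(smq = 99))),
    arch, defs), "99")
})

test_that("the per-PT spectrum emits every observed PT with a signal flag", {
  arch <- test_archive()
  g <- generate_reports(sim_config(
    n_reports = 4000, seed = 31,
    planted_lambda = data.frame(ingredient = "bevacizumab",
                                pt = "Hypertension", lambda = 8)))
  mapped <- map_drugs(dedup_reports(g$reports), arch)
  spec <- pt_spectrum(mapped, "bevacizumab", arch)
  expect_true(all(spec$n_observed >= 1))
  expect_true("Hypertension" %in% spec$pt)
  # the planted pair is the strongest signal
  expect_true(spec$is_signal[spec$pt == "Hypertension"])
  expect_equal(spec$pt[which.max(spec$ic)], "Hypertension")
})
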