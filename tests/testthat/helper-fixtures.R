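# Fixture builders and independent oracles shared by the test files.
# Everything is generated in code; no binary fixtures.

# minimal valid reports table; fields overridable per column
mk_reports <- function(ids, receipt = "2020-01-15", sex = "unknown",
                       age = NA_real_, country = "unknown",
                       event = NA_character_) {
  n <- length(ids)
  rc <- parse_partial_date(rep_len(receipt, n))
  ev <- parse_partial_date(rep_len(ifelse(is.na(event), "", event), n))
  data.frame(
    uid = ids, report_id = ids, case_id = ids,
    receipt_date = rc$date, receipt_precision = rc$precision,
    patient_age_years = rep_len(age, n),
    patient_sex = rep_len(sex, n),
    reporter_type = rep_len("unknown", n),
    country = rep_len(country, n),
    event_date = ev$date, event_precision = ev$precision,
    report_year = as.integer(format(rc$date, "%Y")),
    stringsAsFactors = FALSE)
}

mk_drugs <- function(uid, name, role = "primary_suspect",
                     start = NA_character_, ingredient = NA_character_,
                     drug_class = NA_character_) {
  n <- max(length(uid), length(name))
  sd <- parse_partial_date(rep_len(ifelse(is.na(start), "", start), n))
  data.frame(uid = rep_len(uid, n), verbatim_name = rep_len(name, n),
             role = rep_len(role, n),
             start_date = sd$date, start_precision = sd$precision,
             ingredient = rep_len(ingredient, n),
             drug_class = rep_len(drug_class, n),
             stringsAsFactors = FALSE)
}

mk_reactions <- function(uid, pt) {
  n <- max(length(uid), length(pt))
  data.frame(uid = rep_len(uid, n), pt = rep_len(pt, n),
             stringsAsFactors = FALSE)
}

# a report set where each element of `drug_sets` / `pt_sets` is the vector
# of (already mapped) ingredients / reaction PTs of one report
mk_mapped_rs <- function(drug_sets, pt_sets, roles = "primary_suspect") {
  n <- length(drug_sets)
  ids <- sprintf("T%03d", seq_len(n))
  drugs <- do.call(rbind, lapply(seq_len(n), function(i) {
    ds <- drug_sets[[i]]
    if (!length(ds)) return(NULL)
    mk_drugs(ids[i], name = toupper(ds), role = rep_len(roles, length(ds)),
             ingredient = ds, drug_class = "TKI")
  }))
  reactions <- do.call(rbind, lapply(seq_len(n), function(i) {
    ps <- pt_sets[[i]]
    if (!length(ps)) return(NULL)
    mk_reactions(ids[i], ps)
  }))
  report_set(mk_reports(ids), drugs, reactions)
}

# independent brute-force per-report 2x2 classifier: plain loops, no reuse
# of the package's indicator logic
brute_contingency <- function(x, target_drugs, match_pt, role = "suspect") {
  a <- b <- cc <- d <- 0L
  for (uid in x$reports$uid) {
    dr <- x$drugs[x$drugs$uid == uid, , drop = FALSE]
    if (role == "suspect")
      dr <- dr[dr$role %in% c("primary_suspect", "secondary_suspect"), ,
               drop = FALSE]
    exposed <- FALSE
    for (k in seq_len(nrow(dr)))
      if (!is.na(dr$ingredient[k]) && dr$ingredient[k] %in% target_drugs)
        exposed <- TRUE
    pts <- x$reactions$pt[x$reactions$uid == uid]
    event <- FALSE
    for (p in pts) if (match_pt(p)) event <- TRUE
    if (exposed && event) a <- a + 1L
    else if (exposed) b <- b + 1L
    else if (event) cc <- cc + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

# write a small FAERS-style '$'-delimited fixture; returns the path list
write_faers_fixture <- function(dir,
                                demo_rows, drug_rows, reac_rows,
                                outc_rows = NULL, ther_rows = NULL) {
  w <- function(name, header, rows) {
    path <- file.path(dir, paste0(name, ".txt"))
    writeLines(c(paste(header, collapse = "$"),
                 vapply(rows, paste, character(1), collapse = "$")), path)
    path
  }
  paths <- list(
    demo = w("DEMO", c("primaryid", "caseid", "rept_dt", "event_dt", "age",
                       "age_cod", "sex", "occp_cod", "reporter_country"),
             demo_rows),
    drug = w("DRUG", c("primaryid", "drug_seq", "role_cod", "drugname"),
             drug_rows),
    reac = w("REAC", c("primaryid", "pt"), reac_rows))
  if (!is.null(outc_rows))
    paths$outc <- w("OUTC", c("primaryid", "outc_cod"), outc_rows)
  if (!is.null(ther_rows))
    paths$ther <- w("THER", c("primaryid", "dsg_drug_seq", "start_dt"),
                    ther_rows)
  paths
}

test_archive <- function() {
  read_drug_archive(system.file("extdata", "drug_archive.csv",
                                package = "pvsignal"))
}

test_smq_defs <- function() {
  read_smq_definitions(system.file("extdata", "smq_members_synthetic.csv",
                                   package = "pvsignal"))
}
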