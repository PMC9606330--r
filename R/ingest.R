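# Ingest: FAERS-style '$'-delimited quarterly tables and a normalized CSV
# interchange. Field normalization is strict and logged: nothing is silently
# dropped without a counter.

.age_divisors <- c(YR = 1, DEC = 0.1, MON = 12, WK = 52.1775, DY = 365.25,
                   HR = 8766)

#' Convert reported patient ages to years
#'
#' FAERS records age with a unit code. Accepted codes: YR (years),
#' DEC (decades), MON (months), WK (weeks), DY (days), HR (hours).
#' Unknown codes or values outside [0, 120] years after conversion are set
#' missing (the caller counts them).
#'
#' @param value numeric vector of reported ages
#' @param unit character vector of unit codes (case-insensitive)
#' @return numeric vector of ages in years, NA where unconvertible
#' @examples
#' convert_age_years(70, "MON")  # ~5.83
#' @export
convert_age_years <- function(value, unit) {
  value <- suppressWarnings(as.numeric(value))
  unit <- toupper(trimws(as.character(unit)))
  div <- .age_divisors[unit]
  years <- value / unname(div)
  years[is.na(div)] <- NA_real_
  years[!is.na(years) & (years < 0 | years > 120)] <- NA_real_
  years
}

.read_dollar <- function(path) {
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  enc_fallback <- FALSE
  if (any(!validUTF8(raw))) {  # latin-1 fallback, logged by the caller
    raw <- readLines(path, warn = FALSE, encoding = "latin1")
    raw <- iconv(raw, from = "latin1", to = "UTF-8")
    enc_fallback <- TRUE
  }
  if (!length(raw)) stop("empty file: ", path)
  parts <- strsplit(raw, "$", fixed = TRUE)
  header <- tolower(trimws(parts[[1]]))
  if (anyDuplicated(header)) stop("duplicate header column in ", path)
  ncols <- length(header)
  body <- parts[-1]
  if (length(body)) {
    mat <- do.call(rbind, lapply(body, function(p) { length(p) <- ncols; p }))
  } else {
    mat <- matrix(character(), 0, ncols)
  }
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header
  df[] <- lapply(df, function(col) { col[is.na(col)] <- ""; trimws(col) })
  attr(df, "enc_fallback") <- enc_fallback
  df
}

.require_cols <- function(df, cols, role) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("FAERS ", role, " file missing mandatory column(s): ",
         paste(miss, collapse = ", "))
}

.map_sex <- function(x) {
  x <- toupper(trimws(x))
  out <- rep("unknown", length(x))
  out[x %in% c("M", "MALE", "1")] <- "male"
  out[x %in% c("F", "FEMALE", "2")] <- "female"
  out
}

.map_reporter <- function(x) {
  x <- toupper(trimws(x))
  out <- rep("unknown", length(x))
  out[x %in% c("MD", "PH", "OT", "HP", "RN")] <- "health_professional"
  out[x %in% c("CN", "LW")] <- "non_health_professional"
  out
}

.map_role <- function(x) {
  x <- toupper(trimws(x))
  out <- rep("unknown", length(x))
  out[x == "PS"] <- "primary_suspect"
  out[x == "SS"] <- "secondary_suspect"
  out[x == "C"] <- "concomitant"
  out[x == "I"] <- "interacting"
  out
}

.map_outcome <- function(x) {
  codes <- c(DE = "death", LT = "life_threatening", HO = "hospitalization",
             DS = "disability", CA = "congenital_anomaly",
             OT = "other_serious")
  unname(codes[toupper(trimws(x))])
}

#' Read FAERS-style quarterly ASCII tables
#'
#' Reads the '$'-delimited public-dialect files for one quarter and joins
#' the child tables (DRUG, REAC, OUTC, THER) onto the DEMO case rows by the
#' primary id. One report row per DEMO row; child rows whose primary id
#' cannot be linked, and field values that fail normalization, are counted
#' in the returned log, never silently discarded.
#'
#' The primary id (unique per case version in the public dialect) becomes
#' the row key \code{uid}; the case id, which groups versions of one case,
#' becomes \code{report_id} so that \code{\link{keep_last_version}} retains
#' only the latest version per case. When no case id column is present the
#' primary id serves as both.
#'
#' @param paths named character vector or list with elements \code{demo},
#'   \code{drug}, \code{reac}, and optionally \code{outc}, \code{ther}.
#' @param quarter optional label (e.g. \code{"2020Q1"}) recorded in the log.
#' @return a \code{\link{report_set}}; its \code{log} holds counters:
#'   \code{n_cases_in}, \code{n_reports_out}, \code{n_rejected},
#'   \code{n_age_invalid}, \code{n_bad_dates}, \code{n_orphan_child_rows},
#'   \code{n_empty_reactions}, \code{n_latin1_files}.
#' @export
read_faers_ascii <- function(paths, quarter = NULL) {
  paths <- as.list(paths)
  for (p in c("demo", "drug", "reac"))
    if (is.null(paths[[p]])) stop("paths must name a '", p, "' file")
  for (p in unlist(paths)) if (!file.exists(p)) stop("file not found: ", p)

  demo <- .read_dollar(paths$demo)
  .require_cols(demo, "primaryid", "DEMO")
  drug <- .read_dollar(paths$drug)
  .require_cols(drug, c("primaryid", "drugname"), "DRUG")
  reac <- .read_dollar(paths$reac)
  .require_cols(reac, c("primaryid", "pt"), "REAC")
  outc <- if (!is.null(paths$outc)) .read_dollar(paths$outc) else NULL
  ther <- if (!is.null(paths$ther)) .read_dollar(paths$ther) else NULL
  n_latin1 <- sum(vapply(list(demo, drug, reac, outc, ther), function(d)
    isTRUE(attr(d, "enc_fallback")), logical(1)))

  n_cases_in <- nrow(demo)
  rejected <- !nzchar(demo$primaryid) | duplicated(demo$primaryid)
  n_rejected <- sum(rejected)
  demo <- demo[!rejected, , drop = FALSE]

  getcol <- function(df, col) if (col %in% names(df)) df[[col]] else
    rep("", nrow(df))

  rcpt <- parse_partial_date(getcol(demo, "rept_dt"))
  evt <- parse_partial_date(getcol(demo, "event_dt"))
  n_bad_dates <- sum(nzchar(getcol(demo, "rept_dt")) & rcpt$precision == "none") +
    sum(nzchar(getcol(demo, "event_dt")) & evt$precision == "none")

  age_raw <- getcol(demo, "age")
  age <- convert_age_years(age_raw, getcol(demo, "age_cod"))
  n_age_invalid <- sum(nzchar(age_raw) & is.na(age))

  caseid <- getcol(demo, "caseid")
  reports <- data.frame(
    uid = demo$primaryid,
    report_id = ifelse(nzchar(caseid), caseid, demo$primaryid),
    case_id = ifelse(nzchar(caseid), caseid, demo$primaryid),
    receipt_date = rcpt$date,
    receipt_precision = rcpt$precision,
    patient_age_years = age,
    patient_sex = .map_sex(getcol(demo, "sex")),
    reporter_type = .map_reporter(getcol(demo, "occp_cod")),
    country = {
      cc <- toupper(getcol(demo, "reporter_country"))
      ifelse(nzchar(cc), cc, "unknown")
    },
    event_date = evt$date,
    event_precision = evt$precision,
    report_year = as.integer(format(rcpt$date, "%Y")),
    stringsAsFactors = FALSE)

  known <- reports$uid
  n_orphan <- 0L

  drug <- drug[nzchar(drug$drugname), , drop = FALSE]
  orphan_d <- !(drug$primaryid %in% known)
  n_orphan <- n_orphan + sum(orphan_d)
  drug <- drug[!orphan_d, , drop = FALSE]

  # therapy start dates join by (primaryid, drug_seq) when both present
  start_tok <- rep("", nrow(drug))
  if (!is.null(ther) && nrow(ther) &&
      all(c("primaryid", "start_dt") %in% names(ther))) {
    if ("drug_seq" %in% names(drug) && "dsg_drug_seq" %in% names(ther)) {
      idx <- match(paste(drug$primaryid, drug$drug_seq, sep = "\r"),
                   paste(ther$primaryid, ther$dsg_drug_seq, sep = "\r"))
    } else {
      idx <- match(drug$primaryid, ther$primaryid)
    }
    start_tok <- ifelse(is.na(idx), "", ther$start_dt[idx])
  }
  sd <- parse_partial_date(start_tok)
  n_bad_dates <- n_bad_dates + sum(nzchar(start_tok) & sd$precision == "none")

  drugs <- data.frame(
    uid = drug$primaryid,
    verbatim_name = drug$drugname,
    role = .map_role(getcol(drug, "role_cod")),
    start_date = sd$date,
    start_precision = sd$precision,
    ingredient = NA_character_,
    drug_class = NA_character_,
    stringsAsFactors = FALSE)

  reac <- reac[nzchar(reac$pt), , drop = FALSE]
  orphan_r <- !(reac$primaryid %in% known)
  n_orphan <- n_orphan + sum(orphan_r)
  reac <- reac[!orphan_r, , drop = FALSE]
  reactions <- data.frame(uid = reac$primaryid, pt = reac$pt,
                          stringsAsFactors = FALSE)

  outcomes <- NULL
  if (!is.null(outc) && nrow(outc) &&
      all(c("primaryid", "outc_cod") %in% names(outc))) {
    mapped <- .map_outcome(outc$outc_cod)
    n_orphan <- n_orphan + sum(!(outc$primaryid %in% known))
    keep <- !is.na(mapped) & (outc$primaryid %in% known)
    outcomes <- unique(data.frame(uid = outc$primaryid[keep],
                                  outcome = mapped[keep],
                                  stringsAsFactors = FALSE))
  }

  n_empty_reactions <- sum(!(reports$uid %in% reactions$uid))
  if (n_empty_reactions > 0)
    warning(n_empty_reactions, " report(s) have no reaction rows")

  report_set(reports, drugs, reactions, outcomes, log = list(
    quarter = quarter,
    n_cases_in = n_cases_in,
    n_reports_out = nrow(reports),
    n_rejected = n_rejected,
    n_age_invalid = n_age_invalid,
    n_bad_dates = n_bad_dates,
    n_orphan_child_rows = n_orphan,
    n_empty_reactions = n_empty_reactions,
    n_latin1_files = n_latin1))
}

# interchange serialization of one drug entry: name~role~start_date,
# entries ';'-joined. Verbatim names containing '~' or ';' are rejected at
# write time (they do not occur in normalized extracts).
.ser_drugs <- function(d) {
  if (!nrow(d)) return("")
  if (any(grepl("[~;]", d$verbatim_name)))
    stop("verbatim drug name contains interchange delimiter")
  paste(d$verbatim_name, d$role,
        format_partial_date(d$start_date, d$start_precision),
        sep = "~", collapse = ";")
}

#' Write the normalized interchange CSV
#'
#' Single-table RFC-4180 CSV, one row per report version; list-valued fields
#' are ';'-joined (drug entries serialized as \code{name~role~start_date};
#' parallel \code{ingredients}/\code{drug_classes} columns carry mapping
#' results). Dates are ISO-8601 truncated to their recorded precision.
#' Complete records round-trip bit-exactly through
#' \code{\link{read_interchange_csv}}.
#'
#' @param x report_set
#' @param path output file
#' @return invisibly \code{path}
#' @export
write_interchange_csv <- function(x, path) {
  validate_report_set(x)
  r <- x$reports
  fkey <- function(child) factor(child$uid, levels = r$uid)
  d_split <- split(x$drugs, fkey(x$drugs))
  re_split <- split(x$reactions$pt, fkey(x$reactions))
  o_split <- split(x$outcomes$outcome, fkey(x$outcomes))
  df <- data.frame(
    uid = r$uid,
    report_id = r$report_id,
    case_id = r$case_id,
    receipt_date = format_partial_date(r$receipt_date, r$receipt_precision),
    patient_age_years = r$patient_age_years,
    patient_sex = r$patient_sex,
    reporter_type = r$reporter_type,
    country = r$country,
    event_date = format_partial_date(r$event_date, r$event_precision),
    report_year = r$report_year,
    drugs = vapply(d_split, .ser_drugs, character(1)),
    ingredients = vapply(d_split, function(d)
      paste(ifelse(is.na(d$ingredient), "", d$ingredient), collapse = ";"),
      character(1)),
    drug_classes = vapply(d_split, function(d)
      paste(ifelse(is.na(d$drug_class), "", d$drug_class), collapse = ";"),
      character(1)),
    reactions = vapply(re_split, paste, character(1), collapse = ";"),
    outcomes = vapply(o_split, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read the normalized interchange CSV
#'
#' Inverse of \code{\link{write_interchange_csv}}. Malformed date tokens set
#' the field missing and increment the \code{n_bad_dates} counter in the
#' returned log; unknown enum tokens normalize to \code{"unknown"}.
#'
#' @param path CSV file written by \code{write_interchange_csv}
#' @return report_set
#' @export
read_interchange_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  n_bad_dates <- 0L
  pd <- function(tok) {
    out <- parse_partial_date(tok)
    n_bad_dates <<- n_bad_dates + sum(nzchar(tok) & out$precision == "none")
    out
  }
  rcpt <- pd(df$receipt_date)
  evt <- pd(df$event_date)
  reports <- data.frame(
    uid = df$uid,
    report_id = df$report_id,
    case_id = df$case_id,
    receipt_date = rcpt$date,
    receipt_precision = rcpt$precision,
    patient_age_years = suppressWarnings(as.numeric(df$patient_age_years)),
    patient_sex = .map_sex_token(df$patient_sex),
    reporter_type = ifelse(df$reporter_type %in% .reporter_levels,
                           df$reporter_type, "unknown"),
    country = ifelse(nzchar(df$country), df$country, "unknown"),
    event_date = evt$date,
    event_precision = evt$precision,
    report_year = suppressWarnings(as.integer(df$report_year)),
    stringsAsFactors = FALSE)

  drows <- list(); rrows <- list(); orows <- list()
  for (i in seq_len(nrow(df))) {
    id <- df$uid[i]
    if (nzchar(df$drugs[i])) {
      ent <- strsplit(df$drugs[i], ";", fixed = TRUE)[[1]]
      f <- do.call(rbind, lapply(strsplit(ent, "~", fixed = TRUE),
                                 function(p) { length(p) <- 3; p }))
      f[is.na(f)] <- ""
      sd <- pd(f[, 3])
      splitpad <- function(tok, n) {
        v <- if (nzchar(tok)) strsplit(tok, ";", fixed = TRUE)[[1]] else
          character(0)
        length(v) <- n
        v[is.na(v)] <- ""
        v
      }
      ing <- splitpad(df$ingredients[i], nrow(f))
      cls <- splitpad(df$drug_classes[i], nrow(f))
      drows[[i]] <- data.frame(
        uid = id, verbatim_name = f[, 1],
        role = ifelse(f[, 2] %in% .role_levels, f[, 2], "unknown"),
        start_date = sd$date, start_precision = sd$precision,
        ingredient = ifelse(nzchar(ing), ing, NA_character_),
        drug_class = ifelse(nzchar(cls), cls, NA_character_),
        stringsAsFactors = FALSE)
    }
    if (nzchar(df$reactions[i]))
      rrows[[i]] <- data.frame(
        uid = id,
        pt = strsplit(df$reactions[i], ";", fixed = TRUE)[[1]],
        stringsAsFactors = FALSE)
    if (nzchar(df$outcomes[i])) {
      oc <- strsplit(df$outcomes[i], ";", fixed = TRUE)[[1]]
      orows[[i]] <- data.frame(uid = id,
                               outcome = oc[oc %in% .outcome_levels],
                               stringsAsFactors = FALSE)
    }
  }
  bind <- function(l) {
    l <- l[!vapply(l, is.null, logical(1))]
    if (length(l)) do.call(rbind, l) else NULL
  }
  report_set(reports, bind(drows), bind(rrows), bind(orows),
             log = list(n_bad_dates = n_bad_dates,
                        n_reports_out = nrow(reports)))
}

.map_sex_token <- function(x) {
  out <- .map_sex(x)
  out[x %in% .sex_levels] <- x[x %in% .sex_levels]
  out
}
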