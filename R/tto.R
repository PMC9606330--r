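# Time to onset: days from the start of the target drug to the onset of the
# target event on a report, with strict exclusion accounting. Reports
# lacking a drug start date or an event date, with start after onset, or
# with only partial-precision dates are excluded with a counted reason.

#' Compute time to onset for a report set
#'
#' For each report with at least one target-drug row (passing the role
#' filter) and at least one reaction matching the event predicate, computes
#' \code{days = event_date - start_date}, using the earliest day-precision
#' start date among matching drug rows (first exposure). Exclusion reasons,
#' each counted: \code{missing_start} (no start date on any matching drug
#' row), \code{missing_event} (no event date), \code{partial_date} (a date
#' present but below day precision), \code{negative_interval} (start after
#' onset — aberrant). Same-day onset (0 days) is kept.
#'
#' @param x mapped report_set
#' @param target_drugs character vector of ingredient names
#' @param event_predicate function over the reactions table
#' @param role \code{"suspect"} (default) or \code{"all"}
#' @return list with \code{records} (data.frame: uid, report_id, days) and
#'   \code{exclusions} (named integer vector), plus \code{n_eligible}
#' @export
compute_tto <- function(x, target_drugs, event_predicate,
                        role = c("suspect", "all")) {
  validate_report_set(x)
  role <- match.arg(role)
  d <- x$drugs
  if (role == "suspect")
    d <- d[d$role %in% c("primary_suspect", "secondary_suspect"), ,
           drop = FALSE]
  d <- d[!is.na(d$ingredient) & d$ingredient %in% target_drugs, ,
         drop = FALSE]
  hit_e <- unique(x$reactions$uid[event_predicate(x$reactions)])
  uids <- intersect(unique(d$uid), hit_e)

  excl <- c(missing_start = 0L, missing_event = 0L, partial_date = 0L,
            negative_interval = 0L)
  rec <- list()
  r <- x$reports
  ridx <- match(uids, r$uid)
  for (k in seq_along(uids)) {
    uid <- uids[k]
    i <- ridx[k]
    drows <- d[d$uid == uid, , drop = FALSE]
    has_start <- !is.na(drows$start_date)
    if (!any(has_start)) { excl["missing_start"] <- excl["missing_start"] + 1L; next }
    if (is.na(r$event_date[i])) { excl["missing_event"] <- excl["missing_event"] + 1L; next }
    day_start <- has_start & drows$start_precision == "day"
    if (!any(day_start) || r$event_precision[i] != "day") {
      excl["partial_date"] <- excl["partial_date"] + 1L; next
    }
    start <- min(drows$start_date[day_start])
    days <- as.integer(r$event_date[i] - start)
    if (days < 0) { excl["negative_interval"] <- excl["negative_interval"] + 1L; next }
    rec[[length(rec) + 1L]] <- data.frame(
      uid = uid, report_id = r$report_id[i], days = days,
      stringsAsFactors = FALSE)
  }
  records <- if (length(rec)) do.call(rbind, rec) else
    data.frame(uid = character(), report_id = character(),
               days = integer(), stringsAsFactors = FALSE)
  list(records = records, exclusions = excl, n_eligible = length(uids))
}

#' Summarize a time-to-onset distribution
#'
#' Median and quartiles by type-7 linear interpolation, plus cumulative
#' proportions of onsets within 30 and 90 days (percent, 1 decimal place in
#' the printed rendering; full precision returned).
#'
#' @param days numeric vector of onset intervals in days (or the
#'   \code{records} data.frame from \code{\link{compute_tto}})
#' @return one-row data.frame: n, median, q1, q3, pct_30d, pct_90d
#' @export
summarize_tto <- function(days) {
  if (is.data.frame(days)) days <- days$days
  if (!length(days)) stop("no time-to-onset records to summarize")
  q <- stats::quantile(days, probs = c(0.25, 0.5, 0.75), type = 7,
                       names = FALSE)
  data.frame(n = length(days),
             median = q[2], q1 = q[1], q3 = q[3],
             pct_30d = 100 * mean(days <= 30),
             pct_90d = 100 * mean(days <= 90))
}

#' Time-to-onset table across event groups
#'
#' Runs \code{\link{compute_tto}} + \code{\link{summarize_tto}} for each
#' named event group and binds the rows, carrying exclusion counts.
#'
#' @param x mapped report_set
#' @param target_drugs ingredient vector
#' @param groups named list of event predicates
#' @param role role filter
#' @return data.frame, one row per group (groups with no admissible record
#'   get NA summaries and n = 0)
#' @export
tto_table <- function(x, target_drugs, groups, role = c("suspect", "all")) {
  role <- match.arg(role)
  rows <- lapply(names(groups), function(g) {
    tt <- compute_tto(x, target_drugs, groups[[g]], role = role)
    s <- if (nrow(tt$records)) summarize_tto(tt$records) else
      data.frame(n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                 pct_30d = NA_real_, pct_90d = NA_real_)
    cbind(data.frame(group = g, stringsAsFactors = FALSE), s,
          as.data.frame(as.list(tt$exclusions)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
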