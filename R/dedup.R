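# Two-step data cleaning for spontaneous report sets:
#   1. keep only the last version of each report id;
#   2. remove reports identical on a six-field key
#      (sex, age, reporter country, receipt date, reaction PT multiset,
#       verbatim drug-name multiset).
# Dedup runs on verbatim drug names, before dictionary mapping.

#' Keep only the last version of each report
#'
#' Spontaneous reporting systems receive follow-up versions of the same
#' report under one report id. Among rows sharing a \code{report_id} the
#' survivor maximizes \code{receipt_date}, with partial dates compared by
#' their earliest consistent calendar date. Ties on receipt date keep the
#' lexicographically largest \code{uid} (version numbers grow with id in
#' practice). Output is sorted by \code{report_id} for determinism.
#'
#' @param x report_set
#' @return report_set with at most one row per \code{report_id}; the log
#'   gains \code{n_versions_removed}.
#' @export
keep_last_version <- function(x) {
  validate_report_set(x)
  r <- x$reports
  if (!nrow(r)) return(x)
  # missing receipt dates sort earliest; order by (report_id, date, uid)
  # and keep the last row of each id group
  dkey <- as.numeric(r$receipt_date)
  dkey[is.na(dkey)] <- -Inf
  ord <- order(r$report_id, dkey, r$uid)
  r_ord <- r[ord, , drop = FALSE]
  last <- !duplicated(r_ord$report_id, fromLast = TRUE)
  survivors <- r_ord$uid[last]
  out <- subset_reports(x, survivors,
                        log = list(n_versions_removed = nrow(r) - sum(last)))
  ordr <- order(out$reports$report_id)
  out$reports <- out$reports[ordr, , drop = FALSE]
  rownames(out$reports) <- NULL
  out
}

# canonical six-field duplicate key per report row; missing values compare
# equal to each other (missingness is a value of the field here)
.dedup_key <- function(x) {
  r <- x$reports
  fkey <- function(child) factor(child$uid, levels = r$uid)
  pts <- vapply(split(x$reactions$pt, fkey(x$reactions)),
                function(p) paste(sort(p), collapse = "\x1f"), character(1))
  drg <- vapply(split(x$drugs$verbatim_name, fkey(x$drugs)),
                function(d) paste(sort(d), collapse = "\x1f"), character(1))
  paste(r$patient_sex,
        ifelse(is.na(r$patient_age_years), "<NA>", r$patient_age_years),
        r$country,
        ifelse(is.na(r$receipt_date), "<NA>",
               paste(r$receipt_date, r$receipt_precision)),
        pts, drg, sep = "\x1e")
}

#' Drop reports duplicated on the six-field key
#'
#' Among reports agreeing on patient sex, patient age, reporter country,
#' receipt date, the sorted multiset of reaction PTs, and the sorted
#' multiset of verbatim drug names, exactly one survives: the smallest
#' \code{report_id} (ties broken by smallest \code{uid}). Intended to run
#' after \code{\link{keep_last_version}}.
#'
#' @param x report_set
#' @return report_set; the log gains \code{n_duplicates_removed}.
#' @export
drop_field_duplicates <- function(x) {
  validate_report_set(x)
  r <- x$reports
  if (!nrow(r)) return(x)
  key <- .dedup_key(x)
  ord <- order(key, r$report_id, r$uid)
  key_ord <- key[ord]
  first <- !duplicated(key_ord)
  survivors <- r$uid[ord][first]
  out <- subset_reports(x, survivors,
                        log = list(n_duplicates_removed = nrow(r) - sum(first)))
  ordr <- order(out$reports$report_id, out$reports$uid)
  out$reports <- out$reports[ordr, , drop = FALSE]
  rownames(out$reports) <- NULL
  out
}

#' Two-step deduplication
#'
#' Convenience wrapper: \code{\link{keep_last_version}} then
#' \code{\link{drop_field_duplicates}}. Idempotent.
#'
#' @param x report_set
#' @return deduplicated report_set with both removal counters in the log
#' @export
dedup_reports <- function(x) {
  drop_field_duplicates(keep_last_version(x))
}
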