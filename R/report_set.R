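#' Construct a report set
#'
#' The central container of the package: a relational snapshot of a batch of
#' spontaneous safety reports, held as four linked data.frames. This mirrors
#' the structure of FAERS quarterly extracts (one demographic row per case
#' version, child rows for drugs, reactions, and outcomes) while staying
#' dialect-agnostic.
#'
#' Versioned resubmissions of one report share a \code{report_id}, so every
#' physical row additionally carries a unique surrogate key \code{uid}
#' (generated as \code{make.unique(report_id, sep = "#")} when not supplied);
#' child tables are keyed by \code{uid}.
#'
#' @param reports data.frame with one row per report version: optionally
#'   \code{uid}, then \code{report_id}, \code{case_id}, \code{receipt_date}
#'   (Date), \code{receipt_precision}, \code{patient_age_years},
#'   \code{patient_sex} (male/female/unknown), \code{reporter_type}
#'   (health_professional/non_health_professional/unknown), \code{country},
#'   \code{event_date} (Date), \code{event_precision}, \code{report_year}.
#' @param drugs data.frame: \code{uid}, \code{verbatim_name}, \code{role}
#'   (primary_suspect/secondary_suspect/concomitant/interacting/unknown),
#'   \code{start_date} (Date), \code{start_precision}, \code{ingredient}
#'   (NA until mapped), \code{drug_class} (NA until mapped).
#' @param reactions data.frame: \code{uid}, \code{pt}.
#' @param outcomes data.frame: \code{uid}, \code{outcome} (one of death,
#'   life_threatening, hospitalization, disability, congenital_anomaly,
#'   other_serious).
#' @param log named list of counters accumulated during ingestion.
#' @return object of class \code{report_set}
#' @export
report_set <- function(reports, drugs = NULL, reactions = NULL,
                       outcomes = NULL, log = list()) {
  if (!"uid" %in% names(reports))
    reports <- cbind(uid = make.unique(reports$report_id, sep = "#"),
                     reports, stringsAsFactors = FALSE)
  empty_drugs <- data.frame(
    uid = character(), verbatim_name = character(), role = character(),
    start_date = as.Date(character()), start_precision = character(),
    ingredient = character(), drug_class = character(),
    stringsAsFactors = FALSE)
  empty_reactions <- data.frame(uid = character(), pt = character(),
                                stringsAsFactors = FALSE)
  empty_outcomes <- data.frame(uid = character(), outcome = character(),
                               stringsAsFactors = FALSE)
  x <- structure(list(
    reports = reports,
    drugs = if (is.null(drugs)) empty_drugs else drugs,
    reactions = if (is.null(reactions)) empty_reactions else reactions,
    outcomes = if (is.null(outcomes)) empty_outcomes else outcomes,
    log = log
  ), class = "report_set")
  validate_report_set(x)
  x
}

.sex_levels <- c("male", "female", "unknown")
.reporter_levels <- c("health_professional", "non_health_professional", "unknown")
.role_levels <- c("primary_suspect", "secondary_suspect", "concomitant",
                  "interacting", "unknown")
.outcome_levels <- c("death", "life_threatening", "hospitalization",
                     "disability", "congenital_anomaly", "other_serious")
.precision_levels <- c("day", "month", "year", "none")

#' Validate a report set
#'
#' Checks the structural invariants: required columns, unique row keys,
#' non-empty report ids, ages within [0, 120], enum fields within their
#' level sets, child rows keyed to a known row, and no duplicate outcome
#' code per report row.
#'
#' @param x report_set
#' @return invisibly \code{x}; stops on violation
#' @export
validate_report_set <- function(x) {
  stopifnot(inherits(x, "report_set"))
  r <- x$reports
  need <- c("uid", "report_id", "case_id", "receipt_date",
            "receipt_precision", "patient_age_years", "patient_sex",
            "reporter_type", "country", "event_date", "event_precision",
            "report_year")
  miss <- setdiff(need, names(r))
  if (length(miss)) stop("reports table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(r$uid)) stop("uid must be unique")
  if (anyNA(r$report_id) || any(!nzchar(r$report_id)))
    stop("report_id must be non-empty")
  # duplicate report_id rows are legal pre-dedup (versioned resubmissions)
  age <- r$patient_age_years
  bad_age <- !is.na(age) & (age < 0 | age > 120)
  if (any(bad_age)) stop("patient_age_years outside [0, 120]")
  if (!all(r$patient_sex %in% .sex_levels)) stop("invalid patient_sex value")
  if (!all(r$reporter_type %in% .reporter_levels)) stop("invalid reporter_type")
  if (nrow(x$drugs)) {
    if (!all(x$drugs$role %in% .role_levels)) stop("invalid drug role")
    if (any(!nzchar(trimws(x$drugs$verbatim_name))))
      stop("verbatim_name must be non-empty")
  }
  if (nrow(x$outcomes)) {
    if (!all(x$outcomes$outcome %in% .outcome_levels)) stop("invalid outcome code")
    if (anyDuplicated(x$outcomes[, c("uid", "outcome")]))
      stop("duplicate outcome entries within a report")
  }
  for (child in c("drugs", "reactions", "outcomes")) {
    orphan <- !(x[[child]]$uid %in% r$uid)
    if (any(orphan)) stop("orphan rows in ", child, " table")
  }
  invisible(x)
}

#' @export
print.report_set <- function(x, ...) {
  cat("<report_set> ", nrow(x$reports), " reports | ",
      nrow(x$drugs), " drug rows | ",
      nrow(x$reactions), " reaction rows | ",
      nrow(x$outcomes), " outcome rows\n", sep = "")
  if (nrow(x$drugs))
    cat("  drug rows mapped to ingredient: ",
        sum(!is.na(x$drugs$ingredient)), "/", nrow(x$drugs), "\n", sep = "")
  cnt <- x$log[vapply(x$log, is.numeric, logical(1))]
  if (length(cnt))
    cat("  log counters: ",
        paste(names(cnt), unlist(cnt), sep = "=", collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Number of report rows in a report set
#' @param x report_set
#' @return integer
#' @export
n_reports <- function(x) nrow(x$reports)

#' Subset a report set to a set of row keys
#'
#' Keeps the given \code{uid}s (in the order they appear in the reports
#' table) and drops child rows of removed reports.
#'
#' @param x report_set
#' @param uids character vector of uid values to keep
#' @param log optional named list merged into the log
#' @return report_set
#' @export
subset_reports <- function(x, uids, log = NULL) {
  keep <- x$reports$uid %in% uids
  out <- x
  out$reports <- x$reports[keep, , drop = FALSE]
  for (child in c("drugs", "reactions", "outcomes")) {
    out[[child]] <- x[[child]][x[[child]]$uid %in% uids, , drop = FALSE]
    rownames(out[[child]]) <- NULL
  }
  rownames(out$reports) <- NULL
  if (!is.null(log)) out$log <- utils::modifyList(out$log, log)
  out
}
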