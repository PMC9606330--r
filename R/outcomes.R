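# Outcome severity tabulation. A report may carry several outcome codes;
# the default assignment keeps one category per report by severity
# precedence, so category percentages over reports with any outcome sum to
# exactly 100.

.outcome_precedence <- c("death", "life_threatening", "hospitalization",
                         "disability", "congenital_anomaly", "other_serious")

#' Most severe outcome of a report
#'
#' Precedence: death > life_threatening > hospitalization > disability >
#' congenital_anomaly > other_serious. Empty outcome sets give
#' \code{NA}.
#'
#' @param outcomes character vector of outcome codes for one report (or a
#'   list of such vectors)
#' @return single outcome code or NA (vector of them for list input)
#' @export
worst_outcome <- function(outcomes) {
  one <- function(oc) {
    hit <- .outcome_precedence %in% oc
    if (!any(hit)) NA_character_ else .outcome_precedence[which(hit)[1]]
  }
  if (is.list(outcomes)) vapply(outcomes, one, character(1)) else one(outcomes)
}

#' Outcome proportion table over report groups
#'
#' For each named group of report rows (given as uid vectors, e.g. reports
#' matching an event grouping), tabulates per-category percentages plus the
#' combined death + life-threatening percentage and the hospitalization
#' percentage. By default each report counts once in its most severe
#' category (\code{mode = "worst"}); \code{mode = "all"} counts every
#' recorded category per report for sensitivity analysis. The denominator is
#' every report in the group (\code{denominator = "all"}, matching
#' spontaneous-report table conventions) or only reports with at least one
#' recorded outcome (\code{denominator = "with_outcome"}).
#'
#' @param x report_set
#' @param groups named list of uid character vectors
#' @param mode \code{"worst"} or \code{"all"}
#' @param denominator \code{"all"} or \code{"with_outcome"}
#' @return data.frame: group, n, n_with_outcome, pct_death,
#'   pct_life_threatening, pct_hospitalization, pct_disability,
#'   pct_congenital_anomaly, pct_other_serious, pct_death_lt (combined),
#'   all percentages in [0, 100]; groups with denominator 0 get NA percents.
#' @export
outcome_table <- function(x, groups, mode = c("worst", "all"),
                          denominator = c("all", "with_outcome")) {
  validate_report_set(x)
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  rows <- lapply(names(groups), function(g) {
    uids <- groups[[g]]
    oc <- x$outcomes[x$outcomes$uid %in% uids, , drop = FALSE]
    n <- length(unique(uids))
    n_with <- length(unique(oc$uid))
    if (mode == "worst") {
      per <- vapply(split(oc$outcome, oc$uid), function(v)
        worst_outcome(v), character(1))
      counts <- table(factor(per, levels = .outcome_precedence))
    } else {
      counts <- table(factor(oc$outcome, levels = .outcome_precedence))
    }
    denom <- if (denominator == "all") n else n_with
    pct <- if (denom > 0) 100 * as.numeric(counts) / denom else
      rep(NA_real_, length(.outcome_precedence))
    names(pct) <- paste0("pct_", .outcome_precedence)
    out <- data.frame(group = g, n = n, n_with_outcome = n_with,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(as.list(pct)))
    out$pct_death_lt <- pct[["pct_death"]] + pct[["pct_life_threatening"]]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Report uids matching an event predicate and drug set
#'
#' Helper for grouping \code{\link{outcome_table}} rows: the uids of reports
#' exposed to the target drugs (role-filtered) that carry a matching
#' reaction.
#'
#' @param x mapped report_set
#' @param target_drugs ingredient vector
#' @param event_predicate function over the reactions table
#' @param role role filter
#' @return character vector of uids
#' @export
matching_uids <- function(x, target_drugs, event_predicate,
                          role = c("suspect", "all")) {
  fl <- .report_flags(x, target_drugs, event_predicate, match.arg(role))
  x$reports$uid[fl[, 1] & fl[, 2]]
}
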