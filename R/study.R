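# End-to-end study orchestration: ingest -> dedup -> vocabulary mapping ->
# disproportionality panels -> time to onset -> outcomes, with a
# flowchart-style count log and publication-style table rendering.

#' Round half away from zero
#'
#' Publication tables round 2.605 to 2.61, not the IEC banker's rounding of
#' \code{round()}. Full precision is kept internally; this is a rendering
#' rule only.
#'
#' @param x numeric
#' @param digits decimal places
#' @return numeric
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# "23,177 (32.8)" with the panel total as denominator
.fmt_count_pct <- function(n, total) {
  pct <- round_half_away(100 * n / total, 1)
  sprintf("%s (%s)", formatC(n, big.mark = ",", format = "d"),
          formatC(pct, format = "f", digits = 1))
}

#' Run a complete synthetic or file-based study
#'
#' Orchestrates every stage and returns a bundle: stage counts (flowchart
#' style), the disproportionality panel, per-PT spectrum, time-to-onset and
#' outcome tables, and the configuration echoed back for provenance. Inputs
#' come either from a generator configuration (\code{sim}) or from an
#' interchange CSV (\code{reports_csv}).
#'
#' @param sim optional \code{\link{sim_config}}; generated data replaces
#'   file input
#' @param reports_csv optional path to an interchange CSV (used when
#'   \code{sim} is NULL)
#' @param archive drug_archive (see \code{\link{read_drug_archive}})
#' @param defs smq_definitions (see \code{\link{read_smq_definitions}})
#' @param panels list of analysis specs for \code{\link{run_panel}}; may be
#'   empty, in which case only counts are produced
#' @param tto_groups named list of event predicates for
#'   \code{\link{tto_table}} (NULL to skip)
#' @param outcome_groups named list passed to \code{\link{outcome_table}}
#'   after resolving each entry with \code{\link{matching_uids}}; entries
#'   are lists with \code{drugs} and \code{events} specs (NULL to skip)
#' @param target_drugs ingredient vector used for the per-PT spectrum, the
#'   TTO table, and stage counts (default: all non-background archive
#'   ingredients)
#' @param cfg shrinkage_config
#' @param fuzzy passed to \code{\link{map_drugs}}
#' @param role role filter for all analyses
#' @param out_dir optional directory: writes counts.json, panel.csv,
#'   spectrum.csv, tto.csv, outcomes.csv
#' @return list of class \code{study_bundle}
#' @export
run_study <- function(sim = NULL, reports_csv = NULL, archive, defs,
                      panels = list(), tto_groups = NULL,
                      outcome_groups = NULL, target_drugs = NULL,
                      cfg = shrinkage_config(), fuzzy = FALSE,
                      role = c("suspect", "all"), out_dir = NULL) {
  role <- match.arg(role)
  truth <- NULL
  if (!is.null(sim)) {
    gen <- generate_reports(sim)
    raw <- gen$reports
    truth <- gen$truth
  } else if (!is.null(reports_csv)) {
    raw <- read_interchange_csv(reports_csv)
  } else stop("provide either sim or reports_csv")

  clean <- dedup_reports(raw)
  mapped <- map_reactions(map_drugs(clean, archive, fuzzy = fuzzy), defs)

  if (is.null(target_drugs))
    target_drugs <- sort(unique(archive$ingredient[
      archive$class != "non_target"]))
  exposed <- unique(mapped$drugs$uid[
    !is.na(mapped$drugs$ingredient) &
      mapped$drugs$ingredient %in% target_drugs &
      (role == "all" |
         mapped$drugs$role %in% c("primary_suspect", "secondary_suspect"))])
  any_smq <- smq_predicate(defs$smq$smq_code)
  event_uids <- unique(mapped$reactions$uid[any_smq(mapped$reactions)])

  counts <- list(
    n_raw = n_reports(raw),
    n_after_version_filter = n_reports(raw) -
      (clean$log$n_versions_removed %||% 0L),
    n_after_dedup = n_reports(clean),
    n_versions_removed = clean$log$n_versions_removed %||% 0L,
    n_duplicates_removed = clean$log$n_duplicates_removed %||% 0L,
    n_target_drug_reports = length(exposed),
    n_target_event_reports = length(event_uids),
    n_target_drug_event_reports = length(intersect(exposed, event_uids)))

  panel <- if (length(panels))
    run_panel(mapped, panels, archive, defs, cfg = cfg, role = role) else NULL
  spectrum <- if (length(exposed))
    pt_spectrum(mapped, target_drugs, archive, cfg = cfg, role = role) else NULL
  tto <- if (!is.null(tto_groups))
    tto_table(mapped, target_drugs, tto_groups, role = role) else NULL
  outc <- if (!is.null(outcome_groups)) {
    grp <- lapply(outcome_groups, function(g)
      matching_uids(mapped,
                    .resolve_drug_spec(g$drugs, archive),
                    .resolve_event_spec(g$events, defs), role = role))
    outcome_table(mapped, grp)
  } else NULL

  bundle <- structure(list(
    counts = counts, panel = panel, spectrum = spectrum, tto = tto,
    outcomes = outc, truth = truth, mapped = mapped,
    config = list(role = role, fuzzy = fuzzy, cfg = unclass(cfg),
                  target_drugs = target_drugs)),
    class = "study_bundle")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(counts, file.path(out_dir, "counts.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    tabs <- render_tables(bundle)
    for (nm in names(tabs))
      utils::write.csv(tabs[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE, na = "")
  }
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.study_bundle <- function(x, ...) {
  cat("<study_bundle>\n  stage counts:\n")
  for (nm in names(x$counts))
    cat(sprintf("    %-28s %s\n", nm,
                formatC(x$counts[[nm]], big.mark = ",", format = "d")))
  if (!is.null(x$panel)) cat("  panel rows:", nrow(x$panel), "\n")
  if (!is.null(x$spectrum)) cat("  spectrum PTs:", nrow(x$spectrum), "\n")
  invisible(x)
}

#' Render publication-style tables from a study bundle
#'
#' Formats the panel and spectrum with 2-decimal ROR/IC columns
#' (half-away-from-zero), \code{"N (pct)"} count columns over the panel
#' total, and 1-decimal TTO/outcome percentages. Returns character-valued
#' data.frames ready for CSV or Markdown.
#'
#' @param bundle study_bundle
#' @return named list of data.frames (panel, spectrum, tto, outcomes —
#'   whichever exist; empty tables render as header-only)
#' @export
render_tables <- function(bundle) {
  stopifnot(inherits(bundle, "study_bundle"))
  out <- list()
  fmt2 <- function(v) ifelse(is.na(v), "N",
                             formatC(round_half_away(v, 2), format = "f",
                                     digits = 2))
  if (!is.null(bundle$panel)) {
    p <- bundle$panel
    total <- sum(p$n_observed)
    out$panel <- data.frame(
      analysis = p$analysis,
      N = if (nrow(p)) .fmt_count_pct(p$n_observed, max(total, 1L)) else
        character(0),
      ROR = fmt2(p$ror_shrunk), ROR025 = fmt2(p$ror_ci_low),
      ROR975 = fmt2(p$ror_ci_high), IC = fmt2(p$ic),
      IC025 = fmt2(p$ic_low), IC975 = fmt2(p$ic_high),
      signal = ifelse(p$is_signal, "yes", "no"),
      stringsAsFactors = FALSE)
  }
  if (!is.null(bundle$spectrum)) {
    s <- bundle$spectrum
    out$spectrum <- data.frame(
      pt = s$pt, N = s$n_observed, ROR = fmt2(s$ror_shrunk),
      IC = fmt2(s$ic), IC025 = fmt2(s$ic_low), IC975 = fmt2(s$ic_high),
      signal = ifelse(s$is_signal, "yes", "no"), stringsAsFactors = FALSE)
  }
  fmt1 <- function(v) ifelse(is.na(v), "",
                             formatC(round_half_away(v, 1), format = "f",
                                     digits = 1))
  if (!is.null(bundle$tto)) {
    t <- bundle$tto
    out$tto <- data.frame(
      group = t$group, n = t$n,
      median = fmt1(t$median), q1 = fmt1(t$q1), q3 = fmt1(t$q3),
      pct_30d = fmt1(t$pct_30d), pct_90d = fmt1(t$pct_90d),
      excluded_missing_start = t$missing_start,
      excluded_missing_event = t$missing_event,
      excluded_partial_date = t$partial_date,
      excluded_negative_interval = t$negative_interval,
      stringsAsFactors = FALSE)
  }
  if (!is.null(bundle$outcomes)) {
    o <- bundle$outcomes
    pctcols <- grep("^pct_", names(o), value = TRUE)
    oo <- o
    for (cc in pctcols) oo[[cc]] <- fmt1(o[[cc]])
    out$outcomes <- oo
  }
  out
}
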