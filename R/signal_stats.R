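# Disproportionality statistics: report-level 2x2 contingency tables and
# shrinkage-transformed ROR / information component (IC) estimates with 95%
# interval bounds and the signal rule (ROR025 > 1 or IC025 > 0, with at
# least three reports).

#' Shrinkage and signal-rule configuration
#'
#' Defaults follow standard shrinkage-transformed disproportionality
#' practice: a shrinkage constant of 0.5 added to observed and expected
#' counts, normal z of 1.96 for the ROR confidence interval, the closed-form
#' IC interval constants (3.3, 2) for the lower and (2.4, 0.5) for the upper
#' bound, and a minimum of three reports for a signal.
#'
#' @param shrinkage_k additive shrinkage constant (>= 0), default 0.5
#' @param z normal quantile for the ROR CI, default 1.96
#' @param ic_low_c1,ic_low_c2 IC lower-bound constants, defaults 3.3 and 2
#' @param ic_high_c1,ic_high_c2 IC upper-bound constants, defaults 2.4 and 0.5
#' @param min_reports minimum observed count for a signal (>= 1), default 3
#' @return list of class \code{shrinkage_config}
#' @export
shrinkage_config <- function(shrinkage_k = 0.5, z = 1.96,
                             ic_low_c1 = 3.3, ic_low_c2 = 2,
                             ic_high_c1 = 2.4, ic_high_c2 = 0.5,
                             min_reports = 3L) {
  stopifnot(shrinkage_k >= 0, min_reports >= 1)
  structure(list(shrinkage_k = shrinkage_k, z = z,
                 ic_low_c1 = ic_low_c1, ic_low_c2 = ic_low_c2,
                 ic_high_c1 = ic_high_c1, ic_high_c2 = ic_high_c2,
                 min_reports = as.integer(min_reports)),
            class = "shrinkage_config")
}

#' Construct a 2x2 contingency table
#'
#' Cells: \code{a} reports with target drug and target event, \code{b}
#' target drug only, \code{c} target event only, \code{d} neither. Derived
#' margins: \code{n_drug = a+b}, \code{n_event = a+c},
#' \code{n_total = a+b+c+d}, and the expected count under independence
#' \code{n_expected = n_drug * n_event / n_total}.
#'
#' @param a,b,c,d non-negative counts
#' @return object of class \code{contingency_table}
#' @export
contingency_table <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n_total <- a + b + c + d
  if (n_total < 1) stop("empty contingency table (n_total = 0)")
  structure(list(a = a, b = b, c = c, d = d,
                 n_drug = a + b, n_event = a + c, n_total = n_total,
                 n_expected = (a + b) * (a + c) / n_total),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("target AE", "other AE")))
  print(m)
  cat(sprintf("n_total = %d, n_expected = %.4g\n", x$n_total, x$n_expected))
  invisible(x)
}

# report-level exposure/event indicator logic shared by build_contingency
# and run_panel; returns a logical matrix cbind(exposed, event) over report
# rows of x
.report_flags <- function(x, target_drugs, event_predicate,
                          role = c("suspect", "all")) {
  role <- match.arg(role)
  r_uid <- x$reports$uid
  d <- x$drugs
  if (role == "suspect")
    d <- d[d$role %in% c("primary_suspect", "secondary_suspect"), ,
           drop = FALSE]
  hit_d <- d$uid[!is.na(d$ingredient) & d$ingredient %in% target_drugs]
  exposed <- r_uid %in% hit_d
  hit_e <- x$reactions$uid[event_predicate(x$reactions)]
  event <- r_uid %in% hit_e
  cbind(exposed = exposed, event = event)
}

#' Event predicate matching a set of PT strings
#' @param pts character vector of PT names (canonicalized comparison)
#' @return function over a reactions data.frame returning a logical vector
#' @export
pt_predicate <- function(pts) {
  canon <- canonical_name(pts)
  function(reactions) canonical_name(reactions$pt) %in% canon
}

#' Event predicate matching membership of SMQ codes
#'
#' Requires reactions mapped with \code{\link{map_reactions}} (the
#' \code{smq_codes} list-column).
#'
#' @param codes integer vector of SMQ codes
#' @return function over a reactions data.frame returning a logical vector
#' @export
smq_predicate <- function(codes) {
  codes <- as.integer(codes)
  function(reactions) {
    if (is.null(reactions$smq_codes))
      stop("reactions not mapped to SMQs; run map_reactions() first")
    vapply(reactions$smq_codes, function(cs) any(cs %in% codes), logical(1))
  }
}

#' Event predicate matching any reaction
#' @return function over a reactions data.frame returning all-TRUE
#' @export
any_event_predicate <- function() {
  function(reactions) rep(TRUE, nrow(reactions))
}

#' Build the report-level 2x2 table for one drug set x event predicate
#'
#' Each deduplicated report contributes to exactly one cell: \code{a} if it
#' carries at least one target-drug row passing the role filter AND at least
#' one reaction satisfying the event predicate; \code{b} if drug only;
#' \code{c} if event only; \code{d} otherwise. The counting unit is the
#' report: repeated matching drugs or PTs within one report count once.
#'
#' @param x mapped, deduplicated report_set
#' @param target_drugs character vector of ingredient names
#' @param event_predicate function over the reactions table (see
#'   \code{\link{pt_predicate}}, \code{\link{smq_predicate}})
#' @param role \code{"suspect"} (primary + secondary suspect, default) or
#'   \code{"all"}
#' @return contingency_table
#' @export
build_contingency <- function(x, target_drugs, event_predicate,
                              role = c("suspect", "all")) {
  validate_report_set(x)
  if (!nrow(x$reports)) stop("empty report list")
  fl <- .report_flags(x, target_drugs, event_predicate, role)
  contingency_table(a = sum(fl[, 1] & fl[, 2]),
                    b = sum(fl[, 1] & !fl[, 2]),
                    c = sum(!fl[, 1] & fl[, 2]),
                    d = sum(!fl[, 1] & !fl[, 2]))
}

#' Shrinkage-transformed observed/expected reporting ratio
#'
#' \code{(a + k) / (n_expected + k)} with shrinkage constant \code{k}
#' (default 0.5). Defined for a = 0; equals 1 when observed matches
#' expectation exactly.
#'
#' @param table contingency_table
#' @param cfg shrinkage_config
#' @return positive real
#' @export
shrunk_ratio <- function(table, cfg = shrinkage_config()) {
  stopifnot(inherits(table, "contingency_table"))
  (table$a + cfg$shrinkage_k) / (table$n_expected + cfg$shrinkage_k)
}

#' Information component and its 95\% bounds
#'
#' \code{ic = log2(ratio)} of the shrunk observed/expected ratio, with the
#' closed-form bounds
#' \deqn{IC_{025} = IC - 3.3 (N+0.5)^{-1/2} - 2 (N+0.5)^{-3/2}}
#' \deqn{IC_{975} = IC + 2.4 (N+0.5)^{-1/2} - 0.5 (N+0.5)^{-3/2}}
#' where N is the observed count. Both interval half-widths shrink
#' monotonically as N grows.
#'
#' @param n_observed observed count (cell a), >= 0
#' @param ratio shrunk observed/expected ratio, > 0
#' @param cfg shrinkage_config
#' @return named numeric vector \code{c(ic, ic_low, ic_high)}
#' @export
ic_stats <- function(n_observed, ratio, cfg = shrinkage_config()) {
  stopifnot(n_observed >= 0, ratio > 0)
  ic <- log2(ratio)
  m <- n_observed + 0.5
  ic_low <- ic - cfg$ic_low_c1 * m^-0.5 - cfg$ic_low_c2 * m^-1.5
  ic_high <- ic + cfg$ic_high_c1 * m^-0.5 - cfg$ic_high_c2 * m^-1.5
  c(ic = ic, ic_low = ic_low, ic_high = ic_high)
}

#' 95\% confidence interval around the reporting ratio
#'
#' Uses the classical reporting-odds-ratio standard error
#' \code{sqrt(1/a + 1/b + 1/c + 1/d)} on the log scale:
#' \code{exp(ln(point) -/+ z * se)}. The point estimate is selectable:
#' \code{"shrunk"} (the shrinkage-transformed observed/expected ratio;
#' default, matching the single ROR column convention) or
#' \code{"classical"} (the odds ratio \code{ad/bc}). If any cell is zero the
#' bounds are undefined and returned as NA with \code{defined = FALSE} —
#' never silently substituted.
#'
#' @param table contingency_table
#' @param cfg shrinkage_config
#' @param point \code{"shrunk"} or \code{"classical"}
#' @return list \code{(point, low, high, defined)}
#' @export
ror_ci <- function(table, cfg = shrinkage_config(),
                   point = c("shrunk", "classical")) {
  stopifnot(inherits(table, "contingency_table"))
  point <- match.arg(point)
  pt_est <- if (point == "shrunk") shrunk_ratio(table, cfg) else
    table$a * table$d / (table$b * table$c)
  if (min(table$a, table$b, table$c, table$d) < 1)
    return(list(point = pt_est, low = NA_real_, high = NA_real_,
                defined = FALSE))
  se <- sqrt(1 / table$a + 1 / table$b + 1 / table$c + 1 / table$d)
  list(point = pt_est,
       low = exp(log(pt_est) - cfg$z * se),
       high = exp(log(pt_est) + cfg$z * se),
       defined = TRUE)
}

#' Full signal estimate for one 2x2 table
#'
#' Combines \code{\link{shrunk_ratio}}, \code{\link{ic_stats}},
#' \code{\link{ror_ci}}, and \code{\link{detect_signal}} into one row. The
#' identity \code{ic == log2(ror_shrunk)} holds exactly: both derive from
#' the same shrunk ratio.
#'
#' @param table contingency_table
#' @param cfg shrinkage_config
#' @param point point estimate for the ROR CI (see \code{\link{ror_ci}})
#' @return one-row data.frame: n_observed, n_expected, ror_shrunk,
#'   ror_ci_low, ror_ci_high, ic, ic_low, ic_high, is_signal
#' @export
signal_estimate <- function(table, cfg = shrinkage_config(),
                            point = c("shrunk", "classical")) {
  ratio <- shrunk_ratio(table, cfg)
  ics <- ic_stats(table$a, ratio, cfg)
  ci <- ror_ci(table, cfg, point = point)
  est <- data.frame(
    n_observed = table$a,
    n_expected = table$n_expected,
    ror_shrunk = ratio,
    ror_ci_low = ci$low,
    ror_ci_high = ci$high,
    ic = unname(ics["ic"]),
    ic_low = unname(ics["ic_low"]),
    ic_high = unname(ics["ic_high"]),
    stringsAsFactors = FALSE)
  est$is_signal <- detect_signal(est, cfg)
  est
}

#' Apply the signal rule
#'
#' TRUE iff the observed count reaches \code{min_reports} (default 3) and
#' either the lower ROR bound exceeds 1 or the lower IC bound exceeds 0. An
#' undefined ROR bound (zero cell) never satisfies its clause.
#'
#' @param estimate data.frame or list with \code{n_observed},
#'   \code{ror_ci_low}, \code{ic_low}
#' @param cfg shrinkage_config
#' @return logical
#' @export
detect_signal <- function(estimate, cfg = shrinkage_config()) {
  ror_clause <- !is.na(estimate$ror_ci_low) & estimate$ror_ci_low > 1
  ic_clause <- !is.na(estimate$ic_low) & estimate$ic_low > 0
  estimate$n_observed >= cfg$min_reports & (ror_clause | ic_clause)
}

# resolve a drug spec into a set of ingredients:
#   "ingredient:<name>", "class:<class-or-superclass>", or a plain
#   character vector of ingredients
.resolve_drug_spec <- function(spec, archive) {
  if (length(spec) == 1L && grepl("^class:", spec)) {
    cls <- sub("^class:", "", spec)
    members <- class_members(archive, cls)
    if (!length(members)) stop("no ingredients in class: ", cls)
    return(members)
  }
  spec <- sub("^ingredient:", "", spec)
  known <- canonical_name(spec) %in% canonical_name(archive$ingredient)
  if (!all(known))
    stop("unknown ingredient in drug spec: ",
         paste(spec[!known], collapse = ", "))
  spec
}

# resolve an event spec into a predicate:
#   list(smq = codes), list(pts = c(...)), or "any"
.resolve_event_spec <- function(spec, defs = NULL) {
  if (identical(spec, "any")) return(any_event_predicate())
  if (is.list(spec) && !is.null(spec$smq)) {
    if (!is.null(defs)) {
      unknown <- !(as.integer(spec$smq) %in% defs$smq$smq_code)
      if (any(unknown))
        stop("unknown SMQ code in event spec: ",
             paste(spec$smq[unknown], collapse = ", "))
    }
    return(smq_predicate(spec$smq))
  }
  if (is.list(spec) && !is.null(spec$pts)) return(pt_predicate(spec$pts))
  stop("event spec must be 'any', list(smq=), or list(pts=)")
}

#' Run a panel of disproportionality analyses
#'
#' One \code{\link{signal_estimate}} row per analysis, in the order given.
#' Each analysis is a list with \code{name}, \code{drugs} (ingredient
#' vector, \code{"ingredient:x"}, or \code{"class:TKI"} / \code{"class:mAb"}
#' which aggregate all class members into one exposure set), and
#' \code{events} (\code{"any"}, \code{list(smq = codes)}, or
#' \code{list(pts = ...)}).
#'
#' @param x mapped, deduplicated report_set
#' @param analyses list of analysis specs
#' @param archive drug_archive used to resolve class specs
#' @param defs optional smq_definitions used to validate SMQ codes
#' @param cfg shrinkage_config
#' @param role role filter passed to \code{\link{build_contingency}}
#' @return data.frame, one row per analysis, with an \code{analysis} name
#'   column prepended
#' @export
run_panel <- function(x, analyses, archive, defs = NULL,
                      cfg = shrinkage_config(),
                      role = c("suspect", "all")) {
  role <- match.arg(role)
  rows <- lapply(analyses, function(an) {
    if (is.null(an$name) || is.null(an$drugs) || is.null(an$events))
      stop("each analysis needs name, drugs, events")
    drugs <- .resolve_drug_spec(an$drugs, archive)
    pred <- .resolve_event_spec(an$events, defs)
    tab <- build_contingency(x, drugs, pred, role = role)
    cbind(data.frame(analysis = an$name, stringsAsFactors = FALSE),
          signal_estimate(tab, cfg))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-PT signal spectrum for one drug set
#'
#' Emits one row per distinct reaction PT with at least one observed report
#' under the target drugs, with the full signal estimate and flag —
#' the "spectrum" view of which individual PTs drive a drug's profile.
#' Rows are ordered by decreasing observed count, ties by PT name.
#'
#' @param x mapped, deduplicated report_set
#' @param target_drugs ingredient vector or class spec
#' @param archive drug_archive
#' @param cfg shrinkage_config
#' @param role role filter
#' @return data.frame with a \code{pt} column and estimate columns
#' @export
pt_spectrum <- function(x, target_drugs, archive,
                        cfg = shrinkage_config(),
                        role = c("suspect", "all")) {
  role <- match.arg(role)
  drugs <- .resolve_drug_spec(target_drugs, archive)
  d <- x$drugs
  if (role == "suspect")
    d <- d[d$role %in% c("primary_suspect", "secondary_suspect"), ,
           drop = FALSE]
  exposed_uid <- unique(d$uid[!is.na(d$ingredient) & d$ingredient %in% drugs])
  pts <- sort(unique(x$reactions$pt[x$reactions$uid %in% exposed_uid]))
  rows <- lapply(pts, function(p) {
    tab <- build_contingency(x, drugs, pt_predicate(p), role = role)
    cbind(data.frame(pt = p, stringsAsFactors = FALSE),
          signal_estimate(tab, cfg))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_observed, out$pt), , drop = FALSE]
  rownames(out) <- NULL
  out
}
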