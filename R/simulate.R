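# Synthetic spontaneous-report generator with planted ground truth:
# known drug-event reporting-ratio multipliers (lambda), exact-key
# duplicates, versioned resubmissions, partial/missing dates, and
# configurable log-normal time-to-onset — so every pipeline stage is
# testable without a database download.

.default_drug_catalog <- function() {
  data.frame(
    ingredient = c("bevacizumab", "sunitinib", "aflibercept",
                   "metformin", "lisinopril", "atorvastatin", "omeprazole"),
    class = c("anti_VEGF_mAb", "TKI", "VEGF_trap",
              "non_target", "non_target", "non_target", "non_target"),
    synonyms = c("bevacizumab;AVASTIN;MVASI",
                 "sunitinib;SUTENT",
                 "aflibercept;ZALTRAP",
                 "metformin;GLUCOPHAGE",
                 "lisinopril;ZESTRIL",
                 "atorvastatin;LIPITOR",
                 "omeprazole;PRILOSEC"),
    marginal_prob = c(0.02, 0.02, 0.01, 0.30, 0.25, 0.25, 0.15),
    stringsAsFactors = FALSE)
}

.default_event_catalog <- function() {
  data.frame(
    pt = c("Hypertension", "Blood pressure increased",
           "Deep vein thrombosis", "Pulmonary embolism",
           "Myocardial infarction", "Cardiac failure",
           "Nausea", "Headache", "Diarrhoea"),
    base_rate = c(0.010, 0.005, 0.005, 0.004, 0.004, 0.005,
                  0.050, 0.040, 0.030),
    stringsAsFactors = FALSE)
}

#' Configuration of the synthetic report generator
#'
#' Defaults emulate a plausible spontaneous-report stream received over
#' 2014-2021: mostly background drugs, target antiangiogenic agents at a
#' few percent marginal probability, rare target events at base rates of
#' 0.4-1 percent, common background reactions, follow-up versions and
#' duplicate submissions at 5 percent each, and heavy date missingness.
#' All rates are overridable; \code{planted_lambda} multiplies the base
#' rate of a (ingredient, pt) pair for reports carrying that drug (max over
#' the report's drugs, keeping per-pair interpretability).
#'
#' @param n_reports number of unique reports before duplication/versioning
#' @param seed integer RNG seed (full run reproducibility)
#' @param drug_catalog data.frame: ingredient, class, synonyms
#'   (';'-joined verbatim spellings), marginal_prob (categorical weights
#'   for the first drug draw)
#' @param event_catalog data.frame: pt, base_rate (per-report Bernoulli)
#' @param planted_lambda data.frame: ingredient, pt, lambda (default none:
#'   lambda = 1 everywhere, i.e. independence)
#' @param dup_prob probability a report is also emitted as an exact-key
#'   duplicate under a fresh report id
#' @param version_prob probability a report also gets an earlier version
#'   under the same report id
#' @param second_drug_prob probability of a second, independently drawn drug
#' @param missing_start_prob,missing_event_prob,partial_date_prob date
#'   degradation probabilities (partial = start date truncated to month)
#' @param typo_prob probability a verbatim drug spelling gets a single
#'   character substitution (exercises fuzzy matching)
#' @param tto_default c(median_days, sigma) of the log-normal time to onset
#'   used when no pair-specific entry applies
#' @param tto_lognormal data.frame: ingredient, pt, median_days, sigma
#' @param outcome_probs named numeric over
#'   none/death/life_threatening/hospitalization/disability/
#'   congenital_anomaly/other_serious, summing to 1
#' @param start_window c(from, to) Date range for drug start dates
#' @return list of class \code{sim_config}
#' @export
sim_config <- function(n_reports = 5000L, seed = 1L,
                       drug_catalog = .default_drug_catalog(),
                       event_catalog = .default_event_catalog(),
                       planted_lambda = NULL,
                       dup_prob = 0.05, version_prob = 0.05,
                       second_drug_prob = 0.2,
                       missing_start_prob = 0.3,
                       missing_event_prob = 0.3,
                       partial_date_prob = 0.1,
                       typo_prob = 0,
                       tto_default = c(median_days = 60, sigma = 1),
                       tto_lognormal = NULL,
                       outcome_probs = c(none = 0.35, death = 0.08,
                                         life_threatening = 0.03,
                                         hospitalization = 0.25,
                                         disability = 0.01,
                                         congenital_anomaly = 0.001,
                                         other_serious = 0.279),
                       start_window = as.Date(c("2014-01-01", "2021-06-30"))) {
  probs <- c(dup_prob, version_prob, second_drug_prob, missing_start_prob,
             missing_event_prob, partial_date_prob, typo_prob)
  stopifnot(n_reports >= 1, all(probs >= 0 & probs <= 1),
            abs(sum(outcome_probs) - 1) < 1e-8,
            all(event_catalog$base_rate >= 0))
  if (is.null(planted_lambda))
    planted_lambda <- data.frame(ingredient = character(), pt = character(),
                                 lambda = numeric(), stringsAsFactors = FALSE)
  if (is.null(tto_lognormal))
    tto_lognormal <- data.frame(ingredient = character(), pt = character(),
                                median_days = numeric(), sigma = numeric(),
                                stringsAsFactors = FALSE)
  # per-event Bernoulli rates lambda * base_rate must stay <= 1
  if (nrow(planted_lambda)) {
    br <- event_catalog$base_rate[match(planted_lambda$pt, event_catalog$pt)]
    if (anyNA(br)) stop("planted_lambda pt not in event catalog")
    if (any(planted_lambda$lambda * br > 1))
      stop("lambda * base_rate exceeds 1 for a planted pair")
    if (!all(planted_lambda$ingredient %in% drug_catalog$ingredient))
      stop("planted_lambda ingredient not in drug catalog")
  }
  structure(list(
    n_reports = as.integer(n_reports), seed = as.integer(seed),
    drug_catalog = drug_catalog, event_catalog = event_catalog,
    planted_lambda = planted_lambda, dup_prob = dup_prob,
    version_prob = version_prob, second_drug_prob = second_drug_prob,
    missing_start_prob = missing_start_prob,
    missing_event_prob = missing_event_prob,
    partial_date_prob = partial_date_prob, typo_prob = typo_prob,
    tto_default = tto_default, tto_lognormal = tto_lognormal,
    outcome_probs = outcome_probs, start_window = start_window),
    class = "sim_config")
}

# Independent enumeration of the two-step cleaning rule over the raw tables
# the generator just emitted, used as the sidecar's expected survivor set
# (and hence as an oracle for the dedup module). Step 1: per report_id keep
# the row with the latest receipt date (ties: largest uid). Step 2: among
# survivors, group on the six-field key (sex, age, country, receipt date,
# sorted PT multiset, sorted verbatim drug multiset; missing == missing)
# and keep the smallest report_id (ties: smallest uid). Distinct base
# reports that collide on the key by chance are genuine duplicates under
# the rule and are excluded here too.
.expected_survivors_oracle <- function(reports, drugs, reactions) {
  r <- reports
  dkey <- as.numeric(r$receipt_date)
  dkey[is.na(dkey)] <- -Inf
  ord <- order(r$report_id, dkey, r$uid)
  keep1 <- r$uid[ord][!duplicated(r$report_id[ord], fromLast = TRUE)]
  r <- r[r$uid %in% keep1, , drop = FALSE]
  sorted_join <- function(uid, val) {
    s <- vapply(split(val, factor(uid, levels = r$uid)),
                function(v) paste(sort(v), collapse = "\x1f"), character(1))
    s
  }
  key <- paste(r$patient_sex,
               ifelse(is.na(r$patient_age_years), "<NA>", r$patient_age_years),
               r$country,
               ifelse(is.na(r$receipt_date), "<NA>",
                      as.character(r$receipt_date)),
               sorted_join(reactions$uid[reactions$uid %in% r$uid],
                           reactions$pt[reactions$uid %in% r$uid]),
               sorted_join(drugs$uid[drugs$uid %in% r$uid],
                           drugs$verbatim_name[drugs$uid %in% r$uid]),
               sep = "\x1e")
  ord2 <- order(key, r$report_id, r$uid)
  sort(r$uid[ord2][!duplicated(key[ord2])])
}

# one-character substitution typos, vectorized over a character vector
.inject_typos <- function(x, which) {
  if (!any(which)) return(x)
  idx <- which(which & nchar(x) >= 3)
  for (i in idx) {
    pos <- sample.int(nchar(x[i]), 1)
    ch <- sample(letters[letters != tolower(substr(x[i], pos, pos))], 1)
    substr(x[i], pos, pos) <- ch
  }
  x
}

#' Generate a synthetic raw report set with ground truth
#'
#' Fully reproducible for a fixed seed. Each unique report draws one or two
#' drugs from the catalog, then each catalog PT independently with rate
#' \code{base_rate * max(lambda)} over the report's drugs; verbatim drug
#' spellings are sampled among the catalog synonyms (optionally with
#' injected typos). Reports with no drawn reaction receive the background PT
#' \code{"Malaise"} so every report has at least one reaction, as in real
#' extracts. Drug start dates are drawn uniformly in the window; the event
#' date sits a log-normal number of days after the start (pair-specific
#' parameters when configured); the receipt date follows the event by a
#' uniform 0-60 day reporting lag. Date degradation, duplicate submissions
#' (fresh report id, identical six-field dedup key), and earlier versions
#' (same report id, earlier receipt) are applied last.
#'
#' @param cfg \code{\link{sim_config}}
#' @return list: \code{reports} (raw report_set, pre-dedup) and
#'   \code{truth} sidecar list with \code{schema_version}, \code{seed},
#'   \code{n_unique}, \code{expected_survivor_uids},
#'   \code{duplicate_pairs}, \code{version_uids}, \code{planted_lambda},
#'   \code{tto_lognormal}, \code{tto_default}
#' @export
generate_reports <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_reports
  dcat <- cfg$drug_catalog
  ecat <- cfg$event_catalog

  ids <- sprintf("R%07d", seq_len(n))

  # demographics
  age <- round(pmin(pmax(stats::rnorm(n, 62, 15), 1), 100))
  age[stats::runif(n) < 0.2] <- NA
  sex <- sample(c("male", "female", "unknown"), n, replace = TRUE,
                prob = c(0.45, 0.48, 0.07))
  country <- sample(c("US", "JP", "DE", "FR", "CA", "GB", "CN", "unknown"),
                    n, replace = TRUE,
                    prob = c(0.50, 0.10, 0.08, 0.08, 0.05, 0.05, 0.04, 0.10))
  reporter <- sample(c("health_professional", "non_health_professional",
                       "unknown"), n, replace = TRUE,
                     prob = c(0.60, 0.35, 0.05))

  # drugs: first draw categorical by marginal_prob, optional second draw
  di1 <- sample.int(nrow(dcat), n, replace = TRUE,
                    prob = dcat$marginal_prob)
  has2 <- stats::runif(n) < cfg$second_drug_prob
  di2 <- ifelse(has2, sample.int(nrow(dcat), n, replace = TRUE,
                                 prob = dcat$marginal_prob), NA)
  di2[!is.na(di2) & di2 == di1] <- NA

  # per-report event rates: base_rate * max lambda over the report's drugs
  lam <- matrix(1, nrow(dcat), nrow(ecat),
                dimnames = list(dcat$ingredient, ecat$pt))
  if (nrow(cfg$planted_lambda))
    lam[cbind(match(cfg$planted_lambda$ingredient, dcat$ingredient),
              match(cfg$planted_lambda$pt, ecat$pt))] <- cfg$planted_lambda$lambda
  lam_rep <- lam[di1, , drop = FALSE]
  if (any(has2 & !is.na(di2))) {
    i2 <- which(!is.na(di2))
    lam_rep[i2, ] <- pmax(lam_rep[i2, , drop = FALSE],
                          lam[di2[i2], , drop = FALSE])
  }
  rate <- sweep(lam_rep, 2, ecat$base_rate, `*`)
  if (any(rate > 1)) stop("event rate above 1; lower lambda or base_rate")
  ev <- matrix(stats::runif(n * nrow(ecat)), n) < rate  # n x n_pt indicator

  # time to onset: pair-specific log-normal when a configured (drug, pt)
  # pair is present on the report, else the default
  med <- rep(unname(cfg$tto_default["median_days"]), n)
  sig <- rep(unname(cfg$tto_default["sigma"]), n)
  if (nrow(cfg$tto_lognormal)) {
    for (k in seq_len(nrow(cfg$tto_lognormal))) {
      tk <- cfg$tto_lognormal[k, ]
      je <- match(tk$pt, ecat$pt)
      jd <- match(tk$ingredient, dcat$ingredient)
      if (is.na(je) || is.na(jd)) stop("tto_lognormal pair not in catalogs")
      hit <- ev[, je] & (di1 == jd | (!is.na(di2) & di2 == jd))
      med[hit] <- tk$median_days
      sig[hit] <- tk$sigma
    }
  }
  days <- stats::rlnorm(n, meanlog = log(med), sdlog = sig)
  start <- cfg$start_window[1] +
    floor(stats::runif(n) * as.numeric(diff(cfg$start_window)))
  event_date <- start + round(days)
  receipt <- event_date + floor(stats::runif(n, 0, 61))

  # degrade dates
  start_missing <- stats::runif(n) < cfg$missing_start_prob
  event_missing <- stats::runif(n) < cfg$missing_event_prob
  start_partial <- !start_missing & stats::runif(n) < cfg$partial_date_prob
  start_precision <- ifelse(start_missing, "none",
                            ifelse(start_partial, "month", "day"))
  start_out <- start
  start_out[start_missing] <- NA
  start_out[start_partial] <- as.Date(format(start[start_partial], "%Y-%m-01"))
  event_out <- event_date
  event_out[event_missing] <- NA
  event_precision <- ifelse(event_missing, "none", "day")

  # outcomes: one categorical draw per report ("none" drops the row)
  oc <- sample(names(cfg$outcome_probs), n, replace = TRUE,
               prob = cfg$outcome_probs)

  reports <- data.frame(
    uid = ids, report_id = ids, case_id = ids,
    receipt_date = receipt, receipt_precision = "day",
    patient_age_years = age, patient_sex = sex, reporter_type = reporter,
    country = country,
    event_date = event_out, event_precision = event_precision,
    report_year = as.integer(format(receipt, "%Y")),
    stringsAsFactors = FALSE)

  # drug rows with verbatim spellings
  syn_list <- strsplit(dcat$synonyms, ";", fixed = TRUE)
  pick_syn <- function(di) {
    k <- lengths(syn_list)[di]
    mapply(function(s, j) s[j], syn_list[di],
           1L + floor(stats::runif(length(di)) * k))
  }
  d1 <- data.frame(uid = ids, verbatim_name = pick_syn(di1),
                   role = "primary_suspect",
                   start_date = start_out, start_precision = start_precision,
                   ingredient = NA_character_, drug_class = NA_character_,
                   stringsAsFactors = FALSE)
  i2 <- which(!is.na(di2))
  d2 <- if (length(i2)) data.frame(
    uid = ids[i2], verbatim_name = pick_syn(di2[i2]),
    role = "secondary_suspect",
    start_date = start_out[i2], start_precision = start_precision[i2],
    ingredient = NA_character_, drug_class = NA_character_,
    stringsAsFactors = FALSE) else NULL
  drugs <- rbind(d1, d2)
  drugs$verbatim_name <- .inject_typos(
    drugs$verbatim_name, stats::runif(nrow(drugs)) < cfg$typo_prob)

  # reaction rows; background filler keeps every report non-empty
  rr <- which(ev, arr.ind = TRUE)
  reactions <- data.frame(uid = ids[rr[, 1]], pt = ecat$pt[rr[, 2]],
                          stringsAsFactors = FALSE)
  empty <- !(ids %in% reactions$uid)
  if (any(empty))
    reactions <- rbind(reactions,
                       data.frame(uid = ids[empty], pt = "Malaise",
                                  stringsAsFactors = FALSE))
  outcomes <- data.frame(uid = ids[oc != "none"],
                         outcome = oc[oc != "none"],
                         stringsAsFactors = FALSE)

  # earlier versions: same report_id, receipt 30-210 days earlier
  vsel <- which(stats::runif(n) < cfg$version_prob)
  version_uids <- character(0)
  if (length(vsel)) {
    v <- reports[vsel, , drop = FALSE]
    v$uid <- paste0(v$uid, "#v1")
    v$receipt_date <- v$receipt_date - (30 + floor(stats::runif(length(vsel), 0, 181)))
    v$report_year <- as.integer(format(v$receipt_date, "%Y"))
    version_uids <- v$uid
    reports <- rbind(reports, v)
    copy_children <- function(tab) {
      ch <- tab[tab$uid %in% ids[vsel], , drop = FALSE]
      if (nrow(ch)) ch$uid <- paste0(ch$uid, "#v1")
      ch
    }
    drugs <- rbind(drugs, copy_children(drugs))
    reactions <- rbind(reactions, copy_children(reactions))
    outcomes <- rbind(outcomes, copy_children(outcomes))
  }

  # duplicate submissions: fresh report_id, identical six-field key
  dsel <- which(stats::runif(n) < cfg$dup_prob)
  duplicate_pairs <- data.frame(original_uid = character(),
                                duplicate_uid = character(),
                                stringsAsFactors = FALSE)
  if (length(dsel)) {
    dup <- reports[dsel, , drop = FALSE]
    new_id <- paste0(dup$report_id, "D")
    duplicate_pairs <- data.frame(original_uid = dup$uid,
                                  duplicate_uid = new_id,
                                  stringsAsFactors = FALSE)
    dup$uid <- new_id
    dup$report_id <- new_id
    dup$case_id <- new_id
    reports <- rbind(reports, dup)
    copy_children <- function(tab) {
      ch <- tab[tab$uid %in% ids[dsel], , drop = FALSE]
      if (nrow(ch)) ch$uid <- paste0(ch$uid, "D")
      ch
    }
    drugs <- rbind(drugs, copy_children(drugs))
    reactions <- rbind(reactions, copy_children(reactions))
    outcomes <- rbind(outcomes, copy_children(outcomes))
  }

  rs <- report_set(reports, drugs, reactions, outcomes,
                   log = list(n_unique = n,
                              n_versions = length(version_uids),
                              n_duplicates = nrow(duplicate_pairs)))
  truth <- list(
    schema_version = "1.0",
    seed = cfg$seed,
    n_unique = n,
    expected_survivor_uids = .expected_survivors_oracle(
      reports, drugs, reactions),
    duplicate_pairs = duplicate_pairs,
    version_uids = version_uids,
    planted_lambda = cfg$planted_lambda,
    tto_lognormal = cfg$tto_lognormal,
    tto_default = as.list(cfg$tto_default))
  list(reports = rs, truth = truth)
}

#' Check pipeline recovery of planted ground truth
#'
#' Given the deduplicated (and drug-mapped) report set and the generator's
#' truth sidecar, verifies: (1) the dedup survivors are exactly the unique
#' reports (every planted duplicate and version removed, nothing else);
#' (2) for each planted pair with lambda != 1, the estimated shrunk
#' reporting ratio lies within \code{ratio_tol * lambda}; (3) for each
#' configured time-to-onset pair, the estimated median lies within
#' \code{tto_tol * median_days}.
#'
#' @param cleaned deduplicated report_set (mapped with
#'   \code{\link{map_drugs}} if ratio checks are wanted)
#' @param truth sidecar list from \code{\link{generate_reports}}
#' @param ratio_tol multiplicative envelope around lambda, default
#'   c(0.8, 1.25)
#' @param tto_tol multiplicative envelope around the configured median,
#'   default c(0.93, 1.08)
#' @param cfg shrinkage_config
#' @return data.frame of checks: check, target, estimate, pass
#' @export
truth_check <- function(cleaned, truth, ratio_tol = c(0.8, 1.25),
                        tto_tol = c(0.93, 1.08),
                        cfg = shrinkage_config()) {
  if (is.null(truth$expected_survivor_uids))
    stop("truth sidecar lacks expected_survivor_uids; schema mismatch")
  checks <- list()
  survivors <- cleaned$reports$uid
  exact <- setequal(survivors, truth$expected_survivor_uids)
  checks[[1]] <- data.frame(check = "dedup_exact_recovery",
                            target = 1, estimate = as.numeric(exact),
                            pass = exact, stringsAsFactors = FALSE)
  pl <- truth$planted_lambda
  if (!is.null(pl) && nrow(pl)) {
    for (k in seq_len(nrow(pl))) {
      if (pl$lambda[k] == 1) next
      tab <- build_contingency(cleaned, pl$ingredient[k],
                               pt_predicate(pl$pt[k]), role = "suspect")
      est <- shrunk_ratio(tab, cfg)
      pass <- est >= ratio_tol[1] * pl$lambda[k] &
        est <= ratio_tol[2] * pl$lambda[k]
      checks[[length(checks) + 1]] <- data.frame(
        check = paste0("lambda_recovery:", pl$ingredient[k], ":", pl$pt[k]),
        target = pl$lambda[k], estimate = est, pass = pass,
        stringsAsFactors = FALSE)
    }
  }
  tl <- truth$tto_lognormal
  if (!is.null(tl) && nrow(tl)) {
    for (k in seq_len(nrow(tl))) {
      tt <- compute_tto(cleaned, tl$ingredient[k], pt_predicate(tl$pt[k]))
      if (!nrow(tt$records)) next
      est <- summarize_tto(tt$records)$median
      pass <- est >= tto_tol[1] * tl$median_days[k] &
        est <= tto_tol[2] * tl$median_days[k]
      checks[[length(checks) + 1]] <- data.frame(
        check = paste0("tto_recovery:", tl$ingredient[k], ":", tl$pt[k]),
        target = tl$median_days[k], estimate = est, pass = pass,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, checks)
  rownames(out) <- NULL
  out
}
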