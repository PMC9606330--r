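---
title: "Disproportionality signal detection for spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for spontaneous reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse Event
Reporting System (FAERS) collect millions of voluntary reports linking drugs
to suspected adverse events. They have no denominator — nobody knows how many
patients took each drug — so absolute risks cannot be estimated. What can be
estimated is *disproportionality*: whether a particular adverse event is
reported more often with a target drug than the rest of the database would
predict under independence. `pvsignal` implements a complete desk-scale
pipeline for this kind of case/non-case analysis: ingestion of FAERS-style
quarterly tables, deduplication, vocabulary normalization, shrinkage-
transformed disproportionality statistics, time-to-onset and outcome-severity
summaries, and a synthetic report generator with planted ground truth so that
every stage can be validated without downloading a multi-gigabyte database.

## The statistical model

Each analysis reduces the cleaned database to a report-level 2×2 contingency
table for one drug set and one event set:

|                | target event | other events | total            |
|----------------|--------------|--------------|------------------|
| target drug    | $a$          | $b$          | $N_{drug}=a+b$   |
| other drugs    | $c$          | $d$          | $c+d$            |
| total          | $N_{event}=a+c$ | $b+d$     | $N_{total}$      |

The counting unit is the deduplicated report: a report with three matching
PTs and two matching drugs still contributes 1 to cell $a$. The expected
count under independence is
$N_{expected} = N_{drug} \cdot N_{event} / N_{total}$.

Two shrinkage-transformed statistics are computed from the same shrunk
observed/expected ratio:

$$\mathrm{ROR} = \frac{N_{observed} + 0.5}{N_{expected} + 0.5}, \qquad
\mathrm{IC} = \log_2 \frac{N_{observed} + 0.5}{N_{expected} + 0.5}$$

The additive constant 0.5 stabilizes small-count cells and pulls extreme
ratios toward 1 (`shrunk_ratio()` is defined even at $a = 0$, where an empty
target cell gives exactly 1 when the expectation is also 0). Because both
statistics derive from the same ratio, the identity
$\mathrm{IC} = \log_2 \mathrm{ROR}$ holds exactly on every output row, and
the test suite asserts it.

The 95% bounds use closed forms in the observed count $N$:

$$\mathrm{IC}_{025} = \mathrm{IC} - 3.3\,(N+0.5)^{-1/2} - 2\,(N+0.5)^{-3/2}$$
$$\mathrm{IC}_{975} = \mathrm{IC} + 2.4\,(N+0.5)^{-1/2} - 0.5\,(N+0.5)^{-3/2}$$

Both half-widths are strictly decreasing in $N$, so intervals tighten
monotonically as evidence accumulates. The ROR confidence interval uses the
classical log-scale standard error
$\sqrt{1/a + 1/b + 1/c + 1/d}$ with $z = 1.96$; it is undefined whenever any
cell is zero, in which case `ror_ci()` returns flagged `NA` bounds rather
than substituting a continuity correction.

**A deliberate ambiguity, resolved explicitly.** In this shrinkage
formulation the "ROR" point estimate is an observed/expected reporting
ratio, not the classical odds ratio $ad/bc$, yet the interval formula is the
classical odds-ratio standard error. Back-calculating published lower bounds
reproduces neither construction exactly. `ror_ci(point =)` therefore exposes
both point estimates — `"shrunk"` (default, matching the single published
ROR column) and `"classical"` — and the acceptance checks rely only on the
IC columns, whose closed forms reproduce the published cells bit-for-bit at
their printed precision. Relatedly, the upper IC bound is occasionally
labelled "IC075" in print; it is the 97.5th percentile bound and is named
`ic_high`/IC975 here.

**Signal rule.** A drug–event pair is flagged (`detect_signal()`) when it
has at least `min_reports = 3` reports and either $\mathrm{ROR}_{025} > 1$
or $\mathrm{IC}_{025} > 0$. An undefined ROR bound never satisfies its
clause. All constants live in `shrinkage_config()` and are tunable:
`shrinkage_k` (0.5, dimensionless), `z` (1.96), the four IC bound constants
(3.3, 2, 2.4, 0.5), and `min_reports` (3 reports).

## Data cleaning

Spontaneous databases contain both *versions* (follow-ups of one case under
the same report id) and *duplicates* (the same case submitted through
different channels under different ids). Cleaning is two-step:

1. `keep_last_version()` keeps, per report id, the row with the latest
   receipt date. Partial dates (year or year-month precision) are compared
   by their earliest consistent calendar date; ties keep the
   lexicographically largest row key, since version numbers grow with id in
   practice.
2. `drop_field_duplicates()` removes reports identical on a six-field key:
   patient sex, patient age, reporter country, receipt date, the sorted
   multiset of reaction PTs, and the sorted multiset of *verbatim* drug
   names. The survivor is the smallest report id. Missing values compare
   equal to each other: missingness is treated as a value of the field, a
   documented and testable choice. The key uses verbatim (pre-mapping) drug
   names because deduplication precedes dictionary normalization in the
   pipeline flow.

Both steps are idempotent, log their removal counts, and never mutate
surviving records; property tests check all three claims, and the generator
plants duplicates/versions whose exact recovery is asserted over 100 seeds.

## Vocabulary normalization

Drugs arrive as free text (generic names, brand names, research codes,
misspellings). `read_drug_archive()` loads a synonym → ingredient + class
archive and fails loudly on synonym collisions; `normalize_drug()`
canonicalizes (case-fold, trim, strip punctuation), splits combination
products on `/` and `+`, and optionally accepts a *unique* synonym at edit
distance 1 (`fuzzy = TRUE`; default off, because a conservative default
avoids false mappings and the misspelling rate is unknown). The bundled
archive covers 21 antiangiogenic agents (VEGF/VEGFR-targeted monoclonal
antibodies, the VEGF trap, oral multi-kinase TKIs, and recombinant human
endostatin) with common brand names and research codes; it was curated by
the package authors and is replaceable by any CSV with the same columns.

Reaction PTs map into Standardised MedDRA Queries via
`read_smq_definitions()` / `map_pt_to_smqs()`, narrow scope only, with
parent closure: membership in a sub-SMQ (e.g. venous thromboembolic events)
implies membership in its parent (embolic and thrombotic events). MedDRA is
licensed content, so the package bundles only the nine standard
cardiovascular SMQ names and codes as a header-only file plus a clearly
labelled *synthetic* membership fixture for tests; real analyses require a
user-supplied SMQ membership CSV.

## Time to onset and outcomes

Time to onset is the day count from the earliest day-precision start date of
a matching drug row (first exposure, a documented choice where several rows
of the same ingredient carry dates) to the report's event date. Exclusions
are values, not errors, and each is counted: `missing_start`,
`missing_event`, `partial_date` (day arithmetic is undefined below day
precision), and `negative_interval` (start after onset is aberrant).
Same-day onset is kept. Summaries use type-7 linear-interpolation quartiles
— the convention is not dictated by the method, so the package states one —
plus cumulative onset proportions at 30 and 90 days.

Outcome severity uses one category per report by precedence (death >
life-threatening > hospitalization > disability > congenital anomaly >
other serious), under which category percentages over reports with any
outcome sum to exactly 100; `mode = "all"` counts every recorded category as
a sensitivity analysis, and the denominator (all reports vs reports with an
outcome) is configurable with "all reports" as the default.

## The synthetic generator: what it emulates and what it does not

`sim_config()` / `generate_reports()` produce FAERS-like raw report sets:
demographics, one or two drugs per report drawn from a catalog with verbatim
spellings sampled among synonyms (optional single-character typos), each
catalog event drawn independently per report with rate
$\text{base rate} \times \lambda(\text{drug}, \text{pt})$ using the maximum
$\lambda$ over the report's drugs (maximum rather than product keeps each
planted pair interpretable on its own), log-normal onset intervals,
uniform 0–60-day reporting lag, configurable missingness and partial-date
degradation, exact-key duplicate clones under fresh ids, and earlier
versions under the same id. Every run is reproducible from its seed, and a
truth sidecar records the planted duplicates, versions, $\lambda$ values,
and onset parameters. The sidecar's expected survivor set is computed by an
independent enumeration of the cleaning rule inside the generator, so
deduplication is checked against a second implementation, not against
itself.

Defaults are chosen to look like a plausible reporting stream: target agents
at ~2% marginal reporting probability, rare target events at 0.4–1% base
rates, common background reactions, 5% duplicates and 5% versions, 30% date
missingness. Where a validation scenario needs specific conditions, they are
stated in the test itself (e.g. base event rate 0.01 and drug rate 0.02 at
$n = 10^5$ reports for calibration and recovery runs; log-normal median 23
days with $\sigma = 1$ at $n = 5000$ for onset recovery).

The generator deliberately does **not** model secular reporting trends,
stimulated reporting after safety communications, notoriety bias,
drug–drug interaction effects on reporting, or correlated event clusters
within reports. Passing tests therefore demonstrate that the pipeline's
arithmetic and bookkeeping are correct under known conditions — they do not
demonstrate that shrinkage disproportionality statistics are unbiased on
real spontaneous data, where all of those mechanisms operate.

## Operating characteristics checked by the test suite

* 2×2 construction matches an independent brute-force per-report classifier
  on 1,000 random instances of up to 20 reports.
* Under planted independence ($\lambda \equiv 1$; 20 drug–event pairs,
  $10^5$ reports, 10 seeds) at most 5% of null pairs cross
  $\mathrm{IC}_{025} > 0$; the shrunk bound is conservative, so the observed
  exceedance is typically far below that.
* A planted $\lambda = 4$ on a rare pair is recovered within
  $[3.2, 5.0]$ with a positive $\mathrm{IC}_{025}$ on 10/10 seeds. The
  shrunk ratio estimates the *disproportionality* of the pair, which sits
  slightly below the planted event-rate multiplier because the boosted pair
  also inflates the event margin; the envelope accounts for this.
* A configured 23-day onset median is recovered within $[21.4, 24.8]$ at
  $n = 5000$.

These problem sizes keep the full suite around four minutes on one CPU.

## Numerical and rendering choices

* Full precision is kept internally everywhere; `round_half_away()`
  (round-half-away-from-zero) is applied only when rendering, matching
  publication tables at 2 decimals for ROR/IC columns and 1 decimal for
  percentages.
* Printed count columns render as `N (pct)` with the panel total as the
  denominator. Published tables of this kind occasionally print percentages
  inconsistent with their own totals (e.g. a row whose count/total gives
  32.8% printed as 31.8%); the package always reports count over panel
  total.
* Partial dates carry an explicit precision tag (`year`, `month`, `day`)
  and expand to the earliest consistent date only where an ordering is
  needed; impossible calendar dates parse to missing with a counter, never
  silently.
* The default role filter counts primary and secondary suspect drugs as
  exposure, configurable to all roles; the restriction is a convention, not
  a published rule, so it is stated prominently wherever it applies.
* In class-vs-class comparisons a report exposed to agents of both classes
  appears in each class's exposure set; dual-exposed reports can be excluded
  by filtering the ingredient sets before calling `build_contingency()`.

## Known limitations

* Exact-key deduplication only; no probabilistic record linkage. Two
  genuinely distinct reports that coincide on all six key fields are
  removed as duplicates — rare, but possible, and the generator's oracle
  accounts for it.
* PT→SMQ mapping is flat membership plus parent closure; the full MedDRA
  hierarchy (HLT/HLGT/SOC) is not traversed.
* No multiplicity adjustment across panel rows, matching standard practice
  for this family of statistics; wide panels will contain false positives
  at the rule's operating point.
* The legacy pre-2012 AERS schema and XML E2B dialect are not parsed; the
  normalized model is dialect-agnostic (field semantics follow the public
  quarterly extracts, and the interchange CSV is the canonical internal
  format).
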