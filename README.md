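# pvsignal

Disproportionality signal detection for spontaneous adverse-event report
databases, in R.

Spontaneous reporting systems (FAERS-style) collect voluntary reports linking
drugs to suspected adverse events, with no exposure denominator. The standard
way to mine them is case/non-case **disproportionality analysis**: for a
target drug set and a target event set, reduce the cleaned database to a
report-level 2×2 table

|              | target event | other events |
|--------------|--------------|--------------|
| target drug  | a            | b            |
| other drugs  | c            | d            |

with N<sub>expected</sub> = (a+b)(a+c)/N<sub>total</sub>, and compute
shrinkage-transformed statistics

```
ROR = (N_observed + 0.5) / (N_expected + 0.5)
IC  = log2( (N_observed + 0.5) / (N_expected + 0.5) )

IC025 = IC − 3.3·(N+0.5)^−1/2 − 2·(N+0.5)^−3/2
IC975 = IC + 2.4·(N+0.5)^−1/2 − 0.5·(N+0.5)^−3/2
ROR 95% CI = exp( ln(ROR) ± 1.96·sqrt(1/a + 1/b + 1/c + 1/d) )
```

A drug–event pair is a **signal** when it has at least 3 reports and
ROR025 > 1 or IC025 > 0.

The package is aimed at pharmacoepidemiologists and methodologists who want
the full pipeline — not just the formulas — reproducible at desk scale:

* **ingest** — FAERS-style `'$'`-delimited quarterly tables
  (DEMO/DRUG/REAC/OUTC/THER) and a normalized single-table CSV interchange
  format; partial dates carry precision tags; every normalization failure is
  counted, never silently dropped.
* **dedup** — two-step cleaning: keep the last version per report id, then
  drop reports identical on a six-field key (sex, age, reporter country,
  receipt date, reaction PT multiset, verbatim drug-name multiset).
* **vocab** — verbatim drug strings → ingredient + class via a synonym
  archive (21 antiangiogenic agents bundled; optional edit-distance-1 fuzzy
  matching); reaction PTs → narrow-scope SMQ groupings with parent closure
  (user-supplied membership CSV; MedDRA is licensed).
* **signal_stats** — report-level 2×2 tables, shrunk ROR/IC with interval
  bounds, the signal rule, analysis panels, and per-PT spectra.
* **tto** — time to onset (drug start → event onset) with counted exclusion
  reasons, type-7 quartiles, and 30/90-day cumulative proportions.
* **outcomes** — severity tabulation with one-category-per-report precedence
  and a combined death + life-threatening metric.
* **synthetic_data** — a seeded generator of FAERS-like report sets with
  planted reporting-ratio multipliers, duplicates, versions, typos, and
  log-normal onset times, plus a ground-truth sidecar and `truth_check()`.
* **run_study / render_tables** — end-to-end orchestration with a
  flowchart-style count log and publication-style table rendering.

## Worked example

A small synthetic study with a planted four-fold hypertension signal on
bevacizumab:

```r
library(pvsignal)

archive <- read_drug_archive(system.file("extdata", "drug_archive.csv",
                                         package = "pvsignal"))
defs <- read_smq_definitions(system.file("extdata",
                                         "smq_members_synthetic.csv",
                                         package = "pvsignal"))

sim <- sim_config(
  n_reports = 20000, seed = 42,
  planted_lambda = data.frame(ingredient = "bevacizumab",
                              pt = "Hypertension", lambda = 4),
  tto_lognormal = data.frame(ingredient = "bevacizumab",
                             pt = "Hypertension",
                             median_days = 23, sigma = 1))

bundle <- run_study(
  sim = sim, archive = archive, defs = defs,
  panels = list(
    list(name = "bevacizumab ~ hypertension (SMQ)",
         drugs = "bevacizumab", events = list(smq = 20000147)),
    list(name = "TKI class ~ hypertension (SMQ)",
         drugs = "class:TKI", events = list(smq = 20000147))),
  tto_groups = list(hypertension = smq_predicate(20000147)))
bundle
#> <study_bundle>
#>   stage counts:
#>     n_raw                        21,958
#>     n_after_version_filter       21,006
#>     n_after_dedup                19,974
#>     n_versions_removed           952
#>     n_duplicates_removed         1,032
#>     n_target_drug_reports        1,177
#>     n_target_event_reports       685
#>     n_target_drug_event_reports  49
#>   panel rows: 2
#>   spectrum PTs: 10

render_tables(bundle)$panel
#>                          analysis         N  ROR ROR025 ROR975   IC IC025 IC975 signal
#>  bevacizumab ~ hypertension (SMQ) 19 (67.9) 2.45   1.53   3.94 1.30  0.52  1.83    yes
#>    TKI class ~ hypertension (SMQ)  9 (32.1) 1.12   0.58   2.20 0.17 -0.97  0.93     no
```

Reading the first row: 19 deduplicated reports carry both bevacizumab (as a
suspect drug) and a hypertension-SMQ reaction; that is 2.45 times what
independence predicts after shrinkage, IC = log2(2.45) = 1.30, and the lower
IC bound 0.52 is above 0 with N ≥ 3, so the planted association is flagged.
The TKI class row, where nothing was planted, stays below both thresholds.
The generator's receipts: 952 version resubmissions and 1,032 exact-key
duplicates were removed by the two cleaning steps before any counting.

The onset summary for the same bundle recovers the planted 23-day log-normal
median from the admissible records and accounts for every exclusion:

```r
render_tables(bundle)$tto
#>         group  n median   q1   q3 pct_30d pct_90d excluded_missing_start ...
#>  hypertension 19   25.0 17.0 54.0    52.6    89.5                     10 ...
```

Single statistics are available directly. The interval formulas reproduce
published worked examples at their printed precision — for a row with
N = 71 and shrunk ROR 2.60:

```r
out <- ic_stats(71, 2.60)
round_half_away(out, 2)
#>     ic ic_low ic_high
#>   1.38   0.98    1.66
```

## Notes

* The bundled SMQ *membership* file is synthetic (MedDRA is licensed); real
  analyses need a user-supplied membership CSV with columns
  `smq_code,smq_name,scope,parent_code,pt_name`. The nine standard
  cardiovascular SMQ names/codes ship as a header-only file.
* The drug-name archive was curated by the package authors and is
  replaceable by any CSV with columns `synonym,ingredient,class,region`.
* See `vignettes/pvsignal-methods.Rmd` for the model, the design decisions
  (role filter, duplicate key semantics, quartile convention, the ROR CI
  point-estimate ambiguity), and what the synthetic generator does and does
  not emulate.
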