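# pvsignal

Disproportionality signal detection for spontaneous adverse-event
reports.

Post-marketing drug safety surveillance relies on spontaneous reporting
systems (SRS) such as FAERS: voluntary case reports with no exposure
denominator, heavy missingness, duplicated submissions and strongly
skewed event reporting. `pvsignal` is an R package for analysts mining
such extracts (e.g. OpenVigil-style one-row-per-report-drug-event CSV/TSV
exports). It covers the full workflow:

* **Curation** — ingestion with lenient field parsing, case-level
  deduplication (latest report year wins), primary-suspect role
  filtering, and conserved provenance counts at every exclusion step.
* **Descriptive epidemiology** — report distributions over country,
  region, year, sex, age bin and unfavorable outcomes; per-term reporting
  rates `R = 100·n/N`; top-k preferred terms; System Organ Class
  aggregation against a user-supplied PT→SOC mapping (MedDRA is licensed
  and never bundled).
* **Disproportionality** — per-term 2×2 contingency tables with
  report-level counting and the standard SRS statistics:

  |          | event | no event |
  |----------|-------|----------|
  | drug     | a     | b        |
  | other    | c     | d        |

  PRR `= [a/(a+b)]/[c/(c+d)]`; ROR `= ad/bc` with the Woolf interval
  `exp(ln ROR ± z₁₋α/₂√(1/a+1/b+1/c+1/d))`; χ² in closed 2×2 form with
  optional (default) Yates continuity correction; Haldane–Anscombe +0.5
  zero-cell handling; and the conventional Evans positive-signal rule
  n > 2, χ² > 4, PRR > 2. `bubble_coordinates()` emits the
  (log₂ROR, √χ², n) strength-plot table without rendering it.
* **Synthetic SRS generation** — a seeded generator with a Zipf-skewed
  event background, realistic missingness, case-id duplicates, and
  injected drug–event associations calibrated to an exact report-level
  odds ratio, plus a truth ledger and `recovery_report()` scoring, so the
  whole pipeline is testable without database access.

## Worked example

Simulate a database with two injected associations, curate it, and scan:

```r
library(pvsignal)

cfg <- synth_config(n_reports = 5000, seed = 42,
                    injected_signals = c("DRUG INDUCED TREMOR" = 10,
                                         "ACUTE KIDNEY INJURY" = 4))
extract <- tempfile(fileext = ".csv")
sim <- simulate_reports(cfg, extract)

db <- deduplicate(read_reports(extract))
db
#> <report_db> 5000 reports, 16075 (report, PT) occurrences, 591 distinct PTs
#>   provenance: 17699 rows read, 5500 report versions, 500 duplicates removed, 0 role-excluded
#>   deduplicated: TRUE; role filtered: FALSE

scan <- signal_scan(db, "DRUG_X")
dplyr::filter(scan, is_signal)[, c("pt", "a", "n", "prr", "ror", "chi2")]
#> # A tibble: 6 × 6
#>   pt                      a     n   prr   ror   chi2
#> 1 DRUG INDUCED TREMOR    30    30  9.06  9.63 109.
#> 2 ACUTE KIDNEY INJURY    25    25  6.08  6.37  63.3
#> 3 EVT_0068                6     6  2.85  2.87   4.15
#> 4 EVT_0194                4     4 19.9  20.1   17.6
#> 5 EVT_0360                4     4  6.64  6.69   8.10
#> 6 EVT_0266                3     3  7.47  7.52   5.98

recovery_report(scan, sim$truth)$summary
#> # A tibble: 1 × 5
#>   n_injected detected sensitivity false_positives mean_log_ror_bias
#> 1          2        2           1               4             0.214
```

Reading the output: 500 injected duplicate versions were removed exactly;
both injected associations are recovered as signals with ROR estimates
(9.63, 6.37) near their true values (10, 4); four background terms also
pass the strict thresholds — the expected few-per-scan false positives of
unadjusted Evans criteria, which is why scan results are hypothesis-
generating, not conclusions. The same workflow applies unchanged to a
real extract: point `read_reports()` at the export, supply your PT→SOC
mapping to `load_pt_soc()`, and use your drug of interest.

`run_pipeline(pipeline_config(...))` performs the whole flow and writes
curated data, provenance, descriptive tables, the signal table and
bubble coordinates; `inst/cli/pvsignal.R` exposes it as a command line
(`simulate`, `ingest`, `describe`, `signals`, `plot-coords`, `run`).

The methods vignette (`vignettes/disproportionality-methods.Rmd`)
documents the statistical model, the zero-cell and rounding conventions,
the generator's design and its limits.

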