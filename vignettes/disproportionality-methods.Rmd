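---
title: "Disproportionality signal detection in spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection in spontaneous reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous reporting systems (SRS) such as FAERS collect voluntary
adverse-event reports for marketed drugs. They have no denominator of
exposed patients, heavy missingness in demographics, duplicated
submissions of the same case, and strong reporting skew: a handful of
event terms dominate the database. Signal detection in this setting does
not estimate risk; it asks whether a drug–event pair is reported
*disproportionately* often relative to everything else in the database.
`pvsignal` implements that workflow end to end — curation, descriptive
epidemiology, disproportionality statistics, signal classification — plus
a synthetic SRS generator so the whole pipeline can be validated against a
known ground truth.

## Report curation

A raw extract has one row per (report, drug, event). `read_reports()`
groups rows into report versions keyed by (case id, report year): a
resubmitted case keeps its case id but carries a later year. Within a
version, events are collapsed to a set of normalized preferred terms (PTs)
and demographics take the first non-missing value. Unparseable optional
fields become missing values with a warning, never errors — real SRS
extracts are messy, and losing a report over a malformed age would bias
the curated series.

`deduplicate()` keeps, per case id, the version with the latest report
year (a missing year loses to any known year). The rationale: later
submissions of a FAERS case supersede earlier ones, so the freshest
version is authoritative. Because equal-year rows merge into one version
at read time, distinct versions of a case always differ in year and the
rule is decisive.

`filter_by_role()` then derives the curated case series: reports where
the drug of interest carries the configured role, by default the primary
suspect. A report qualifies if *any* mention of the drug has that role —
the filter operates on reports, not rows. Drug matching is exact after
upper-casing and whitespace normalization; no synonym or active-ingredient
expansion is attempted, which is a deliberate limitation (ingredient
dictionaries are licensed and extract-specific).

Provenance is conserved at every step: report versions read = reports
kept + duplicates removed + role exclusions, and the pipeline logs each
exclusion count.

## Descriptive layer

`distribution()` tabulates reports by country, region (a bundled UN M49
continental lookup), year, sex, age bin or outcome. Missing demographics
are first-class categories (`NS`, `UNKNOWN`) because in SRS data they
usually dominate — a curated series can easily have ~90% missing sex and
~93% missing age, and hiding that would misrepresent the data. Age bins
are fixed at `<18`, `18–64`, `65–85`, `>85`, `NS`; the extreme bins are
kept even when empty so tables are exhaustive. Outcome rows are
non-exclusive (one report can carry both hospitalization and death), so
they do not sum to the case total; every exclusive dimension does.

The reporting rate of a PT is `R = 100 · n / N` where `n` is the number
of curated reports carrying the term and `N` the case total. One
*occurrence* is one (report, PT) pair after within-report collapse; the
same counting unit drives `pt_occurrences()`, `top_terms()` and the SOC
aggregation, so their totals agree by construction. R is descriptive
only: it compares nothing against a background, which is exactly why the
disproportionality layer exists.

All printed percentages use half-up rounding to one decimal
(`round_half_up()`), the convention that matches published
pharmacovigilance tables; banker's rounding would disagree on exact
halves. Over `k` categories the rounded percent column can drift from 100
by up to `k × 0.05`.

MedDRA is licensed, so the package bundles no dictionary content: the
PT→SOC mapping is user-supplied as a two-column file, and the shipped
`synthetic_pt_soc.tsv` fixture is a synthetic stand-in for examples only.
Terms absent from the mapping are routed to the reserved class
`UNMAPPED` so SOC counts always partition the occurrence total.

## Disproportionality statistics

For each PT the 2×2 table against the rest of the database is

|          | event | no event |
|----------|-------|----------|
| drug     | a     | b        |
| other    | c     | d        |

with report-level counting (a report counts once per PT). The statistics
are the standard SRS forms:

* **PRR** `= [a/(a+b)] / [c/(c+d)]` — the event's share among the drug's
  reports relative to its share elsewhere.
* **ROR** `= ad / bc`, with the Woolf (log-scale Wald) interval
  `exp(ln ROR ± z₁₋α/₂ √(1/a + 1/b + 1/c + 1/d))`, α = 0.05 by default;
  the z quantile is computed via `qnorm`, not hard-coded.
* **χ²** in the closed 2×2 form `N(ad − bc)² / [(a+b)(c+d)(a+c)(b+d)]`;
  with Yates' continuity correction the deviation `|ad − bc|` is reduced
  by `N/2` and floored at zero. The corrected form is the default for
  classification — the classical signal criteria were formulated with
  it — and the flag is recorded in every output row. Both forms agree
  with `stats::chisq.test()` to machine precision.

Two algebraic identities hold for all positive tables and are enforced by
property tests: PRR − 1 and ROR − 1 share their sign, and ROR ≥ PRR
whenever both exceed 1.

**Zero cells.** The default policy is the Haldane–Anscombe correction:
+0.5 on *all four* cells, applied only when some cell is zero, with the
row flagged (`zero_corrected`). A strict mode errors instead, for callers
who refuse corrected estimates. Applying the correction to every cell
(not just the zero one) keeps the estimator's standard small-sample
behaviour.

**Classification.** The conventional positive-signal rule: case count
n > 2 (i.e. n ≥ 3), χ² > 4, PRR > 2, all strict inequalities — a
published signal with n = 3 confirms the strictness of the case gate.
Thresholds are configurable via `signal_criteria()`. No
multiple-comparison adjustment is applied, matching standard SRS
practice; the false-positive behaviour of the strict thresholds is
instead characterized empirically on null synthetic databases.

`signal_scan()` applies all of the above to every PT observed with the
drug, against the complete deduplicated database (the comparator
background is every report outside the curated series). Output order is
deterministic: n descending, then PT alphabetically.
`bubble_coordinates()` emits the conventional strength plot as data —
x = log₂ROR, y = √χ², size = n — leaving rendering to the caller.

## The synthetic generator

`synth_config()` / `simulate_reports()` produce extracts with the
statistical structure the analysis assumes, so every stage can be tested
without a real database:

* **Event background:** each report carries `1 + Poisson(μ − 1)` events
  (so never zero), sampled without replacement from a Zipf-weighted
  (weight ∝ 1/rank) vocabulary — a few PTs dominate, as in real SRS data.
* **Injected associations:** each injected term enters a report as an
  independent Bernoulli draw with probability
  `calibrate_event_prob(ROR, q₀) = r·q₀ / (1 − q₀ + r·q₀)` on
  primary-suspect target reports and `q₀` elsewhere, making the
  report-level ROR the directly calibrated quantity — the same counting
  unit the analysis uses.
* **Duplicates:** a configurable fraction of reports is re-emitted as an
  earlier version (same case id, year − 1), which deduplication removes
  exactly.
* **Truth ledger:** realized a/b/c/d cells are recounted from the emitted
  reports, so `recovery_report()` can score sensitivity, false positives
  and log-ROR bias against exact ground truth.

Defaults encode the marginal structure of a curated post-marketing series
for a recently approved specialty drug: 593 candidate PTs, mean 3.173
events per report, country weights led by one country at 84% (then 5%,
3.6%, and a tail), 90% missing sex, 92.6% missing age, and 92.8% of the
target drug's mentions as primary suspect. Where no published marginal
exists, values were chosen once at what a pharmacoepidemiologist would
call realistic scale and not revisited: 5,000 reports with 10% on the
target drug (the scale of the recovery experiments, giving expected
a ≈ 40 for an injected ROR of 10 at baseline probability 0.009), a 10%
duplication rate, and a female-to-male ratio of 3.4:1 among the ~10% of
reports with known sex. The generator is fully deterministic given its
seed and restores the caller's RNG state.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: drug synonym noise and ingredient-level
coding, reporting waves over time (the Weber effect), masking and
competition bias between drugs, correlated event co-reporting beyond the
shared Zipf background, and MedDRA coding drift across versions.

## Numerical and design choices

* Percent rounding: half-up at one decimal, everywhere a percent is
  printed; internal computation is never rounded.
* Cell arithmetic is done in doubles: products like `ad` overflow 32-bit
  integers at realistic database sizes.
* Chi-square requires all four marginals positive and errors otherwise;
  PRR requires comparator events (after the zero-cell policy).
* Ties in every ranking (top terms, scan order) break alphabetically, so
  all outputs are reproducible byte for byte.
* A report with several mentions of the target drug at different roles is
  categorized, for the role distribution, by its highest-precedence role
  (primary suspect > secondary suspect > concomitant > interacting), so
  each report counts once.
* The role filter, by contrast, is an any-mention rule at the requested
  role, because curation selects reports.

## Validation strategy and problem sizes

The test suite validates each layer against an independent oracle:
hand-enumerated fixtures for ingestion and curation; brute-force
double-loop counting for contingency cells; `stats::chisq.test()` and an
expected-counts Σ(O−E)²/E implementation for χ²; frozen hand arithmetic
for PRR/ROR/CI values; and simulation for the frequentist properties. The
standard problem sizes are: 200 random tables for the χ² oracle and the
algebraic identities, 2,000 binomial-margin tables (n = 300 per arm, true
OR 2) for CI coverage — the Woolf interval covers within 95% ± 1.5% there
— 20 replicates of 5,000 reports for recovery of an injected ROR of 10
(mean |log-ROR bias| ≤ 0.1, sensitivity 1), and 50 null replicates of
1,000 reports for the empirical false-positive rate of the Evans
thresholds (a few percent of scanned PTs, stable across seeds). A curated
782-case fixture constructed to published marginal counts checks every
percentage the descriptive layer prints.

## Known limitations

Disproportionality is hypothesis-generating, not causal: a signal means
"reported more than expected under independence", nothing more. PRR/ROR
magnitudes from different databases are not comparable. The package
deliberately omits Bayesian shrinkage methods (BCPNN, EBGM), PT-synonym
clustering, and any live database querying; with very small comparator
backgrounds the χ² approximation itself is fragile, which is why the
classifier keeps the n ≥ 3 gate.
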