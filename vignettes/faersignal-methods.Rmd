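---
title: "Disproportionality signal detection on FAERS-style report data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on FAERS-style report data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
library(data.table)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse Event
Reporting System (FAERS) accumulate millions of individual case safety
reports: who reported, which drugs the patient took and in which role,
which reactions occurred (coded as MedDRA preferred terms, PTs), outcomes,
and therapy dates. Post-marketing surveillance asks whether a particular
drug-event pair is reported *disproportionately* often relative to the
rest of the database. There is no denominator of exposed patients, so all
inference is on reporting rates, not incidence: a disproportionality
signal is a statistical association in the reporting stream, never a
causal claim.

`faersignal` implements the full analysis chain for this question —
ingestion of the FAERS quarterly ASCII dialect, case deduplication,
cohort assembly for a target drug, four disproportionality estimators
with conventional signal criteria at PT and SOC (system organ class)
level, and the descriptive summaries that accompany such analyses — plus
a synthetic data generator with known ground truth so that every stage is
testable without the multi-gigabyte FAERS download.

## The 2×2 table and the four estimators

For one drug-event pair the database collapses to

|                  | target event | other events |
|------------------|--------------|--------------|
| target drug      | a            | b            |
| all other drugs  | c            | d            |

with \(N = a+b+c+d\). The four estimators, in the closed forms this
package implements:

* **ROR** (reporting odds ratio): \(\mathrm{ROR} = ad/bc\), with
  \(95\%\,\mathrm{CI} = \exp\{\ln \mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d}\}\).
* **PRR** (proportional reporting ratio):
  \(\mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)}\), accompanied by the Pearson
  chi-squared
  \(\chi^2 = \frac{(ad-bc)^2\,N}{(a+b)(c+d)(a+c)(b+d)}\)
  without continuity correction.
* **BCPNN information component**:
  \(\mathrm{IC} = \log_2 \frac{aN}{(a+c)(a+b)}\), the log2
  observed-over-expected count, with \(\mathrm{IC025} = \mathrm{IC} -
  2\sqrt{V(\mathrm{IC})}\).
* **EBGM**: \(\mathrm{EBGM} = \frac{aN}{(a+c)(a+b)}\) with
  \(\mathrm{EBGM05} = \exp\{\ln \mathrm{EBGM} - 1.96\sqrt{1/a+1/b+1/c+1/d}\}\).

In these forms \(\mathrm{IC} = \log_2 \mathrm{EBGM}\) holds identically,
and the test suite asserts it. Independence tables
(\(a/N = \frac{(a+b)}{N}\frac{(a+c)}{N}\)) give ROR = PRR = EBGM = 1,
IC = 0 and \(\chi^2 = 0\) exactly.

**What is deliberately absent.** The names BCPNN and MGPS historically
denote Bayesian procedures: a Dirichlet/beta prior posterior for the IC,
and the gamma-Poisson shrinker whose EB05 comes from a posterior mixture.
The closed forms above are the non-shrunk versions widely printed in
published FAERS signal tables, and they are what this package computes.
The shrinkage variants are out of scope and nothing in the package
pretends otherwise; for small \(a\) the non-shrunk estimates are noisier
and their lower bounds lean on a normal approximation.

**Variance of the IC.** The delta method on the log2 scale gives
\(V(\mathrm{IC}) = (1/a+1/b+1/c+1/d)/\ln(2)^2\); that is the default.
Published tables in this field sometimes show an IC-to-IC025 gap that is
nearly constant across rows — behaviour no sample-size-dependent variance
can produce. For reproducing such tables, `bcpnn_ic(variance = "fixed",
kappa = ...)` subtracts a constant offset instead. The default is the
defensible estimator; the fixed mode is a reproduction device, and the
package does not claim either as the convention of any particular
publication.

**Zero cells.** With any empty cell the affected statistic is reported as
undefined (`NA`) rather than infinite, and an undefined statistic always
fails its signal flag. A Haldane-style +0.5 correction is available by
option (`zero_correction = "haldane"`) but off by default, since published
signal tables in this field generally show uncorrected values.

**Signal criteria.** The conventional per-algorithm rules are the
defaults of `signal_criteria()`: ROR positive if \(n \ge 3\) and the CI
lower limit exceeds 1; PRR positive if \(\mathrm{PRR} \ge 2\),
\(\chi^2 \ge 4\) and \(n \ge 3\); BCPNN positive if \(\mathrm{IC025} > 0\);
MGPS positive if \(\mathrm{EBGM05} > 2\). The *consensus* flag is their
conjunction — requiring all four reduces single-algorithm artifacts at
the cost of sensitivity. No multiplicity adjustment is applied anywhere;
with hundreds of PTs tested, the per-algorithm false-positive rates are
per-comparison rates, and users should treat marginal signals
accordingly. This mirrors standard practice in the field and is a
documented limitation, not an oversight.

## Counting units and the comparator universe

FAERS practice counts *report-event pairs*: a deduplicated report
contributes one unit for each distinct PT it lists, and at SOC level one
unit per distinct SOC regardless of how many of its PTs map there (the
SOC-level `a` therefore counts distinct reports, which is why a SOC's
case count can sit well below the sum of its PT rows). `build_tables()`
defaults to pair counting and offers `unit = "report"` for whole-report
margins. The comparator universe is every deduplicated report in the
ingested window that is not in the cohort; nothing else is excluded.

## Case processing

**Deduplication.** FAERS carries multiple versions of one case across
quarters. The reduction implemented: within each CASEID keep the version
with the most recent FDA_DT; among receipt-date ties keep the highest
PRIMARYID. PRIMARYIDs are compared numerically when all of a case's ids
parse as numbers, lexicographically otherwise. Versions with missing or
uninterpretable FDA_DT are excluded and logged. Partial receipt dates
(YYYY or YYYYMM) defer to any fully dated sibling version; when no
version of the case has a full date, partial dates are completed to their
period end (Dec 31 / last day of month) for ordering only. Dedup is
idempotent, and on synthetic data its output equals the generator's
designated survivors for every seed tested.

**Name matching.** Verbatim FAERS drug names carry salts, strengths and
formatting noise ("VORTIOXETINE HYDROBROMIDE 10MG"). Matching is
therefore normalized containment: trim, case-fold, collapse internal
whitespace, then test whether any configured target name is a substring
of `drugname` or `prod_ai`. The matching row must also carry the required
role code (default PS, primary suspect), so reports that mention the
target drug only as concomitant are comparators, not cohort members.
Containment can over-match in principle (a target string embedded in an
unrelated brand name); with ingredient-level names of reasonable length
this is not observed, and the match list is configurable.

**Indication filtering.** Reaction PTs that name the treated condition
(default list: major depressive disorder, depression, depressive symptom)
are removed from the cohort's reaction lists — they are indications
leaking into the reaction field, not adverse events. A report whose only
PTs are removed stays in the report-level demographics but contributes no
event-level pairs. Removal counts are logged, never silent.

## Descriptive summaries

Every breakdown partitions the cohort (missing is a bin), counts sum to
the cohort size, and percentages are `100·count/cohort_size` rounded
half-up to one decimal — missing values stay in the denominator, so
percentages are comparable across breakdowns. Age bins are <18, [18, 65),
[65, 85), ≥85 years after normalizing age-unit codes (DEC, YR, MON, WK,
DY, HR) to years; weight bins <50, [50, 100], >100 kg. A report with
several outcome codes counts once under its most serious code (death >
life-threatening > hospitalization > disability > congenital anomaly >
required intervention > other). Reporter occupation codes map MD →
Physician, PH → Pharmacist, CN → Consumer, HP → Health Professional, OT →
Other health-professional.

Time to onset is the event date minus the earliest therapy start date of
the report's target-drug rows. Reports with partial or missing dates on
either side, or a negative difference (event before therapy start — an
inaccurate report), are excluded and counted; evaluable plus excluded
reconciles to the cohort size. Quantiles use linear interpolation
(type 7), and "within the first month" means ≤ 30 days. The choice of
the therapy-start/event-date pair is the one the FAERS fields support
directly; other definitions (e.g. dechallenge-based) are not available in
the raw tables.

## The synthetic generator as study conditions

`synthetic_config()` defines the conditions every test and the analysis
scripts run under, chosen once to emulate a realistic spontaneous-report
stream:

* **Scale**: 50,000 cases over 4 quarters by default (the scripts'
  problem size; tests use smaller streams where the property under test
  allows it).
* **Exposure**: 2% of reports carry the target drug as primary suspect.
  Any one drug is a small share of a reporting universe; at much larger
  shares the drug's own reports dominate the expected-count baseline
  \((a+c)(a+b)/N\) and bias IC and EBGM toward the null by roughly
  \(1/(f\rho + 1 - f)\) for exposure share \(f\) — a property of the
  estimators, not of the implementation, and the reason a realistic
  share matters.
* **Event rates**: each PT's baseline probability is log-uniform in
  \([10^{-4}, 10^{-2}]\) (events are rare), rescaled so the expected
  number of distinct PTs per report is 2.5; exposed reports use
  \(\min(\rho p_0, 0.5)\), where \(\rho\) is the configured
  reporting-rate ratio (1 = null). Per-PT baselines can be pinned via
  `base_rate` when a property needs a known expected cell count. Reports
  drawing no PT receive one proportionally to the rates (FAERS reports
  always list at least one reaction).
* **Duplicates**: 5% of cases are re-submitted with a later receipt date;
  20% of those pairs have tied FDA_DT to exercise the PRIMARYID
  tie-break, and half of all pairs have their ids swapped so the later
  version carries the *smaller* id — forcing the date rule, not id order,
  to decide. The ground-truth sidecar records the full lineage and the
  designated survivor.
* **Missingness**: 13% of reports lack sex, 56% age, 79% weight — the
  profile of a real antidepressant cohort. Event and therapy-start dates
  degrade to partial (YYYYMM/YYYY) or missing at 15%, and 2% of reports
  get an event date before therapy start, so the time-to-onset exclusion
  rules are always exercised. FDA_DT is kept complete so duplicate
  lineage stays exactly decidable; the partial-FDA_DT dedup fallback is
  covered by hand-built records in the unit tests instead.
* **Onset**: time to onset is log-normal with median 7 days
  (sdlog = 1.5), giving the right-skewed early-onset profile typical of
  antidepressant adverse events.
* **Demographics**: sex 70/30 female among known; ages normal around 45
  (sd 18, clipped to 12–95) with a mix of YR/DEC/MON unit codes; weights
  normal around 75 kg with an LBS admixture; reporter occupations and
  countries drawn with consumer- and US-heavy weights; outcome codes
  present on ~31% of reports with "other serious" dominant.

What the generator does **not** emulate: drug-drug confounding,
duplicate reports with *divergent* content across versions, verbatim
drug-name misspellings, non-target drugs that share ingredient strings,
MedDRA versioning drift, or reporting waves after label changes. Passing
tests on this stream therefore demonstrate correctness of the pipeline's
logic under known ground truth — not robustness to every pathology of
real FAERS data.

## Numerical choices

* Rounding for report output is half-up (away from zero) at 2 decimals
  for statistics and 1 decimal for percentages, matching regulatory
  table conventions; base R's round-half-even is not used for display.
* Dollar-delimited parsing enforces the exact field count from the
  header; malformed rows are quarantined with file, line and reason.
  Files are read as UTF-8 with a latin-1 fallback per file.
* PRIMARYID tie-breaks compare numerically only when every id in the
  case parses as a number, avoiding mixed-type surprises.
* All randomness flows from the single config seed; generation and the
  whole pipeline are byte-reproducible for a fixed seed and config.

## Scope and interfaces

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` (simulate → cohort → signals → descriptives) are thin
narrative drivers that write their tables under `results/`, and
`run_pipeline()` runs the same chain as one call with a JSON manifest
(stage counts, input checksums, config echo). All computation lives in
package functions, which is what the tests exercise. Plot rendering is
intentionally out of scope: the forest-plot table (`forest_data()`) and
the histogram tables are emitted plot-ready instead.
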