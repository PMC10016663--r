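# prepmonitor

Quarterly monitoring indicators for publicly funded HIV pre-exposure
prophylaxis (PrEP) programs, computed from flat pharmacy/laboratory event
tables.

## The problem

A province-wide PrEP program dispenses oral antiretroviral medication at no
cost to residents at substantial risk of HIV. Running such a program safely
means watching, every calendar quarter, a fixed panel of indicators derived
from routinely collected event streams: who is dispensed PrEP (gender
identity, age, health authority of residence and of the prescriber's
practice), who newly enrols and through which provider types, how
concentrated prescriber caseloads are, the qualifying HIV risk factors
recorded at enrolment, who is active in care versus lost to follow-up,
daily versus on-demand use, quantity dispensed in 30-tablet supply units,
HIV and syphilis testing around dispensations, incident infections, and
adverse-drug-reaction (ADR) events.

`prepmonitor` is for program analysts and surveillance epidemiologists who
need those fourteen indicator blocks as a reproducible, auditable pipeline
rather than ad-hoc queries. Because the real data are confidential registry
linkages, the package also ships a synthetic-cohort simulator with
independently bookkept ground truth, so every pipeline stage is exercisable
and testable with no data access.

## The core definitions

For a quarter *q* with last day *e(q)*, each indicator is a set of strata
with counts *(n_s, D)* displayed as `n_s` and `round(100 n_s / D)` (halves
away from zero). The two nontrivial computations:

**Client status (indicator 9).** A client is active from their first
dispensation until the earliest of: a formal discontinuation notification;
a lapse of more than 6 calendar months between consecutive prescription
dates (rule in force while its candidate date falls on or before the last
day of 2019Q2); or more than 6 calendar months beyond the expected refill
date `effective_date + days_of_supply` of the latest dispensation (rule in
force afterwards). Days of supply are tablets × 1 for daily use and
tablets × 2 (configurable) for on-demand use; the effective date is the
pickup date when known, else the fill date. A later dispensation
re-activates a lapsed client; nothing re-activates a formally discontinued
one.

**Testing coverage (indicators 12a/13b).** A dispensation is covered when a
test of the assay falls in `[effective_date − 30, effective_date + 15]`
(inclusive); the denominator is in-quarter dispensations of clients active
on the dispensation date.

Public releases apply small-cell suppression: counts in 1–4 are masked, and
within partition blocks the smallest remaining positive cell is masked too
so the hidden count cannot be recovered by subtraction.

## Worked example

```r
library(prepmonitor)

sim <- simulate_cohort(sim_config(base_arrivals = 42), seed = 2020)  # ~1,000 clients
rep <- build_quarterly_report(sim$store, "2020Q4")
rep
#> <quarterly_report> 2020Q4 | 14 indicator blocks

rep$blocks[["9"]][[1]]
#> Indicator 9 | BC-PrEP client status (active vs inactive) | 2020Q4
#>   stratum  numerator denominator percent suppressed
#> 1 active         811         939      86 FALSE
#> 2 inactive       128         939      14 FALSE

rep$blocks[["10"]][[1]]
#> Indicator 10 | PrEP usage type among active BC-PrEP clients | 2020Q4
#>   stratum   numerator denominator percent suppressed
#> 1 daily           763         811      94 FALSE
#> 2 non_daily        48         811       6 FALSE

rep$blocks[["12"]][[1]]$rows   # syphilis testing around dispensations
#>   stratum numerator denominator percent suppressed
#> 1 covered       928        1165      80 FALSE
```

Of the 939 clients ever dispensed by the end of 2020Q4, 86% are active
(no lapse > 6 months past their expected refill and no formal
discontinuation); 94% of active clients are on daily dosing; 80% of the
quarter's 1,165 dispensations had a syphilis test within the 46-day
coverage window. The report equals the simulator's independently bookkept
ground truth cell for cell:

```r
nrow(compare_report_truth(rep, sim$truth))
#> [1] 0
```

Reading real exports instead of simulating:

```r
store <- read_event_store("path/to/event_tables/")   # validates on load
rep   <- suppress_small_cells(build_quarterly_report(store, "2020Q4"))
write_report(rep, "markdown", "report_2020Q4.md")
```

## Analysis workflow

The `analysis/` scripts run the whole pipeline end to end on the synthetic
cohort, writing tables under `results/`:

1. `01_simulate_cohort.R` — simulate the 12-quarter cohort and write the six
   event tables plus ground truth.
2. `02_client_status.R` — per-client status timelines and quarterly
   active/inactive counts.
3. `03_quarterly_report.R` — the suppressed 14-block report for 2020Q4 in
   CSV/JSON/markdown.
4. `04_indicator_trends.R` — per-quarter indicator time series, verified
   against ground truth.

## Vignette

`vignettes/prep-monitoring.Rmd` documents the status model and its staged
lapse rules, the window/rounding/quantile conventions and why each
configurable choice exists, what the synthetic cohort emulates (and what it
deliberately does not), and known limitations.
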