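---
title: "Quarterly PrEP program monitoring: methods and conventions"
author: "prepmonitor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quarterly PrEP program monitoring: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prepmonitor)
```

## The monitoring problem

Publicly funded HIV pre-exposure prophylaxis (PrEP) programs dispense oral
antiretroviral medication to HIV-negative people at substantial risk of
acquiring HIV. Monitoring such a program means answering, every calendar
quarter, a fixed set of questions from routinely collected event streams:
who is being dispensed PrEP (gender identity, age, health region), who is
enrolling and through which providers, how concentrated the prescriber
caseload is, which qualifying risk factors clients carry, who is still in
care versus lost to follow-up, whether laboratory monitoring (HIV and
syphilis testing) accompanies dispensations, how much medication is moving,
and what adverse drug reactions are reported.

`prepmonitor` implements this as a pipeline over six flat event tables —
client roster, enrolment authorizations, pharmacy dispensations, laboratory
results, adverse-drug-reaction (ADR) reports and a provider roster, plus
optional formal discontinuation notifications — producing a quarterly report
of fourteen indicator blocks, each a set of (stratum, numerator,
denominator, percentage) rows with small-cell suppression for public
release.

## The client-status model

The only genuinely algorithmic indicator is client status. A client is
**active** from their first dispensation until the earliest of:

1. a **formal discontinuation notification** (its date wins whenever it is
   earliest, and no later dispensation re-activates the client);
2. a **prescription gap lapse**: more than six calendar months between two
   consecutive prescription dates;
3. an **expected-refill lapse**: more than six calendar months beyond the
   projected end of the last dispensed supply.

A later dispensation after a lapse re-activates the client on its date.
"Six months" is calendar-month arithmetic with end-of-month clamping
(January 31 + 1 month = February 28/29), not a fixed day count, because the
rule is stated in months. The two lapse rules are historically staged: the
gap rule applies when its candidate lapse date falls on or before the last
day of the cutover quarter (default 2019Q2), the expected-refill rule
afterwards. Because the program's published rule wording is ambiguous about
whether both rules were confined to the pre-cutover era, the package makes
this a three-way configuration (`lapse_rule = "cutover"`, `"gap"` or
`"refill"`) rather than hard-coding one reading; `"cutover"` is the default
and every report footer records the active convention.

Two interpretive choices had to be fixed and are exposed in configuration:

* **"Prescription periods"** are taken to be consecutive *effective dispense
  dates* — the pickup date when recorded, otherwise the prescription fill
  date. The effective date is applied uniformly across all indicators so a
  single client timeline underlies the whole report.
* **Days of supply** for daily use equal the tablet count. On-demand
  (non-daily) dosing has no fixed cadence, so a configurable stretch factor
  (default 2 days per tablet) converts tablets to supply; the factor is
  flagged in every report footer because it is a reporting convention, not a
  clinical fact.

Timelines are materialised as dated state-change entries (first
dispensation, lapse, re-dispensation, formal notification), so the status on
any date is the state of the last entry on or before it. The entry after the
final dispensation is the *scheduled* lost-to-follow-up date; queries before
it simply see an active client.

## Testing-coverage linkage

A dispensation counts as covered by laboratory monitoring when a test of the
relevant assay falls within a window around its effective date: by default
30 days before through 15 days after, **both endpoints inclusive** (a 46-day
window). The endpoint convention is not stated in the program's published
rule wording, so it is configurable (`window_inclusive`) and auditable; one
test may cover several dispensations. The coverage denominator is
dispensations whose client is active *on the dispensation date* (a
re-dispensation is active on its own date), since the published definition
names active clients without fixing a timepoint.

## Display conventions

* Percentages are rounded to whole integers, halves away from zero
  (configurable to banker's rounding); a zero denominator yields an absent
  percentage, never an error.
* The days-from-last-negative-HIV-test-to-first-dispensation summary uses
  linear interpolation between order statistics (`quantile type 7`),
  configurable because no convention is published.
* Age bins (`<18, 18-28, 29-40, 41-48, >=49`) are inclusive ranges of
  completed years at the dispensation date; provider caseload bins are
  `1, 2-5, 6-19, 20-49, >=50` distinct clients dispensed within the quarter.
* Tablet quantities are reported in 30-tablet supply units, kept at full
  precision internally so per-region units sum exactly to total tablets /
  30, and rounded to one decimal only at serialization.
* Small-cell suppression masks any stratum count strictly between 0 and the
  threshold (default 5, a common public-health convention since the program
  publishes no threshold). In partition blocks a single masked cell would be
  recoverable by subtraction, so the smallest remaining positive cell is
  masked too. Suppression sets flags only; writers render masked cells as
  `*`.

Choices the published material leaves open were decided once and documented
here rather than branched on: incident cases are dated by specimen (test)
date; the incident-case "active" restriction is assessed at the test date;
ADR event counts collapse duplicate reports by (client, date, event label)
and drop events classified "unlikely" before counting; the ADR block is not
additionally gated on active status since its published calculation excludes
only duplicates and unlikely causality. A client seen by providers in two
caseload bins contributes to both bins' client-coverage numerators while the
denominator stays distinct clients.

## The synthetic cohort and what it does (not) show

Real program data are confidential registry linkages, so the package ships a
synthetic-cohort generator whose defaults emulate the published cohort
structure: twelve quarters of enrolment growing ~12% per quarter from 85
first-quarter arrivals (~2,050 clients), ~98.5% cisgender-male clients, a
Vancouver-Coastal-dominant health-region mix (~68%), an age mix peaking at
29–40 years (~43%), a risk-factor mix dominated by the risk-index-score
category (72% score-only, 16% score+STI, matching the published cumulative
shares), 30/60/90-tablet supplies at a 55/15/30 mix, 95% daily use, ~3.4%
of authorized clients never dispensing, per-refill hazards of silent lapse
(2%), lapse-then-return breaks (1%) and formal discontinuation (0.8%),
in-window test-scheduling probabilities of 0.88 (HIV) and 0.75 (syphilis),
quarterly incidence of 1% (syphilis) and 0.04% (HIV, rare by design), and
ADR reports (1.5% of clients) with duplicate (25%) and "unlikely" (15%)
report probabilities and an 84% discontinuation link. Where the published
material states no value, the defaults are fixed at what routine program
data of this kind typically show and are not revisited.

The generator bookkeeps **ground truth during generation**: client
attributes, scripted status episodes (every stop, break and return carries
its hand-computed lapse date), and brute-force all-pairs window matches on
the final test tables. The ground truth never calls the indicator engine —
calendar, binning and quantile arithmetic are re-derived independently
inside the simulator — so engine-equals-truth is a genuine two-implementation
check, exercised over 20 seeds in the test suite. Randomness is seeded once
and split into per-table streams so adding events to one table does not
perturb the others.

What passing these tests shows: the engine computes every published
indicator definition exactly on event streams with known answers, including
lapse/re-activation edge cases, window boundaries, duplicate ADRs and
multi-provider clients. What it does not show: robustness to the
pathologies of real registry data (reporting lag, reversed claims, linkage
errors, under-reported discontinuations), none of which the generator
emulates; the validation layer rejects malformed input rather than repairing
it.

## Problem sizes and runtime

The test suite simulates cohorts of ~2,050 clients over 12 quarters for the
20-seed oracle check (a scale at which every stratum is populated and
provider caseloads span all five bins), ~90-client cohorts for unit tests,
and a ~6,000-client cohort for the mix-convergence check; the full suite
runs in a few minutes on one core. `scripts/acceptance.R` re-runs the
worked percentage pairs, a ~1,000-client report build and a five-seed oracle
sweep.

## Known limitations

* Re-enrolment after formal discontinuation is representable in the data
  model (the notification simply truncates the timeline) but the published
  indicator definitions do not define second-episode semantics, so the
  engine never re-activates after a notification.
* The non-daily stretch factor is a convention; true on-demand consumption
  is unobservable from dispensation records.
* Ground-truth bookkeeping assumes the default indicator configuration
  (cutover lapse rule, inclusive 30/15-day window); alternative
  configurations are exercised by hand-worked fixtures instead.
* The generator scripts no epidemic dynamics: incidence is a constant
  per-quarter hazard, and the optional arrival-rate dip is a scenario knob,
  not an epidemic model.
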