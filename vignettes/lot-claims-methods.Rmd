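---
title: "Methods: line-of-therapy derivation and PPPM burden analysis from claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: line-of-therapy derivation and PPPM burden analysis from claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncolot)
```

`oncolot` implements a complete retrospective-claims analysis of first-line
(1L) systemic anticancer therapy (SACT) in metastatic non-small cell lung
cancer (NSCLC): cohort selection, line-of-therapy (LOT) derivation, censored
treatment duration, time to next treatment (TTNT), and per-patient-per-month
(PPPM) utilization and cost summaries. This vignette documents the model, its
tunable parameters, the numerical conventions, the synthetic-data generator
that stands in for confidential claims extracts, and the design choices made
where the underlying methodology is genuinely open.

## The data model

Four tables describe a claims extract: patient demographics (year of birth,
sex, region, payer, optional death date), enrollment spans (with medical and
pharmacy benefit flags), medical claims (service date, setting, ordered
diagnosis codes, optional drug code, paid amount), and pharmacy claims (fill
date, drug code, days supply, paid amount). A fifth table — the drug
dictionary — is deliberately data, not code: it maps each drug code to a
therapeutic class (`ICI`, `PLATINUM`, `NONPLAT_CHEMO`, `TARGETED`, `VEGF`,
`SCLC_TYPICAL`, `OTHER`), an optional substitution group, a maintenance
eligibility flag, and a default runout length for medically administered
agents. The bundled dictionary covers ~40 generic agents; any table with the
same columns can replace it, because exclusion rules and classification operate
on classes, not codes.

Dates are ISO-8601 calendar dates and all derived durations are inclusive
integer day counts; `days_between()`/`interval_days()` centralize the
convention so ±1-day questions have a single answer. Enrollment spans that
overlap or abut are merged on read; "continuous" enrollment tolerates a
configurable gap of 0 days by default — the strictest reading, since the
source methodology is silent on gap tolerance.

## Cohort selection

The eligibility cascade is applied in a fixed order, and each patient is
labeled with the *first* criterion failed, which makes the attrition table a
partition:

1. lung-cancer diagnosis: earliest claim with an ICD-10-CM C34 code in any
   position inside the study window (2016-01-01 to 2023-03-31) = **Dx date**;
2. metastasis: earliest C77–C79 claim on/after Dx = **SM date** ("on or
   after" is inclusive: a metastasis code on the Dx date itself qualifies);
3. first SACT on/after the SM date = **index date** (1L start);
4. index on/after 2020-01-01;
5. continuous medical **and** pharmacy enrollment over
   `[Dx − 180, index + 30]`, endpoints inclusive;
6. no SCLC-typical agent strictly before the index date;
7. no targeted-therapy claim anywhere in the study period — immune checkpoint
   inhibitors (ICIs) and anti-VEGF agents never trigger this rule;
8. no metastasis diagnosis or SACT use within the 180 days before Dx;
9. age ≥ 18 at index (age = index year − birth year; claims carry only birth
   year);
10. the 1L regimen window contains at least one NSCLC-appropriate agent.

The source methodology states the index date two ways (first metastatic date
vs. 1L SACT start). This package anchors eligibility ordering on the SM date
and uses the 1L SACT start as *the* index date for baseline, outcomes and
costs; the discrepancy is recorded rather than resolved. Similarly, the
"≥1 LOT initiated on or after 1 January 2020" criterion is implemented as
"index date (1L start) on/after the floor" — deriving LOTs before cohorting
would be circular, and on generator output the readings coincide.

Baseline characteristics use only claims in `[index − 180, index − 1]` — the
index date itself is excluded. Comorbidity and metastasis-site flags come from
an editable ICD-10 prefix map; smoking is ascertained from nicotine-dependence
codes (F17) and is knowingly under-captured in claims. The comorbidity score
is a pure weighted sum over flagged conditions with the index cancer excluded;
the weight table ships as swappable configuration (integer Charlson-style
weights over the flags the package derives). It is a score of the same *form*
as the NCI-adapted Charlson index, but the exact published weight table is not
reproduced here, and the score is not an acceptance-tested quantity.

## The line-of-therapy algorithm

For each eligible patient, every SACT claim on/after the index date becomes a
dated **episode** with a runout date: `fill + days_supply − 1` for pharmacy
claims, `service + default_runout_days − 1` for infusions (claims carry no
days supply for medically administered drugs, so a per-drug cycle length —
default 21 days, the dominant cycle — is imputed; configurable per drug).
Episode identity is the **canonical id**: the substitution group when one
exists, else the generic name, so cisplatin↔carboplatin swaps are invisible
to everything downstream.

Line 1 opens at the first episode. The **regimen** is the set of canonical ids
starting in `[start, start + 29]` (the 30-day window includes day 0 and day
29; a drug on day 30 is outside and is evaluated as an event). Each later
episode is evaluated in order:

* **gap rule first**: if the episode starts ≥ 60 days after the latest runout
  of the current line, the line advances (`ADVANCE_GAP`) regardless of drug
  identity; a gap of exactly 60 days advances, 59 does not;
* an in-regimen drug **continues** the line (pauses and reintroductions never
  advance it) and extends the running maximum runout;
* a maintenance-eligible drug whose backbone is in the regimen is **absorbed**:
  it extends the line but does not join the regimen used for classification.
  The bundled maintenance map is pemetrexed-after-platinum and
  bevacizumab-after-platinum; continuation of an ICI already in the regimen is
  plain continuation and needs no map entry. The map is editable configuration
  — the methodology names the concept (guideline-recommended maintenance), not
  the list;
* anything else advances the line (`ADVANCE_NEW_DRUG`).

A line closed by advancement ends the day before the next line starts (so the
order of the gap and new-drug checks affects only the recorded end reason,
never the boundary). The final line ends at the earliest of enrollment end,
study end, or death, with the matching end reason. Every SACT episode
therefore belongs to exactly one line — a property the test suite asserts on
generated data.

Classification looks only at the classes present in the regimen: ICI with
platinum → `ICI_PBCT`; ICI with non-platinum chemotherapy → `ICI_NONPBCT`;
ICI alone (one or two ICIs) → `ICI_MONO_DUAL`; platinum without ICI →
`PBCT_MONO_COMBO`; exactly one / two-or-more non-platinum chemotherapies →
`NONPBCT_MONO` / `NONPBCT_COMBO`; everything else → `OTHER`. An anti-VEGF
agent added to an otherwise-determined category never changes it, but a
regimen whose only non-VEGF content is an ICI or nothing (VEGF-only,
VEGF + ICI without chemotherapy) is `OTHER`.

## Outcomes and costing windows

**1L duration** runs from the index date to the earliest of: the maximum
runout over all 1L therapies, the day before the 2L start, the study end, or
the end of follow-up — counted inclusively (runout on day 180 after index ⇒
181 days). The record is **censored** when the end was imposed by study end or
follow-up end; ends determined by runout, a next line, or death are events.
The product-limit estimate is fitted through `survival::survfit` (an
independent naive risk-set implementation lives in the test suite and must
agree exactly); the median is the smallest time with S(t) ≤ 0.5, no
interpolation, undefined if S never reaches 0.5. Durations convert to months
by `month_length_days` (default 30.4375 = 365.25/12; the source unit
convention is unstated, so the constant is explicit configuration).

**TTNT** is the day count from the 1L start to the day before the 2L start
(equal to `2L start − 1L start` in days), reported as a plain arithmetic mean
over patients who started 2L — no censoring adjustment, matching the "among
patients who received 2L" framing.

The **SACT period** — the costing window — runs from the index to the earliest
of `max runout + 30`, the day before 2L, or the end of follow-up. Claims
outside it contribute nothing to utilization or cost (a property test perturbs
out-of-window claims and asserts every summary is unchanged).

## HCRU and costs

Within the SACT period, per patient: outpatient visits (outpatient claim
count; chemotherapy/ICI administration claims are outpatient claims, so drug
costs ride with the outpatient setting), inpatient **admissions** (consecutive
inpatient claim dates collapsed into stays; an ED visit that leads to an
admission counts in both settings), ED visits, and pharmacy fills — each
all-cause and NSCLC-related (C34 in any position, or a lung-cancer
medication). Paid amounts are inflated to reference-year dollars by the ratio
of medical-CPI index values (identity when all CPI values are equal; a service
year missing from the table is fatal, not silently imputed). PPPM is the
patient-level value divided by `period_days / month_length_days`; summaries
average the patient-level PPPM values (ratio of patient means, not a pooled
ratio), so per-patient total cost PPPM is exactly additive across settings.

## The synthetic generator

Confidential claims cannot ship, so `simulate_claims()` builds datasets whose
*pipeline output* is calibrated to the published summary statistics of a 1L
metastatic-NSCLC population of 15,659 patients, with per-patient ground truth
(eligibility, intended failure filter, category, line starts, duration,
censoring, 2L start). Defaults encode the study conditions:

* **category shares** 0.470 / 0.264 / 0.197 for ICI+PBCT, PBCT mono/combo and
  ICI mono/dual (published), the remaining four categories apportioned to sum
  to one;
* **durations**: intended 1L duration is log-normal (log-SD 0.6) with
  per-category medians spread 2.7–6.5 months (chemotherapy-only shortest —
  the published range; the per-category values themselves are not published
  and are package choices). Treatment is emitted as whole 21-day cycles, so
  the derived duration is the intended duration rounded up to a cycle
  boundary. 4.2 months (127.8 days) is not on the 21-day grid; a closed-form
  root-find on the mixture CDF rescales the medians at generation time so the
  quantized median lands on the nearest grid point, 126 days = 4.14 months.
  Acceptance tolerances for the median carry a ±0.25-month discretization
  allowance for exactly this reason;
* **censoring**: a configurable fraction (default 0.25) of patients lose
  enrollment before their intended 1L end. The truncation time is an
  *independent* log-normal draw scaled (again a deterministic root-find) so
  that P(truncation < duration) equals the target fraction — independence
  keeps the Kaplan–Meier estimate consistent for the duration distribution,
  which a truncation time drawn conditionally on the duration would not.
  Late-index patients are additionally administratively censored by the study
  end, which is likewise independent of duration;
* **TTNT**: the 2L delay after the 1L end is exponential. Its mean is solved
  at generation time (truncated-exponential means weighted by the probability
  the delay fits before study end) so the mean TTNT among *observed* 2L
  patients hits 8.0 months; if even a 7-day mean overshoots, the mean floors
  at 7 days with a warning;
* **utilization**: outpatient visits top up the SACT administration claims to
  per-category Poisson rates whose share-weighted mean is exactly 6.6 PPPM
  (published per-category values fixed, the rest solved). Patients whose
  administration claims alone exceed their category rate would truncate at
  zero and bias the pooled mean, so the overshoot is redistributed within the
  category across patients with slack. Inpatient stays (0.12 PPPM pooled) are
  placed with guaranteed date separation so stay-collapsing preserves the
  count; ED visits pool to 0.11 PPPM;
* **costs**: log-normal with mean-targeting parameterization
  (`meanlog = log(mean) − sdlog²/2`, `sdlog` default 1.0, giving SD > mean as
  observed in claims). Outpatient cost is one per-patient total with mean
  `rate × months`, split over the patient's in-period outpatient claims;
  inpatient cost is per stay. Pooled targets: total $32,215, outpatient
  $28,045, inpatient $3,412 PPPM in 2022 USD; the remaining $758 is split
  ED $300 / pharmacy $458 (not published; package choice). The generator
  draws costs in 2022 dollars and *deflates* them to each claim's service
  year, so the pipeline's CPI adjustment recovers the calibrated values
  exactly;
* **ineligible patients** are injected on top of `n_patients` (≈11% total by
  default), each violating exactly one cascade criterion — e.g. the
  targeted-therapy patient receives osimertinib *after* the 1L start so the
  claim can never shift the index date, and the SCLC-typical agent is placed
  strictly between Dx and SM so it is SACT-before-index and nothing else.

Because eligible patients receive only rule-consistent streams (constant
regimen every 21 days, a 2L drug chosen outside the regimen and outside the
maintenance map, delays clamped so the 2L start can never fall inside the
30-day regimen window), the LOT engine must recover the true line starts,
categories, durations and censoring flags for 100% of eligible patients; the
acceptance suite asserts exactly that at the default scale.

What the generator does **not** emulate: NDC-level coding realism, billing
adjudication, comorbidity-correlated costs, dose/units, regimen changes inside
a line beyond platinum substitution, or death competing with treatment (deaths
are recorded only after treatment end so they never truncate a duration).
Passing tests therefore demonstrate algorithmic correctness and calibration
recovery, not robustness to the full messiness of production claims — with one
deliberate exception: the reader tolerates and counts malformed rows, and the
pipeline tolerates claims that postdate death or fall in coverage holes.

## Numerical choices and degenerate inputs

* Day arithmetic is closed-form on calendar dates; no time zones.
* Boundary conventions asserted by tests: regimen window day 29 in / day 30
  out; gap of exactly 60 advances; enrollment span ending exactly
  `index + 30` qualifies; metastasis on the Dx date qualifies; baseline claim
  on the index date does not.
* Ties: same-day episodes sort by canonical id (stable, order-invariant under
  input shuffling); a pharmacy fill and an infusion on the same day tie
  immaterially for the index date.
* Degenerate inputs: an empty dataset flows through every stage and renders
  header-only tables; a single-patient summary has SD 0; zero-length SACT
  periods are excluded with a counted warning; degenerate category shares
  (all mass on one category) disable the unsolvable pooled-cost constraints
  with a warning rather than failing.
* Unknown SACT drug codes are fatal at dataset construction (silent
  misclassification would corrupt every downstream stage); malformed rows are
  rejected and counted, never silently dropped.

## Problem sizes

The default test run exercises hand-built fixtures plus generated cohorts of
150–2,000 eligible patients for unit and property tests, one full-scale cohort
of 15,659 (fixed seed) for the acceptance checks, 1,000 patients for the
substitution-invariance property, and 100 random small instances (n ≤ 50) for
the product-limit oracle comparison. `scripts/acceptance.R` regenerates the
full-scale cohort from scratch and completes in about a minute.

## Known limitations

* Infusion runout is an imputed constant per drug; real dosing intervals vary.
* The targeted-therapy exclusion is class-based; a dictionary that misclasses
  a code misclassifies the patient.
* Age uses birth year only (±1 year).
* The "any LOT ≥ 2020" criterion is read as "1L start ≥ 2020" (see above).
* NSCLC-related pharmacy costs are near zero in generated data because
  background fills are non-oncology by construction.
* The comorbidity score uses package-chosen integer weights, not the published
  NCI-adapted table.
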