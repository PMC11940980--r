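# oncolot

Line-of-therapy derivation and economic-burden analysis for oncology
administrative claims, built around the first-line (1L) treatment of metastatic
non-small cell lung cancer (NSCLC) without actionable alterations.

## The problem

Real-world-evidence studies of 1L metastatic NSCLC work from insurance claims:
enrollment spans, medical claims (diagnosis codes, settings, paid amounts) and
pharmacy fills. Nothing in a claims stream says "line of therapy" — it has to
be derived by rule. `oncolot` implements the full analysis chain for that kind
of study, for health-economics and outcomes researchers:

1. **Cohort selection** — an eligibility cascade with attrition accounting:
   lung-cancer diagnosis (ICD-10-CM C34, any position; earliest claim = Dx
   date), metastasis on/after Dx (C77–C79; SM date), first systemic
   anticancer therapy (SACT) on/after the SM date (= the **index date**),
   index on/after 2020-01-01, continuous medical+pharmacy enrollment from
   180 days before Dx to 30 days after index, no SCLC-typical agent before
   index, no targeted therapy during the study period (ICIs and anti-VEGF
   agents never count as targeted), no metastasis/SACT in the 180 days before
   Dx, age ≥ 18.
2. **Line-of-therapy (LOT) algorithm** — the 1L regimen is every SACT received
   in the 30-day window starting at the 1L start (days 0–29), collapsed over
   substitution groups (cisplatin ↔ carboplatin, paclitaxel ↔ nab-paclitaxel).
   The line advances on a new non-regimen drug or a treatment gap ≥ 60 days
   from the latest *runout* date (pharmacy: fill + days-supply − 1; infusions:
   an imputed per-drug cycle length, default 21 days). Pauses/reintroductions
   of regimen drugs and guideline maintenance additions (e.g. pemetrexed or
   bevacizumab after a platinum backbone) do not advance the line.
3. **Regimen classification** — ICI mono/dual, ICI + platinum chemotherapy
   (PBCT), ICI + non-PBCT, PBCT mono/combo, non-PBCT mono, non-PBCT combo,
   other.
4. **Outcomes** — 1L treatment duration (index to the earliest of max runout,
   day before 2L, study end, end of follow-up; censoring handled by the
   Kaplan–Meier product-limit estimator, median = smallest *t* with
   S(t) ≤ 0.5), time to next treatment (TTNT), and the **SACT period**
   costing window (index to the earliest of runout + 30 days, day before 2L,
   end of follow-up).
5. **HCRU & costs** — per-patient-per-month (PPPM: value ÷ period-days/30.4375)
   visit counts and costs inside the SACT period, by setting (outpatient,
   inpatient stays from collapsed claim dates, ED, pharmacy), all-cause and
   NSCLC-related (C34 in any dx position or a lung-cancer medication), with
   paid amounts inflated to 2022 USD via the medical CPI.

Real claims extracts of this kind are confidential, so the package ships a
**calibrated synthetic-claims generator** (`simulate_claims()`) with
per-patient ground truth: regimen-category shares, duration medians, TTNT,
visit rates, and PPPM costs default to the published summary statistics of a
15,659-patient 1L metastatic-NSCLC population, and deliberately ineligible
patients are injected so every cascade filter is exercised. Because the
generator emits rule-consistent event streams, the LOT engine must recover its
ground-truth line starts exactly — that oracle equivalence is the core of the
test suite.

## Worked example

```r
library(oncolot)

calib <- default_calibration(n_patients = 2000, seed = 7)
sim   <- simulate_claims(calib)          # claims_dataset + ground truth
res   <- run_pipeline(sim$dataset)
res
#> <oncolot pipeline result>
#>   eligible cohort : 2000 of 2220 patients
#>   KM median 1L duration: 4.14 months (n = 2000)
#>   mean TTNT       : 8.11 months (n = 468 with 2L)

res$category_distribution
#>           category     n   pct
#> 1:        ICI_PBCT   946 47.30
#> 2: PBCT_MONO_COMBO   513 25.65
#> 3:   ICI_MONO_DUAL   399 19.95
#> 4:    NONPBCT_MONO    54  2.70
#> ...

res$hcru_summary[category == "ALL" & scope == "ALL_CAUSE" &
                 setting %in% c("OUTPATIENT", "INPATIENT", "TOTAL")]
#>       measure    setting mean_pppm  sd_pppm ...
#> 1:     visits OUTPATIENT      6.54     4.45
#> 2: admissions  INPATIENT      0.13     0.20
#> 3:       cost OUTPATIENT  28444.43 41775.60
#> 4:       cost  INPATIENT   3614.91  8098.42
#> 5:       cost      TOTAL  32786.29 42463.15
```

Reading: 2,000 of 2,220 simulated patients survive the cascade (the 220
injected ineligibles each fail exactly one criterion — `res$attrition` shows
the cascade). The pooled Kaplan–Meier median 1L duration is 4.14 months; among
the 468 patients who started a second line, mean TTNT is 8.11 months.
Outpatient visits dominate utilization (6.54 PPPM) and outpatient costs
dominate spending ($28,444 of $32,786 total PPPM, 2022 USD), with cost SDs
exceeding means, as is typical of claims.

`self_check(sim$dataset, sim$truth, calib)` compares every calibrated quantity
with its target and flags deviations beyond 4 standardized errors.

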