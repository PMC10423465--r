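---
title: "Counterfactual savings models for biosimilar market entry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual savings models for biosimilar market entry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biosavings)
```

## The question the package answers

When a biosimilar of a biologic drug enters a single-payer market, tender
competition pushes the final (not list) price down. Two different questions
follow for the payer's budget, and they have two different answers:

* **Estimated savings** — how much *would* the payer have spent on the
  observed utilisation had the price stayed at its pre-biosimilar level?
  With reference unit price $p_{\mathrm{ref}} = E_{\mathrm{ref}} /
  V_{\mathrm{ref}}$ (spend over milligrams in the reference year),
  $$ S^{\mathrm{est}}_t = p_{\mathrm{ref}} \, V_t - E_t , $$
  summed over all years after the reference year. This measures the value
  of the price erosion at actual consumption.
* **Real-life savings** — how much less does the payer *actually* spend than
  in the reference year?
  $$ S^{\mathrm{real}}_t = E_{\mathrm{ref}} - E_t , $$
  which is negative in years when expenditure grew. This measures the
  realised budget relief, i.e. the part of the price erosion that was *not*
  reinvested in treating more patients.

Both models are implemented in `estimated_savings()` and
`real_life_savings()`, with `aggregate_savings()` summing algebraically
across drugs within one sector. The packaged national data set
(`poland_tnfi()`) covers infliximab (INF), etanercept (ETN) and adalimumab
(ADA) reimbursement in Poland 2013–2021, for all reimbursed indications
(`ALL`) and for the rheumatic musculoskeletal disease sector (`RMD`).

## Reference years

The reference year anchors the counterfactual and is configuration, never
hard-code (`bia_config()`):

* the estimated model anchors each drug at the year preceding first
  biosimilar reimbursement (INF 2013, ETN 2015, ADA 2018 — ETN's first
  biosimilar arrived mid-2016, so 2015 is its last full pre-biosimilar
  year);
* the real-life model anchors INF at 2018 instead, the year of its peak
  expenditure (`select_reference_year(rule = "peak_expenditure")`), because
  pre-2014 infliximab use was marginal and a 2013 anchor would compare a
  mature market against a nearly empty one;
* the *alternative* real-life scenario keeps INF at 2013; it turns the INF
  component into an expense increase and is reachable purely via
  `bia_config(rs, ref_years_real_life = c(INF = 2013))`.

## The sub-sector estimated model

For the RMD sector the payer's milligram series is not reliable across
source tables (the packaged data flag one year in which the published RMD
volume exceeds the whole-market volume). The sub-sector estimated model
therefore derives the RMD counterfactual from the whole-market potential,
scaled by the sub-sector's share of actual spending:
$$ P^{\mathrm{RMD}}_t = p_{\mathrm{ref}} V^{\mathrm{ALL}}_t
   \frac{E^{\mathrm{RMD}}_t}{E^{\mathrm{ALL}}_t}, \qquad
   S^{\mathrm{RMD}}_t = P^{\mathrm{RMD}}_t - E^{\mathrm{RMD}}_t . $$
This is the `scale_by` argument of `estimated_savings()` and reproduces the
published sub-sector table cell-for-cell, which a direct
reference-price-times-RMD-volume computation does not. The fixed-volume
alternative scenario instead anchors each sector at its own reference
expenditure ($p_{\mathrm{ref}} V_{\mathrm{ref}} = E_{\mathrm{ref}}$ exactly),
which preserves the identity between fixed-volume estimated savings and
real-life savings at the pre-biosimilar reference year.

```{r}
bundle <- run_pipeline(poland_tnfi())
glance(bundle)
```

## Treatment costs and the two-method sensitivity check

`unit_cost_series()` computes EUR per milligram, $E_t / V_t$;
`per_patient_cost_series()` computes EUR per patient-year,
$E_t / \mathrm{patients}_t$. Because the payer publishes volumes, spends and
patient counts in *different* data sets, agreement between the two methods
is evidence against reporting artefacts. `sensitivity_compare()` passes
when the two overall cost reductions, $100(1 - c_{\mathrm{last}} /
c_{\mathrm{ref}})$, differ by at most 5 percentage points (the default).
Single mid-series years can differ by more — per-patient cost responds to
within-year patient turnover and dose titration, per-mg cost does not — so
the per-year differences are reported descriptively, not gated.

The payer also publishes an independent per-patient cost series
(`poland_per_patient_costs()`). It deviates from spend/patients by up to
~2% in single years; the published reinvestment table was computed from
that independent series, which is why our derived counterfactual patient
counts differ from the printed ones by a fraction of a percent in some
cells.

## Exposure, access and the reinvestment counterfactual

* `ddd_series()`: milligrams over the WHO defined daily dose (INF 3.75 mg,
  ETN 7 mg, ADA 2.9 mg; configurable, as WHO revises DDDs), and the rate
  per 1000 inhabitants per year. The population default is 38.0 million,
  the national average over the period, back-derived from the published
  rate cells. Displayed DDD counts are rounded half away from zero to whole
  doses, matching the published tables.
* `potential_additional_patients()`: how many *additional* patients each
  year's real-life savings could fund at that year's per-patient cost,
  $\lfloor \max(S_t, 0) / c_t \rfloor$ — floored because a partial
  patient-year cannot be funded, clamped because negative savings fund
  nobody. The pipeline always prices patients at the whole-market
  per-patient cost, also for the RMD sector, mirroring the published
  computation.
* `era_growth()`: absolute and relative patient growth between two years,
  for comparing the biosimilar-competition era against the corresponding
  span of market exclusivity.
* `eligible_coverage()`: relates a total potential patient count to the
  biologic-eligible fraction of the disease population
  (e.g. 40–60% of ~550 000 inflammatory arthritis patients).

## The synthetic market generator

`market_scenario()` + `generate_series()` emulate the structure of a payer
series: a flat pre-biosimilar unit price `p0`; from the entry year onwards
a multiplicative decay `price_decay` per year (the entry-year price is
already reduced, as observed in practice where the first tender after
entry resets prices); volume growth `volume_growth`; patients derived from
volume at a fixed `dose_per_patient` (which makes the two costing methods
agree by construction — the sensitivity check's known null); a linear
biosimilar share takeover; and optional mean-one multiplicative lognormal
noise on price and volume (`noise_cv`), chosen because it preserves the
positivity of monetary and mass quantities. Generation is deterministic
given `seed`.

`expected_estimated_savings()` gives the closed-form noise-free expectation
$\sum_{t} V_t (p_0 - p_t)$ via geometric-series sums; the test suite checks
the pipeline against it to $10^{-9}$ relative on noise-free data and within
two standard errors over 200 noisy replicates at `noise_cv = 0.05`. The
default scenario (9 years, entry in year 4, 20% yearly price decay, 10%
volume growth) is a stylised mid-sized market; the INF-like trajectory
(decay ≈ 0.79, growth ≈ 1.2) is exercised explicitly in the tests. What the
generator does *not* emulate: tender-level price jumps (real prices fall in
steps, not smooth geometric decay), indication mix shifts, and the
sub-sector reporting inconsistencies present in real payer data — so green
synthetic tests validate the arithmetic, not the data quality issues,
which is what the packaged real data set is for.

## Numerical choices

* Monetary values are stored in EUR at full precision and rendered to
  millions with 3 decimals only at report time; reference prices are
  computed from full-precision spend/volume, never from rounded display
  costs. PLN inputs are divided by the PLN-per-EUR rate (4.4124).
* Display rounding is half-away-from-zero (`67.5% → 68%`), matching the
  payer's tables; all tests compare at full precision with explicit
  tolerances.
* Years absent from a drug's series stay absent ("N/A"), never zero-filled;
  savings sums run strictly over years after the reference year.
* Ties in `select_reference_year(rule = "peak_expenditure")` resolve to the
  earliest year.
* Flagged source-inconsistent cells are stored verbatim with a `note` and
  exempted from the cross-sector validation check.

## Known limitations

A handful of published display cells are not reachable from the published
inputs at full precision (they were evidently computed from unrounded
internal values): the ETN 2021 per-mg cost (1.07 vs printed 1.08), the
whole-market ETN reference price display (4.30 vs printed 4.29), the INF
per-patient overall reduction (84% derived vs 86% published), and the
alternative *fixed-volume* scenario totals, which the published summary
gives as slightly lower than any recomputation from the printed tables.
These discrepancies are documented here and in the tests' tolerances; they
are display-level, not model-level. The analysis applies no discounting or
inflation adjustment and reports no confidence intervals: the data are a
census of a single payer, not a sample.
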