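# biosavings

Budget-impact analysis of biosimilar market entry from annual public-payer
reimbursement records, for health-economics and pharmacoepidemiology
analysts. The package quantifies what biosimilar-driven price erosion of
TNF inhibitors (infliximab, etanercept, adalimumab) was worth to a
single-payer system, and what share of it was turned into treating more
patients, using final tender prices rather than list prices.

Two counterfactual savings models sit at its core. With
`E_t` the payer's spend, `V_t` the milligrams reimbursed, and a
reference year anchoring the pre-biosimilar state
(`p_ref = E_ref / V_ref`):

* **estimated savings** `S_t = p_ref · V_t − E_t` — the value of the
  price drop at observed utilisation;
* **real-life savings** `S_t = E_ref − E_t` — the realised budget relief
  (negative when spending grew).

Around them: per-mg and per-patient treatment-cost series with a
two-method sensitivity check, WHO DDD population-exposure rates, biosimilar
market shares, and a reinvestment counterfactual converting savings into
potential additional treated patients at the prevailing per-patient cost.
The national Poland 2013–2021 data set ships as a packaged fixture
(`poland_tnfi()`), and `market_scenario()` / `generate_series()` provide a
synthetic generator with closed-form expected savings for validation.

## Worked example

```r
library(biosavings)

rs <- poland_tnfi()
bundle <- run_pipeline(rs)
glance(bundle)
#> # A tibble: 8 × 3
#>   model                  sector grand_total_meur
#>   <chr>                  <chr>             <dbl>
#> 1 estimated              ALL                243.
#> 2 estimated              RMD                167.
#> 3 estimated_fixed_volume ALL                112.
#> 4 estimated_fixed_volume RMD                104.
#> 5 real_life              ALL                133.
#> 6 real_life              RMD                107.
#> 7 real_life_alternative  ALL                112.
#> 8 real_life_alternative  RMD                104.
```

Estimated savings across all indications total €243 million over
2014–2021, of which €167 million arise in rheumatic musculoskeletal
diseases (RMD); realised (real-life) savings are €133 million and €107
million. The alternative scenario re-anchors infliximab at its
pre-biosimilar year and shows what happens when treatment growth eats the
price cut.

Single-drug analyses chain with the pipe:

```r
ada <- drug_series(rs, "ADA", "ALL")
sav <- real_life_savings(ada, ref_year = 2018)
sav
#> <savings_series ADA [ALL, REAL_LIFE] ref 2018, total 70.879 MEUR>
#> # A tibble: 3 × 4
#>    year potential   actual  savings
#>   <int>     <dbl>    <dbl>    <dbl>
#> 1  2019  31080000 11457000 19623000
#> 2  2020  31080000  5951000 25129000
#> 3  2021  31080000  4953000 26127000

potential_additional_patients(sav, per_patient_cost_series(ada, 2018))
#> <access_report ADA [ALL], savings reference 2018>
#> ...
#> 7  2019          5706                 9772           15478
```

Reinvesting the 2019 adalimumab savings (€19.6M) at that year's
per-patient cost (€2 008) would have funded 9 772 additional
patient-years — tripling access. `render_tables(bundle, dir = "out")`
writes the seven report tables (savings, costs, exposure, reinvestment) in
the payer-report layout; `autoplot()` methods draw the corresponding
figures, and `tidy()` / `glance()` return flat tibbles.

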