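test_that("reference unit prices reproduce the published per-mg costs", {
  inf <- drug_series(poland, "INF", "ALL")
  rp <- reference_unit_price(inf, 2013)
  expect_equal(rp$unit_price, 4604000 / 958714)
  expect_equal(round(rp$unit_price, 2), 4.80)

  etn <- drug_series(poland, "ETN", "ALL")
  # published display is 4.29; the full-precision ratio sits at 4.29501
  expect_equal(reference_unit_price(etn, 2015)$unit_price,
               18455000 / 4296845)
  expect_equal(reference_unit_price(etn, 2015)$unit_price, 4.295,
               tolerance = 1e-3)

  zero <- tibble::tibble(year = 2013, mg_volume = 0, reimbursement_value = 10)
  expect_error(reference_unit_price(zero, 2013),
               class = "biosavings_error_validation")
  expect_error(reference_unit_price(inf, 1999),
               class = "biosavings_error_validation")
})

test_that("reference-year rules select pre-biosimilar and peak years", {
  inf <- drug_series(poland, "INF", "ALL")
  expect_equal(select_reference_year(inf, "peak_expenditure"), 2018)
  expect_equal(select_reference_year(inf, "pre_biosimilar",
                                     first_biosimilar_year = 2014), 2013)
  one <- tibble::tibble(year = 2015, mg_volume = 1, reimbursement_value = 5)
  expect_equal(select_reference_year(one, "peak_expenditure"), 2015)
  tie <- tibble::tibble(year = 2015:2017, mg_volume = 1,
                        reimbursement_value = c(3, 5, 5))
  expect_equal(select_reference_year(tie, "peak_expenditure"), 2016)
})

test_that("estimated savings reproduce the published single cells", {
  inf <- drug_series(poland, "INF", "ALL")
  s <- estimated_savings(inf, reference_unit_price(inf, 2013))
  expect_equal(s$savings[s$year == 2014], 2.189e6, tolerance = 5e-4)

  ada <- drug_series(poland, "ADA", "ALL")
  s <- estimated_savings(ada, reference_unit_price(ada, 2018))
  expect_equal(s$savings[s$year == 2019], 26.19e6, tolerance = 0.01 / 26.19)
  expect_equal(s$potential[s$year == 2019], (31.080e6 / 3304828) * 4003127)
})

test_that("sub-sector estimated savings use the whole-market spending share", {
  all_s <- drug_series(poland, "ETN", "ALL")
  rmd_s <- drug_series(poland, "ETN", "RMD")
  s <- estimated_savings(rmd_s, reference_unit_price(all_s, 2015),
                         scale_by = all_s)
  # published sub-sector potential = whole-market potential * spend share
  expect_equal(s$potential[s$year == 2016],
               (18.455e6 / 4296845) * 4379420 * (17.052 / 17.098),
               tolerance = 1e-9)
  expect_equal(round(s$savings[s$year == 2016] / 1e6, 2), 1.71)
})

test_that("zero price change means identically zero estimated savings", {
  series <- tibble::tibble(year = 2013:2020,
                           mg_volume = 100 * 1.3^(0:7))
  series$reimbursement_value <- 2.5 * series$mg_volume
  s <- estimated_savings(series, reference_unit_price(series, 2013))
  expect_equal(s$savings, rep(0, 7))
  expect_equal(attr(s, "total"), 0)
})

test_that("estimated savings increase as the actual unit price falls", {
  base <- tibble::tibble(year = 2013:2015, mg_volume = c(100, 120, 140))
  prices <- seq(3, 0.5, by = -0.5)
  sav <- vapply(prices, function(p) {
    s <- base
    s$reimbursement_value <- c(2 * 100, p * 120, p * 140)
    attr(estimated_savings(s, reference_unit_price(s, 2013)), "total")
  }, numeric(1))
  expect_true(all(diff(sav) > 0))
})

test_that("real-life savings are reference-minus-actual expenditure", {
  etn <- drug_series(poland, "ETN", "ALL")
  s <- real_life_savings(etn, 2015)
  expect_equal(s$savings[s$year == 2016], 1.357e6)
  inf <- drug_series(poland, "INF", "ALL")
  s <- real_life_savings(inf, 2018)
  expect_equal(s$savings[s$year == 2019], 3.152e6)
  flat <- tibble::tibble(year = 2015:2018, reimbursement_value = 7)
  expect_equal(real_life_savings(flat, 2015)$savings, rep(0, 3))
  expect_error(real_life_savings(etn, 2030),
               class = "biosavings_error_validation")
})

test_that("fixed-volume estimated savings coincide with real-life savings at the pre-biosimilar reference", {
  for (drug in c("INF", "ETN", "ADA")) {
    s <- drug_series(poland, drug, "ALL")
    ref <- poland$meta$drugs[[drug]]$first_biosimilar_year - 1
    fixed <- estimated_savings(s, reference_unit_price(s, ref),
                               mode = "fixed_volume")
    real <- real_life_savings(s, ref)
    expect_equal(fixed$savings, real$savings, tolerance = 1e-12)
  }
})

test_that("aggregation sums per-year and per-drug savings algebraically", {
  mk <- function(drug, ref) {
    s <- drug_series(poland, drug, "ALL")
    real_life_savings(s, ref)
  }
  agg <- aggregate_savings(mk("INF", 2018), mk("ETN", 2015), mk("ADA", 2018))
  expect_equal(agg$grand_total, 133.447e6)
  expect_equal(agg$per_year$savings[agg$per_year$year == 2016], 1.357e6)
  # additivity: grand total equals the sum of per-drug totals
  expect_equal(agg$grand_total, sum(agg$by_drug$total))

  alt <- aggregate_savings(mk("INF", 2013), mk("ETN", 2015), mk("ADA", 2018))
  expect_equal(alt$grand_total, 111.95e6, tolerance = 0.01 / 111.95)
  expect_equal(alt$by_drug$total[alt$by_drug$drug == "INF"], -5.913e6,
               tolerance = 0.001 / 5.913)

  expect_error(aggregate_savings(list()), class = "biosavings_error_validation")
  rmd <- real_life_savings(drug_series(poland, "INF", "RMD"), 2018)
  expect_error(aggregate_savings(mk("ETN", 2015), rmd),
               "sector", class = "biosavings_error_validation")
})

test_that("estimated savings on noise-free synthetic data equal the closed form", {
  for (cfg in list(
    market_scenario(noise_cv = 0, seed = 1L),
    market_scenario(price_decay = 0.6, volume_growth = 1.25, noise_cv = 0),
    market_scenario(years = c(2012, 2022), entry_year = 2015,
                    price_decay = 0.9, volume_growth = 0.97, noise_cv = 0))) {
    rs <- generate_series(cfg)
    s <- drug_series(rs, cfg$drug, "ALL")
    ref <- cfg$entry_year - 1
    got <- attr(estimated_savings(s, reference_unit_price(s, ref)), "total")
    expect_equal(got, expected_estimated_savings(cfg), tolerance = 1e-9)
  }
})

test_that("mean recovered savings over noisy replicates match the closed form", {
  base <- market_scenario(price_decay = 0.75, volume_growth = 1.1,
                          noise_cv = 0.05)
  expected <- expected_estimated_savings(base)
  recovered <- vapply(1:200, function(i) {
    cfg <- base
    cfg$seed <- 1000L + i
    rs <- generate_series(cfg)
    s <- drug_series(rs, cfg$drug, "ALL")
    attr(estimated_savings(s, reference_unit_price(s, cfg$entry_year - 1)),
         "total")
  }, numeric(1))
  se <- stats::sd(recovered) / sqrt(length(recovered))
  expect_lt(abs(mean(recovered) - expected), 2 * se)
})
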