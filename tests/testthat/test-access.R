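test_that("DDD counts and exposure rates reproduce the published cells", {
  inf <- ddd_series(drug_series(poland, "INF", "ALL"), ddd_mg = 3.75,
                    population = 38e6, ref_year = 2013)
  expect_equal(inf$n_ddd[inf$year == 2013], 255657)
  expect_equal(round(inf$ddd_per_1000[inf$year == 2013], 2), 6.73)
  expect_equal(round(inf$pct_of_reference[inf$year == 2021]), 448)

  ada <- ddd_series(drug_series(poland, "ADA", "ALL"), ddd_mg = 2.9,
                    population = 38e6, ref_year = 2018)
  expect_equal(ada$n_ddd[ada$year == 2018], 1139596)

  etn <- ddd_series(drug_series(poland, "ETN", "ALL"), ddd_mg = 7,
                    population = 38e6, ref_year = 2015)
  expect_equal(round(etn$pct_of_reference[etn$year == 2021]), 154)

  zero <- tibble::tibble(year = 2013, mg_volume = 0)
  z <- ddd_series(zero, 3.75, 38e6, 2013)
  expect_equal(z$n_ddd, 0)
  expect_equal(z$ddd_per_1000, 0)

  expect_error(ddd_series(zero, -1, 38e6, 2013),
               class = "biosavings_error_validation")
  expect_error(ddd_series(zero, 3.75, 0, 2013),
               class = "biosavings_error_validation")
})

test_that("DDD exposure on the whole market is what sector splits sum to", {
  # rate depends only on total milligrams, not on how volume is split
  s <- tibble::tibble(year = 2015:2017, mg_volume = c(700, 1400, 2100))
  whole <- ddd_series(s, 7, 1e6, 2015)
  half <- s; half$mg_volume <- half$mg_volume / 2
  parts <- ddd_series(half, 7, 1e6, 2015)
  expect_equal(whole$ddd_per_1000, 2 * parts$ddd_per_1000)
  expect_equal(whole$pct_of_reference, parts$pct_of_reference)
})

test_that("reinvested savings fund the published additional patient counts", {
  ada <- drug_series(poland, "ADA", "ALL")
  acc <- potential_additional_patients(real_life_savings(ada, 2018),
                                       per_patient_cost_series(ada, 2018))
  expect_equal(acc$potential_additional[acc$year == 2019], 9772)
  expect_equal(acc$total_potential[acc$year == 2019], 5706 + 9772)

  etn <- drug_series(poland, "ETN", "ALL")
  acc <- potential_additional_patients(real_life_savings(etn, 2015),
                                       per_patient_cost_series(etn, 2015))
  expect_equal(acc$potential_additional[acc$year == 2016], 206)

  # zero savings fund nobody; negative savings clamp to zero
  flat <- tibble::tibble(year = 2015:2017, reimbursement_value = c(10, 10, 20),
                         patients = c(2, 2, 2))
  acc <- potential_additional_patients(
    real_life_savings(flat, 2015), per_patient_cost_series(flat, 2015))
  expect_equal(acc$potential_additional[acc$year %in% 2016:2017], c(0, 0))
  expect_true(all(acc$potential_additional >= 0, na.rm = TRUE))
})

test_that("additional patients fall with cost and rise with savings", {
  mk_cost <- function(cost) as_cost_series(
    tibble::tibble(year = 2015:2016, cost = cost), 2015)
  sav <- real_life_savings(
    tibble::tibble(year = 2015:2016, reimbursement_value = c(100000, 40000)),
    2015)
  costs <- c(500, 1000, 2000, 4000)
  adds <- vapply(costs, function(cc)
    potential_additional_patients(
      sav, mk_cost(c(cc, cc)),
      real_patients = tibble::tibble(year = 2016, patients = 10)
    )$potential_additional, numeric(1))
  expect_true(all(diff(adds) < 0))

  deltas <- c(10000, 20000, 40000, 60000)
  adds2 <- vapply(deltas, function(d) {
    s <- real_life_savings(
      tibble::tibble(year = 2015:2016,
                     reimbursement_value = c(100000, 100000 - d)), 2015)
    potential_additional_patients(
      s, mk_cost(c(1000, 1000)),
      real_patients = tibble::tibble(year = 2016, patients = 10)
    )$potential_additional
  }, numeric(1))
  expect_true(all(diff(adds2) > 0))
})

test_that("published reinvestment table is reconstructed from printed per-patient costs", {
  printed <- poland_per_patient_costs()
  refs <- c(INF = 2018, ETN = 2015, ADA = 2018)
  expected_all <- list(  # printed all-indications additional-patient cells
    INF = c("2019" = 1234, "2020" = 4092, "2021" = 5549),
    ETN = c("2016" = 206, "2017" = 978, "2018" = 2214, "2019" = 3760,
            "2020" = 5337, "2021" = 5787),
    ADA = c("2019" = 9772, "2020" = 24606, "2021" = 35009))
  for (drug in names(expected_all)) {
    s <- drug_series(poland, drug, "ALL")
    pc <- printed[printed$drug == drug, ]
    costs <- as_cost_series(tibble::tibble(year = pc$year, cost = pc$cost_eur),
                            ref_year = refs[[drug]], method = "per_patient",
                            drug = drug, sector = "ALL")
    acc <- potential_additional_patients(
      real_life_savings(s, refs[[drug]]), costs,
      real_patients = s[, c("year", "patients")])
    exp_cells <- expected_all[[drug]]
    got <- acc$potential_additional[match(as.integer(names(exp_cells)),
                                          acc$year)]
    tol <- pmax(2, 0.005 * exp_cells)  # paper rounding slack
    expect_true(all(abs(got - exp_cells) <= tol),
                label = paste(drug, "reinvestment cells"))
  }
})

test_that("era growth matches the published patient increases", {
  inf <- era_growth(drug_series(poland, "INF", "RMD"), c(2013, 2021))
  expect_equal(inf$absolute, 216)
  expect_equal(inf$relative, 100 * 216 / 106)

  etn <- era_growth(drug_series(poland, "ETN", "RMD"), c(2015, 2021))
  expect_equal(etn$absolute, 955)

  same <- era_growth(drug_series(poland, "INF", "RMD"), c(2016, 2016))
  expect_equal(same$absolute, 0)
  expect_equal(same$relative, 0)

  expect_error(era_growth(drug_series(poland, "INF", "RMD"), c(2005, 2021)),
               "2005", class = "biosavings_error_validation")
})

test_that("market shares split spending between originator and biosimilars", {
  products <- tibble::tibble(name = c("Ref", "BioA", "BioB"),
                             biosimilar = c(FALSE, TRUE, TRUE))
  only_ref <- tibble::tibble(product = "Ref", year = 2015, spend = 10)
  ms <- market_share(only_ref, products)
  expect_equal(ms$reference_share, 100)
  expect_equal(ms$biosimilar_share, 0)

  equal_split <- tibble::tibble(product = c("Ref", "BioA"), year = 2016,
                                spend = c(5, 5))
  ms <- market_share(equal_split, products)
  expect_equal(ms$reference_share, 50)
  expect_equal(ms$biosimilar_share, 50)

  unknown <- tibble::tibble(product = "Mystery", year = 2016, spend = 1)
  expect_error(market_share(unknown, products),
               class = "biosavings_error_validation")
})

test_that("eligible-population coverage matches the published 14-20% band", {
  expect_equal(eligible_coverage(44663, 550000, 0.40), 20.3, tolerance = 0.05 / 20.3)
  expect_equal(eligible_coverage(44663, 550000, 0.60), 13.5, tolerance = 0.05 / 13.5)
  expect_equal(eligible_coverage(1000, 1000, 1), 100)
  expect_error(eligible_coverage(0, 550000, 0.4),
               class = "biosavings_error_validation")
  expect_error(eligible_coverage(100, 550000, 1.4),
               class = "biosavings_error_validation")
})
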