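#' DDD-based population exposure series
#'
#' Converts annual milligram utilisation into WHO defined daily doses
#' (`n_ddd = mg / ddd_mg`, displayed as whole doses, rounded half away from
#' zero as in the payer's published tables) and into the exposure rate
#' `DDD per 1000 inhabitants per year`, with a percent-of-reference index.
#' A year is preferred to a day as the rate's time unit because annual
#' national volumes of these drugs are small on the per-day scale.
#'
#' @param series Annual series with `mg_volume`.
#' @param ddd_mg WHO defined daily dose in milligrams (positive).
#' @param population Inhabitants (positive); average over the period.
#' @param ref_year Anchor year for the percentage index.
#' @return A `ddd_series` tibble: `year`, `n_ddd` (whole doses),
#'   `ddd_per_1000` (full precision), `pct_of_reference`.
#' @examples
#' rs <- poland_tnfi()
#' ddd_series(drug_series(rs, "INF", "ALL"), ddd_mg = 3.75,
#'            population = 38e6, ref_year = 2013)
#' @export
ddd_series <- function(series, ddd_mg, population, ref_year) {
  if (!is.numeric(ddd_mg) || ddd_mg <= 0) stop_validation("ddd_mg must be positive")
  if (!is.numeric(population) || population <= 0) {
    stop_validation("population must be positive")
  }
  series <- assert_year_series(series, c("year", "mg_volume"))
  keep <- series[!is.na(series$mg_volume), ]
  n_exact <- keep$mg_volume / ddd_mg
  ref_idx <- which(keep$year == ref_year)
  if (length(ref_idx) == 0) {
    stop_validation(paste0("reference year ", ref_year, " absent from series"))
  }
  per_year <- tibble(
    year = keep$year,
    n_ddd = round_half_up(n_exact),
    ddd_per_1000 = n_exact / (population / 1000),
    pct_of_reference = 100 * n_exact / n_exact[ref_idx])
  new_result_tbl(per_year, "ddd_series",
                 drug = attr(series, "drug") %||% NA_character_,
                 ddd_mg = ddd_mg, population = population,
                 ref_year = ref_year)
}

#' Savings-reinvestment counterfactual: potential additional patients
#'
#' For each year with realised savings, the number of additional patients
#' whose full annual treatment those savings could fund at that year's
#' per-patient cost: `floor(savings_t / cost_t)`, since a partial
#' patient-year cannot be funded; negative savings fund nobody (clamped to
#' zero, never negative counts). The total potential is the real count plus
#' the hypothetical additions.
#'
#' @param savings A `savings_series` (typically [real_life_savings()]).
#' @param per_patient_cost A `cost_series` with `method = "per_patient"`
#'   covering every savings year.
#' @param real_patients Optional `year`/`patients` data frame of real
#'   treated counts; defaults to the counts carried by `per_patient_cost`
#'   when it was derived from payer records.
#' @return An `access_report` tibble: `year`, `real_patients`,
#'   `potential_additional`, `total_potential`.
#' @examples
#' rs <- poland_tnfi()
#' ada <- drug_series(rs, "ADA", "ALL")
#' potential_additional_patients(
#'   real_life_savings(ada, 2018),
#'   per_patient_cost_series(ada, 2018))
#' @export
potential_additional_patients <- function(savings, per_patient_cost,
                                          real_patients = NULL) {
  stopifnot(inherits(savings, "savings_series"),
            inherits(per_patient_cost, "cost_series"))
  missing_years <- setdiff(savings$year, per_patient_cost$year)
  if (length(missing_years) > 0) {
    stop_validation(paste0("no per-patient cost for year ", missing_years[1]))
  }
  if (is.null(real_patients)) {
    pts <- attr(per_patient_cost, "patients")
    if (!is.null(pts)) {
      real_patients <- tibble(year = as.integer(names(pts)),
                              patients = as.numeric(pts))
    } else {
      real_patients <- tibble(year = savings$year, patients = NA_real_)
    }
  }
  real_patients <- assert_year_series(real_patients, c("year", "patients"))
  cost <- per_patient_cost$cost[match(real_patients$year,
                                      per_patient_cost$year)]
  sav <- savings$savings[match(real_patients$year, savings$year)]
  additional <- ifelse(is.na(sav), NA_real_,
                       floor(pmax(sav, 0) / cost))
  real_n <- real_patients$patients
  per_year <- tibble(
    year = real_patients$year,
    real_patients = real_n,
    potential_additional = additional,
    total_potential = real_n + dplyr::coalesce(additional, 0))
  new_result_tbl(per_year, "access_report",
                 drug = attr(savings, "drug"),
                 sector = attr(savings, "sector"),
                 ref_year = attr(savings, "ref_year"))
}

#' Patient-count growth over an era
#'
#' Absolute and relative change in the number of treated patients between
#' two years, used to compare growth under biosimilar competition with the
#' corresponding span of reference-drug market exclusivity.
#'
#' @param series Annual series with `patients`.
#' @param era Length-2 vector `c(start_year, end_year)`, both present.
#' @return One-row tibble: `start_year`, `end_year`, `absolute` (patients),
#'   `relative` (percent of the start-year count).
#' @examples
#' rs <- poland_tnfi()
#' era_growth(drug_series(rs, "INF", "RMD"), c(2013, 2021)) # +216 patients
#' @export
era_growth <- function(series, era) {
  series <- assert_year_series(series, c("year", "patients"))
  if (length(era) != 2) stop_validation("era must be c(start, end)")
  p <- series$patients[match(era, series$year)]
  if (anyNA(p)) {
    stop_validation(paste0("patient count absent for year ",
                           era[which(is.na(p))[1]]))
  }
  tibble(start_year = era[1], end_year = era[2],
         absolute = p[2] - p[1],
         relative = 100 * (p[2] - p[1]) / p[1])
}

#' Reference versus biosimilar market share by spending
#'
#' Shares of annual reimbursement value attributed to the reference
#' (originator) product versus biosimilars, summing to 100% per year.
#'
#' @param product_spend Data frame with columns `product`, `year`, `spend`.
#' @param meta Drug metadata entry whose `products` table flags each product
#'   (columns `name`, `biosimilar`), or such a products data frame directly.
#' @return Tibble: `year`, `reference_share`, `biosimilar_share` (percent).
#' @export
market_share <- function(product_spend, meta) {
  products <- if (is.data.frame(meta)) meta else meta$products
  if (is.null(products)) stop_validation("no product flags supplied")
  if (!is.data.frame(product_spend) ||
      !all(c("product", "year", "spend") %in% names(product_spend))) {
    stop_schema("product_spend needs columns product, year, spend")
  }
  unknown <- setdiff(unique(product_spend$product), products$name)
  if (length(unknown) > 0) {
    stop_validation(paste0("product without biosimilar flag: ", unknown[1]))
  }
  product_spend |>
    mutate(biosimilar = products$biosimilar[match(.data$product,
                                                  products$name)]) |>
    group_by(.data$year) |>
    summarise(
      reference_share = 100 * sum(.data$spend[!.data$biosimilar]) /
        sum(.data$spend),
      biosimilar_share = 100 * sum(.data$spend[.data$biosimilar]) /
        sum(.data$spend),
      .groups = "drop") |>
    arrange(.data$year)
}

#' Share of the biologic-eligible population that could be treated
#'
#' Relates a total potential number of treated patients (real plus
#' savings-funded additions) to the biologic-eligible fraction of the
#' disease population: `100 * total_potential / (population * rate)`.
#'
#' @param total_potential Total potential treated patients.
#' @param ia_population Disease (inflammatory arthritis) population size.
#' @param eligibility_rate Fraction of that population eligible for
#'   biologics, in (0, 1].
#' @return Coverage percentage.
#' @examples
#' eligible_coverage(44663, 550000, 0.40) # ~20%
#' @export
eligible_coverage <- function(total_potential, ia_population, eligibility_rate) {
  if (any(c(total_potential, ia_population, eligibility_rate) <= 0) ||
      eligibility_rate > 1) {
    stop_validation(
      "inputs must be positive and eligibility_rate in (0, 1]")
  }
  100 * total_potential / (ia_population * eligibility_rate)
}

#' @export
print.ddd_series <- function(x, ...) {
  cat(sprintf("<ddd_series %s: DDD %.4g mg, population %s, ref %d>\n",
              attr(x, "drug"), attr(x, "ddd_mg"),
              format(attr(x, "population"), big.mark = " "),
              attr(x, "ref_year")))
  NextMethod()
}

#' @export
print.access_report <- function(x, ...) {
  cat(sprintf("<access_report %s [%s], savings reference %d>\n",
              attr(x, "drug"), attr(x, "sector"), attr(x, "ref_year")))
  NextMethod()
}
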