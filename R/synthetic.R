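#' Synthetic biosimilar market scenario
#'
#' Configuration for a synthetic annual payer series with known ground
#' truth: a flat pre-biosimilar unit price, multiplicative price decay from
#' the biosimilar entry year onwards (the entry-year price is already
#' reduced), multiplicative volume growth, patient counts derived from
#' volume at a fixed mean annual dose, and a linear biosimilar market-share
#' takeover. Optional multiplicative lognormal noise (mean 1) perturbs
#' price and volume independently, preserving positivity.
#'
#' @param drug Identifier for the synthetic drug.
#' @param years Length-2 span `c(start, end)`.
#' @param entry_year First biosimilar year (within the span, after `start`).
#' @param p0 Pre-entry unit price (EUR/mg).
#' @param price_decay Per-year multiplicative price factor after entry,
#'   in (0, 1]; the price in entry year is already `p0 * price_decay`.
#' @param v0 Baseline annual volume (mg) in the start year.
#' @param volume_growth Per-year multiplicative volume factor.
#' @param dose_per_patient Mean annual milligrams per treated patient.
#' @param share_takeover Per-year increase of the biosimilar share of
#'   spending from entry onwards, in `[0, 1]` (capped at 1).
#' @param noise_cv Coefficient of variation of the lognormal noise applied
#'   to yearly price and volume (0 = deterministic).
#' @param seed Integer seed; generation is deterministic given the config.
#' @param ddd_mg Defined daily dose (mg) recorded in the metadata.
#' @param population Population used for exposure rates.
#' @return An object of class `market_scenario`.
#' @export
market_scenario <- function(drug = "SYN",
                            years = c(2013, 2021),
                            entry_year = 2016,
                            p0 = 5,
                            price_decay = 0.8,
                            v0 = 1e6,
                            volume_growth = 1.1,
                            dose_per_patient = 1500,
                            share_takeover = 0.35,
                            noise_cv = 0,
                            seed = 1L,
                            ddd_mg = 3.5,
                            population = 38e6) {
  cfg <- structure(as.list(environment()), class = "market_scenario")
  if (length(years) != 2 || years[2] < years[1]) {
    stop_validation("years must be c(start, end) with end >= start")
  }
  if (entry_year <= years[1] || entry_year > years[2]) {
    stop_validation("entry_year must lie inside the span (after the start year)")
  }
  if (p0 <= 0 || v0 <= 0) stop_validation("p0 and v0 must be positive")
  if (price_decay <= 0 || price_decay > 1) {
    stop_validation("price_decay must be in (0, 1]")
  }
  if (share_takeover < 0 || share_takeover > 1) {
    stop_validation("share_takeover must be in [0, 1]")
  }
  if (noise_cv < 0) stop_validation("noise_cv must be nonnegative")
  cfg
}

# noise-free price and volume paths implied by a scenario
scenario_paths <- function(config) {
  yrs <- seq(config$years[1], config$years[2])
  post <- pmax(0, yrs - config$entry_year + 1)
  tibble(
    year = yrs,
    price = config$p0 * config$price_decay^post,
    volume = config$v0 * config$volume_growth^(yrs - config$years[1]),
    biosimilar_share = pmin(1, ifelse(post > 0, post * config$share_takeover, 0)))
}

#' Generate a synthetic payer record set
#'
#' Yearly unit price `p_t = p0 * price_decay^max(0, t - entry_year + 1)` and
#' volume `V_t = v0 * volume_growth^(t - start)`, each multiplied by
#' independent mean-1 lognormal noise; `reimbursement_value = p_t * V_t` and
#' `patients = round(V_t / dose_per_patient)`. The returned record set
#' passes [validate_recordset()] and carries a `truth` attribute with the
#' noise-free paths, the configured biosimilar spending shares, product-level
#' spending, and the closed-form expected savings.
#'
#' @param config A [market_scenario()].
#' @return A `recordset` (sector `"ALL"`) with attribute `truth`.
#' @export
generate_series <- function(config) {
  stopifnot(inherits(config, "market_scenario"))
  paths <- scenario_paths(config)
  n <- nrow(paths)
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  noisy <- withr::with_seed(config$seed, {
    list(price = paths$price * rlnorm(n, -sdlog^2 / 2, sdlog),
         volume = paths$volume * rlnorm(n, -sdlog^2 / 2, sdlog))
  })
  rec <- tibble(
    drug = config$drug,
    year = paths$year,
    sector = "ALL",
    mg_volume = noisy$volume,
    reimbursement_value = noisy$price * noisy$volume,
    patients = as.integer(round(noisy$volume / config$dose_per_patient)),
    currency = "EUR",
    note = "")
  meta <- list(
    population = config$population,
    pln_per_eur = 1,
    drugs = setNames(list(list(
      name = config$drug,
      first_biosimilar_year = config$entry_year,
      ddd_mg = config$ddd_mg,
      products = tibble(
        name = paste0(config$drug, c("_ref", "_biosim")),
        biosimilar = c(FALSE, TRUE),
        from = c(config$years[1], config$entry_year),
        to = config$years[2]))), config$drug))
  rs <- recordset(rec, meta)
  attr(rs, "truth") <- list(
    paths = paths,
    product_spend = tibble(
      product = rep(paste0(config$drug, c("_ref", "_biosim")), each = n),
      year = rep(paths$year, 2),
      spend = c(rec$reimbursement_value * (1 - paths$biosimilar_share),
                rec$reimbursement_value * paths$biosimilar_share)),
    expected_savings = expected_estimated_savings(config))
  rs
}

#' Closed-form expected estimated savings of a scenario
#'
#' Noise-free expectation of the estimated-savings counterfactual on a
#' generated series: `sum over post-entry years of V_t * (p0 - p_t)`,
#' evaluated analytically via geometric-series sums (the reference year is
#' the year before biosimilar entry, whose unit price is `p0`).
#'
#' @param config A [market_scenario()].
#' @return Expected total savings in EUR.
#' @export
expected_estimated_savings <- function(config) {
  stopifnot(inherits(config, "market_scenario"))
  n <- config$years[2] - config$entry_year + 1
  g <- config$volume_growth
  f <- config$price_decay
  e0 <- config$entry_year - config$years[1]
  # sum_{k=1..n} g^(k-1) and sum_{k=1..n} g^(k-1) f^k
  geom <- function(r, n) if (abs(r - 1) < 1e-12) n else (r^n - 1) / (r - 1)
  config$p0 * config$v0 * g^e0 * (geom(g, n) - f * geom(g * f, n))
}

#' @export
print.market_scenario <- function(x, ...) {
  cat(sprintf(
    "<market_scenario %s: %d-%d, entry %d, p0=%.3g, decay=%.3g, growth=%.3g, cv=%.3g>\n",
    x$drug, x$years[1], x$years[2], x$entry_year, x$p0, x$price_decay,
    x$volume_growth, x$noise_cv))
  invisible(x)
}
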