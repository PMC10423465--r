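#' Reference unit price for the counterfactual
#'
#' The counterfactual "pre-biosimilar" price is the reference year's spend
#' divided by its volume, kept at full precision (never the rounded per-mg
#' display cost), so that multi-year potential-spend sums do not compound
#' rounding error.
#'
#' @param series Annual series for one drug/sector (see [drug_series()]).
#' @param ref_year Reference year; must be present with positive volume.
#' @return A one-row tibble of class `reference_price` with columns
#'   `drug`, `sector`, `ref_year`, `unit_price` (EUR/mg).
#' @examples
#' rs <- poland_tnfi()
#' reference_unit_price(drug_series(rs, "INF", "ALL"), 2013) # ~4.80 EUR/mg
#' @export
reference_unit_price <- function(series, ref_year) {
  series <- assert_year_series(series, c("year", "mg_volume",
                                         "reimbursement_value"))
  row <- series[series$year == ref_year, ]
  if (nrow(row) == 0) {
    stop_validation(paste0("reference year ", ref_year, " absent from series"))
  }
  if (is.na(row$mg_volume) || row$mg_volume <= 0) {
    stop_validation(paste0("reference year ", ref_year,
                           " has no positive mg_volume"))
  }
  new_result_tbl(
    tibble(drug = attr(series, "drug") %||% NA_character_,
           sector = attr(series, "sector") %||% NA_character_,
           ref_year = ref_year,
           unit_price = row$reimbursement_value / row$mg_volume),
    "reference_price")
}

#' Select the reference year for a savings model
#'
#' `"pre_biosimilar"` anchors at the year preceding first biosimilar
#' reimbursement; `"peak_expenditure"` anchors at the year of maximum
#' spending (ties resolved to the earliest year), the rule used for drugs
#' whose expenditure peaked after biosimilar entry because pre-entry use
#' was marginal.
#'
#' @param series Annual series.
#' @param rule Reference-year rule.
#' @param first_biosimilar_year Needed for the `"pre_biosimilar"` rule.
#' @return The selected calendar year.
#' @export
select_reference_year <- function(series,
                                  rule = c("pre_biosimilar", "peak_expenditure"),
                                  first_biosimilar_year = NULL) {
  rule <- match.arg(rule)
  series <- assert_year_series(series)
  if (nrow(series) == 0) stop_validation("empty series")
  if (rule == "pre_biosimilar") {
    if (is.null(first_biosimilar_year)) {
      stop_validation("first_biosimilar_year required for the pre_biosimilar rule")
    }
    yr <- first_biosimilar_year - 1
    if (!yr %in% series$year) {
      stop_validation(paste0("pre-biosimilar year ", yr, " absent from series"))
    }
    yr
  } else {
    ok <- !is.na(series$reimbursement_value)
    cand <- series[ok, ]
    cand$year[which.max(cand$reimbursement_value)]
  }
}

new_savings_series <- function(per_year, model, ref_year, series) {
  new_result_tbl(per_year, "savings_series",
                 drug = attr(series, "drug") %||% NA_character_,
                 sector = attr(series, "sector") %||% NA_character_,
                 model = model, ref_year = ref_year,
                 total = sum(per_year$savings))
}

#' Estimated (counterfactual-price) savings
#'
#' The estimated model prices each post-reference year's utilisation at the
#' reference unit price: `potential_t = unit_price * V_t` (actual-volume
#' mode) or `potential_t = unit_price * V_ref` (fixed-volume alternative
#' scenario); savings are `potential_t - actual_t` and may be negative.
#'
#' For a sub-sector (e.g. RMDs) the payer reports volumes that are not
#' always consistent across tables, so the published analysis derives the
#' sub-sector potential by scaling the whole-market potential with the
#' sub-sector's share of actual spending. Pass the whole-market series as
#' `scale_by` to reproduce that:
#' `potential_t = unit_price(parent) * V_parent_t * (E_t / E_parent_t)`.
#'
#' @param series Annual series for the drug/sector being analysed.
#' @param ref_price A [reference_unit_price()] (computed on `scale_by`
#'   when scaling is used).
#' @param mode `"actual_volume"` (default) or `"fixed_volume"`.
#' @param scale_by Optional whole-market annual series for spending-share
#'   scaling of a sub-sector.
#' @return A `savings_series` tibble: `year`, `potential`, `actual`,
#'   `savings` (EUR), with attributes `model`, `ref_year` and `total`.
#' @examples
#' rs <- poland_tnfi()
#' inf <- drug_series(rs, "INF", "ALL")
#' estimated_savings(inf, reference_unit_price(inf, 2013))
#' @export
estimated_savings <- function(series, ref_price,
                              mode = c("actual_volume", "fixed_volume"),
                              scale_by = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(ref_price, "reference_price"))
  series <- assert_year_series(series, c("year", "reimbursement_value"))
  ref_year <- ref_price$ref_year
  post <- series[series$year > ref_year, ]
  if (nrow(post) == 0) stop_validation("no years after the reference year")
  bad <- post$year[is.na(post$reimbursement_value)]
  if (length(bad) > 0) {
    stop_validation(paste0("missing reimbursement value for year ", bad[1]))
  }
  p <- ref_price$unit_price
  if (is.null(scale_by)) {
    if (!"mg_volume" %in% names(series)) {
      stop_schema("series is missing column(s): mg_volume")
    }
    bad <- post$year[is.na(post$mg_volume)]
    if (length(bad) > 0 && mode == "actual_volume") {
      stop_validation(paste0("missing mg_volume for year ", bad[1]))
    }
    v_ref <- series$mg_volume[series$year == ref_year]
    potential <- switch(mode,
      actual_volume = p * post$mg_volume,
      fixed_volume = rep(p * v_ref, nrow(post)))
  } else {
    parent <- assert_year_series(scale_by, c("year", "mg_volume",
                                             "reimbursement_value"))
    pp <- parent[match(post$year, parent$year), ]
    if (anyNA(pp$reimbursement_value) || anyNA(pp$mg_volume)) {
      stop_validation("scale_by series does not cover all post-reference years")
    }
    v_ref <- parent$mg_volume[parent$year == ref_year]
    parent_potential <- switch(mode,
      actual_volume = p * pp$mg_volume,
      fixed_volume = rep(p * v_ref, nrow(post)))
    potential <- parent_potential *
      (post$reimbursement_value / pp$reimbursement_value)
  }
  per_year <- tibble(year = post$year, potential = potential,
                     actual = post$reimbursement_value,
                     savings = potential - post$reimbursement_value)
  model <- if (mode == "actual_volume") "ESTIMATED" else "ESTIMATED_FIXED_VOLUME"
  new_savings_series(per_year, model, ref_year, series)
}

#' Real-life (expenditure-difference) savings
#'
#' Realised payer savings: reference-year expenditure minus each subsequent
#' year's expenditure, `savings_t = E_ref - E_t`. Negative values mean the
#' payer's spending grew relative to the reference year.
#'
#' @param series Annual series.
#' @param ref_year Reference year present in the series.
#' @return A `savings_series` tibble (`potential` is the constant `E_ref`).
#' @examples
#' rs <- poland_tnfi()
#' real_life_savings(drug_series(rs, "ETN", "ALL"), 2015)
#' @export
real_life_savings <- function(series, ref_year) {
  series <- assert_year_series(series, c("year", "reimbursement_value"))
  ref <- series$reimbursement_value[series$year == ref_year]
  if (length(ref) == 0 || is.na(ref)) {
    stop_validation(paste0("reference year ", ref_year, " absent from series"))
  }
  post <- series[series$year > ref_year & !is.na(series$reimbursement_value), ]
  if (nrow(post) == 0) stop_validation("no years after the reference year")
  per_year <- tibble(year = post$year, potential = ref,
                     actual = post$reimbursement_value,
                     savings = ref - post$reimbursement_value)
  new_savings_series(per_year, "REAL_LIFE", ref_year, series)
}

#' Aggregate savings series across drugs
#'
#' Per-year totals sum algebraically across drugs (years absent from a
#' drug's series contribute nothing; negative savings are included), and the
#' grand total sums the per-year totals. All series must come from the same
#' sector.
#'
#' @param ... `savings_series` objects, or a single list of them.
#' @return An object of class `savings_aggregate`: list with `by_drug`
#'   (drug, ref_year, model, total), `per_year` (year, savings) and
#'   `grand_total` (EUR).
#' @export
aggregate_savings <- function(...) {
  serieses <- list(...)
  if (length(serieses) == 1 && !inherits(serieses[[1]], "savings_series")) {
    serieses <- serieses[[1]]
  }
  if (length(serieses) == 0) stop_validation("nothing to aggregate")
  ok <- vapply(serieses, inherits, logical(1), "savings_series")
  if (!all(ok)) stop_validation("inputs must be savings_series objects")
  sectors <- unique(vapply(serieses, attr, character(1), "sector"))
  sectors <- sectors[!is.na(sectors)]
  if (length(sectors) > 1) {
    stop_validation(paste0("cannot aggregate across sectors: ",
                           paste(sectors, collapse = ", ")))
  }
  by_drug <- purrr::map_dfr(serieses, function(s) {
    tibble(drug = attr(s, "drug"), sector = attr(s, "sector"),
           model = attr(s, "model"), ref_year = attr(s, "ref_year"),
           total = attr(s, "total"))
  })
  per_year <- purrr::map_dfr(serieses, ~ .x[, c("year", "savings")]) |>
    group_by(.data$year) |>
    summarise(savings = sum(.data$savings), .groups = "drop") |>
    arrange(.data$year)
  structure(list(by_drug = by_drug, per_year = per_year,
                 grand_total = sum(per_year$savings),
                 sector = if (length(sectors)) sectors else NA_character_),
            class = "savings_aggregate")
}

#' @export
print.savings_series <- function(x, ...) {
  cat(sprintf("<savings_series %s [%s, %s] ref %d, total %.3f MEUR>\n",
              attr(x, "drug"), attr(x, "sector"), attr(x, "model"),
              attr(x, "ref_year"), attr(x, "total") / 1e6))
  NextMethod()
}

#' @export
print.savings_aggregate <- function(x, ...) {
  cat(sprintf("<savings_aggregate [%s]: %d drugs, grand total %.3f MEUR>\n",
              x$sector, nrow(x$by_drug), x$grand_total / 1e6))
  print(x$by_drug)
  invisible(x)
}
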