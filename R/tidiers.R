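# broom-style tidiers: tidy() returns the per-year rows with the series
# annotations as columns; glance() returns the one-row summary.

#' @export
tidy.savings_series <- function(x, ...) {
  tibble(drug = attr(x, "drug"), sector = attr(x, "sector"),
         model = attr(x, "model"), ref_year = attr(x, "ref_year"),
         as_tibble(x))
}

#' @export
glance.savings_series <- function(x, ...) {
  tibble(drug = attr(x, "drug"), sector = attr(x, "sector"),
         model = attr(x, "model"), ref_year = attr(x, "ref_year"),
         n_years = nrow(x), total = attr(x, "total"))
}

#' @export
tidy.savings_aggregate <- function(x, ...) x$per_year

#' @export
glance.savings_aggregate <- function(x, ...) {
  tibble(sector = x$sector, n_drugs = nrow(x$by_drug),
         grand_total = x$grand_total)
}

#' @export
tidy.cost_series <- function(x, ...) {
  tibble(drug = attr(x, "drug"), sector = attr(x, "sector"),
         method = attr(x, "method"), ref_year = attr(x, "ref_year"),
         as_tibble(x))
}

#' @export
glance.cost_series <- function(x, ...) {
  tibble(drug = attr(x, "drug"), sector = attr(x, "sector"),
         method = attr(x, "method"), ref_year = attr(x, "ref_year"),
         overall_reduction = attr(x, "overall_reduction"))
}

#' @export
tidy.ddd_series <- function(x, ...) {
  tibble(drug = attr(x, "drug"), ddd_mg = attr(x, "ddd_mg"), as_tibble(x))
}

#' @export
glance.ddd_series <- function(x, ...) {
  last <- x[which.max(x$year), ]
  tibble(drug = attr(x, "drug"), ddd_mg = attr(x, "ddd_mg"),
         population = attr(x, "population"), ref_year = attr(x, "ref_year"),
         last_year = last$year, last_pct_of_reference = last$pct_of_reference)
}

#' @export
tidy.access_report <- function(x, ...) {
  tibble(drug = attr(x, "drug"), sector = attr(x, "sector"), as_tibble(x))
}

#' @export
glance.access_report <- function(x, ...) {
  tibble(drug = attr(x, "drug"), sector = attr(x, "sector"),
         ref_year = attr(x, "ref_year"),
         total_additional = sum(x$potential_additional, na.rm = TRUE),
         last_total_potential = x$total_potential[which.max(x$year)])
}

#' @export
tidy.sensitivity_comparison <- function(x, ...) {
  tibble(drug = attr(x, "drug"), sector = attr(x, "sector"), as_tibble(x))
}

#' @export
glance.sensitivity_comparison <- function(x, ...) {
  tibble(drug = attr(x, "drug"), sector = attr(x, "sector"),
         overall_diff = attr(x, "overall_diff"),
         max_abs_diff = attr(x, "max_abs_diff"),
         tolerance = attr(x, "tolerance"), pass = attr(x, "pass"))
}

#' @export
tidy.bia_bundle <- function(x, ...) {
  purrr::map_dfr(names(x$savings), function(model)
    purrr::map_dfr(names(x$savings[[model]]), function(sector)
      purrr::map_dfr(x$savings[[model]][[sector]]$series, tidy)))
}
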