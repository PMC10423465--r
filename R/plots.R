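#' Plot methods for analysis results
#'
#' `autoplot()` methods give quick diagnostic figures: yearly savings bars,
#' cost percent-of-reference trajectories, DDD exposure rates, and real
#' versus potential treated patients.
#'
#' @param object A result object from this package.
#' @param ... Unused.
#' @return A ggplot object.
#' @name biosavings-autoplot
NULL

#' @rdname biosavings-autoplot
#' @export
autoplot.savings_series <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = factor(.data$year), y = .data$savings / 1e6)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = "Year", y = "Savings (million EUR)",
      title = sprintf("%s savings, %s [%s], reference %d",
                      attr(object, "model"), attr(object, "drug"),
                      attr(object, "sector"), attr(object, "ref_year"))) +
    ggplot2::theme_minimal()
}

#' @rdname biosavings-autoplot
#' @export
autoplot.cost_series <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$year, y = .data$pct_of_reference)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(
      x = "Year", y = "% of reference cost",
      title = sprintf("Treatment cost (%s), %s, reference %d",
                      attr(object, "method"), attr(object, "drug"),
                      attr(object, "ref_year"))) +
    ggplot2::theme_minimal()
}

#' @rdname biosavings-autoplot
#' @export
autoplot.ddd_series <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$year, y = .data$ddd_per_1000)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Year", y = "DDD per 1000 inhabitants per year",
                  title = sprintf("Drug exposure, %s", attr(object, "drug"))) +
    ggplot2::theme_minimal()
}

#' @rdname biosavings-autoplot
#' @export
autoplot.access_report <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("real_patients", "potential_additional"),
                        names_to = "component", values_to = "patients") |>
    filter(!is.na(.data$patients))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$year),
                                   y = .data$patients,
                                   fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(real_patients = "grey40",
                 potential_additional = "steelblue"),
      labels = c(real_patients = "treated",
                 potential_additional = "potential additional")) +
    ggplot2::labs(
      x = "Year", y = "Patients", fill = NULL,
      title = sprintf("Reinvestment counterfactual, %s [%s]",
                      attr(object, "drug"), attr(object, "sector"))) +
    ggplot2::theme_minimal()
}
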