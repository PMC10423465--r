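# internal helpers shared across modules

# round half away from zero; base round() is half-to-even, which disagrees
# with how the payer tables are printed (e.g. 67.5% -> 68%)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# thousands separated with a thin space, the convention used for milligram,
# DDD and patient counts in rendered tables ("255 657")
fmt_thin <- function(x) {
  ifelse(is.na(x), "N/A",
         formatC(x, format = "d", big.mark = " "))
}

# monetary EUR -> "millions, 3 decimals" display string
fmt_meur <- function(x) {
  ifelse(is.na(x), "N/A", sprintf("%.3f", x / 1e6))
}

stop_schema <- function(msg) abort(msg, class = "biosavings_error_schema")
stop_validation <- function(msg) abort(msg, class = "biosavings_error_validation")
stop_lookup <- function(msg) abort(msg, class = "biosavings_error_lookup")

# attribute-preserving constructor for classed result tibbles
new_result_tbl <- function(df, class, ...) {
  out <- as_tibble(df)
  attrs <- list(...)
  for (nm in names(attrs)) attr(out, nm) <- attrs[[nm]]
  class(out) <- c(class, class(out))
  out
}

assert_year_series <- function(series, cols = c("year", "reimbursement_value")) {
  if (!is.data.frame(series)) {
    stop_validation("`series` must be a data frame of annual records")
  }
  missing <- setdiff(cols, names(series))
  if (length(missing) > 0) {
    stop_schema(paste0("series is missing column(s): ",
                       paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(series$year) > 0) {
    stop_validation("series has duplicated years")
  }
  dplyr::arrange(series, .data$year)
}
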