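#' Annual payer record sets
#'
#' A record set bundles the long-format annual reimbursement records
#' (one row per drug x year x sector) with drug metadata, the population
#' size and the currency rate, after validating the joint invariants.
#'
#' Records carry: `drug` (identifier, e.g. `"INF"`), `year`, `sector`
#' (`"ALL"` = all reimbursed indications; `"RMD"` = rheumatic musculoskeletal
#' diseases only), `mg_volume` (milligrams reimbursed, `NA` when the payer did
#' not report volume for that year), `reimbursement_value` (EUR, full
#' precision), `patients` (treated individuals) and an optional free-text
#' `note` flagging source-table inconsistencies. Flagged rows are stored
#' verbatim and exempted from the cross-sector consistency check.
#'
#' @param records Data frame of annual records (see Details).
#' @param meta Metadata list as returned by [read_meta()]: per-drug
#'   `first_biosimilar_year`, `ddd_mg` and product list, plus `population`
#'   and `pln_per_eur`.
#' @param population Average population over the analysed period; defaults to
#'   `meta$population`.
#' @param pln_per_eur PLN per 1 EUR; defaults to `meta$pln_per_eur`.
#' @return An object of class `recordset`.
#' @seealso [read_recordset()], [drug_series()], [poland_tnfi()]
#' @export
recordset <- function(records, meta, population = meta$population,
                      pln_per_eur = meta$pln_per_eur) {
  records <- as_tibble(records)
  if (!"note" %in% names(records)) records$note <- ""
  records$note[is.na(records$note)] <- ""
  rs <- structure(
    list(records = dplyr::arrange(records, .data$drug, .data$sector, .data$year),
         meta = meta,
         population = population,
         pln_per_eur = pln_per_eur),
    class = "recordset")
  validate_recordset(rs)
}

required_record_cols <- c("drug", "year", "sector", "mg_volume",
                          "reimbursement_value", "patients", "currency")

#' Validate a record set
#'
#' Enforces the domain invariants: nonnegative quantities, unique
#' (drug, year, sector) keys, known sectors, metadata present for every drug,
#' contiguous year span per drug and sector, and sub-sector (RMD) values not
#' exceeding the all-indications values unless the row is flagged with a
#' `note` recording a source inconsistency.
#'
#' @param rs A `recordset`.
#' @return `rs`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_recordset <- function(rs) {
  rec <- rs$records
  missing <- setdiff(setdiff(required_record_cols, "currency"), names(rec))
  if (length(missing) > 0) {
    stop_schema(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  for (col in c("mg_volume", "reimbursement_value", "patients")) {
    bad <- which(!is.na(rec[[col]]) & rec[[col]] < 0)
    if (length(bad) > 0) {
      stop_validation(sprintf("negative %s at row %d", col, bad[1]))
    }
  }
  key <- paste(rec$drug, rec$year, rec$sector)
  if (anyDuplicated(key) > 0) {
    dup <- key[which(duplicated(key))[1]]
    stop_validation(paste0("duplicate (drug, year, sector) record: ", dup))
  }
  bad_sector <- setdiff(unique(rec$sector), c("ALL", "RMD"))
  if (length(bad_sector) > 0) {
    stop_validation(paste0("unknown sector: ", paste(bad_sector, collapse = ", ")))
  }
  no_meta <- setdiff(unique(rec$drug), names(rs$meta$drugs))
  if (length(no_meta) > 0) {
    stop_validation(paste0("no metadata for drug(s): ",
                           paste(no_meta, collapse = ", ")))
  }
  if (!is.numeric(rs$population) || rs$population <= 0) {
    stop_validation("population must be positive")
  }
  if (!is.numeric(rs$pln_per_eur) || rs$pln_per_eur <= 0) {
    stop_validation("pln_per_eur must be positive")
  }
  # contiguous year span per drug-sector
  chk <- split(rec$year, paste(rec$drug, rec$sector))
  gap <- vapply(chk, function(y) length(y) > 1 &&
                  any(diff(sort(y)) != 1), logical(1))
  if (any(gap)) {
    stop_validation(paste0("non-contiguous year span for: ",
                           paste(names(chk)[gap], collapse = ", ")))
  }
  # RMD must not exceed ALL for the same drug-year unless flagged
  both <- merge(rec[rec$sector == "ALL", ], rec[rec$sector == "RMD", ],
                by = c("drug", "year"), suffixes = c("_all", "_rmd"))
  flagged <- nzchar(both$note_all) | nzchar(both$note_rmd)
  for (col in if (nrow(both) > 0)
         c("mg_volume", "reimbursement_value", "patients") else character(0)) {
    a <- both[[paste0(col, "_all")]]
    r <- both[[paste0(col, "_rmd")]]
    bad <- which(!flagged & !is.na(a) & !is.na(r) & r > a + 1e-9)
    if (length(bad) > 0) {
      stop_validation(sprintf(
        "RMD %s exceeds ALL-sector value for %s %d (unflagged)",
        col, both$drug[bad[1]], both$year[bad[1]]))
    }
  }
  invisible(rs)
}

#' Read a record set from a long-format CSV
#'
#' The CSV dialect is one row per (drug, year, sector) with columns
#' `drug, year, sector, mg_volume, reimbursement_value, patients, currency`
#' and an optional `note`. Monetary values in PLN are converted to EUR on
#' read by division by the PLN-per-EUR rate from `meta`.
#'
#' @param path CSV file path.
#' @param meta Metadata list (see [read_meta()]).
#' @param currency_mode `"auto"` uses each row's `currency` column;
#'   `"EUR"`/`"PLN"` force the interpretation of monetary values.
#' @return A validated [recordset()].
#' @export
read_recordset <- function(path, meta, currency_mode = c("auto", "EUR", "PLN")) {
  currency_mode <- match.arg(currency_mode)
  if (!file.exists(path)) stop_lookup(paste0("file not found: ", path))
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               col_types = readr::cols(.default = "c")))
  missing <- setdiff(required_record_cols, hdr)
  if (length(missing) > 0) {
    stop_schema(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  types <- list(drug = "c", sector = "c", currency = "c", note = "c",
                year = "i", mg_volume = "d", reimbursement_value = "d",
                patients = "d")
  rec <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = do.call(readr::cols,
                                             types[intersect(names(types),
                                                             hdr)]))
  cur <- switch(currency_mode, auto = rec$currency,
                rep(currency_mode, nrow(rec)))
  if (nrow(rec) > 0) {
    bad <- setdiff(unique(cur), c("EUR", "PLN"))
    if (length(bad) > 0) stop_schema(paste0("unknown currency: ", bad[1]))
    pln <- !is.na(cur) & cur == "PLN"
    rec$reimbursement_value[pln] <-
      convert_currency(rec$reimbursement_value[pln], meta$pln_per_eur)
    rec$currency <- "EUR"
  }
  recordset(rec, meta)
}

#' Write a record set back to the CSV dialect read by [read_recordset()]
#'
#' @param rs A `recordset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recordset <- function(rs, path) {
  out <- rs$records
  out$currency <- "EUR"
  cols <- c(required_record_cols, "note")
  readr::write_csv(out[, intersect(cols, names(out))], path, na = "")
  invisible(path)
}

#' Read drug metadata, population and currency rate from YAML
#'
#' @param path YAML file with `population`, `pln_per_eur`, a `drugs` map
#'   (each with `first_biosimilar_year`, `ddd_mg`, `products`) and optional
#'   `reference_years` presets.
#' @return A metadata list; product tables are tibbles with columns
#'   `name`, `biosimilar`, `from`, `to`.
#' @export
read_meta <- function(path) {
  if (!file.exists(path)) stop_lookup(paste0("file not found: ", path))
  meta <- yaml::read_yaml(path)
  meta$drugs <- lapply(meta$drugs, function(d) {
    if (d$ddd_mg <= 0) stop_validation("ddd_mg must be positive")
    if (!is.null(d$products)) {
      d$products <- purrr::map_dfr(d$products, as_tibble)
      if (!any(!d$products$biosimilar)) {
        stop_validation("drug must have at least one non-biosimilar product")
      }
    }
    d
  })
  meta
}

#' Convert a PLN amount to EUR
#'
#' @param amount_pln Monetary amount(s) in PLN.
#' @param rate PLN per 1 EUR (positive scalar).
#' @return Amount(s) in EUR: `amount_pln / rate`.
#' @examples
#' convert_currency(4.4124, 4.4124) # 1 EUR
#' @export
convert_currency <- function(amount_pln, rate) {
  if (!is.numeric(rate) || length(rate) != 1 || is.na(rate) || rate <= 0) {
    stop_validation("exchange rate must be a positive number")
  }
  amount_pln / rate
}

#' Extract the ordered year series for one drug and sector
#'
#' Missing years stay absent (never zero-filled); downstream model functions
#' tolerate absent years the way the source tables mark them "N/A".
#'
#' @param rs A `recordset`.
#' @param drug Drug identifier present in the metadata.
#' @param sector `"ALL"` or `"RMD"`.
#' @return Tibble of annual records sorted by year, carrying `drug` and
#'   `sector` attributes for downstream annotation.
#' @export
drug_series <- function(rs, drug, sector = c("ALL", "RMD")) {
  sector <- match.arg(sector)
  if (!drug %in% names(rs$meta$drugs)) {
    stop_lookup(paste0("unknown drug: ", drug))
  }
  out <- rs$records |>
    filter(.data$drug == !!drug, .data$sector == !!sector) |>
    arrange(.data$year)
  attr(out, "drug") <- drug
  attr(out, "sector") <- sector
  out
}

#' @export
print.recordset <- function(x, ...) {
  cat(sprintf("<recordset: %d records, %d drugs, years %s-%s>\n",
              nrow(x$records), length(unique(x$records$drug)),
              min(x$records$year), max(x$records$year)))
  cat(sprintf("  population %s, rate %.4f PLN/EUR\n",
              format(x$population, big.mark = " "), x$pln_per_eur))
  print(as_tibble(x$records), n = 6)
  invisible(x)
}
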