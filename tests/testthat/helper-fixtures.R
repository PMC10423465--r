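# shared fixtures built in code

poland <- poland_tnfi()

# a tiny hand-checkable metadata/record pair for validation tests
tiny_meta <- function() {
  list(population = 1e6, pln_per_eur = 4,
       drugs = list(DRG = list(
         name = "drug", first_biosimilar_year = 2015, ddd_mg = 2,
         products = tibble::tibble(name = c("Ref", "Bio"),
                                   biosimilar = c(FALSE, TRUE),
                                   from = c(2013, 2015), to = 2017))))
}

tiny_records <- function() {
  tibble::tibble(
    drug = "DRG", year = rep(2013:2017, 2),
    sector = rep(c("ALL", "RMD"), each = 5),
    mg_volume = c(100, 110, 120, 130, 140, 50, 55, 60, 65, 70),
    reimbursement_value = c(200, 220, 180, 160, 150, 100, 110, 90, 80, 75),
    patients = c(10, 11, 12, 13, 14, 5, 5, 6, 6, 7),
    currency = "EUR", note = "")
}

tiny_recordset <- function() recordset(tiny_records(), tiny_meta())

# write a record set to a temp CSV and return the path
write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path, na = "")
  path
}
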