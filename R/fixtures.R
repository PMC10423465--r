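#' Poland 2013-2021 TNF-inhibitor reimbursement data
#'
#' The packaged national data set behind the published budget-impact
#' analysis: annual National Health Fund reimbursement records for
#' infliximab (INF), etanercept (ETN) and adalimumab (ADA), 2013-2021,
#' for all reimbursed indications (`ALL`) and the rheumatic musculoskeletal
#' disease sector (`RMD`), in EUR. A handful of cells carry a `note`
#' flagging inconsistencies between the source tables; they are stored
#' verbatim.
#'
#' @return A validated [recordset()].
#' @examples
#' rs <- poland_tnfi()
#' drug_series(rs, "ADA", "ALL")
#' @export
poland_tnfi <- function() {
  read_recordset(
    system.file("extdata", "poland_tnfi_2013_2021.csv",
                package = "biosavings", mustWork = TRUE),
    meta = poland_meta())
}

#' @rdname poland_tnfi
#' @export
poland_meta <- function() {
  read_meta(system.file("extdata", "poland_meta.yaml",
                        package = "biosavings", mustWork = TRUE))
}

#' Published per-patient annual treatment costs (independent payer source)
#'
#' The payer publishes average annual per-patient treatment costs from a
#' data source independent of the spend/patient-count records, which is what
#' makes the two-method sensitivity check possible. These published values
#' (all-indications sector, EUR per patient-year) deviate from
#' `reimbursement_value / patients` by up to ~2% in single years.
#'
#' @return Tibble with columns `drug`, `year`, `cost_eur`.
#' @seealso [sensitivity_compare()], [potential_additional_patients()]
#' @export
poland_per_patient_costs <- function() {
  readr::read_csv(
    system.file("extdata", "poland_per_patient_costs.csv",
                package = "biosavings", mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE)
}
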