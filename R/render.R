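# Rendering of the seven report tables in the payer-report layout:
# one column per year, "Reference" marking the anchor year of a savings or
# percentage row and "N/A" marking years outside a drug's data coverage.

# place per-year values into the full year span as display strings
year_cells <- function(years, value_years, values, fmt,
                       ref_year = NULL, na_label = "N/A") {
  out <- rep(na_label, length(years))
  idx <- match(value_years, years)
  keep <- !is.na(idx)
  out[idx[keep]] <- fmt(values[keep])
  if (!is.null(ref_year) && ref_year %in% years) {
    out[years == ref_year] <- "Reference"
  }
  out
}

table_row <- function(drug, metric, cells, total = "") {
  as_tibble(c(list(drug = drug, metric = metric),
              setNames(as.list(cells), names(cells)),
              list(total = total)))
}

#' Render the report tables of a pipeline bundle
#'
#' Produces the seven tables of the published layout: estimated savings
#' (all indications and RMDs), real-life savings (both sectors), treatment
#' costs with product availability, DDD exposure, and the reinvestment
#' counterfactual. Monetary cells are millions of EUR with 3 decimals;
#' counts use a thousands separator in markdown output (a thin space, as in
#' the payer reports) and stay unformatted in CSV output.
#'
#' @param bundle A [run_pipeline()] result.
#' @param dir Optional output directory; when given, each table is written
#'   as `table<N>_<name>.csv` (and `.md` when `"markdown"` is in `format`).
#' @param format Output formats to write; the returned tables always use
#'   plain (machine-readable) number formatting.
#' @return Named list of display tibbles
#'   (`table1_estimated_all`, ..., `table7_access`), invisibly when `dir`
#'   is given.
#' @export
render_tables <- function(bundle, dir = NULL, format = c("csv", "markdown")) {
  format <- match.arg(format, several.ok = TRUE)
  needed <- c("series", "meta", "savings", "costs", "ddd", "access",
              "era_growth")
  missing <- setdiff(needed, names(bundle))
  if (length(missing) > 0) {
    stop_validation(paste0("incomplete bundle, missing: ",
                           paste(missing, collapse = ", ")))
  }
  tables <- build_tables(bundle, thousands = "")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if ("csv" %in% format) {
      purrr::iwalk(tables, function(tab, nm)
        readr::write_csv(tab, file.path(dir, paste0(nm, ".csv"))))
    }
    if ("markdown" %in% format) {
      pretty <- build_tables(bundle, thousands = " ")
      purrr::iwalk(pretty, function(tab, nm)
        writeLines(md_table(tab), file.path(dir, paste0(nm, ".md"))))
    }
    return(invisible(tables))
  }
  tables
}

build_tables <- function(bundle, thousands = "") {
  yrs <- seq(bundle$provenance$fixture_years[1],
             bundle$provenance$fixture_years[2])
  ynm <- as.character(yrs)
  drugs <- bundle$config$drugs
  f_count <- function(x) formatC(round_half_up(x), format = "d",
                                 big.mark = thousands)
  f_meur <- function(x) sprintf("%.3f", x / 1e6)
  f_pct <- function(x) paste0(formatC(round_half_up(x), format = "d"), "%")
  f_cost2 <- function(x) sprintf("%.2f", x)
  f_rate2 <- function(x) sprintf("%.2f", x)

  savings_table <- function(block, estimated = TRUE) {
    rows <- purrr::map_dfr(drugs, function(d) {
      s <- bundle$series[[attr(block$series[[d]], "sector")]][[d]]
      sav <- block$series[[d]]
      ref <- attr(sav, "ref_year")
      cov <- s$year[!is.na(s$reimbursement_value)]
      out <- list()
      if (estimated) {
        mg <- s[!is.na(s$mg_volume), ]
        out$mg <- table_row(d, "Milligrams of the drug",
          setNames(year_cells(yrs, mg$year, mg$mg_volume, f_count), ynm))
      }
      val <- s[!is.na(s$reimbursement_value), ]
      out$val <- table_row(
        d, if (estimated) "Actual refund value" else "Reimbursement value",
        setNames(year_cells(yrs, val$year, val$reimbursement_value,
                            f_meur), ynm))
      if (estimated) {
        # the reference-year potential equals the actual value by definition
        ref_val <- val$reimbursement_value[val$year == ref]
        out$pot <- table_row(d, "Potential refund value",
          setNames(year_cells(yrs, c(ref, sav$year),
                              c(ref_val, sav$potential), f_meur), ynm))
      }
      label <- if (estimated) "Estimated savings value"
               else "Savings versus reference value"
      out$sav <- table_row(d, label,
        setNames(year_cells(yrs, sav$year, sav$savings, f_meur,
                            ref_year = ref), ynm),
        total = f_meur(attr(sav, "total")))
      bind_rows(out)
    })
    agg <- block$aggregate$per_year
    bind_rows(rows, table_row("Total", "Total savings",
      setNames(year_cells(yrs, agg$year, agg$savings, f_meur), ynm),
      total = f_meur(block$aggregate$grand_total)))
  }

  costs_table <- function() {
    purrr::map_dfr(drugs, function(d) {
      prods <- bundle$meta$drugs[[d]]$products
      prod_rows <- purrr::map_dfr(seq_len(nrow(prods)), function(i) {
        avail <- ifelse(yrs >= prods$from[i] & yrs <= prods$to[i],
                        "Yes", "No")
        table_row(d, prods$name[i], setNames(avail, ynm))
      })
      mg_cost <- bundle$costs[[d]]$per_mg
      pt_cost <- bundle$costs[[d]]$per_patient
      ref <- attr(mg_cost, "ref_year")
      bind_rows(
        prod_rows,
        table_row(d, "Cost for 1 mg (EUR)",
          setNames(year_cells(yrs, mg_cost$year, mg_cost$cost, f_cost2), ynm)),
        table_row(d, "% of the reference cost",
          setNames(year_cells(yrs, mg_cost$year[mg_cost$year > ref],
                              mg_cost$pct_of_reference[mg_cost$year > ref],
                              f_pct, ref_year = ref), ynm)),
        table_row(d, "Annual cost per pt (EUR)",
          setNames(year_cells(yrs, pt_cost$year, pt_cost$cost,
                              function(x) f_count(x)), ynm)),
        table_row(d, "% of the reference cost (per pt)",
          setNames(year_cells(yrs, pt_cost$year[pt_cost$year > ref],
                              pt_cost$pct_of_reference[pt_cost$year > ref],
                              f_pct, ref_year = ref), ynm)))
    })
  }

  ddd_table <- function() {
    purrr::map_dfr(drugs, function(d) {
      s <- bundle$series[["ALL"]][[d]]
      dd <- bundle$ddd[[d]]
      ref <- attr(dd, "ref_year")
      mg <- s[!is.na(s$mg_volume), ]
      bind_rows(
        table_row(d, "Milligrams of the drug",
          setNames(year_cells(yrs, mg$year, mg$mg_volume, f_count), ynm)),
        table_row(d, "Number of DDD",
          setNames(year_cells(yrs, dd$year, dd$n_ddd, f_count), ynm)),
        table_row(d, "DDD per 1000 inhabitants per year",
          setNames(year_cells(yrs, dd$year, dd$ddd_per_1000, f_rate2), ynm)),
        table_row(d, "% of the reference prescription",
          setNames(year_cells(yrs, dd$year[dd$year > ref],
                              dd$pct_of_reference[dd$year > ref],
                              f_pct, ref_year = ref), ynm)))
    })
  }

  access_table <- function() {
    purrr::map_dfr(drugs, function(d) {
      purrr::map_dfr(bundle$config$sectors, function(sector) {
        a <- bundle$access[[sector]][[d]]
        lab <- if (sector == "ALL") "all" else "REUMA"
        add <- a[!is.na(a$potential_additional), ]
        bind_rows(
          table_row(d, sprintf("Real number of pts (%s)", lab),
            setNames(year_cells(yrs, a$year, a$real_patients, f_count), ynm)),
          table_row(d, sprintf("Potential additional number of pts (%s)", lab),
            setNames(year_cells(yrs, add$year, add$potential_additional,
                                f_count), ynm)),
          table_row(d, sprintf("Total potential number of pts (%s)", lab),
            setNames(year_cells(yrs, a$year, a$total_potential,
                                f_count), ynm)))
      })
    })
  }

  tabs <- list()
  sectors <- bundle$config$sectors
  if ("ALL" %in% sectors) {
    tabs$table1_estimated_all <- savings_table(bundle$savings$estimated$ALL)
  }
  if ("RMD" %in% sectors) {
    tabs$table2_estimated_rmd <- savings_table(bundle$savings$estimated$RMD)
  }
  if ("ALL" %in% sectors) {
    tabs$table3_real_life_all <-
      savings_table(bundle$savings$real_life$ALL, estimated = FALSE)
  }
  if ("RMD" %in% sectors) {
    tabs$table4_real_life_rmd <-
      savings_table(bundle$savings$real_life$RMD, estimated = FALSE)
  }
  tabs$table5_costs <- costs_table()
  tabs$table6_ddd <- ddd_table()
  tabs$table7_access <- access_table()
  tabs
}

# minimal github-style pipe table
md_table <- function(df) {
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}
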