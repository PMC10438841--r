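# Delimited-text I/O for catchment-year tables and climate series.
#
# Catchment-year CSV schema (12 columns):
#   catchment_id, year, Q_TN (kg N yr-1, > 0), P_annual (mm),
#   P_MAM95 (mm), T_annual (degC), ln_Nsurplus, ln_Nsurplus_lag12,
#   LU_D, LU_C, LU_FSH, L_TD (percent, 0-100).
# Climate series are two CSVs: daily precipitation (watershed_id, date, mm)
# and monthly temperature (watershed_id, year, month, degC).

validate_catchment_rows <- function(df) {
  pct_cols <- c("LU_D", "LU_C", "LU_FSH", "L_TD")
  bad <- rep(FALSE, nrow(df))
  reasons <- character(0)
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    if (any(cond))
      reasons <<- c(reasons, sprintf("row %d: %s", which(cond), why))
    bad <<- bad | cond
  }
  flag(!(df$Q_TN > 0), "Q_TN must be > 0")
  flag(df$P_MAM95 < 0, "P_MAM95 must be >= 0")
  flag(df$P_annual < df$P_MAM95, "P_annual must be >= P_MAM95")
  for (v in pct_cols) flag(df[[v]] < 0 | df[[v]] > 100, paste0(v, " outside [0, 100]"))
  list(bad = bad, reasons = reasons)
}

#' Read and write catchment-year tables
#'
#' `read_catchment_table()` reads the 12-column CSV, checks the schema, and
#' rejects rows violating the invariants (positive load, `P_annual >=
#' P_MAM95 >= 0`, percentages in \[0, 100\]) with row-numbered diagnostics;
#' rejected rows are reported via a warning and recorded in the attribute
#' `"rejected"`.
#'
#' @param path CSV file path.
#' @return Data frame of validated records.
#' @export
read_catchment_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CATCHMENT_YEAR_COLUMNS, names(df))
  if (length(missing_cols))
    stop_invalid("missing required column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, CATCHMENT_YEAR_COLUMNS]
  chk <- validate_catchment_rows(df)
  if (any(chk$bad)) {
    warning("rejected ", sum(chk$bad), " row(s): ",
            paste(utils::head(chk$reasons, 10L), collapse = "; "), call. = FALSE)
  }
  out <- df[!chk$bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- which(chk$bad)
  out
}

#' @rdname read_catchment_table
#' @param records catchment-year data frame.
#' @export
write_catchment_table <- function(records, path) {
  utils::write.csv(records[, CATCHMENT_YEAR_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read and write climate series
#'
#' A climate series is stored as two CSVs: daily precipitation
#' (`watershed_id, date, mm`) and monthly temperature (`watershed_id, year,
#' month, degC`).
#'
#' @param series a `climate_series`.
#' @param precip_path,temp_path CSV file paths.
#' @return `write_climate_series` returns the paths invisibly;
#'   `read_climate_series` returns a `climate_series`.
#' @export
write_climate_series <- function(series, precip_path, temp_path) {
  utils::write.csv(data.frame(watershed_id = series$watershed_id,
                              date = format(series$precip$date),
                              mm = series$precip$mm),
                   precip_path, row.names = FALSE)
  utils::write.csv(data.frame(watershed_id = series$watershed_id, series$temp),
                   temp_path, row.names = FALSE)
  invisible(c(precip_path, temp_path))
}

#' @rdname write_climate_series
#' @export
read_climate_series <- function(precip_path, temp_path) {
  pr <- utils::read.csv(precip_path, stringsAsFactors = FALSE)
  tm <- utils::read.csv(temp_path, stringsAsFactors = FALSE)
  for (need in list(c("watershed_id", "date", "mm"),
                    c("watershed_id", "year", "month", "degC"))) {
    df <- if ("mm" %in% need) pr else tm
    miss <- setdiff(need, names(df))
    if (length(miss)) stop_invalid("missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(pr$mm < 0)) stop_invalid("negative precipitation in ", precip_path)
  structure(list(watershed_id = pr$watershed_id[1L],
                 precip = data.frame(date = as.Date(pr$date), mm = pr$mm),
                 temp = tm[, c("year", "month", "degC")]),
            class = "climate_series")
}
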