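# CSV schemas shared by the analysis and generator modules. All readers
# use base read.csv with dec = "." explicitly, so parsing is independent of
# the session locale, and raise errors naming the offending file and
# columns.

check_columns <- function(d, required, path) {
  if (nrow(d) == 0L)
    stop(sprintf("'%s' contains no data rows", path))
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop(sprintf("'%s' lacks required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  invisible(d)
}

#' Read / write a reversal-potential series CSV
#'
#' Schema: `oocyte_id`, `na_o_mM`, `e_rev_mV`, header required.
#'
#' @param path File path.
#' @return `read_reversal_series()`: a `rev_pot_series` data frame.
#' @export
read_reversal_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, dec = ".")
  check_columns(d, c("oocyte_id", "na_o_mM", "e_rev_mV"), path)
  for (col in c("na_o_mM", "e_rev_mV"))
    if (!is.numeric(d[[col]]))
      stop(sprintf("'%s': column '%s' is not numeric", path, col))
  class(d) <- c("rev_pot_series", "data.frame")
  d
}

#' @rdname read_reversal_series
#' @param series A data frame with the schema columns.
#' @export
write_reversal_series <- function(series, path) {
  check_columns(as.data.frame(series), c("oocyte_id", "na_o_mM", "e_rev_mV"),
                "reversal series")
  utils::write.csv(
    as.data.frame(series)[, c("oocyte_id", "na_o_mM", "e_rev_mV")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an uptake CSV
#'
#' Schema: `construct`, `varied_species`, `concentration`, `conc_unit`,
#' `rate_nmol_per_mg_10min`, `replicate`. Rows with `construct == "mock"`
#' are returned separately as the background dataset.
#'
#' @param path File path.
#' @return `read_uptake_csv()`: a list with elements `data` (an
#'   [uptake_dataset()]) and `mock` (an `uptake_dataset` or NULL).
#' @export
read_uptake_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, dec = ".")
  check_columns(d, c("construct", "varied_species", "concentration",
                     "conc_unit", "rate_nmol_per_mg_10min", "replicate"), path)
  if (!is.numeric(d$concentration) || !is.numeric(d$rate_nmol_per_mg_10min))
    stop(sprintf("'%s': 'concentration' and 'rate_nmol_per_mg_10min' must be numeric",
                 path))
  as_uds <- function(dd) {
    if (nrow(dd) == 0L) return(NULL)
    uptake_dataset(dd$concentration, dd$rate_nmol_per_mg_10min,
                   replicate = dd$replicate,
                   conc_unit = dd$conc_unit[1L],
                   construct = dd$construct[1L],
                   varied_species = dd$varied_species[1L])
  }
  is_mock <- d$construct == "mock"
  list(data = as_uds(d[!is_mock, , drop = FALSE]),
       mock = as_uds(d[is_mock, , drop = FALSE]))
}

#' @rdname read_uptake_csv
#' @param data An [uptake_dataset()].
#' @param mock Optional mock-background [uptake_dataset()].
#' @export
write_uptake_csv <- function(data, path, mock = NULL) {
  stopifnot(inherits(data, "uptake_dataset"))
  as_rows <- function(u) {
    data.frame(construct = attr(u, "construct"),
               varied_species = attr(u, "varied_species"),
               concentration = u$concentration,
               conc_unit = attr(u, "conc_unit"),
               rate_nmol_per_mg_10min = u$rate,
               replicate = u$replicate)
  }
  rows <- as_rows(data)
  if (!is.null(mock)) rows <- rbind(rows, as_rows(mock))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an I/V curve CSV
#'
#' Schema: `potential_mV`, `current_nA`, `sem_nA`, `n`.
#'
#' @param path File path.
#' @return `read_iv_csv()`: an [iv_curve()].
#' @export
read_iv_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, dec = ".")
  check_columns(d, c("potential_mV", "current_nA", "sem_nA", "n"), path)
  iv_curve(d$potential_mV, d$current_nA, sem_nA = d$sem_nA,
           n_oocytes = d$n[1L])
}

#' @rdname read_iv_csv
#' @param iv An [iv_curve()].
#' @export
write_iv_csv <- function(iv, path) {
  stopifnot(inherits(iv, "iv_curve"))
  utils::write.csv(data.frame(potential_mV = iv$potential_mV,
                              current_nA = iv$current_nA,
                              sem_nA = iv$sem_nA,
                              n = iv$n_oocytes),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a current trace (CSV + JSON sidecar)
#'
#' The trace samples live in a CSV with columns `time_s`, `current_nA`;
#' the holding potential, application window and condition metadata live in
#' a JSON sidecar at `<path>.json`.
#'
#' @param path CSV file path (sidecar at `paste0(path, ".json")`).
#' @return `read_trace_csv()`: a [current_trace()].
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, dec = ".")
  check_columns(d, c("time_s", "current_nA"), path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
          else list()
  current_trace(d$time_s, d$current_nA,
                holding_mV = meta$holding_mV %||% -60,
                window = meta$window %||% range(d$time_s),
                condition = meta$condition %||% list())
}

#' @rdname read_trace_csv
#' @param trace A [current_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  utils::write.csv(data.frame(time_s = trace$time_s,
                              current_nA = trace$current_nA),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(holding_mV = trace$holding_mV,
                            window = trace$window,
                            condition = trace$condition),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
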