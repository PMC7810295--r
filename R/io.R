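# Canonical five-arm design of the ex vivo study: RF alone, and 0.9% saline
# or deionized water infused at ambient (~23 C) or refrigerated (5 C)
# temperature.
GROUP_LEVELS <- c("PURERF", "SALINE23", "SALINE5", "DEI23", "DEI5")

group_factor_map <- function() {
  tibble::tibble(
    group = GROUP_LEVELS,
    solution = c("none", "saline", "saline", "deionized", "deionized"),
    temperature = c("none", "ambient", "refrigerated", "ambient", "refrigerated")
  )
}

#' Experimental-group factor mapping
#'
#' Returns the mapping between the five study arms and the two design
#' factors (infused solution and solution temperature). The RF-only control
#' arm carries `none` for both factors.
#'
#' @return A tibble with columns `group`, `solution`, `temperature`.
#' @export
group_factors <- function() group_factor_map()

# --- log reading -------------------------------------------------------------

std_channel_aliases <- list(
  t = c("t", "time", "tempo", "t_s", "time_s", "seconds"),
  V = c("v", "voltage", "volt", "tensao", "v_v"),
  I = c("i", "current", "corrente", "i_ma", "current_ma"),
  P = c("p", "power", "potencia", "p_w"),
  Z = c("z", "impedance", "imp", "impedancia", "z_ohm")
)

normalise_header <- function(x) {
  x <- tolower(trimws(x))
  x <- sub("\\s*[\\[(].*$", "", x)   # strip unit annotations like "t [s]"
  gsub("[^a-z0-9_]+", "_", trimws(x))
}

resolve_columns <- function(headers, column_map) {
  norm <- normalise_header(headers)
  out <- list()
  for (ch in names(std_channel_aliases)) {
    if (!is.null(column_map) && ch %in% names(column_map)) {
      idx <- match(column_map[[ch]], headers)
      if (is.na(idx)) {
        abort_format(sprintf(
          "Mapped column '%s' (for channel %s) not found in the log.",
          column_map[[ch]], ch
        ))
      }
      out[[ch]] <- idx
    } else {
      idx <- match(std_channel_aliases[[ch]], norm)
      idx <- idx[!is.na(idx)]
      if (length(idx)) out[[ch]] <- idx[1]
    }
  }
  out
}

#' Read an RFA equipment log
#'
#' Reads a delimited text log with per-sample time, voltage, current and
#' power channels (the format written by the ablation equipment), computes
#' the impedance channel when the log does not carry one, and returns a
#' validated [rfa_curve()]. Columns are located case-insensitively by common
#' names (`t`/`time`, `V`/`voltage`, `I`/`current`, `P`/`power`,
#' `Z`/`impedance`); `column_map` overrides the automatic match.
#'
#' Cleaning rule: rows with a missing timestamp, missing or negative voltage,
#' missing or non-positive current, or (when an impedance column is used)
#' missing or non-positive impedance are dropped and counted — these are
#' generator cut-out artifacts, and dropping is the least-assuming rule. The
#' number of dropped rows is recorded on the returned curve.
#'
#' @param path Path to the delimited log file.
#' @param column_map Optional named character vector mapping any of
#'   `t`, `V`, `I`, `P`, `Z` to the log's column names.
#' @param current_unit Unit of the current channel; the equipment logs
#'   milliamps, but `"A"` is accepted for logs of undocumented provenance.
#' @param delim Field delimiter (default comma; semicolon is common in
#'   locales that use a decimal comma).
#' @param decimal_mark Decimal mark used in the file.
#' @param sample_id Identifier for the curve; defaults to the file name.
#' @param check_consistency Passed to [rfa_curve()]; set to `FALSE` for logs
#'   whose impedance column was rounded by the equipment.
#'
#' @return An [rfa_curve()] with `dropped_rows` filled in.
#' @export
read_rfa_log <- function(path, column_map = NULL,
                         current_unit = c("mA", "A"),
                         delim = ",", decimal_mark = ".",
                         sample_id = NULL, check_consistency = TRUE) {
  current_unit <- match.arg(current_unit)
  if (!file.exists(path)) abort_format(sprintf("Log file not found: %s", path))
  df <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    locale = readr::locale(decimal_mark = decimal_mark),
    trim_ws = TRUE
  )
  cols <- resolve_columns(names(df), column_map)
  if (is.null(cols$t)) abort_format("No time column found (looked for 't'/'time').")
  has_vi <- !is.null(cols$V) && !is.null(cols$I)
  if (is.null(cols$Z) && !has_vi) {
    abort_format("Log carries neither an impedance column nor both V and I.")
  }

  num <- function(idx) suppressWarnings(as.numeric(df[[idx]]))
  t <- num(cols$t)
  V <- if (!is.null(cols$V)) num(cols$V)
  I <- if (!is.null(cols$I)) num(cols$I)
  P <- if (!is.null(cols$P)) num(cols$P)
  Z <- if (!is.null(cols$Z)) num(cols$Z)

  keep <- is.finite(t)
  if (has_vi) keep <- keep & is.finite(V) & V >= 0 & is.finite(I) & I > 0
  if (!is.null(Z)) keep <- keep & is.finite(Z) & Z > 0
  if (is.null(Z)) {
    amps <- if (current_unit == "mA") I * 1e-3 else I
    Zcalc <- V / amps
    keep <- keep & is.finite(Zcalc) & Zcalc > 0
  }
  dropped <- sum(!keep)

  t <- t[keep]
  V <- if (!is.null(V)) V[keep]
  I <- if (!is.null(I)) I[keep]
  P <- if (!is.null(P)) P[keep]
  Z <- if (!is.null(Z)) Z[keep]
  if (length(t) < 3L) {
    abort_data(sprintf(
      "Fewer than 3 valid rows remain after cleaning (%d dropped) in %s.",
      dropped, path
    ))
  }
  if (any(diff(t) <= 0)) {
    abort_data(sprintf("Timestamps are not strictly increasing in %s.", path))
  }
  if (is.null(Z)) {
    amps <- if (current_unit == "mA") I * 1e-3 else I
    Z <- V / amps
    # store current in milliamps regardless of the log's unit
    if (current_unit == "A") I <- I * 1e3
  }

  rfa_curve(
    t = t, Z = Z,
    sample_id = sample_id %||% tools::file_path_sans_ext(basename(path)),
    V = V, I = I, P = P,
    source_path = path, dropped_rows = dropped,
    check_consistency = check_consistency
  )
}

# --- cohort table ------------------------------------------------------------

#' Read a cohort table mapping samples to study arms
#'
#' Reads a tabular file (XLSX workbook or delimited text) with at least
#' `sample_id` and `group` columns; `volume` (ablation volume in cm^3) and
#' explicit `solution`/`temperature` columns are optional. Factor levels are
#' derived from the group label when absent and cross-checked when present.
#' Any further columns (for instance precomputed indices in a deposited
#' dataset laid out one sample per row) are carried through untouched, so
#' both raw-curve and precomputed-index layouts can be ingested.
#'
#' @param path Path to an `.xlsx`/`.xls` workbook or a delimited text file.
#' @param sheet Worksheet to read from a workbook (default the first).
#' @param delim Delimiter for text files.
#' @return A tibble with columns `sample_id`, `group`, `solution`,
#'   `temperature`, `volume` plus any extra columns found.
#' @export
read_cohort_table <- function(path, sheet = 1, delim = ",") {
  if (!file.exists(path)) abort_format(sprintf("Cohort table not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("xlsx", "xls")) {
    readxl::read_excel(path, sheet = sheet)
  } else {
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      progress = FALSE, trim_ws = TRUE)
  }
  names(df) <- normalise_header(names(df))
  id_col <- intersect(c("sample_id", "sample", "id"), names(df))[1]
  if (is.na(id_col)) abort_format("Cohort table needs a sample_id column.")
  if (!"group" %in% names(df)) abort_format("Cohort table needs a group column.")

  out <- tibble::as_tibble(df)
  out$sample_id <- as.character(out[[id_col]])
  if (id_col != "sample_id") out[[id_col]] <- NULL
  out$group <- toupper(trimws(as.character(out$group)))

  bad <- setdiff(unique(out$group), GROUP_LEVELS)
  if (length(bad)) {
    abort_validation(sprintf(
      "Unknown group label(s): %s. Allowed labels: %s.",
      paste(bad, collapse = ", "), paste(GROUP_LEVELS, collapse = ", ")
    ))
  }
  if (anyDuplicated(out$sample_id)) {
    abort_validation(sprintf(
      "Duplicate sample_id(s): %s.",
      paste(unique(out$sample_id[duplicated(out$sample_id)]), collapse = ", ")
    ))
  }

  map <- group_factor_map()
  derived <- map[match(out$group, map$group), ]
  for (f in c("solution", "temperature")) {
    if (f %in% names(out)) {
      given <- tolower(trimws(as.character(out[[f]])))
      mismatch <- !is.na(given) & given != derived[[f]]
      if (any(mismatch)) {
        abort_validation(sprintf(
          "Column '%s' disagrees with the group label for: %s.",
          f, paste(out$sample_id[mismatch], collapse = ", ")
        ))
      }
    }
    out[[f]] <- derived[[f]]
  }
  if ("volume" %in% names(out)) {
    out$volume <- as.numeric(out$volume)
    if (any(out$volume < 0, na.rm = TRUE)) {
      abort_validation("Ablation volumes must be non-negative.")
    }
  } else {
    out$volume <- NA_real_
  }
  front <- c("sample_id", "group", "solution", "temperature", "volume")
  out[, c(front, setdiff(names(out), front))]
}

# --- result tables -----------------------------------------------------------

#' Write a result table to CSV or JSON
#'
#' Writes parameter, index or statistics records so that reading the file
#' back ([read_results()]) reproduces every numeric field at full double
#' precision.
#'
#' @param records A non-empty data frame of results.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  }
  records <- as.data.frame(records)
  if (nrow(records) == 0L) {
    abort_data("Refusing to write an empty result table.")
  }
  ok <- tryCatch({
    if (format == "csv") {
      readr::write_csv(tibble::as_tibble(records), path)
    } else {
      # 17 significant digits: the shortest representation that always
      # round-trips an IEEE double
      jsonlite::write_json(records, path, dataframe = "rows",
                           digits = I(17), na = "null")
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    rfa_abort(sprintf("Could not write results to %s: %s",
                      path, conditionMessage(ok)), "rfa_io_error")
  }
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Path to a `.csv` or `.json` result file.
#' @return A tibble.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("Result file not found: %s", path))
  if (tolower(tools::file_ext(path)) == "json") {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}
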