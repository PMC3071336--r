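spectra_columns <- c("subject_id", "group", "visit", "condition",
                     "frequency_hz", "resistance", "reactance")

#' Read a cohort of impedance spectra from CSV
#'
#' The interchange dialect is a long, comma-separated, dot-decimal, UTF-8
#' table with exactly the columns `subject_id, group, visit, condition,
#' frequency_hz, resistance, reactance` — one row per measured frequency.
#' Records are grouped by (subject, visit, condition), validated and
#' canonically sorted; duplicate keys, non-numeric cells and non-positive
#' frequencies are rejected with the offending row number.
#'
#' @param path Path to a spectra CSV.
#' @return An `ios_cohort` tibble (one row per record, spectra as a list
#'   column), as produced by [generate_cohort()].
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  miss <- setdiff(spectra_columns, names(raw))
  if (length(miss) > 0) {
    abort(sprintf("spectra file is missing column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "iosmodel_parse_error")
  }
  raw <- raw[spectra_columns]
  raw$row <- seq_len(nrow(raw)) + 1L  # header is line 1
  for (col in c("frequency_hz", "resistance", "reactance")) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric %s at row %d", col, raw$row[bad[1]]),
            class = "iosmodel_parse_error")
    }
    raw[[col]] <- num
  }
  bad_f <- which(raw$frequency_hz <= 0)
  if (length(bad_f) > 0) {
    abort(sprintf("non-positive frequency at row %d", raw$row[bad_f[1]]),
          class = "iosmodel_parse_error")
  }
  key <- paste(raw$subject_id, raw$visit, raw$condition, raw$frequency_hz)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort(sprintf("duplicate (subject, visit, condition, frequency) at row %d",
                  raw$row[dup[1]]),
          class = "iosmodel_parse_error")
  }
  bad_g <- which(!raw$group %in% c("H", "SAI"))
  if (length(bad_g) > 0) {
    abort(sprintf("unknown group '%s' at row %d (expected H or SAI)",
                  raw$group[bad_g[1]], raw$row[bad_g[1]]),
          class = "iosmodel_parse_error")
  }
  cohort <- raw |>
    dplyr::arrange(.data$subject_id, .data$visit, .data$condition,
                   .data$frequency_hz) |>
    dplyr::group_by(.data$subject_id, .data$group, .data$visit, .data$condition) |>
    dplyr::summarise(spectrum = list(ios_spectrum(.data$frequency_hz,
                                                  .data$resistance,
                                                  .data$reactance)),
                     .groups = "drop")
  class(cohort) <- c("ios_cohort", class(cohort))
  cohort
}

#' Write a cohort of impedance spectra to CSV
#'
#' Inverse of [read_spectra()]: expands the spectrum list column into the
#' long interchange dialect. Round-trips losslessly up to numeric printing
#' (full double precision is written).
#'
#' @param cohort An `ios_cohort` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(cohort, path) {
  long <- cohort |>
    tibble::as_tibble() |>
    dplyr::select("subject_id", "group", "visit", "condition", "spectrum") |>
    tidyr::unnest("spectrum") |>
    dplyr::rename(frequency_hz = "frequency")
  readr::write_csv(long[spectra_columns], path)
  invisible(path)
}

fixture_names <- c("table7_oc", "table7_noc", "table2_means", "table3_means",
                   "table8_means")

#' Load a built-in published-table fixture
#'
#' Small plain-text fixtures transcribed from the printed tables of the
#' source study ship with the package: the group-averaged
#' small-airway-impaired spectra with (`table7_oc`) and without
#' (`table7_noc`) an overweight child, and the group-mean index/parameter
#' tables (`table2_means`, `table3_means`, `table8_means`). Spectra load
#' as [ios_spectrum()] tibbles; mean tables load as long tibbles with
#' columns `visit`, `condition`, `group`, `parameter`, `value` ready for
#' [percent_change_report()].
#'
#' @param name One of `"table7_oc"`, `"table7_noc"`, `"table2_means"`,
#'   `"table3_means"`, `"table8_means"`.
#' @return A tibble; spectra carry class `ios_spectrum`.
#' @examples
#' compute_indices(load_fixture("table7_oc"))
#' @export
load_fixture <- function(name) {
  if (length(name) != 1 || !name %in% fixture_names) {
    abort(sprintf("unknown fixture '%s'; available: %s",
                  paste(name, collapse = ","),
                  paste(fixture_names, collapse = ", ")),
          class = "iosmodel_invalid_input")
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "iosmodel",
                      mustWork = TRUE)
  if (startsWith(name, "table7")) {
    tab <- readr::read_csv(path, col_types = "ddd", progress = FALSE)
    return(ios_spectrum(tab$frequency_hz, tab$resistance, tab$reactance))
  }
  readr::read_csv(path, col_types = "ccccd", progress = FALSE)
}
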