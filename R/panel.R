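# Rating-panel container helpers.
#
# A rating panel is a long-format tibble with columns case_id, rater_id,
# rater_group and grade. The reference standard travels as a pseudo-rater
# with rater_group == "reference", so one format serves panels, consensus
# inputs and file round-trips.

#' Validate a rating panel tibble
#'
#' Checks the long-format contract: required columns, valid grades (0-5 or
#' missing), unique (case_id, rater_id) pairs, and — when
#' `require_reference` — a complete reference grade for every case.
#'
#' @param panel A data frame with columns `case_id`, `rater_id`,
#'   `rater_group`, `grade`.
#' @param require_reference Require reference rows covering every case?
#' @return The validated panel as a tibble, invisibly classed as input.
#' @export
validate_panel <- function(panel, require_reference = TRUE) {
  needed <- c("case_id", "rater_id", "rater_group", "grade")
  missing_cols <- setdiff(needed, names(panel))
  if (length(missing_cols) > 0) {
    abort_pk("format", paste0("Panel is missing column(s): ",
                              paste(missing_cols, collapse = ", "), "."))
  }
  panel <- tibble::as_tibble(panel)
  check_grades(panel$grade, "grade", allow_na = TRUE)
  dup <- panel |>
    dplyr::count(.data$case_id, .data$rater_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_pk("format", sprintf(
      "Duplicate (case_id, rater_id) rows, e.g. (%s, %s).",
      dup$case_id[1], dup$rater_id[1]))
  }
  if (require_reference) {
    ref <- dplyr::filter(panel, .data$rater_group == "reference")
    cases <- unique(panel$case_id)
    if (nrow(ref) == 0 || !setequal(ref$case_id, cases) || anyNA(ref$grade)) {
      abort_pk("config",
               "Panel needs a complete reference grade for every case (rater_group \"reference\").")
    }
  }
  panel
}

# Wide view: list(case_id, reference vector, ratings matrix cases x raters).
# Case order: sorted case_id; rater columns: sorted rater_id (non-reference).
panel_wide <- function(panel) {
  panel <- validate_panel(panel)
  ref <- panel |>
    dplyr::filter(.data$rater_group == "reference") |>
    dplyr::arrange(.data$case_id)
  raters <- panel |>
    dplyr::filter(.data$rater_group != "reference") |>
    dplyr::arrange(.data$case_id, .data$rater_id)
  if (nrow(raters) == 0) abort_pk("empty_input", "Panel has no raters.")
  wide <- raters |>
    dplyr::select("case_id", "rater_id", "grade") |>
    tidyr::pivot_wider(names_from = "rater_id", values_from = "grade") |>
    dplyr::arrange(.data$case_id)
  stopifnot(identical(wide$case_id, ref$case_id))
  m <- as.matrix(wide[, setdiff(names(wide), "case_id"), drop = FALSE])
  storage.mode(m) <- "integer"
  list(case_id = ref$case_id, reference = as.integer(ref$grade), ratings = m)
}

# One row of metadata per non-reference rater, sorted by rater_id.
panel_rater_meta <- function(panel) {
  panel |>
    dplyr::filter(.data$rater_group != "reference") |>
    dplyr::distinct(.data$rater_id, .data$rater_group) |>
    dplyr::arrange(.data$rater_id)
}

#' Read a long-format ratings CSV into a rating panel
#'
#' The file must be UTF-8 CSV with header columns `case_id`, `rater_id`,
#' `rater_group`, `grade`. Grades are integers 0-5 (0 = benign, k = ISUP
#' GG k); a blank grade is a missing review. Reference-standard rows carry
#' `rater_group = reference`. Malformed grades and duplicate
#' (case_id, rater_id) rows raise errors naming the offending data line.
#'
#' @param path Path to the CSV file.
#' @return A validated rating panel tibble.
#' @seealso [write_ratings()] for the inverse; the pair round-trips.
#' @export
read_ratings <- function(path) {
  # header problems are reported through problems()/our own checks below,
  # so readr's own column-name warning is redundant here
  df <- tryCatch(
    suppressWarnings(readr::read_csv(path, col_types = readr::cols(
      case_id = readr::col_character(),
      rater_id = readr::col_character(),
      rater_group = readr::col_character(),
      grade = readr::col_double()
    ), progress = FALSE)),
    error = function(e) abort_pk("format", conditionMessage(e))
  )
  needed <- c("case_id", "rater_id", "rater_group", "grade")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort_pk("format", paste0(path, ": missing column(s) ",
                              paste(missing_cols, collapse = ", "),
                              " in header line 1."))
  }
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort_pk("format", sprintf("%s: malformed value at line %d.",
                               path, probs$row[1] + 1L))
  }
  g <- df$grade
  bad <- which(!is.na(g) & (g != floor(g) | g < 0 | g > 5))
  if (length(bad) > 0) {
    abort_pk("invalid_grade", sprintf(
      "%s: grade %s outside 0-5 at line %d.", path, format(g[bad[1]]),
      bad[1] + 1L))
  }
  df$grade <- as.integer(df$grade)
  validate_panel(df, require_reference = FALSE)
}

#' Write a rating panel to CSV
#'
#' Rows are sorted by case id then rater id, so output is deterministic and
#' [read_ratings()] followed by `write_ratings()` round-trips. Missing
#' grades are serialized as blank fields.
#'
#' @param panel A rating panel tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(panel, path) {
  panel <- validate_panel(panel, require_reference = FALSE)
  out <- panel |>
    dplyr::select("case_id", "rater_id", "rater_group", "grade") |>
    dplyr::arrange(.data$case_id, .data$rater_id)
  readr::write_csv(out, path, na = "")
  invisible(path)
}
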