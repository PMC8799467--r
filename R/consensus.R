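#' Two-reviewer consensus with third-reviewer adjudication
#'
#' Implements the sequential reference-standard protocol in which each
#' specimen is graded by two panel uropathologists and a third reviews only
#' discordant cases to arrive at a majority opinion. If the first two
#' reviewers agree, that grade stands and the third reviewer is never
#' consulted. Otherwise the third grade is obtained: if it matches either
#' earlier review, the strict 2-of-3 majority wins; if it matches neither,
#' no majority exists and the ordinal median of the three grades is
#' returned with the `unresolved` flag set.
#'
#' @param first,second Grade labels (0-5) from the first two reviewers.
#' @param third A grade label, or a function of no arguments returning one;
#'   a function is only called when the first two reviews differ, mirroring
#'   the on-demand adjudication.
#' @return A one-row tibble: `grade`, `third_consulted`, `unresolved`.
#' @examples
#' sequential_majority(2, 2, function() stop("never called"))
#' sequential_majority(1, 3, 3)
#' sequential_majority(1, 3, 2) # three-way split -> median, unresolved
#' @export
sequential_majority <- function(first, second, third) {
  check_grades(first, "first")
  check_grades(second, "second")
  if (first == second) {
    return(tibble::tibble(grade = as.integer(first),
                          third_consulted = FALSE, unresolved = FALSE))
  }
  t3 <- if (is.function(third)) third() else third
  check_grades(t3, "third")
  if (t3 == first || t3 == second) {
    grade <- as.integer(t3)
    unresolved <- FALSE
  } else {
    grade <- as.integer(sort(c(first, second, t3))[2])
    unresolved <- TRUE
  }
  tibble::tibble(grade = grade, third_consulted = TRUE,
                 unresolved = unresolved)
}

#' Majority vote of a grading panel
#'
#' Returns the modal grade of k >= 2 panel votes. Tied modes are resolved
#' ordinally: if the median of all votes is itself a tied mode it wins;
#' otherwise the lowest tied mode is chosen, a conservative tie-break that
#' avoids overcalling. The result is deterministic and invariant to vote
#' order.
#'
#' @param grades Integer vector of grade labels (0-5), length >= 2.
#' @return The consensus grade (integer scalar).
#' @examples
#' panel_majority(c(2, 2, 2, 4)) # unique mode
#' panel_majority(c(1, 1, 3, 3)) # tied modes, median 2 not a mode -> 1
#' @export
panel_majority <- function(grades) {
  if (length(grades) == 0) abort_pk("empty_input", "Empty grading panel.")
  check_grades(grades, "grades")
  if (length(grades) < 2) {
    abort_pk("invalid_config", "panel_majority needs at least 2 votes.")
  }
  counts <- tabulate(grades + 1L, nbins = 6L)
  modes <- which(counts == max(counts)) - 1L
  if (length(modes) == 1) return(modes)
  med <- stats::median(grades) # may be half-integer for even counts
  if (med %in% modes) return(as.integer(med))
  min(modes)
}

#' Build consensus reference grades from a panel-review table
#'
#' Applies a consensus protocol per case to a long table of reviews. For
#' `"sequential_majority"` the review order column determines the first,
#' second and third reviewer (cases need 2 reviews, plus a third available
#' for discordant pairs); for `"panel_majority"` all reviews per case are
#' pooled into a majority vote.
#'
#' @param reviews A tibble with columns `case_id`, `reviewer_id`, `order`
#'   (integer review position, 1-based) and `grade`.
#' @param protocol `"sequential_majority"` or `"panel_majority"`.
#' @return A tibble with one row per case: `case_id`, `grade`,
#'   `third_consulted`, `unresolved` (the flags are `NA` under
#'   `"panel_majority"`).
#' @export
consensus_reviews <- function(reviews,
                              protocol = c("sequential_majority",
                                           "panel_majority")) {
  protocol <- rlang::arg_match(protocol)
  needed <- c("case_id", "reviewer_id", "order", "grade")
  if (!all(needed %in% names(reviews))) {
    abort_pk("format", paste0("Review table needs columns: ",
                              paste(needed, collapse = ", "), "."))
  }
  check_grades(reviews$grade, "grade")
  reviews |>
    dplyr::arrange(.data$case_id, .data$order) |>
    dplyr::group_by(.data$case_id) |>
    dplyr::group_modify(function(d, key) {
      if (protocol == "panel_majority") {
        tibble::tibble(grade = panel_majority(d$grade),
                       third_consulted = NA, unresolved = NA)
      } else {
        if (nrow(d) < 2) {
          abort_pk("config", sprintf(
            "Case %s has fewer than 2 reviews for sequential consensus.",
            key$case_id))
        }
        third <- function() {
          if (nrow(d) < 3) {
            abort_pk("config", sprintf(
              "Case %s is discordant but has no third review.", key$case_id))
          }
          d$grade[3]
        }
        sequential_majority(d$grade[1], d$grade[2], third)
      }
    }) |>
    dplyr::ungroup()
}
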