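#' Cross-tabulate two grade vectors over the full 6-category space
#'
#' Builds the 6x6 observed-count matrix used inside the weighted-kappa
#' computation. Rows index the first vector's grade, columns the second's.
#' The full 0-5 label space is always used, so counts are comparable across
#' panels even when some grades are absent from a sample.
#'
#' @param ratings_a,ratings_b Equal-length integer vectors of grade labels
#'   in 0-5, with no missing values (exclude incomplete pairs beforehand).
#' @return A 6x6 integer matrix with dimnames `0:5`, entries summing to
#'   `length(ratings_a)`.
#' @examples
#' build_confusion(c(0, 5), c(5, 0))
#' @export
build_confusion <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b)) {
    abort_pk("shape", "Rating vectors must have equal length.")
  }
  if (length(ratings_a) == 0) {
    abort_pk("empty_input", "Rating vectors are empty.")
  }
  a <- check_grades(ratings_a, "ratings_a")
  b <- check_grades(ratings_b, "ratings_b")
  counts <- tabulate(a * 6L + b + 1L, nbins = 36L)
  m <- matrix(counts, nrow = 6, ncol = 6, byrow = TRUE,
              dimnames = list(0:5, 0:5))
  storage.mode(m) <- "integer"
  m
}

# Quadratic disagreement weights w_ij = (i - j)^2 / (K - 1)^2 on K = 6 labels.
qwk_weights <- function() {
  outer(0:5, 0:5, function(i, j) (i - j)^2 / 25)
}

# Fast numeric kappa from two clean integer grade vectors (no validation).
# Returns NA_real_ when the expected weighted disagreement is zero (both
# raters constant and equal), the undefined-marker used throughout.
qwk_value <- function(a, b) {
  n <- length(a)
  o <- tabulate(a * 6L + b + 1L, nbins = 36L) / n
  om <- matrix(o, 6, 6, byrow = TRUE)
  w <- qwk_weights()
  e <- outer(rowSums(om), colSums(om))
  denom <- sum(w * e)
  if (denom == 0) return(NA_real_)
  1 - sum(w * om) / denom
}

#' Quadratically weighted Cohen's kappa
#'
#' Chance-corrected agreement between two ordinal grade vectors, penalizing
#' disagreements by squared ordinal distance: with weights
#' \eqn{w_{ij} = (i-j)^2/(K-1)^2} on the fixed K = 6 label space (0 = benign,
#' 1-5 = ISUP GG1-5),
#' \deqn{\kappa = 1 - \sum w_{ij} O_{ij} / \sum w_{ij} E_{ij},}
#' where O is the observed joint proportion matrix and E the outer product
#' of the two observed marginals. Pairs with a missing value on either side
#' are dropped before computing (complete-case).
#'
#' When both vectors are constant and identical the expected weighted
#' disagreement is zero and kappa is undefined; `NA` is returned as the
#' undefined-marker rather than an error.
#'
#' @param ratings_a,ratings_b Equal-length grade vectors (0-5, `NA` allowed).
#' @return An object of class `"qwk_agreement"`: a list with elements
#'   `kappa` (double, possibly `NA`), `confusion` (6x6 count matrix) and
#'   `n` (number of complete pairs). Has [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @examples
#' qw_kappa(c(0, 1, 2, 3, 4, 5), c(0, 1, 2, 3, 4, 5))$kappa # 1
#' qw_kappa(c(0, 5), c(5, 0))$kappa # -1
#' @export
qw_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b)) {
    abort_pk("shape", "Rating vectors must have equal length.")
  }
  check_grades(ratings_a, "ratings_a", allow_na = TRUE)
  check_grades(ratings_b, "ratings_b", allow_na = TRUE)
  keep <- !is.na(ratings_a) & !is.na(ratings_b)
  a <- as.integer(ratings_a[keep])
  b <- as.integer(ratings_b[keep])
  if (length(a) == 0) {
    abort_pk("empty_input", "No complete rating pairs.")
  }
  structure(
    list(kappa = qwk_value(a, b), confusion = build_confusion(a, b),
         n = length(a)),
    class = "qwk_agreement"
  )
}

#' @export
print.qwk_agreement <- function(x, ...) {
  cat("Quadratically weighted Cohen's kappa\n")
  cat(sprintf("  kappa = %s on n = %d pairs\n",
              ifelse(is.na(x$kappa), "undefined", format(x$kappa, digits = 4)),
              x$n))
  invisible(x)
}

#' Benign-versus-cancer detection metrics
#'
#' Binarizes ratings and reference into benign/cancer (cancer = grade >= 1,
#' the positive class) and computes sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP) and balanced accuracy (their mean). Pairs with a missing
#' rating are dropped; the reference must contain at least one benign and
#' one cancer case among the retained pairs.
#'
#' @param ratings Grade vector (0-5, `NA` allowed).
#' @param reference Grade vector of reference-standard labels, same length.
#' @return A one-row tibble: `sensitivity`, `specificity`,
#'   `balanced_accuracy`, `tp`, `fp`, `tn`, `fn`, `n`.
#' @examples
#' detection_metrics(c(0, 1, 1, 2), c(0, 0, 1, 2))
#' @export
detection_metrics <- function(ratings, reference) {
  if (length(ratings) != length(reference)) {
    abort_pk("shape", "`ratings` and `reference` must have equal length.")
  }
  check_grades(ratings, "ratings", allow_na = TRUE)
  check_grades(reference, "reference")
  keep <- !is.na(ratings)
  r <- as.integer(ratings[keep]) >= 1L
  ref <- as.integer(reference[keep]) >= 1L
  if (length(r) == 0) abort_pk("empty_input", "No complete rating pairs.")
  if (all(ref)) {
    abort_pk("degenerate_reference",
             "Reference contains no benign case; specificity undefined.")
  }
  if (!any(ref)) {
    abort_pk("degenerate_reference",
             "Reference contains no cancer case; sensitivity undefined.")
  }
  tp <- sum(r & ref); fn <- sum(!r & ref)
  tn <- sum(!r & !ref); fp <- sum(r & !ref)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble::tibble(
    sensitivity = sens, specificity = spec,
    balanced_accuracy = (sens + spec) / 2,
    tp = tp, fp = fp, tn = tn, fn = fn, n = length(r)
  )
}

#' Per-rater agreement with the reference standard
#'
#' Computes quadratically weighted kappa against the panel's reference
#' column for every rater, on that rater's complete cases.
#'
#' @param panel A rating panel tibble (see [read_ratings()]): columns
#'   `case_id`, `rater_id`, `rater_group`, `grade`, with reference rows
#'   tagged `rater_group == "reference"`.
#' @return A tibble with one row per rater: `rater_id`, `rater_group`,
#'   `n` (complete pairs) and `kappa`.
#' @export
rater_agreement <- function(panel) {
  wide <- panel_wide(panel)
  ref <- wide$reference
  meta <- panel_rater_meta(panel)
  dplyr::mutate(
    meta,
    stats = purrr::map(.data$rater_id, function(r) {
      res <- qw_kappa(wide$ratings[, r], ref)
      tibble::tibble(n = res$n, kappa = res$kappa)
    })
  ) |>
    tidyr::unnest("stats")
}

#' Per-rater detection metrics against the reference standard
#'
#' @inheritParams rater_agreement
#' @return A tibble with one row per rater: rater metadata plus the columns
#'   of [detection_metrics()].
#' @export
rater_detection <- function(panel) {
  wide <- panel_wide(panel)
  meta <- panel_rater_meta(panel)
  dplyr::mutate(
    meta,
    stats = purrr::map(.data$rater_id,
                       ~detection_metrics(wide$ratings[, .x], wide$reference))
  ) |>
    tidyr::unnest("stats")
}

#' Select the representative rater by median balanced accuracy
#'
#' A group's performance is reported through the rater whose balanced
#' accuracy is the sample median, rather than by averaging raters. For an
#' even number of raters the lower of the two middle values is used, so an
#' actually existing rater is always selected; ties on the selected value
#' are broken by the lexicographically smallest rater id.
#'
#' @param detection A tibble with columns `rater_id` and
#'   `balanced_accuracy`, e.g. from [rater_detection()], typically
#'   restricted to one rater group.
#' @return The selected `rater_id` (character scalar).
#' @examples
#' d <- tibble::tibble(rater_id = c("r1", "r2", "r3"),
#'                     balanced_accuracy = c(0.6, 0.75, 0.9))
#' select_representative(d)
#' @export
select_representative <- function(detection) {
  if (nrow(detection) == 0) abort_pk("empty_input", "Empty rater panel.")
  ba <- check_finite(detection$balanced_accuracy, "balanced_accuracy")
  k <- length(ba)
  target <- sort(ba)[floor((k + 1) / 2)] # lower-middle for even counts
  ids <- detection$rater_id[ba == target]
  sort(ids)[1]
}

#' Average a metric over repeated runs
#'
#' Nondeterministic raters (for example algorithms with unfrozen test-time
#' augmentation seeds) are evaluated several times and the computed metric
#' is averaged; this is the arithmetic mean with validation.
#'
#' @param metric_values Numeric vector of finite metric values, length >= 1.
#' @return The arithmetic mean.
#' @examples
#' average_over_runs(c(0.90, 0.92, 0.91, 0.89, 0.93))
#' @export
average_over_runs <- function(metric_values) {
  mean(check_finite(metric_values, "metric_values"))
}
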