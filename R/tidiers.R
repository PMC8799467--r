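# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an agreement result into the long confusion table
#'
#' @param x A `qwk_agreement` object from [qw_kappa()].
#' @param ... Unused.
#' @return A tibble with columns `rating_a`, `rating_b`, `count`.
#' @export
tidy.qwk_agreement <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$confusion,
                                        responseName = "count")) |>
    dplyr::transmute(
      rating_a = as.integer(as.character(.data$Var1)),
      rating_b = as.integer(as.character(.data$Var2)),
      count = as.integer(.data$count)
    )
}

#' @rdname tidy.qwk_agreement
#' @export
glance.qwk_agreement <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, n = x$n)
}

#' Tidy a permutation test result
#'
#' @param x A `perm_test` object from [permutation_test()].
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `p_value`, `n_permutations`,
#'   `exhaustive`, `n_a`, `n_b`.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_permutations = x$n_permutations,
                 exhaustive = x$exhaustive, n_a = x$n_a, n_b = x$n_b)
}

#' @rdname tidy.perm_test
#' @export
glance.perm_test <- tidy.perm_test

#' Tidy a bootstrap confidence interval
#'
#' @param x A `boot_ci` object from [bootstrap_ci()].
#' @param ... Unused.
#' @return A one-row tibble: `point`, `lower`, `upper`, `level`,
#'   `n_replicates`, `n_degenerate`.
#' @export
tidy.boot_ci <- function(x, ...) {
  tibble::tibble(point = x$point, lower = x$lower, upper = x$upper,
                 level = x$level, n_replicates = x$n_replicates,
                 n_degenerate = x$n_degenerate)
}

#' @rdname tidy.boot_ci
#' @export
glance.boot_ci <- tidy.boot_ci

#' Tidy a study report
#'
#' `tidy()` returns the per-rater metric table; `glance()` returns the
#' one-row-per-group summary joined with the group comparisons.
#'
#' @param x A `study_report` from [evaluate_panel_study()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.study_report <- function(x, ...) {
  x$raters
}

#' @rdname tidy.study_report
#' @export
glance.study_report <- function(x, ...) {
  dplyr::left_join(x$groups,
                   dplyr::select(x$comparisons, rater_group = "group_b",
                                 "statistic", "p_value"),
                   by = "rater_group")
}
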