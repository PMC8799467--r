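# ggplot2 views of the result objects. These are thin display layers; all
# numbers come from the computation functions.

#' Plot a leaderboard timeline
#'
#' Draws the best-so-far and daily-median score series from
#' [leaderboard_timeline()].
#'
#' @param timeline A tibble from [leaderboard_timeline()].
#' @return A ggplot object.
#' @export
plot_leaderboard_timeline <- function(timeline) {
  long <- timeline |>
    tidyr::pivot_longer(c("best_so_far", "daily_median"),
                        names_to = "series", values_to = "score") |>
    dplyr::filter(is.finite(.data$score))
  ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$score,
                                     colour = .data$series)) +
    ggplot2::geom_step(data = ~dplyr::filter(.x, series == "best_so_far")) +
    ggplot2::geom_point(data = ~dplyr::filter(.x, series == "daily_median")) +
    ggplot2::labs(x = "competition day", y = "score", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ordered grade-assignment matrix
#'
#' Heatmap of the cases-by-raters grade matrix from
#' [grade_matrix_report()], cases ordered by reference grade then mean
#' assigned grade, raters ordered by agreement with the reference.
#'
#' @param report A `grade_matrix_report` object.
#' @return A ggplot object.
#' @export
plot_grade_matrix <- function(report) {
  m <- report$matrix
  long <- tibble::as_tibble(as.data.frame.table(m, responseName = "grade",
                                                stringsAsFactors = FALSE)) |>
    dplyr::rename(case_id = "Var1", rater_id = "Var2") |>
    dplyr::mutate(
      case_id = factor(.data$case_id, levels = rownames(m)),
      rater_id = factor(.data$rater_id, levels = colnames(m)),
      grade = factor(.data$grade, levels = 0:5)
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$rater_id, .data$case_id,
                                     fill = .data$grade)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_d(na.value = "grey90", drop = FALSE) +
    ggplot2::labs(x = "rater (by agreement with reference)",
                  y = "case (by reference grade)", fill = "grade") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot a study report
#'
#' Per-rater kappa by group, with the group mean and its bootstrap
#' confidence interval overlaid.
#'
#' @param object A `study_report` from [evaluate_panel_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_report <- function(object, ...) {
  ggplot2::ggplot(object$raters,
                  ggplot2::aes(.data$rater_group, .data$kappa)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.6) +
    ggplot2::geom_pointrange(
      data = object$groups,
      ggplot2::aes(y = .data$mean_kappa, ymin = .data$ci_lower,
                   ymax = .data$ci_upper),
      colour = "firebrick"
    ) +
    ggplot2::labs(x = NULL, y = "quadratically weighted kappa") +
    ggplot2::theme_minimal()
}
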