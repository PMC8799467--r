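#' Leaderboard timeline series
#'
#' Summarizes a stream of challenge submissions into two day-indexed
#' series: the best score obtained by any team up to each day (running
#' maximum) and the median score over that day's submissions (days with no
#' submissions carry no median point).
#'
#' @param submissions A tibble of submission records with columns `day` and
#'   a score column.
#' @param score Name of the score column; default `"tuning_score"`.
#' @return A tibble with one row per day from 0 to the last submission day:
#'   `day`, `best_so_far`, `daily_median` (`NA` on days without
#'   submissions), `n_submissions`.
#' @export
leaderboard_timeline <- function(submissions, score = "tuning_score") {
  if (nrow(submissions) == 0) {
    abort_pk("empty_input", "No submissions.")
  }
  if (!all(c("day", score) %in% names(submissions))) {
    abort_pk("format", sprintf("Submissions need columns `day` and `%s`.",
                               score))
  }
  daily <- submissions |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(
      daily_median = stats::median(.data[[score]]),
      daily_best = max(.data[[score]]),
      n_submissions = dplyr::n(),
      .groups = "drop"
    )
  tibble::tibble(day = 0:max(daily$day)) |>
    dplyr::left_join(daily, by = "day") |>
    dplyr::mutate(
      n_submissions = tidyr::replace_na(.data$n_submissions, 0L),
      best_so_far = cummax(tidyr::replace_na(.data$daily_best, -Inf))
    ) |>
    dplyr::select("day", "best_so_far", "daily_median", "n_submissions")
}

#' Ordered grade-assignment matrix
#'
#' Prepares the cases-by-raters grade matrix for display the way reader
#' studies present it: cases ordered primarily by the reference grade,
#' secondarily by the mean assigned grade across raters (missing reviews
#' excluded from the mean), then by case id; raters ordered by descending
#' agreement (quadratically weighted kappa) with the reference, then by
#' rater id. Raters with no case overlapping the reference are dropped
#' with a warning.
#'
#' @param panel A rating panel with a reference.
#' @return A list of class `"grade_matrix_report"`: `matrix` (ordered
#'   integer matrix, cases x raters), `case_order` (tibble: `case_id`,
#'   `reference`, `mean_assigned`), `rater_order` (tibble: `rater_id`,
#'   `rater_group`, `kappa`).
#' @export
grade_matrix_report <- function(panel) {
  wide <- panel_wide(panel)
  m <- wide$ratings
  overlap <- colSums(!is.na(m)) > 0
  if (any(!overlap)) {
    rlang::warn(paste0("Dropping rater(s) with no reviewed case: ",
                       paste(colnames(m)[!overlap], collapse = ", ")))
    m <- m[, overlap, drop = FALSE]
  }
  if (ncol(m) == 0) abort_pk("empty_input", "No rater overlaps the reference.")
  agree <- rater_agreement(
    dplyr::filter(panel, .data$rater_id %in% c(colnames(m), "reference"))
  )
  rater_order <- agree |>
    dplyr::arrange(dplyr::desc(.data$kappa), .data$rater_id)
  case_order <- tibble::tibble(
    case_id = wide$case_id,
    reference = wide$reference,
    mean_assigned = rowMeans(m, na.rm = TRUE)
  ) |>
    dplyr::arrange(.data$reference, .data$mean_assigned, .data$case_id)
  ordered <- m[match(case_order$case_id, wide$case_id),
               rater_order$rater_id, drop = FALSE]
  rownames(ordered) <- case_order$case_id
  structure(
    list(matrix = ordered, case_order = case_order,
         rater_order = dplyr::select(rater_order, "rater_id", "rater_group",
                                     "kappa")),
    class = "grade_matrix_report"
  )
}

#' Evaluate a full panel study
#'
#' Runs the whole blinded-validation analysis pipeline on a rating panel:
#' per-rater agreement (quadratically weighted kappa) and benign/cancer
#' detection metrics against the reference, group mean kappa with crossed
#' rater-by-case bootstrap confidence intervals, a two-sided permutation
#' test of the algorithm group against each pathologist group, and the
#' representative rater (median balanced accuracy) per group. The report
#' is a deterministic function of the panel and `seed`.
#'
#' @param panel A rating panel with rater group `"algorithm"`, at least one
#'   pathologist group, and a reference.
#' @param seed Integer seed driving the permutation and bootstrap draws.
#' @param n_perm Monte-Carlo permutations for non-exhaustive tests.
#' @param n_replicates Bootstrap replicates per group.
#' @param level Confidence level for the bootstrap intervals.
#' @return An object of class `"study_report"`: a list with tibbles
#'   `raters` (per-rater kappa and detection metrics), `groups` (mean
#'   kappa, CI bounds, representative rater and its
#'   sensitivity/specificity), and `comparisons` (one permutation test per
#'   algorithm-versus-pathologist-group contrast), plus the `boot` and
#'   `tests` objects. Has `tidy()`, `glance()` and `autoplot()` methods.
#' @export
evaluate_panel_study <- function(panel, seed = 1, n_perm = 9999,
                                 n_replicates = 1000, level = 0.95) {
  panel <- validate_panel(panel)
  groups <- sort(unique(panel_rater_meta(panel)$rater_group))
  if (!"algorithm" %in% groups || length(groups) < 2) {
    abort_pk("config",
             "Panel needs an \"algorithm\" group and at least one pathologist group.")
  }
  agree <- rater_agreement(panel)
  detect <- rater_detection(panel)
  raters <- dplyr::left_join(agree, detect,
                             by = c("rater_id", "rater_group", "n"))

  boot <- purrr::map(rlang::set_names(groups), function(g) {
    bootstrap_ci(panel, group = g, level = level,
                 n_replicates = n_replicates,
                 seed = child_seed(seed, match(g, groups)))
  })
  group_tbl <- purrr::map_dfr(rlang::set_names(groups), function(g) {
    det_g <- dplyr::filter(detect, .data$rater_group == g)
    rep_id <- select_representative(det_g)
    rep_row <- dplyr::filter(det_g, .data$rater_id == rep_id)
    tibble::tibble(
      rater_group = g,
      n_raters = nrow(det_g),
      mean_kappa = mean(dplyr::filter(agree, .data$rater_group == g)$kappa),
      ci_lower = boot[[g]]$lower,
      ci_upper = boot[[g]]$upper,
      level = level,
      representative = rep_id,
      rep_sensitivity = rep_row$sensitivity,
      rep_specificity = rep_row$specificity
    )
  })

  others <- setdiff(groups, "algorithm")
  tests <- purrr::map(rlang::set_names(others), function(g) {
    permutation_test(
      dplyr::filter(agree, .data$rater_group == "algorithm")$kappa,
      dplyr::filter(agree, .data$rater_group == g)$kappa,
      n_perm = n_perm, seed = child_seed(seed, 100L + match(g, groups))
    )
  })
  comparisons <- purrr::map_dfr(others, function(g) {
    t <- tests[[g]]
    tibble::tibble(
      group_a = "algorithm", group_b = g, statistic = t$statistic,
      p_value = t$p_value, n_permutations = t$n_permutations,
      exhaustive = t$exhaustive
    )
  })

  structure(
    list(raters = raters, groups = group_tbl, comparisons = comparisons,
         boot = boot, tests = tests,
         config = list(seed = as.integer(seed), n_perm = n_perm,
                       n_replicates = n_replicates, level = level)),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("Panel study report\n")
  cat(sprintf("  %d raters in %d groups on %d cases\n",
              nrow(x$raters), nrow(x$groups), x$raters$n[1]))
  cat("\nGroup summary (mean kappa with bootstrap CI):\n")
  print(x$groups)
  cat("\nGroup comparisons (two-sided permutation tests):\n")
  print(x$comparisons)
  invisible(x)
}
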