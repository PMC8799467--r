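#' Two-sided permutation test for a difference in group mean agreement
#'
#' Compares two rater groups on a per-rater metric (in the study design,
#' each rater's quadratically weighted kappa with the reference standard).
#' The test statistic is T = mean(group A) - mean(group B); the null is
#' generated by reassigning group labels over the pooled raters while
#' preserving group sizes, and the two-sided p-value is the proportion of
#' reassignments with |T*| >= |T_obs|.
#'
#' When the number of distinct assignments `choose(n_a + n_b, n_a)` is at
#' most 20,000 the null is enumerated exhaustively, giving an exact p-value
#' (a ratio of integer counts, independent of `seed`). Otherwise `n_perm`
#' Monte-Carlo reassignments are drawn and the add-one corrected estimate
#' p = (b + 1)/(m + 1) is reported, which is never zero.
#'
#' @param group_a,group_b Numeric vectors of per-rater metric values.
#' @param n_perm Number of Monte-Carlo permutations (ignored when the test
#'   is exhaustive). Default 9999.
#' @param seed Optional integer seed for the Monte-Carlo draw.
#' @return An object of class `"perm_test"`: `statistic`, `p_value`,
#'   `n_permutations`, `exhaustive`, `n_a`, `n_b`. Has `tidy()`/`glance()`
#'   methods.
#' @examples
#' permutation_test(c(2, 3), c(0, 1)) # exhaustive over 6 splits: p = 1/3
#' @export
permutation_test <- function(group_a, group_b, n_perm = 9999, seed = NULL) {
  a <- check_finite(group_a, "group_a")
  b <- check_finite(group_b, "group_b")
  if (length(n_perm) != 1 || !is.finite(n_perm) || n_perm < 1) {
    abort_pk("invalid_parameter", "`n_perm` must be a positive integer.")
  }
  n_perm <- as.integer(n_perm)
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  s_total <- sum(pooled)
  t_obs <- mean(a) - mean(b)
  # mean difference for a subset (group A) given its sum
  t_from_sum <- function(s_a) s_a / n_a - (s_total - s_a) / n_b
  tol <- 1e-12 * max(1, abs(t_obs))
  n_comb <- choose(n_a + n_b, n_a)
  if (n_comb <= 20000) {
    sums <- utils::combn(pooled, n_a, sum)
    t_star <- t_from_sum(sums)
    hits <- sum(abs(t_star) >= abs(t_obs) - tol)
    res <- list(statistic = t_obs, p_value = hits / n_comb,
                n_permutations = as.integer(n_comb), exhaustive = TRUE)
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    n <- n_a + n_b
    hits <- 0L
    for (i in seq_len(n_perm)) {
      s_a <- sum(pooled[sample.int(n, n_a)])
      if (abs(t_from_sum(s_a)) >= abs(t_obs) - tol) hits <- hits + 1L
    }
    res <- list(statistic = t_obs, p_value = (hits + 1) / (n_perm + 1),
                n_permutations = n_perm, exhaustive = FALSE)
  }
  structure(c(res, list(n_a = n_a, n_b = n_b)), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Two-sided permutation test (difference of group means)\n")
  cat(sprintf("  T = %.4f, p = %.4g (%s, %d permutations; n = %d vs %d)\n",
              x$statistic, x$p_value,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$n_permutations, x$n_a, x$n_b))
  invisible(x)
}

# Default bootstrap metric: kappa vs reference on complete pairs, NA when
# undefined or when no pairs overlap.
metric_qwk <- function(ratings, reference) {
  keep <- !is.na(ratings) & !is.na(reference)
  if (!any(keep)) return(NA_real_)
  qwk_value(as.integer(ratings[keep]), as.integer(reference[keep]))
}

#' Crossed rater-by-case bootstrap confidence interval
#'
#' Confidence interval for a group's mean per-rater metric that propagates
#' both rater-to-rater and case-to-case variability: each replicate
#' independently resamples raters with replacement and cases with
#' replacement, then averages the metric of the resampled raters against
#' the reference on the resampled cases. The interval is the percentile
#' interval of the replicate distribution.
#'
#' Replicates where the metric is undefined (for example a constant
#' degenerate kappa, or a rater with no reviewed cases in the case
#' resample) are discarded and redrawn, up to a cap of `10 * n_replicates`
#' total draws; the number discarded is reported as `n_degenerate`.
#'
#' @param panel A rating panel containing one rater group plus reference
#'   rows (use `group` to restrict a multi-group panel).
#' @param metric A function `(ratings, reference) -> numeric scalar`;
#'   default is quadratically weighted kappa on complete pairs.
#' @param group Optional rater group to restrict to before resampling.
#' @param level Confidence level, default 0.95.
#' @param n_replicates Bootstrap replicates, default 1000.
#' @param seed Optional integer seed.
#' @return An object of class `"boot_ci"`: `point` (mean metric on the
#'   observed panel), `lower`, `upper`, `level`, `n_replicates`,
#'   `n_degenerate`, and the replicate values in `replicates`.
#' @export
bootstrap_ci <- function(panel, metric = metric_qwk, group = NULL,
                         level = 0.95, n_replicates = 1000, seed = NULL) {
  if (!is.null(group)) {
    panel <- dplyr::filter(panel,
                           .data$rater_group %in% c(group, "reference"))
  }
  if (level <= 0 || level >= 1) {
    abort_pk("invalid_parameter", "`level` must be in (0, 1).")
  }
  if (n_replicates < 1) {
    abort_pk("invalid_parameter", "`n_replicates` must be >= 1.")
  }
  wide <- panel_wide(panel)
  m <- wide$ratings
  ref <- wide$reference
  n_cases <- length(ref)
  n_raters <- ncol(m)
  if (n_cases < 2) abort_pk("invalid_config", "Need at least 2 cases.")
  if (!is.null(seed)) set.seed(as.integer(seed))
  observed <- vapply(seq_len(n_raters),
                     function(r) metric(m[, r], ref), numeric(1))
  point <- mean(observed)
  reps <- numeric(n_replicates)
  got <- 0L
  degenerate <- 0L
  cap <- 10L * n_replicates
  draws <- 0L
  while (got < n_replicates && draws < cap) {
    draws <- draws + 1L
    ci <- sample.int(n_cases, n_cases, replace = TRUE)
    ri <- sample.int(n_raters, n_raters, replace = TRUE)
    refb <- ref[ci]
    vals <- vapply(ri, function(r) metric(m[ci, r], refb), numeric(1))
    v <- mean(vals)
    if (is.finite(v)) {
      got <- got + 1L
      reps[got] <- v
    } else {
      degenerate <- degenerate + 1L
    }
  }
  if (got < n_replicates) {
    abort_pk("degenerate_panel", sprintf(
      "Could not obtain %d defined replicates within %d draws.",
      n_replicates, cap))
  }
  q <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  structure(
    list(point = point, lower = q[1], upper = q[2], level = level,
         n_replicates = n_replicates, n_degenerate = degenerate,
         replicates = reps),
    class = "boot_ci"
  )
}

#' @export
print.boot_ci <- function(x, ...) {
  cat(sprintf(
    "Crossed rater-by-case bootstrap: %.4f (%d%% CI %.4f-%.4f, %d replicates%s)\n",
    x$point, round(100 * x$level), x$lower, x$upper, x$n_replicates,
    if (x$n_degenerate > 0) sprintf(", %d degenerate redraws", x$n_degenerate)
    else ""))
  invisible(x)
}

#' Combine algorithms' grades into an ensemble grade
#'
#' Per-case ordinal median across algorithms, with even counts resolved to
#' the lower of the two middle grades (rounding toward benign). The median
#' makes the combination robust to outlier algorithms, and the downward
#' tie-break biases the ensemble toward specificity.
#'
#' @param grades A cases-by-algorithms matrix (or data frame) of grade
#'   labels 0-5; `NA` marks a missing prediction. Every case needs at
#'   least one grade.
#' @return An integer vector of ensemble grades, one per case (row).
#' @examples
#' ensemble_grades(rbind(c(0, 0, 1), c(1, 2, 4)))
#' @export
ensemble_grades <- function(grades) {
  m <- as.matrix(grades)
  if (length(m) == 0) abort_pk("empty_input", "No grades supplied.")
  check_grades(as.vector(m), "grades", allow_na = TRUE)
  apply(m, 1, function(g) {
    g <- sort(g[!is.na(g)])
    if (length(g) == 0) {
      abort_pk("missing_data", "A case has no algorithm grades.")
    }
    as.integer(g[floor((length(g) + 1) / 2)])
  })
}
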