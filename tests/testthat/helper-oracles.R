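# Independent brute-force oracles used to validate the implementation.
# These deliberately avoid the package's internal code paths: everything is
# explicit double/triple sums and literal vote counting.

# Quadratically weighted kappa by the explicit O(K^2) double sum over the
# fixed 6-category space.
oracle_qwk <- function(a, b) {
  n <- length(a)
  O <- matrix(0, 6, 6)
  for (k in seq_len(n)) O[a[k] + 1, b[k] + 1] <- O[a[k] + 1, b[k] + 1] + 1
  O <- O / n
  pa <- rowSums(O)
  pb <- colSums(O)
  num <- 0
  den <- 0
  for (i in 0:5) {
    for (j in 0:5) {
      w <- (i - j)^2 / 25
      num <- num + w * O[i + 1, j + 1]
      den <- den + w * pa[i + 1] * pb[j + 1]
    }
  }
  if (den == 0) return(NA_real_)
  1 - num / den
}

# Enumerate-and-vote oracle for a panel majority: literal counting, ties
# resolved by the stated rule (median of all votes if it is a tied mode,
# otherwise the lowest tied mode).
oracle_panel_majority <- function(votes) {
  tab <- sapply(0:5, function(g) sum(votes == g))
  best <- max(tab)
  modes <- (0:5)[tab == best]
  if (length(modes) == 1) return(modes)
  med <- median(votes)
  if (any(modes == med)) return(med)
  min(modes)
}

# Oracle for the two-reviewer + adjudicator protocol.
oracle_sequential <- function(first, second, third) {
  if (first == second) {
    return(list(grade = first, third_consulted = FALSE, unresolved = FALSE))
  }
  if (third == first || third == second) {
    return(list(grade = third, third_consulted = TRUE, unresolved = FALSE))
  }
  list(grade = sort(c(first, second, third))[2], third_consulted = TRUE,
       unresolved = TRUE)
}

# Random grade vector.
rand_grades <- function(n) sample(0:5, n, replace = TRUE)

# Random row-stochastic 6x6 confusion matrix.
rand_confusion <- function() {
  m <- matrix(stats::rexp(36), 6, 6)
  m / rowSums(m)
}

# Small valid panel fixture: k raters, one group, reference = truth.
tiny_panel <- function(n_cases = 12, raters = c(a1 = 0.3, a2 = 0.6),
                       group = "algorithm", seed = 42) {
  set.seed(seed)
  truth <- sample(0:5, n_cases, replace = TRUE)
  case_id <- sprintf("c%02d", seq_len(n_cases))
  rows <- lapply(names(raters), function(r) {
    tibble::tibble(
      case_id = case_id, rater_id = r, rater_group = group,
      grade = simulate_rater_latent(truth, bias = 0, noise = raters[[r]])
    )
  })
  dplyr::bind_rows(c(rows, list(
    tibble::tibble(case_id = case_id, rater_id = "reference",
                   rater_group = "reference", grade = truth)
  )))
}
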