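# Synthetic rater-panel generator.
#
# The generator emulates the data structure of a blinded multi-rater
# grading study: a case population drawn from a fixed grade prevalence, and
# groups of raters whose assigned grades are noisy ordinal functions of the
# true grade, with per-rater bias (under/overgrading), per-rater noise, and
# a shared per-case difficulty that induces inter-rater correlation beyond
# the truth.

#' Default grade prevalence of the simulated case population
#'
#' Six probabilities over grades 0-5 (0 = benign, k = ISUP GG k) matching
#' the case mix of a large multi-site prostate biopsy cohort: 29% benign,
#' then 25/13/11/11/11% for GG1-GG5.
#'
#' @return A numeric 6-vector summing to 1.
#' @export
default_prevalence <- function() {
  c(0.29, 0.25, 0.13, 0.11, 0.11, 0.11)
}

check_prevalence <- function(prevalence) {
  if (length(prevalence) != 6 || !is.numeric(prevalence) ||
      any(!is.finite(prevalence)) || any(prevalence < 0) ||
      abs(sum(prevalence) - 1) > 1e-9) {
    abort_pk("invalid_config",
             "`prevalence` must be 6 nonnegative probabilities summing to 1.")
  }
  invisible(as.double(prevalence))
}

check_confusion <- function(confusion) {
  if (!is.matrix(confusion) || any(dim(confusion) != c(6, 6)) ||
      any(!is.finite(confusion)) || any(confusion < 0) ||
      any(abs(rowSums(confusion) - 1) > 1e-9)) {
    abort_pk("invalid_config",
             "`confusion` must be a 6x6 row-stochastic matrix.")
  }
  invisible(confusion)
}

#' Confusion matrix of a latent-threshold rater
#'
#' Closed-form 6x6 confusion matrix of a rater whose latent score is
#' `truth + bias + Normal(0, sigma)`, thresholded at the half-integers
#' 0.5, ..., 4.5 and clipped to \[0, 5\]. Row t gives
#' P(assigned grade | true grade t). Useful both as a rater specification
#' and as the analytic counterpart of [simulate_rater_latent()] (add the
#' shared-difficulty scale in quadrature to `sigma` to get the marginal
#' confusion of a latent rater in a panel).
#'
#' @param bias Systematic shift in grade units (positive = overgrading).
#' @param sigma Rater noise standard deviation in grade units, >= 0.
#' @return A 6x6 row-stochastic matrix with dimnames `0:5`.
#' @export
latent_confusion <- function(bias = 0, sigma = 0.5) {
  if (!is.finite(bias) || !is.finite(sigma) || sigma < 0) {
    abort_pk("invalid_config", "`bias` must be finite and `sigma` >= 0.")
  }
  cuts <- c(-Inf, seq(0.5, 4.5, by = 1), Inf)
  m <- t(vapply(0:5, function(t) {
    diff(stats::pnorm(cuts, mean = t + bias, sd = sigma))
  }, numeric(6)))
  dimnames(m) <- list(0:5, 0:5)
  m
}

#' Specify a simulated rater
#'
#' A rater is either a `confusion`-model rater (grades drawn independently
#' across cases from the truth-indexed row of a 6x6 confusion matrix) or a
#' `latent`-model rater (ordinal discretization of truth + bias + shared
#' case difficulty + Gaussian noise). Latent raters in the same panel share
#' the per-case difficulty, so their errors are correlated beyond the truth.
#'
#' @param id Rater identifier (character scalar).
#' @param group Rater group, e.g. `"algorithm"`, `"general_pathologist"`,
#'   `"uropathologist"`.
#' @param confusion Optional 6x6 row-stochastic matrix; supplying it makes
#'   this a confusion-model rater.
#' @param bias,sigma Latent-model parameters (grade units); used when
#'   `confusion` is `NULL`.
#' @param missing_rate Probability in \[0, 1) that each of this rater's
#'   reviews is missing, applied uniformly at random.
#' @return A `rater_spec` list.
#' @export
rater_spec <- function(id, group, confusion = NULL, bias = 0, sigma = 0.5,
                       missing_rate = 0) {
  if (!is.null(confusion)) {
    check_confusion(confusion)
  } else if (!is.finite(bias) || !is.finite(sigma) || sigma < 0) {
    abort_pk("invalid_config", "`bias` must be finite and `sigma` >= 0.")
  }
  if (!is.finite(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    abort_pk("invalid_config", "`missing_rate` must be in [0, 1).")
  }
  structure(
    list(id = as.character(id), group = as.character(group),
         confusion = confusion, bias = bias, sigma = sigma,
         missing_rate = missing_rate),
    class = "rater_spec"
  )
}

#' Configure a panel simulation
#'
#' Bundles the generative-model parameters: number of cases, grade
#' prevalence, rater specifications, the shared-difficulty scale `tau`
#' (grade units; the per-case difficulty is drawn once per case from
#' Normal(0, tau) and added to every latent rater's score), and the seed.
#'
#' @param n_cases Number of cases, >= 0.
#' @param prevalence Probability 6-vector over grades 0-5.
#' @param raters List of [rater_spec()] objects.
#' @param tau Shared per-case difficulty scale, >= 0.
#' @param seed Integer seed; the whole panel is reproducible from it.
#' @return A `panel_sim_config` list.
#' @seealso [default_sim_config()] for the study-shaped default panel.
#' @export
panel_sim_config <- function(n_cases, prevalence = default_prevalence(),
                             raters = list(), tau = 0, seed = 1) {
  if (!is.finite(n_cases) || n_cases < 0 || n_cases != floor(n_cases)) {
    abort_pk("invalid_config", "`n_cases` must be a nonnegative integer.")
  }
  check_prevalence(prevalence)
  if (!is.finite(tau) || tau < 0) {
    abort_pk("invalid_config", "`tau` must be >= 0.")
  }
  if (!all(vapply(raters, inherits, logical(1), "rater_spec"))) {
    abort_pk("invalid_config", "`raters` must be a list of rater_spec objects.")
  }
  ids <- vapply(raters, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    abort_pk("invalid_config", "Rater ids must be unique.")
  }
  structure(
    list(n_cases = as.integer(n_cases), prevalence = as.double(prevalence),
         raters = raters, tau = tau, seed = as.integer(seed)),
    class = "panel_sim_config"
  )
}

#' Draw true case grades from the prevalence
#'
#' @param n_cases Number of independent draws.
#' @param prevalence Probability 6-vector over grades 0-5.
#' @param seed Optional integer seed (set before drawing).
#' @return Integer vector of true grades, length `n_cases`.
#' @export
simulate_truth <- function(n_cases, prevalence = default_prevalence(),
                           seed = NULL) {
  check_prevalence(prevalence)
  if (!is.finite(n_cases) || n_cases < 0) {
    abort_pk("invalid_config", "`n_cases` must be a nonnegative integer.")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (n_cases == 0) return(integer(0))
  sample(0:5, n_cases, replace = TRUE, prob = prevalence)
}

#' Simulate a confusion-model rater
#'
#' Each assigned grade is drawn from the truth-indexed row of the rater's
#' confusion matrix, independently across cases.
#'
#' @param truth Integer vector of true grades (0-5).
#' @param confusion 6x6 row-stochastic matrix, `confusion[t + 1, g + 1]` =
#'   P(assigned g | true t).
#' @param seed Optional integer seed.
#' @return Integer vector of assigned grades.
#' @export
simulate_rater_confusion <- function(truth, confusion, seed = NULL) {
  check_grades(truth, "truth")
  check_confusion(confusion)
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- integer(length(truth))
  for (t in 0:5) {
    idx <- which(truth == t)
    if (length(idx) > 0) {
      out[idx] <- sample(0:5, length(idx), replace = TRUE,
                         prob = confusion[t + 1, ])
    }
  }
  out
}

#' Simulate a latent-threshold rater
#'
#' The rater's latent score is `truth + bias + difficulty + Normal(0,
#' noise)`, thresholded at the half-integers and clipped to \[0, 5\]. Pass
#' the same `difficulty` vector to several raters to induce the shared
#' "hard case" correlation of a real panel.
#'
#' @param truth Integer vector of true grades (0-5).
#' @param bias Systematic shift in grade units.
#' @param noise Rater noise standard deviation, >= 0.
#' @param difficulty Per-case difficulty (numeric, recycled); typically
#'   drawn once per panel from Normal(0, tau).
#' @param seed Optional integer seed.
#' @return Integer vector of assigned grades.
#' @export
simulate_rater_latent <- function(truth, bias = 0, noise = 0,
                                  difficulty = 0, seed = NULL) {
  check_grades(truth, "truth")
  if (!is.finite(bias) || !is.finite(noise) || noise < 0) {
    abort_pk("invalid_config", "`bias` must be finite and `noise` >= 0.")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(truth)
  latent <- truth + bias + rep_len(difficulty, n) +
    stats::rnorm(n, 0, noise)
  pmin(5L, pmax(0L, as.integer(floor(latent + 0.5))))
}

#' Expected quadratically weighted kappa of two confusion-model raters
#'
#' Analytic oracle: under conditional independence given the truth, the
#' joint rating distribution is
#' \eqn{P(i, j) = \sum_t \pi_t C_a[t, i]\, C_b[t, j]}, and kappa follows
#' from this joint and its marginals by the quadratic-weight formula. Use
#' `diag(6)` for one side to get a rater's expected agreement with a
#' perfect reference.
#'
#' @param prevalence Probability 6-vector over true grades.
#' @param confusion_a,confusion_b 6x6 row-stochastic confusion matrices.
#' @return Expected kappa (scalar <= 1), or `NA` if degenerate.
#' @export
expected_qwk <- function(prevalence, confusion_a, confusion_b) {
  check_prevalence(prevalence)
  check_confusion(confusion_a)
  check_confusion(confusion_b)
  joint <- t(confusion_a) %*% (prevalence * confusion_b)
  w <- qwk_weights()
  denom <- sum(w * outer(rowSums(joint), colSums(joint)))
  if (denom == 0) return(NA_real_)
  1 - sum(w * joint) / denom
}

#' Simulate a full rating panel
#'
#' Draws the true grades, the shared per-case difficulty, and every
#' rater's grades, applies per-rater missingness, and returns the panel in
#' the long ratings format with the truth attached as the reference
#' pseudo-rater. The whole panel is a deterministic function of the
#' config (including its seed).
#'
#' @param config A [panel_sim_config()].
#' @return A rating panel tibble (columns `case_id`, `rater_id`,
#'   `rater_group`, `grade`), with attribute `"truth"` carrying the true
#'   grade vector.
#' @examples
#' cfg <- panel_sim_config(20, raters = list(
#'   rater_spec("alg_01", "algorithm", sigma = 0.4),
#'   rater_spec("path_01", "general_pathologist", sigma = 0.8)
#' ), tau = 0.15, seed = 7)
#' simulate_panel(cfg)
#' @export
simulate_panel <- function(config) {
  if (!inherits(config, "panel_sim_config")) {
    abort_pk("invalid_config", "`config` must come from panel_sim_config().")
  }
  if (length(config$raters) == 0) {
    abort_pk("invalid_config", "Config has no raters.")
  }
  set.seed(config$seed)
  n <- config$n_cases
  truth <- simulate_truth(n, config$prevalence)
  difficulty <- stats::rnorm(n, 0, config$tau)
  case_id <- sprintf("case_%0*d", max(3L, nchar(n)), seq_len(n))
  rows <- purrr::map(config$raters, function(rs) {
    g <- if (!is.null(rs$confusion)) {
      simulate_rater_confusion(truth, rs$confusion)
    } else {
      simulate_rater_latent(truth, rs$bias, rs$sigma, difficulty)
    }
    if (rs$missing_rate > 0) {
      g[stats::runif(n) < rs$missing_rate] <- NA_integer_
    }
    tibble::tibble(case_id = case_id, rater_id = rs$id,
                   rater_group = rs$group, grade = g)
  })
  ref <- tibble::tibble(case_id = case_id, rater_id = "reference",
                        rater_group = "reference", grade = truth)
  out <- dplyr::bind_rows(c(rows, list(ref)))
  attr(out, "truth") <- truth
  out
}

#' Study-shaped default simulation config
#'
#' The out-of-the-box panel mirrors the structure of the motivating reader
#' study's pathologist comparison: 70 biopsies drawn from the default
#' prevalence, 15 algorithm raters and 13 general pathologists, with the
#' uropathologist-consensus reference standard taken as the truth.
#' Algorithms slightly overgrade (positive bias) with low noise;
#' pathologists undergrade with higher noise; both groups share a per-case
#' difficulty (`tau` = 0.15). The latent noise levels are set so that the
#' groups' expected mean kappas (by [expected_qwk()]) sit near 0.88 and
#' 0.77 — a mean-kappa gap of about 0.1.
#'
#' @param seed Integer seed.
#' @param n_cases Number of cases; default 70.
#' @param missing_rate Per-rater review missingness; default 0.
#' @return A [panel_sim_config()].
#' @export
default_sim_config <- function(seed = 1, n_cases = 70, missing_rate = 0) {
  algs <- purrr::map(1:15, function(i) {
    rater_spec(sprintf("alg_%02d", i), "algorithm",
               bias = 0.10 + 0.02 * ((i - 1) %% 5 - 2),
               sigma = 0.93 + 0.05 * ((i - 1) %% 6 - 2.5),
               missing_rate = missing_rate)
  })
  paths <- purrr::map(1:13, function(i) {
    rater_spec(sprintf("path_%02d", i), "general_pathologist",
               bias = -0.15 + 0.03 * ((i - 1) %% 5 - 2),
               sigma = 1.48 + 0.08 * ((i - 1) %% 6 - 2.5),
               missing_rate = missing_rate)
  })
  panel_sim_config(n_cases, raters = c(algs, paths), tau = 0.15, seed = seed)
}

#' Simulate a challenge submission stream
#'
#' Generates per-team score trajectories over the competition days:
#' each team's expected tuning score rises from its starting level toward
#' a team-specific ceiling (exponential saturation), with Gaussian
#' submission noise; the validation score is the tuning score minus a small
#' generalization gap plus noise. Teams submit on day 0 and thereafter on
#' each day independently with probability `p_submit`.
#'
#' @param n_teams,n_days Positive counts.
#' @param start Mean starting score.
#' @param ceiling_range Range of team score ceilings (uniform draw).
#' @param rate_range Range of per-day improvement rates (uniform draw).
#' @param noise Submission score noise standard deviation.
#' @param p_submit Daily submission probability after day 0.
#' @param seed Optional integer seed.
#' @return A tibble of submission records: `team_id`, `day`,
#'   `tuning_score`, `validation_score`.
#' @export
simulate_submissions <- function(n_teams, n_days, start = 0.5,
                                 ceiling_range = c(0.80, 0.95),
                                 rate_range = c(0.05, 0.3),
                                 noise = 0.02, p_submit = 0.6, seed = NULL) {
  if (!is.finite(n_teams) || n_teams < 1 || !is.finite(n_days) || n_days < 1) {
    abort_pk("invalid_config", "`n_teams` and `n_days` must be >= 1.")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  ceilings <- stats::runif(n_teams, ceiling_range[1], ceiling_range[2])
  rates <- stats::runif(n_teams, rate_range[1], rate_range[2])
  starts <- pmin(ceilings, start + stats::rnorm(n_teams, 0, 0.05))
  purrr::map_dfr(seq_len(n_teams), function(tm) {
    days <- c(0L, which(stats::runif(n_days - 1) < p_submit))
    mu <- ceilings[tm] - (ceilings[tm] - starts[tm]) * exp(-rates[tm] * days)
    tuning <- pmin(1, mu + stats::rnorm(length(days), 0, noise))
    valid <- pmin(1, tuning - 0.02 + stats::rnorm(length(days), 0, noise))
    tibble::tibble(team_id = sprintf("team_%03d", tm), day = days,
                   tuning_score = tuning, validation_score = valid)
  })
}
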