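test_that("ratings CSV round-trips through write and read", {
  panel <- tiny_panel(n_cases = 8, raters = c(a1 = 0.3, b1 = 0.8))
  panel$grade[3] <- NA_integer_ # a missing review survives the round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratings(panel, path)
  back <- read_ratings(path)
  sorted <- dplyr::arrange(panel, case_id, rater_id)
  attr(sorted, "truth") <- NULL
  expect_identical(as.data.frame(back), as.data.frame(sorted))
})

test_that("an empty panel writes a header-only file", {
  empty <- tibble::tibble(case_id = character(0), rater_id = character(0),
                          rater_group = character(0), grade = integer(0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratings(empty, path)
  expect_identical(readLines(path), "case_id,rater_id,rater_group,grade")
})

test_that("malformed ratings files are rejected with the offending line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("case_id,rater_id,rater_group,grade",
               "c1,r1,algorithm,2",
               "c2,r1,algorithm,7"), path)
  err <- expect_error(read_ratings(path), class = "panelkappa_error_invalid_grade")
  expect_match(conditionMessage(err), "line 3")

  writeLines(c("case_id,rater_id,grade", "c1,r1,2"), path)
  expect_error(read_ratings(path), class = "panelkappa_error_format")

  writeLines(c("case_id,rater_id,rater_group,grade",
               "c1,r1,algorithm,2",
               "c1,r1,algorithm,3"), path)
  expect_error(read_ratings(path), class = "panelkappa_error_format")
})

test_that("panel validation enforces the reference contract", {
  panel <- tiny_panel()
  expect_silent(validate_panel(panel))
  no_ref <- dplyr::filter(panel, rater_group != "reference")
  expect_error(validate_panel(no_ref), class = "panelkappa_error_config")
  expect_silent(validate_panel(no_ref, require_reference = FALSE))
})

test_that("leaderboard series compute running best and daily medians", {
  one <- tibble::tibble(team_id = "t", day = 0L, tuning_score = 0.5)
  tl <- leaderboard_timeline(one)
  expect_equal(tl$best_so_far, 0.5)
  expect_equal(tl$daily_median, 0.5)

  subs <- tibble::tibble(
    team_id = c("a", "b", "a"), day = c(0L, 0L, 1L),
    tuning_score = c(0.5, 0.7, 0.6)
  )
  tl2 <- leaderboard_timeline(subs)
  expect_equal(tl2$best_so_far, c(0.7, 0.7))
  expect_equal(tl2$daily_median, c(0.6, 0.6))

  # gap days carry no median but continue the running max
  gap <- tibble::tibble(team_id = "a", day = c(0L, 2L),
                        tuning_score = c(0.4, 0.3))
  tl3 <- leaderboard_timeline(gap)
  expect_equal(tl3$best_so_far, c(0.4, 0.4, 0.4))
  expect_true(is.na(tl3$daily_median[2]))

  set.seed(19)
  stream <- simulate_submissions(8, 40, seed = 19)
  tl4 <- leaderboard_timeline(stream)
  expect_true(all(diff(tl4$best_so_far) >= 0))
  expect_error(leaderboard_timeline(stream[0, ]),
               class = "panelkappa_error_empty_input")
})

test_that("grade matrix ordering follows reference grade, mean grade and kappa", {
  panel <- tiny_panel(n_cases = 20, raters = c(good = 0.2, mid = 0.6, bad = 1.2),
                      seed = 13)
  rep <- grade_matrix_report(panel)
  co <- rep$case_order
  expect_true(all(diff(co$reference) >= 0))
  within <- split(co$mean_assigned, co$reference)
  expect_true(all(vapply(within, function(x) all(diff(x) >= -1e-12), logical(1))))
  # rater order equals an independently recomputed kappa ranking
  wide_ref <- dplyr::filter(panel, rater_group == "reference") |>
    dplyr::arrange(case_id)
  ks <- vapply(c("bad", "good", "mid"), function(r) {
    d <- dplyr::filter(panel, rater_id == r) |> dplyr::arrange(case_id)
    oracle_qwk(d$grade, wide_ref$grade)
  }, numeric(1))
  expect_identical(rep$rater_order$rater_id,
                   names(sort(ks, decreasing = TRUE)))
  expect_true(all(diff(rep$rater_order$kappa) <= 1e-12))

  # a rater with no reviewed case is dropped with a warning
  blank <- tibble::tibble(case_id = sprintf("c%02d", 1:20),
                          rater_id = "ghost", rater_group = "algorithm",
                          grade = NA_integer_)
  expect_warning(grade_matrix_report(dplyr::bind_rows(panel, blank)),
                 "ghost")
})

test_that("secondary case ordering uses the mean assigned grade", {
  panel <- tibble::tibble(
    case_id = rep(c("c1", "c2"), each = 3),
    rater_id = rep(c("r1", "r2", "reference"), 2),
    rater_group = rep(c("algorithm", "algorithm", "reference"), 2),
    grade = c(4L, 3L, 2L, 2L, 2L, 2L)
  )
  rep <- grade_matrix_report(panel)
  expect_identical(rep$case_order$case_id, c("c2", "c1")) # means 2.0 < 3.5
})

test_that("evaluate_panel_study is deterministic and row-order invariant", {
  cfg <- default_sim_config(seed = 5, n_cases = 40)
  cfg$raters <- cfg$raters[c(1:4, 16:19)] # 4 algorithms vs 4 pathologists
  panel <- simulate_panel(cfg)
  r1 <- evaluate_panel_study(panel, seed = 2, n_perm = 200, n_replicates = 50)
  r2 <- evaluate_panel_study(panel, seed = 2, n_perm = 200, n_replicates = 50)
  expect_identical(r1, r2)
  shuffled <- panel[sample(nrow(panel)), ]
  r3 <- evaluate_panel_study(shuffled, seed = 2, n_perm = 200, n_replicates = 50)
  expect_identical(r1, r3)
  expect_true(all(c("algorithm", "general_pathologist") %in%
                    r1$groups$rater_group))
  expect_identical(nrow(r1$raters), 8L)
})

test_that("perfect panels give kappa 1, T = 0 and p = 1", {
  truth <- rep(0:5, 4)
  case_id <- sprintf("c%02d", seq_along(truth))
  mk <- function(r, g) tibble::tibble(case_id = case_id, rater_id = r,
                                      rater_group = g, grade = truth)
  panel <- dplyr::bind_rows(mk("a1", "algorithm"), mk("a2", "algorithm"),
                            mk("p1", "general_pathologist"),
                            mk("p2", "general_pathologist"),
                            mk("reference", "reference"))
  rep <- evaluate_panel_study(panel, seed = 1, n_perm = 100, n_replicates = 50)
  expect_true(all(rep$raters$kappa == 1))
  expect_equal(rep$comparisons$statistic, 0)
  expect_equal(rep$comparisons$p_value, 1)
})

test_that("panels without the required groups are rejected", {
  panel <- tiny_panel() # algorithms only
  expect_error(evaluate_panel_study(panel), class = "panelkappa_error_config")
  no_ref <- dplyr::filter(panel, rater_group != "reference")
  expect_error(evaluate_panel_study(no_ref), class = "panelkappa_error_config")
})

test_that("tidiers return the documented shapes", {
  k <- qw_kappa(c(0, 1, 2), c(0, 2, 2))
  expect_identical(nrow(tidy(k)), 36L)
  expect_identical(sum(tidy(k)$count), 3L)
  expect_named(glance(k), c("kappa", "n"))

  pt <- permutation_test(c(2, 3), c(0, 1))
  expect_named(tidy(pt), c("statistic", "p_value", "n_permutations",
                           "exhaustive", "n_a", "n_b"))

  panel <- tiny_panel(n_cases = 15, raters = c(a = 0.4, b = 0.9))
  ci <- bootstrap_ci(panel, n_replicates = 30, seed = 1)
  expect_identical(tidy(ci)$point, ci$point)
})
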