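test_that("truth draws follow the prevalence and respect the seed", {
  expect_identical(simulate_truth(5, c(0, 0, 0, 1, 0, 0), seed = 1),
                   rep(3L, 5))
  expect_length(simulate_truth(0, seed = 1), 0)
  t1 <- simulate_truth(1000, seed = 8)
  t2 <- simulate_truth(1000, seed = 8)
  expect_identical(t1, t2)
  freq <- tabulate(simulate_truth(100000, seed = 3) + 1L, 6) / 100000
  expect_true(all(abs(freq - default_prevalence()) < 0.01))
  expect_error(simulate_truth(10, c(0.5, 0.5, 0.5, 0, 0, 0)),
               class = "panelkappa_error_invalid_config")
})

test_that("confusion-model raters reproduce their specified rows", {
  truth <- rand_grades(200)
  expect_identical(simulate_rater_confusion(truth, diag(6), seed = 1), truth)
  all0 <- matrix(c(rep(1, 6), rep(0, 30)), 6, 6)
  expect_identical(simulate_rater_confusion(truth, all0, seed = 1),
                   rep(0L, 200))
  # row fidelity at 50,000 draws per true grade, so the 0.01 band tests the
  # sampler rather than multinomial noise
  C <- latent_confusion(0.25, 0.75)
  big_truth <- rep(0:5, each = 50000)
  g <- simulate_rater_confusion(big_truth, C, seed = 16)
  for (t in 0:5) {
    emp <- tabulate(g[big_truth == t] + 1L, 6) / 50000
    expect_lt(sum(abs(emp - C[t + 1, ])) / 2, 0.01) # total variation
  }
  expect_error(simulate_rater_confusion(truth, diag(6) * 2),
               class = "panelkappa_error_invalid_config")
})

test_that("latent raters threshold, saturate and degenerate to the truth", {
  truth <- rand_grades(100)
  expect_identical(simulate_rater_latent(truth, 0, 0, 0), truth)
  expect_identical(simulate_rater_latent(truth, bias = 10), rep(5L, 100))
  expect_identical(simulate_rater_latent(truth, bias = -10), rep(0L, 100))
})

test_that("shared difficulty induces excess error correlation between raters", {
  n <- 20000
  truth <- simulate_truth(n, seed = 41)
  d <- rnorm(n, 0, 0.6)
  set.seed(42)
  a_shared <- simulate_rater_latent(truth, 0, 0.5, d)
  b_shared <- simulate_rater_latent(truth, 0, 0.5, d)
  # independence-matched pair: same marginal noise sqrt(0.5^2 + 0.6^2)
  a_ind <- simulate_rater_latent(truth, 0, sqrt(0.5^2 + 0.6^2), 0)
  b_ind <- simulate_rater_latent(truth, 0, sqrt(0.5^2 + 0.6^2), 0)
  cor_shared <- cor(a_shared - truth, b_shared - truth)
  cor_ind <- cor(a_ind - truth, b_ind - truth)
  expect_gt(cor_shared, cor_ind + 0.2)
})

test_that("expected_qwk matches a brute-force triple sum and its edge cases", {
  expect_equal(expected_qwk(default_prevalence(), diag(6), diag(6)), 1)
  unif <- matrix(1 / 6, 6, 6)
  set.seed(23)
  Ca <- rand_confusion()
  expect_equal(expected_qwk(default_prevalence(), Ca, unif), 0,
               tolerance = 1e-12)
  # brute force: joint by explicit triple loop, kappa by double loop
  pi <- default_prevalence()
  Cb <- rand_confusion()
  J <- matrix(0, 6, 6)
  for (t in 0:5) for (i in 0:5) for (j in 0:5) {
    J[i + 1, j + 1] <- J[i + 1, j + 1] + pi[t + 1] * Ca[t + 1, i + 1] * Cb[t + 1, j + 1]
  }
  num <- 0; den <- 0
  pa <- rowSums(J); pb <- colSums(J)
  for (i in 0:5) for (j in 0:5) {
    w <- (i - j)^2 / 25
    num <- num + w * J[i + 1, j + 1]
    den <- den + w * pa[i + 1] * pb[j + 1]
  }
  expect_equal(expected_qwk(pi, Ca, Cb), 1 - num / den, tolerance = 1e-12)
})

test_that("empirical kappa between simulated raters converges to expected_qwk", {
  set.seed(33)
  Ca <- latent_confusion(0.1, 0.8)
  Cb <- rand_confusion()
  truth <- simulate_truth(50000, seed = 34)
  a <- simulate_rater_confusion(truth, Ca, seed = 35)
  b <- simulate_rater_confusion(truth, Cb, seed = 36)
  expect_lt(abs(qw_kappa(a, b)$kappa -
                  expected_qwk(default_prevalence(), Ca, Cb)), 0.01)
})

test_that("rater confusion is recoverable from simulated grades", {
  C <- latent_confusion(-0.3, 0.85)
  truth <- rep(0:5, each = 50000)
  g <- simulate_rater_confusion(truth, C, seed = 53)
  for (t in 0:5) {
    est <- tabulate(g[truth == t] + 1L, 6) / 50000
    expect_lt(sum(abs(est - C[t + 1, ])) / 2, 0.01)
  }
})

test_that("whole panels are bitwise reproducible from their config", {
  cfg <- panel_sim_config(
    40,
    raters = list(
      rater_spec("a1", "algorithm", sigma = 0.5),
      rater_spec("p1", "general_pathologist", confusion = rand_confusion(),
                 missing_rate = 0.2)
    ),
    tau = 0.3, seed = 77
  )
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1, p2)
  expect_true(anyNA(dplyr::filter(p1, rater_id == "p1")$grade))
  expect_identical(
    dplyr::filter(p1, rater_group == "reference")$grade,
    attr(p1, "truth")
  )
})

test_that("latent_confusion is the analytic law of the latent rater", {
  set.seed(61)
  truth <- simulate_truth(50000, seed = 62)
  g <- simulate_rater_latent(truth, bias = 0.2, noise = 0.7)
  C <- latent_confusion(0.2, 0.7)
  for (t in 0:5) {
    emp <- tabulate(g[truth == t] + 1L, 6) / sum(truth == t)
    expect_lt(sum(abs(emp - C[t + 1, ])) / 2, 0.015)
  }
})

test_that("submission streams are reproducible with sane structure", {
  s1 <- simulate_submissions(5, 30, seed = 9)
  s2 <- simulate_submissions(5, 30, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(s1$tuning_score <= 1))
  expect_true(all(s1$day >= 0))
  one <- simulate_submissions(1, 1, seed = 2)
  expect_gte(nrow(one), 1)
  expect_identical(one$day[1], 0L)
  expect_error(simulate_submissions(0, 5), class = "panelkappa_error_invalid_config")
})
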