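test_that("differences respect scale and reference-zero is impossible by construction", {
  p <- make_pairs(c(20, 40), c(22, 38))
  expect_equal(gfr_differences(p, "percent"), c(10, -5))
  expect_equal(gfr_differences(p, "absolute"), c(2, -2))
  expect_equal(gfr_differences(make_pairs(c(30, 30), c(30, 30))), c(0, 0))
})

test_that("ccc matches Lin's closed form on hand-computable cases", {
  expect_equal(ccc(make_pairs(c(10, 20, 30), c(10, 20, 30))), 1)
  expect_equal(ccc(make_pairs(c(1, 2, 3), c(2, 3, 4))), 4 / 7)
  expect_error(ccc(make_pairs(c(5, 5, 5), c(5, 5, 5))), "denominator")
  expect_error(ccc(make_pairs(c(1, 2), c(1, 2))), ">= 3")
})

test_that("ccc never exceeds the Pearson correlation in absolute value", {
  set.seed(14)
  for (i in 1:25) {
    ref <- runif(12, 15, 45)
    test <- pmax(0.5, 0.9 * ref + rnorm(12, runif(1, -5, 5), 3))
    p <- make_pairs(ref, test)
    expect_lte(abs(ccc(p)), abs(cor(ref, test)) + 1e-12)
  }
})

test_that("tdi follows the normal closed form and is translation-monotone", {
  p0 <- make_pairs(c(25, 25, 30), c(25, 25, 30))
  expect_equal(tdi(p0), 0)
  # moment-matched percent differences: mean 0, population SD 5
  p <- make_pairs(c(100, 100, 100, 100), c(95, 105, 95, 105))
  expect_equal(tdi(p), qnorm(0.95) * 5)
  # adding constant bias never decreases tdi
  set.seed(15)
  ref <- runif(30, 20, 40)
  test <- ref * (1 + rnorm(30, 0, 0.05))
  base <- tdi(make_pairs(ref, test))
  for (shift in c(1.02, 1.05, 1.10)) {
    expect_gte(tdi(make_pairs(ref, test * shift)), base)
  }
})

test_that("empirical and normal TDI agree on Gaussian differences", {
  set.seed(16)
  n <- 10000
  ref <- rep(100, n)
  test <- 100 + rnorm(n, 0, 6)  # absolute == percent at ref 100
  p <- paired_gfr(paste0("P", 1:n), rep(1, n), ref, test)
  expect_lt(abs(tdi(p, method = "empirical") / tdi(p, method = "normal") - 1),
            0.05)
})

test_that("coverage probability matches the normal closed form", {
  ident <- make_pairs(c(30, 31, 32), c(30, 31, 32))
  expect_equal(coverage_probability(ident, delta = 5), 100)
  # differences with mean 0 and population SD 2.5 at delta = 5 -> Phi(2)-Phi(-2)
  p <- make_pairs(rep(30, 4), c(27.5, 32.5, 27.5, 32.5))
  expect_equal(coverage_probability(p, delta = 5),
               100 * (pnorm(2) - pnorm(-2)))
  expect_equal(coverage_probability(p, delta = 5, method = "empirical"), 100)
  # zero-variance branch
  shifted <- make_pairs(c(30, 31, 32), c(36, 37, 38))
  expect_equal(coverage_probability(shifted, delta = 5), 0)
  expect_equal(coverage_probability(shifted, delta = 7), 100)
})

test_that("cp is monotone in bias and noise and saturates as delta grows", {
  set.seed(17)
  ref <- runif(50, 20, 40)
  base <- ref * (1 + rnorm(50, 0, 0.04))
  cps <- vapply(c(0, 1, 2, 4), function(b) {
    coverage_probability(make_pairs(ref, base + b), delta = 5)
  }, numeric(1))
  expect_true(all(diff(cps) < 0))
  noisier <- vapply(c(0.02, 0.05, 0.10), function(s) {
    set.seed(18)
    coverage_probability(make_pairs(ref, ref * (1 + rnorm(50, 0, s))), delta = 5)
  }, numeric(1))
  expect_true(all(diff(noisier) < 0))
  expect_gt(coverage_probability(make_pairs(ref, base), delta = 1e4), 99.999)
})

test_that("p_within counts percent deviations and orders P10 <= P15", {
  ident <- make_pairs(c(20, 30), c(20, 30))
  expect_equal(p_within(ident, 10), 100)
  p <- make_pairs(c(20, 30, 40), c(21, 36, 40))  # percent diffs 5, 20, 0
  expect_equal(p_within(p, 10), 200 / 3)
  expect_equal(p_within(p, 15), 200 / 3)
  set.seed(19)
  for (i in 1:10) {
    ref <- runif(20, 15, 45)
    test <- ref * (1 + rnorm(20, 0, 0.12))
    q <- make_pairs(ref, test)
    expect_lte(p_within(q, 10), p_within(q, 15))
    d <- abs(gfr_differences(q, "percent"))
    expect_equal(p_within(q, 10), 100 * mean(d <= 10))
  }
})

test_that("bland_altman returns bias +/- 1.96 sample SD", {
  ident <- make_pairs(c(25, 30, 35), c(25, 30, 35))
  ba0 <- bland_altman(ident)
  expect_equal(c(ba0$bias, ba0$loa_lower, ba0$loa_upper), c(0, 0, 0))
  # percent differences (-2, 0, 2): sample SD 2 -> limits +/- 3.92
  p <- make_pairs(c(100, 100, 100), c(98, 100, 102))
  ba <- bland_altman(p, "percent")
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_upper, 1.96 * 2)
  expect_equal(ba$loa_lower, -1.96 * 2)
  expect_equal(ba$means, c(99, 100, 101))
})

test_that("mountain curve folds rank percentiles at 50", {
  # differences (-1, 0, 1, 2) on test - ref orientation
  p <- make_pairs(rep(30, 4), c(29, 30, 31, 32))
  mc <- mountain_curve(p, "absolute", orientation = "test_minus_ref")
  expect_equal(mc$percentile, c(20, 40, 60, 80))
  expect_equal(mc$folded, c(20, 40, 40, 20))
  expect_equal(mc$difference, c(-1, 0, 1, 2))
  # default orientation is reference - test: overestimation deviates left
  over <- make_pairs(rep(30, 5), rep(33, 5) + c(-0.2, -0.1, 0, 0.1, 0.2))
  mc2 <- mountain_curve(over)
  expect_true(all(mc2$difference < 0))
  expect_true(all(mc2$folded <= 50))
})

test_that("random-intercept regression recovers identity and falls back honestly", {
  p <- make_pairs(c(20, 25, 30, 35, 40, 45), c(20, 25, 30, 35, 40, 45),
                  patients = c("a", "a", "b", "b", "c", "c"))
  m <- random_intercept_regression(p)
  expect_equal(m$slope, 1, tolerance = 1e-6)
  expect_equal(m$intercept, 0, tolerance = 1e-6)
  expect_true(m$slope_ci[1] <= m$slope && m$slope <= m$slope_ci[2])
  expect_error(random_intercept_regression(make_pairs(c(20, 30), c(20, 30))),
               ">= 2 patients")
})

test_that("random-intercept regression covers the generating truth", {
  # simulation oracle: slope 0.8, intercept 6, patient SD 2, residual SD 3
  set.seed(20)
  hits_slope <- 0L; hits_int <- 0L
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    ref <- runif(120, 15, 45)
    pat <- rep(sprintf("P%02d", 1:40), each = 3)
    u <- rep(rnorm(40, 0, 2), each = 3)
    test <- pmax(1, 6 + 0.8 * ref + u + rnorm(120, 0, 3))
    m <- random_intercept_regression(
      paired_gfr(pat, rep(1:3, times = 40), ref, test))
    if (m$slope_ci[1] <= 0.8 && 0.8 <= m$slope_ci[2]) hits_slope <- hits_slope + 1L
    if (m$intercept_ci[1] <= 6 && 6 <= m$intercept_ci[2]) hits_int <- hits_int + 1L
  }
  expect_gte(hits_slope / n_rep, 0.90)
  expect_gte(hits_int / n_rep, 0.90)
})

test_that("baseline_subset keeps one earliest study per patient", {
  p <- paired_gfr(c("a", "a", "b", "c", "c", "c"), c(1, 2, 1, 2, 3, 5),
                  c(20, 21, 30, 40, 41, 42), c(20, 22, 31, 39, 42, 44))
  b <- baseline_subset(p)
  expect_equal(nrow(b), 3L)
  expect_equal(b$study_index, c(1L, 1L, 2L))  # earliest, not literally 1
  expect_equal(b$test_value, c(20, 31, 39))
  single <- make_pairs(c(20, 30), c(21, 29))
  expect_identical(baseline_subset(single), single)
})

test_that("cluster bootstrap is seed-reproducible and degenerate on identity", {
  p <- make_pairs(runif(12, 20, 40), runif(12, 20, 40) + 20,
                  patients = rep(letters[1:4], each = 3))
  stat <- function(pp) mean(gfr_differences(pp, "absolute"))
  ci1 <- cluster_bootstrap_ci(p, stat, B = 200, seed = 5)
  ci2 <- cluster_bootstrap_ci(p, stat, B = 200, seed = 5)
  expect_identical(ci1$replicates, ci2$replicates)
  expect_identical(c(ci1$lower, ci1$upper), c(ci2$lower, ci2$upper))
  ident <- make_pairs(c(20, 25, 30, 35), c(20, 25, 30, 35))
  ci0 <- cluster_bootstrap_ci(ident, stat, B = 200, seed = 1)
  expect_equal(c(ci0$lower, ci0$upper), c(0, 0))
  expect_error(cluster_bootstrap_ci(p, stat, B = 50, seed = 1), "B must be")
})

test_that("bootstrap redraws resamples on statistic failure and reports the count", {
  p <- make_pairs(runif(9, 20, 40), runif(9, 22, 42),
                  patients = rep(c("a", "b", "c"), each = 3))
  flaky <- local({
    calls <- 0L
    function(pp) {
      calls <<- calls + 1L
      if (calls %% 17L == 0L) stop("boom")
      mean(gfr_differences(pp, "absolute"))
    }
  })
  ci <- cluster_bootstrap_ci(p, flaky, B = 200, seed = 3)
  expect_gt(ci$n_failed, 0)
  expect_equal(nrow(ci$replicates), 200L)
})

test_that("agreement_report assembles consistent statistics with CIs", {
  # identity: perfect concordance across the board
  ident <- make_pairs(seq(20, 40, length.out = 8), seq(20, 40, length.out = 8))
  rep0 <- agreement_report(ident, B = 200, seed = 2)
  expect_equal(rep0$ccc, 1)
  expect_equal(rep0$tdi_p, 0)
  expect_equal(rep0$cp_delta, 100)
  expect_equal(rep0$p10, 100)
  expect_equal(rep0$bias, 0)
  # 5% proportional disagreement: tdi ~ 1.645 * 5, cp(10%) ~ 95.45
  set.seed(23)
  n <- 400
  ref <- runif(n, 20, 40)
  test <- ref * exp(rnorm(n, 0, sqrt(log(1 + 0.05^2))))
  p <- paired_gfr(rep(sprintf("P%03d", 1:100), each = 4),
                  rep(1:4, times = 100), ref, test)
  rep1 <- agreement_report(p, delta = 10, cp_scale = "percent",
                           B = 300, seed = 4)
  expect_equal(rep1$tdi_p, qnorm(0.95) * 5, tolerance = 0.10)
  expect_equal(rep1$cp_delta, 95.45, tolerance = 0.02)
  expect_lt(rep1$ci_ccc[1], rep1$ccc + 1e-9)
  expect_gt(rep1$ci_ccc[2], rep1$ccc - 1e-9)
  expect_true(rep1$loa_lower <= rep1$bias && rep1$bias <= rep1$loa_upper)
  expect_lte(rep1$p10, rep1$p15)
  row <- agreement_report_row(rep1)
  expect_equal(row$ccc, rep1$ccc)
  expect_equal(row$n_studies, 400L)
})
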