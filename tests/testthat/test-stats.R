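test_that("D'Agostino-Pearson matches independently computed reference values", {
  # reference: scipy.stats.normaltest on the same vectors
  r1 <- dagostino_pearson_test(c(2.3, 1.9, 3.1, 2.8, 2.2, 2.7, 1.5, 3.6,
                                 2.9, 2.4))
  expect_equal(unname(r1$statistic), 0.036447071125971654, tolerance = 1e-10)
  expect_equal(r1$p.value, 0.9819415089755453, tolerance = 1e-10)
  r2 <- dagostino_pearson_test(c(0.5, 0.7, 0.6, 0.9, 5.0, 0.8, 0.55, 0.65,
                                 4.2, 0.75, 0.62, 0.71))
  expect_equal(unname(r2$statistic), 12.749170239579605, tolerance = 1e-10)
  expect_equal(r2$p.value, 0.001704326740580112, tolerance = 1e-10)
  expect_error(dagostino_pearson_test(1:5), "n >= 8")
})

test_that("exact Mann-Whitney on 3 vs 3 matches brute-force enumeration", {
  A <- c(1, 2, 3); B <- c(4, 5, 6)
  # enumerate all rank assignments of 3 labels among 6 observations
  combos <- utils::combn(6, 3)
  pooled <- c(A, B)
  u_obs <- sum(rank(pooled)[1:3]) - 3 * 4 / 2  # U for group A = 0
  u_all <- apply(combos, 2, function(ix) sum(rank(pooled)[ix]) - 3 * 4 / 2)
  p_exact <- mean(u_all <= u_obs) + mean(u_all >= 3 * 3 - u_obs)  # two-sided
  expect_equal(u_obs, 0)
  expect_equal(p_exact, 0.1)

  # the package's rank engine agrees with the enumeration
  res <- necsim:::mann_whitney_test(A, B)
  expect_true(res$exact)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)
})

test_that("the Sidak adjustment is exact and monotone", {
  expect_identical(sidak_adjust(0.01, 6), 1 - 0.99^6)
  expect_equal(sidak_adjust(0.01, 6), 0.05851985, tolerance = 1e-7)
  expect_equal(sidak_adjust(0.2, 1), 0.2)
  p <- runif(50)
  expect_true(all(sidak_adjust(p, 6) >= p))
  expect_true(all(sidak_adjust(p, 6) <= 1))
})

test_that("well-separated groups are significant, equal groups are not", {
  set.seed(1)
  a <- rnorm(10, 0, 1); b <- rnorm(10, 10, 1)
  res <- choose_and_run(a, b)
  expect_true(res$significant)
  expect_lt(res$p_value, 1e-4)

  same <- choose_and_run(a, a)
  expect_false(same$significant)
  expect_gt(same$p_value, 0.9)
})

test_that("degenerate and half-degenerate groups are handled, not thrown", {
  res <- choose_and_run(rep(1, 5), rep(1, 6))
  expect_true(res$degenerate)
  expect_false(res$significant)
  # one constant group: normality unscreenable -> rank test
  set.seed(2)
  res2 <- choose_and_run(rep(100, 10), 100 + rnorm(10, 0, 1e-3))
  expect_equal(res2$test_name, "mann_whitney")
})

test_that("unequal variances trigger Welch's correction", {
  set.seed(3)
  a <- rnorm(20, 0, 1); b <- rnorm(20, 0.2, 12)
  res <- choose_and_run(a, b)
  expect_equal(res$test_name, "welch_t")
  expect_true(any(grepl("Welch", res$decision_trail)))
})

test_that("the decision trail records every normality screen", {
  set.seed(4)
  res <- choose_and_run(rnorm(10), rnorm(10))
  expect_true(any(grepl("Shapiro-Wilk", res$decision_trail)))
  expect_true(any(grepl("D'Agostino", res$decision_trail)))
})

test_that("timecourse comparison adjusts per-timepoint p with Sidak m", {
  set.seed(5)
  mk <- function(cond, shift) {
    expand.grid(mouse_id = paste0(cond, 1:8), time_post_min = c(20, 40, 60),
                stringsAsFactors = FALSE) |>
      transform(condition = cond,
                pct_baseline = 100 + shift + rnorm(24, 0, 5))
  }
  series <- rbind(mk("sham", 30), mk("depleted", 0))
  tc <- timecourse_comparison(series)
  expect_equal(tc$m, 3L)
  for (r in tc$per_timepoint) {
    expect_equal(r$sidak_p, sidak_adjust(r$p_value, 3L))
    expect_true(r$significant)
  }
  expect_equal(tc$n_excluded, 0L)
  # normal cells -> the mixed-design ANOVA is produced with a group effect
  expect_false(is.null(tc$rm_anova))
  expect_lt(tc$rm_anova$p_value, 0.01)
})

test_that("mice missing timepoints are excluded listwise", {
  set.seed(6)
  mk <- function(cond) {
    expand.grid(mouse_id = paste0(cond, 1:6), time_post_min = c(20, 40),
                stringsAsFactors = FALSE) |>
      transform(condition = cond, pct_baseline = 100 + rnorm(12, 0, 5))
  }
  series <- rbind(mk("sham"), mk("depleted"))
  series <- series[!(series$mouse_id == "sham1" & series$time_post_min == 40), ]
  tc <- timecourse_comparison(series)
  expect_equal(tc$n_excluded, 1L)
  # groups are reported in sorted condition order (depleted, sham)
  expect_equal(tc$per_timepoint[[1]]$group_labels, c("depleted", "sham"))
  expect_equal(tc$per_timepoint[[1]]$n_per_group, c(6L, 5L))
})

test_that("baseline equivalence reports group means and detects shifts", {
  set.seed(7)
  mk <- function(cond, mu) {
    data.frame(mouse_id = paste0(cond, 1:10), condition = cond,
               baseline_pg = rnorm(10, mu, 0.01))
  }
  same <- rbind(mk("sham", 0.4), mk("depleted", 0.4))
  res <- baseline_equivalence(same)
  expect_false(res$significant)
  expect_equal(res$group_means$mean, c(0.4, 0.4), tolerance = 0.05)

  shifted <- rbind(mk("sham", 0.4), mk("depleted", 0.5))
  expect_true(baseline_equivalence(shifted)$significant)
})
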