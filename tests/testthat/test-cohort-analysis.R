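test_that("percent change is signed, exact, and invertible", {
  expect_equal(percent_change(0.73, 0.63), -13.6986, tolerance = 1e-4)
  expect_equal(round_half_away(percent_change(0.73, 0.63)), -14)
  expect_equal(percent_change(1.09, 0.80), -26.6055, tolerance = 1e-4)
  expect_equal(round_half_away(percent_change(1.09, 0.80)), -27)
  expect_identical(percent_change(2.5, 2.5), 0)
  expect_error(percent_change(0, 1), class = "iosmodel_invalid_input")
  expect_error(percent_change(-1, 1), class = "iosmodel_invalid_input")

  # exact inverse relation of forward and backward changes
  set.seed(71)
  a <- runif(50, 0.1, 3); b <- runif(50, 0.1, 3)
  p1 <- percent_change(a, b); p2 <- percent_change(b, a)
  expect_equal((1 + p1 / 100) * (1 + p2 / 100), rep(1, 50), tolerance = 1e-12)
})

test_that("paired t-test matches the hand computation", {
  r <- paired_t(c(1, 2, 3), c(2, 4, 5))
  # differences 1, 2, 2: mean 5/3, sd 0.5774, t = 5 on 2 df
  expect_equal(r$statistic, 5, tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 2 * pt(-5, 2), tolerance = 1e-12)
  expect_true(r$significant)

  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)
  expect_false(same$significant)

  expect_error(paired_t(1, 1), class = "iosmodel_insufficient_data")

  shifted <- paired_t(c(1, 2, 3) + 10, c(2, 4, 5) + 10)
  expect_equal(shifted$statistic, r$statistic, tolerance = 1e-12)

  zv <- paired_t(c(1, 2, 3), c(2, 3, 4))
  expect_identical(zv$flag, "zero_variance")
  expect_identical(zv$p_value, 0)
})

test_that("Welch two-sample test matches the hand formula", {
  r <- two_sample_t(c(1, 2, 3), c(2, 4, 6))
  # means 2 vs 4, variances 1 vs 4: t = -2/sqrt(5/3), df = 50/17
  expect_equal(r$statistic, -2 / sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(r$df, 50 / 17, tolerance = 1e-12)

  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)

  # one constant group: finite t, df below the pooled n_a + n_b - 2
  r2 <- two_sample_t(c(2, 2, 2, 2), c(1, 3, 5))
  expect_true(is.finite(r2$statistic))
  expect_lt(r2$df, 5)

  shifted <- two_sample_t(c(1, 2, 3) + 7, c(2, 4, 6) + 7)
  expect_equal(shifted$statistic, r$statistic, tolerance = 1e-12)
  expect_error(two_sample_t(1, c(1, 2)), class = "iosmodel_insufficient_data")
})

test_that("linear fit matches the normal equations", {
  r <- linear_fit(c(1, 2, 3), c(2, 3, 5))
  expect_equal(r$slope, 1.5, tolerance = 1e-12)
  expect_equal(r$intercept, 1 / 3, tolerance = 1e-12)
  expect_equal(r$r, 3 / sqrt(2 * 42 / 9), tolerance = 1e-12)

  col <- linear_fit(c(1, 2, 3), c(2, 4, 6))
  expect_equal(col$r, 1, tolerance = 1e-12)

  neg <- linear_fit(c(1, 2, 3), -c(2, 3, 5))
  expect_equal(neg$slope, -r$slope, tolerance = 1e-12)
  expect_equal(neg$r, -r$r, tolerance = 1e-12)

  expect_error(linear_fit(c(2, 2, 2), c(1, 2, 3)),
               class = "iosmodel_degenerate_fit")

  # r^2 equals the regression/total sum-of-squares ratio
  set.seed(81)
  x <- rnorm(40); y <- 2 * x + rnorm(40)
  fit <- linear_fit(x, y)
  yhat <- fit$intercept + fit$slope * x
  expect_equal(fit$r_squared,
               sum((yhat - mean(y))^2) / sum((y - mean(y))^2),
               tolerance = 1e-10)
})

test_that("cell means and layout follow the study structure", {
  co <- generate_cohort(cohort_config(n_h = 2, n_sai = 2, seed = 3))
  idx <- cohort_indices(co)
  fits <- fit_cohort(co, "eric")
  summ <- summarize_cohort(idx, fits)
  expect_equal(nrow(summ), 6)  # 3 visit-conditions x 2 groups
  expect_equal(sort(unique(paste(summ$visit, summ$condition))),
               sort(c("2006 preB", "2008 preB", "2008 postB")))
  expect_true(all(summ$n == 2))

  # hand mean of a cell
  cell <- fits[fits$group == "SAI" & fits$visit == "2006", ]
  expect_equal(summ$Cp[summ$group == "SAI" & summ$visit == "2006"],
               mean(cell$Cp), tolerance = 1e-12)

  expect_error(summarize_cohort(idx[0, ]), class = "iosmodel_invalid_input")
})

test_that("percent-change stage reproduces the published index changes from fixture means", {
  pct <- percent_change_report(load_fixture("table2_means"))
  get <- function(g, p, e) {
    pct$percent_rounded[pct$group == g & pct$parameter == p & pct$effect == e]
  }
  expect_equal(get("SAI", "r5", "growth"), -14)
  expect_equal(get("SAI", "r5", "bronchodilator"), -16)
  expect_equal(get("H", "r5", "growth"), -17)
  expect_equal(get("H", "r5", "bronchodilator"), -12)
  expect_equal(get("SAI", "fdr", "growth"), -13)
  expect_equal(get("SAI", "fdr", "bronchodilator"), -26)
  expect_equal(get("H", "fdr", "growth"), -13)
  expect_equal(get("H", "fdr", "bronchodilator"), -38)
  expect_equal(get("SAI", "ax", "growth"), -20)
  expect_equal(get("SAI", "ax", "bronchodilator"), -33)
  expect_equal(get("H", "ax", "growth"), -27)
  expect_equal(get("H", "ax", "bronchodilator"), -29)
})

test_that("study report composes deterministically and flags the group contrasts", {
  co <- generate_cohort(cohort_config(n_h = 3, n_sai = 4, seed = 8))
  r1 <- study_report(co, models = "eric")
  r2 <- study_report(co, models = "eric")
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$percent_change, r2$percent_change)
  expect_identical(r1$paired_tests, r2$paired_tests)

  expect_true(all(c("summary", "percent_change", "paired_tests",
                    "group_tests", "correlations") %in% names(r1)))
  expect_true(all(r1$group_tests$p_value >= 0 & r1$group_tests$p_value <= 1))
  expect_identical(r1$group_tests$significant, r1$group_tests$p_value < 0.05)
  expect_error(study_report(co[0, ]), class = "iosmodel_invalid_input")
})

test_that("compliance correlates negatively with reactance area in synthetic cohorts", {
  co <- generate_cohort(cohort_config(n_h = 4, n_sai = 6, seed = 12))
  rep <- study_report(co, models = "eric")
  cp_ax <- rep$correlations[rep$correlations$comparison == "eric Cp vs AX", ]
  expect_lt(cp_ax$slope, 0)
  expect_lt(cp_ax$r, 0)
  rp_fdr <- rep$correlations[rep$correlations$comparison == "eric Rp vs fdR", ]
  expect_gt(rp_fdr$r, 0)
})
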