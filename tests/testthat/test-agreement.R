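test_that("point metrics match hand-computed values", {
  z <- point_metrics(c(0, 0, 0))
  expect_equal(z$mae, 0)
  expect_equal(z$rmse, 0)
  expect_equal(c(z$loa_low, z$loa_high), c(0, 0))

  pm <- point_metrics(c(1, -1, 3))
  expect_equal(pm$mae, 5 / 3)
  expect_equal(pm$rmse, sqrt(11 / 3))
  expect_equal(pm$bias, 1)
  expect_equal(pm$sd_diff, 2)
  expect_equal(round(c(pm$loa_low, pm$loa_high), 2), c(-2.92, 4.92))
})

test_that("limits of agreement are bias +/- 1.96 sample SD", {
  # a difference set constructed to have mean 1.92 and SD 5.444 exactly
  set.seed(4)
  z <- rnorm(93)
  d <- 1.92 + 5.444 * (z - mean(z)) / sd(z)
  pm <- point_metrics(d)
  expect_equal(round(pm$loa_low, 2), -8.75)
  expect_equal(round(pm$loa_high, 2), 12.59)
})

test_that("degenerate difference sets are handled per contract", {
  expect_error(point_metrics(numeric(0)),
               class = "vitalval_insufficient_data_error")
  one <- point_metrics(2.5)
  expect_equal(one$mae, 2.5)
  expect_equal(one$bias, 2.5)
  expect_true(is.na(one$sd_diff))
  expect_true(is.na(one$loa_low))
})

test_that("bootstrap CIs are deterministic given seed and inputs", {
  set.seed(77)
  d <- rnorm(60, 1, 2)
  cfg <- bootstrap_config(n_replicates = 300, seed = 42)
  expect_identical(bootstrap_ci(d, "mae", cfg), bootstrap_ci(d, "mae", cfg))
  cfg2 <- bootstrap_config(n_replicates = 300, seed = 43)
  expect_false(identical(bootstrap_ci(d, "mae", cfg),
                         bootstrap_ci(d, "mae", cfg2)))
})

test_that("constant differences give a zero-width CI at |c|", {
  ci <- bootstrap_ci(rep(-3, 10), "mae",
                     bootstrap_config(n_replicates = 200, seed = 1))
  expect_equal(unname(ci), c(3, 3))
})

test_that("participant-unit bootstrap requires group ids and runs", {
  set.seed(12)
  d <- rnorm(40)
  cfg <- bootstrap_config(n_replicates = 200, seed = 5, unit = "participant")
  expect_error(bootstrap_ci(d, "mae", cfg), class = "vitalval_config_error")
  ci <- bootstrap_ci(d, "mae", cfg, group_ids = rep(1:4, each = 10))
  expect_true(ci["low"] <= ci["high"])
})

test_that("Pearson correlation matches the direct covariance formula", {
  expect_equal(pearson_cor(1:10, 1:10)$r, 1)
  expect_equal(pearson_cor(1:10, -(1:10) + 7)$r, -1)

  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  got <- pearson_cor(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_oracle)
  t_stat <- r_oracle * sqrt((4 - 2) / (1 - r_oracle^2))
  expect_equal(got$p_value, 2 * pt(-abs(t_stat), df = 2))

  expect_error(pearson_cor(rep(1, 5), 1:5),
               class = "vitalval_undefined_correlation_error")
  expect_error(pearson_cor(1:2, 1:2),
               class = "vitalval_insufficient_data_error")
})

test_that("analyze_stratum flags undefined correlation but keeps the metrics", {
  w <- tibble::tibble(
    participant_id = "p", variable = "HR", stage_id = "at_rest",
    median_test = rep(70, 3), median_ref = rep(70, 3),
    difference = rep(0, 3)
  )
  expect_warning(
    res <- analyze_stratum(w, "at_rest",
                           bootstrap_config(n_replicates = 100, seed = 2)),
    "constant"
  )
  expect_equal(res$mae, 0)
  expect_equal(res$rmse, 0)
  expect_true(is.na(res$pearson_r))
  expect_equal(res$n_windows, 3)
})

test_that("analyze_stratum recovers injected bias and LoA from simulated windows", {
  set.seed(2024)
  n <- 200
  d <- rnorm(n, mean = 2, sd = 1)
  w <- tibble::tibble(
    participant_id = "p", variable = "HR", stage_id = "at_rest",
    median_ref = rnorm(n, 70, 10), difference = d
  )
  w$median_test <- w$median_ref + d
  res <- analyze_stratum(w, "sim", bootstrap_config(n_replicates = 500, seed = 6))
  expect_lt(abs(res$bias - 2), 0.2)
  expect_lt(abs(res$loa_low - 0.04), 0.35)
  expect_lt(abs(res$loa_high - 3.96), 0.35)
  expect_true(res$mae_ci_low <= res$mae && res$mae <= res$mae_ci_high)
})

test_that("results table formats CIs, LoA and small p-values for display", {
  w <- tibble::tibble(
    participant_id = "p", variable = "RR", stage_id = "tablet",
    median_ref = c(15, 16, 17, 18), median_test = c(14, 15.5, 16, 17),
    difference = c(-1, -0.5, -1, -1)
  )
  res <- analyze_stratum(w, "tablet", bootstrap_config(n_replicates = 100, seed = 3))
  tab <- format_results_table(res)
  expect_match(tab$mae, "^\\d+\\.\\d{2} \\(\\d+\\.\\d{2} to \\d+\\.\\d{2}\\)$")
  expect_match(tab$bias_loa, "to")
  expect_true(tab$p %in% c("<.001", sprintf("%.3f", res$p_value)))
})
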