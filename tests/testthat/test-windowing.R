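test_that("window grid covers a stage with consecutive whole windows", {
  g <- window_grid(list(start_s = 0, end_s = 120))
  expect_equal(g$window_start_s, c(0, 40, 80))
  expect_equal(g$center_s, c(20, 60, 100))

  g2 <- window_grid(list(start_s = 0, end_s = 130))
  expect_equal(nrow(g2), 3)
  expect_true(all(g2$window_end_s <= 130))

  expect_message(g3 <- window_grid(list(start_s = 0, end_s = 39)), "skipped")
  expect_equal(nrow(g3), 0)
})

test_that("windowed medians match the sort-based convention", {
  rec <- const_recording(0, 0:39)
  rec$value <- 1:40
  expect_equal(median_in_window(rec, 0, 40)$median, 20.5)

  t <- seq(2, 38, by = 4)
  rec2 <- recording(t, t, "d", "HR", nominal_interval_s = 4)
  m <- median_in_window(rec2, 0, 40)
  expect_equal(m$median, 20)  # mean of central values 18 and 22
  expect_equal(m$n, 10L)

  empty <- median_in_window(rec2, 100, 140)
  expect_true(is.na(empty$median))
  expect_equal(empty$n, 0L)
})

test_that("windowed median agrees with brute-force filter-then-sort", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(5:200, 1)
    t <- sort(runif(n, 0, 300))
    t <- t[!duplicated(round(t, 6))]
    v <- rnorm(length(t), 70, 15)
    rec <- recording(t, v, "d", "HR", nominal_interval_s = 1)
    a <- runif(1, 0, 250)
    got <- median_in_window(rec, a, a + 40)
    inside <- sort(v[t >= a & t < a + 40])
    if (length(inside) == 0) {
      expect_true(is.na(got$median))
    } else {
      k <- length(inside)
      want <- if (k %% 2 == 1) inside[(k + 1) / 2] else
        (inside[k / 2] + inside[k / 2 + 1]) / 2
      expect_equal(got$median, want)
    }
  }
})

test_that("paired windows on constant channels have full counts and zero difference", {
  s <- constant_session(duration = 120)
  w <- extract_paired_windows(s, "HR")
  expect_equal(nrow(w), 3)
  expect_true(all(w$difference == 0))
  expect_true(all(w$n_test == 10L))
  expect_true(all(w$n_ref == 40L))
  expect_true(all(is.na(w$median_spo2)))
})

test_that("identical streams on both roles give exactly zero differences", {
  set.seed(8)
  t <- 0:200
  v <- 70 + cumsum(rnorm(201, 0, 0.3))
  ann <- stage_annotations("at_rest", "movement", 0, 200)
  s <- assemble_session("p1", list(
    test_HR = recording(t, v, "a", "HR", nominal_interval_s = 1),
    test_RR = const_recording(15, t, "RR", 1),
    ref_HR = recording(t, v, "b", "HR", nominal_interval_s = 1),
    ref_RR = const_recording(15, t, "RR", 1)
  ), ann)
  w <- extract_paired_windows(s, "HR")
  expect_true(all(w$difference == 0))
})

test_that("a window empty on one device is excluded; others are kept", {
  t_test <- seq(0, 120, by = 4)
  drop <- t_test >= 40 & t_test < 80
  s <- constant_session(duration = 120)
  s$recordings$test_HR <- const_recording(70, t_test[!drop], "HR", 4)
  w <- suppressMessages(extract_paired_windows(s, "HR"))
  expect_equal(nrow(w), 2)
  expect_false(60 %in% w$center_s)
  log <- exclusion_log(w)
  expect_equal(log$n_candidate, 3L)
  expect_equal(log$n_excluded, 1L)
  expect_equal(log$n_kept, 2L)
})

test_that("raising min_fraction never increases the number of retained windows", {
  spec <- session_spec(seed = 9)
  spec$test_error$dropout_prob <- 0.4
  sim <- simulate_session(spec)
  fractions <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  kept <- vapply(fractions, function(f) {
    nrow(suppressMessages(
      extract_paired_windows(sim$session, "HR", windowing_config(min_fraction = f))
    ))
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("windows never cross stage boundaries", {
  sim <- simulate_session(zero_error_spec(seed = 2))
  w <- extract_paired_windows(sim$session, "HR")
  ann <- sim$session$annotations
  for (i in seq_len(nrow(ann))) {
    wi <- w[w$stage_id == ann$stage_id[i], ]
    expect_true(all(wi$center_s - 20 >= ann$start_s[i]))
    expect_true(all(wi$center_s + 20 <= ann$end_s[i]))
    expect_equal(nrow(wi),
                 floor((ann$end_s[i] - ann$start_s[i]) / 40))
  }
})
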