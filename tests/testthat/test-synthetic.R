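test_that("truth generation is deterministic and matches the protocol structure", {
  spec <- session_spec(seed = 4)
  a <- generate_truth(spec)
  b <- generate_truth(spec)
  expect_identical(a, b)

  expect_equal(nrow(a$annotations), 8)
  expect_equal(sum(a$annotations$phase == "movement"), 7)

  # lowest plateau holds near the final 80% target
  hyp_start <- a$annotations$start_s[a$annotations$stage_id == "hypoxia"]
  last_plateau <- a$truth$t_s >= max(a$truth$t_s) - 170
  expect_lt(abs(mean(a$truth$SPO2[last_plateau]) - 80), 1)
})

test_that("zero wander and zero shifts leave HR constant during movement", {
  spec <- session_spec(seed = 1, effects = {
    e <- constant_stage_effects()
    e$hr_shift <- 0
    e$rr_shift <- 0
    e
  }, hr_per_spo2 = 0)
  gt <- generate_truth(spec)
  mv <- gt$truth$t_s < gt$annotations$start_s[gt$annotations$stage_id == "hypoxia"]
  expect_equal(unique(gt$truth$HR[mv]), spec$profile$hr_baseline)
})

test_that("sit-to-stand raises the truth mean by the configured shift", {
  spec <- session_spec(seed = 6)
  gt <- generate_truth(spec)
  ann <- gt$annotations
  in_stage <- function(id) {
    i <- ann$stage_id == id
    gt$truth$t_s >= ann$start_s[i] & gt$truth$t_s < ann$end_s[i]
  }
  shift_est <- mean(gt$truth$HR[in_stage("sts")]) -
    mean(gt$truth$HR[in_stage("at_rest")])
  expect_lt(abs(shift_est - 18), 4)  # wander SD 1.5 per stage
})

test_that("zero-error observation reproduces the truth on the device grid", {
  spec <- zero_error_spec(seed = 2)
  gt <- generate_truth(spec)
  rec <- observe(gt$truth, gt$annotations, "HR", zero_error_model(), 4,
                 "patch", seed = 9)
  expect_equal(rec$t_s, seq(0, max(gt$truth$t_s), by = 4))
  expect_equal(rec$value,
               gt$truth$HR[match(rec$t_s, gt$truth$t_s)])
})

test_that("full dropout empties the recording; pure bias shifts it exactly", {
  spec <- zero_error_spec(seed = 3)
  gt <- generate_truth(spec)

  m_drop <- zero_error_model()
  m_drop$dropout_prob <- 1
  rec <- observe(gt$truth, gt$annotations, "HR", m_drop, 4, "patch", seed = 1)
  expect_equal(nrow(rec), 0)

  m_bias <- zero_error_model()
  m_bias$bias <- 2
  rec2 <- observe(gt$truth, gt$annotations, "HR", m_bias, 4, "patch", seed = 1)
  truth_on_grid <- gt$truth$HR[match(rec2$t_s, gt$truth$t_s)]
  expect_equal(rec2$value, truth_on_grid + 2)
})

test_that("a pure-bias device yields an exact pipeline bias estimate", {
  spec <- zero_error_spec(seed = 5)
  spec$test_error$bias <- 2
  sim <- simulate_session(spec)
  w <- extract_paired_windows(sim$session, "HR")
  expect_equal(unique(w$difference), 2)
})

test_that("cohort generation is reproducible and draws plausible baselines", {
  c1 <- generate_cohort(3, session_spec(), master_seed = 50)
  c2 <- generate_cohort(3, session_spec(), master_seed = 50)
  expect_identical(c1$ledger, c2$ledger)
  expect_identical(c1$sessions[[2]]$recordings$test_HR,
                   c2$sessions[[2]]$recordings$test_HR)

  # sampling-distribution check on the profile draws (3 SE band)
  coh <- default_cohort()
  hr <- unique(coh$ledger[, c("participant_id", "hr_baseline")])$hr_baseline
  expect_equal(length(hr), 29)
  expect_lt(abs(mean(hr) - 72.9), 3 * 11.9 / sqrt(29))
  expect_true(all(hr >= 40 & hr <= 150))
  rr <- unique(coh$ledger[, c("participant_id", "rr_baseline")])$rr_baseline
  expect_true(all(rr >= 4 & rr <= 31))
})

test_that("the truth ledger records every governing parameter", {
  coh <- generate_cohort(2, session_spec(), master_seed = 60)
  expect_equal(nrow(coh$ledger), 2 * 2 * 8)  # participants x variables x stages
  need <- c("participant_id", "seed", "hr_baseline", "rr_baseline", "variable",
            "stage_id", "stage_shift", "wander_sd", "bias", "noise_sd",
            "artifact_rate", "artifact_magnitude_sd", "dropout_prob",
            "ref_noise_sd", "ref_dropout_prob", "expected_window_sd")
  expect_true(all(need %in% names(coh$ledger)))
  expect_false(any(is.na(coh$ledger)))
})

test_that("the analytic window SD matches simulation for the median filter", {
  # median of 10 samples of white noise vs median of 40, independent devices
  set.seed(99)
  sims <- replicate(4000, {
    stats::median(rnorm(10, 0, 2)) - stats::median(rnorm(40, 0, 0.5))
  })
  expect_lt(abs(sd(sims) / expected_window_sd(2, 0.5) - 1), 0.05)
})

test_that("invalid specs are rejected", {
  expect_error(session_spec(hypoxia_targets = c(90, 95)),
               class = "vitalval_config_error")
  sched <- default_movement_schedule()
  sched$duration_s[3] <- 30
  expect_error(session_spec(movement_schedule = sched),
               class = "vitalval_config_error")
  expect_error(participant_profile(hr_baseline = 200),
               class = "vitalval_config_error")
})
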