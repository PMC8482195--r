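# Synthetic session generator: known-truth cohorts emulating a wearable
# validation protocol (seven movement activities, then stepwise controlled
# desaturation to 80%), with stage-dependent device bias, noise, artifact
# bursts and dropout.

HR_BOUNDS <- c(40, 150)
RR_BOUNDS <- c(4, 31)

#' Participant baseline profile
#'
#' Resting baselines for one simulated participant. Cohort draws come from
#' Normal(72.9, 11.9) bpm for HR and Normal(16.3, 3.6) rpm for RR —
#' matching a healthy-volunteer cohort — truncated to the physiological
#' ranges 40-150 bpm and 4-31 rpm.
#'
#' @param hr_baseline Resting HR, bpm.
#' @param rr_baseline Resting RR, rpm.
#' @return A `participant_profile` list.
#' @export
participant_profile <- function(hr_baseline = 72.9, rr_baseline = 16.3) {
  if (hr_baseline < HR_BOUNDS[1] || hr_baseline > HR_BOUNDS[2]) {
    abort_config("hr_baseline outside physiological bounds [40, 150] bpm")
  }
  if (rr_baseline < RR_BOUNDS[1] || rr_baseline > RR_BOUNDS[2]) {
    abort_config("rr_baseline outside physiological bounds [4, 31] rpm")
  }
  structure(list(hr_baseline = hr_baseline, rr_baseline = rr_baseline),
            class = "participant_profile")
}

# Truncated-normal draw by rejection (acceptance ~0.99 at these bounds).
rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Default per-stage physiological effects
#'
#' Additive shifts to the participant baseline and slow within-stage wander.
#' Sit-to-stand, the one dynamic activity, raises HR by 18 bpm and RR by 2
#' rpm; turning pages raises RR by 2 rpm; other activities leave the
#' baselines unchanged. `wander_sd_*` is the SD of the slow drift
#' accumulated over a stage (implemented as a random walk whose per-second
#' step SD is `wander_sd / sqrt(duration)`).
#'
#' @return Tibble with `stage_id`, `hr_shift`, `rr_shift`, `wander_sd_hr`,
#'   `wander_sd_rr`.
#' @export
default_stage_effects <- function() {
  tibble::tibble(
    stage_id = ALL_STAGES,
    hr_shift = ifelse(ALL_STAGES == "sts", 18, 0),
    rr_shift = ifelse(ALL_STAGES %in% c("sts", "turning_pages"), 2, 0),
    wander_sd_hr = 1.5,
    wander_sd_rr = 0.8
  )
}

#' Zero (no-drift) stage effects
#'
#' Stage shifts as in [default_stage_effects()] but with zero within-stage
#' wander, so the ground truth is piecewise constant. Useful for exact
#' identity checks.
#' @return Tibble like [default_stage_effects()].
#' @export
constant_stage_effects <- function() {
  out <- default_stage_effects()
  out$wander_sd_hr <- 0
  out$wander_sd_rr <- 0
  out
}

# Instantaneous-noise SD that produces a requested window-level difference
# SD after the median filter, given the reference channel's own noise.
noise_sd_for_window_sd <- function(window_sd, ref_noise_sd = 0.3,
                                   n_test = 10, n_ref = 40) {
  v <- window_sd^2 - median_var_factor(n_ref) * ref_noise_sd^2
  sqrt(pmax(0, v) / median_var_factor(n_test))
}

#' Analytic window-level difference SD for a device-error pair
#'
#' White instantaneous noise is attenuated by the in-window median: the
#' median of k iid Gaussian estimates has variance `median_var_factor(k)`
#' times the per-sample variance (0.1383 for k = 10, 0.0379 for k = 40).
#' The SD of the test-minus-reference window difference is therefore
#' `sqrt(v_test * test_sd^2 + v_ref * ref_sd^2)`. This is the honest
#' recovery target recorded in the cohort truth ledger.
#'
#' @param test_noise_sd,ref_noise_sd Instantaneous noise SDs.
#' @param n_test,n_ref Samples per window for each device.
#' @return Expected SD of windowed differences.
#' @export
expected_window_sd <- function(test_noise_sd, ref_noise_sd,
                               n_test = 10, n_ref = 40) {
  sqrt(median_var_factor(n_test) * test_noise_sd^2 +
         median_var_factor(n_ref) * ref_noise_sd^2)
}

#' Default test-device error model
#'
#' Per-(variable, stage) additive bias, white noise on the instantaneous
#' estimates, Poisson-timed artifact bursts and sample dropout. Defaults
#' are loosely calibrated to the bias and limits-of-agreement magnitudes
#' reported in chest-patch validation studies — a marginal HR
#' overestimation that worsens during sit-to-stand, and a consistent RR
#' underestimation — but they are configuration, not claims about any
#' particular device. Noise SDs are derived from target window-level
#' difference SDs via [noise_sd_for_window_sd()].
#'
#' @return Tibble with `variable`, `stage_id`, `bias`, `noise_sd`,
#'   `artifact_rate` (bursts/min), `artifact_magnitude_sd`, `dropout_prob`.
#' @export
default_test_error_model <- function() {
  hr_bias <- c(0.31, 1.92, 0.08, 0.15, 0.32, 0.06, 0.25, 0.49)
  hr_loa_half <- c(4.11, 10.67, 1.76, 2.19, 2.53, 2.38, 1.88, 2.07)
  rr_bias <- c(-1.94, -1.59, -1.68, -1.97, -1.44, -1.69, -2.43, -0.08)
  rr_loa_half <- c(4.74, 9.12, 4.57, 5.66, 5.19, 7.42, 5.49, 5.73)
  dyn <- ALL_STAGES == "sts"
  hyp <- ALL_STAGES == "hypoxia"
  dplyr::bind_rows(
    tibble::tibble(
      variable = "HR", stage_id = ALL_STAGES,
      bias = hr_bias,
      noise_sd = noise_sd_for_window_sd(hr_loa_half / 1.96),
      artifact_rate = ifelse(dyn, 0.5, ifelse(hyp, 0.1, 0.2)),
      artifact_magnitude_sd = ifelse(dyn, 8, ifelse(hyp, 3, 4)),
      dropout_prob = 0.02
    ),
    tibble::tibble(
      variable = "RR", stage_id = ALL_STAGES,
      bias = rr_bias,
      noise_sd = noise_sd_for_window_sd(rr_loa_half / 1.96),
      artifact_rate = ifelse(dyn, 0.5, ifelse(hyp, 0.1, 0.2)),
      artifact_magnitude_sd = ifelse(dyn, 5, ifelse(hyp, 3, 3)),
      dropout_prob = 0.02
    )
  )
}

#' Default reference-device error model
#'
#' The reference monitor is treated as a lightly noisy gold standard: no
#' bias, small white noise, no artifact bursts, rare dropout.
#' @return Tibble like [default_test_error_model()] (includes `SPO2`).
#' @export
default_ref_error_model <- function() {
  dplyr::bind_rows(lapply(c("HR", "RR", "SPO2"), function(v) {
    tibble::tibble(
      variable = v, stage_id = ALL_STAGES,
      bias = 0,
      noise_sd = if (v == "SPO2") 0.2 else 0.3,
      artifact_rate = 0, artifact_magnitude_sd = 0,
      dropout_prob = 0.005
    )
  }))
}

#' Error-free device model
#'
#' All biases, noise SDs, artifact rates and dropout probabilities zero,
#' for every variable and stage. Under this model an observed recording
#' equals the truth sampled on the device grid exactly.
#' @return Tibble like [default_test_error_model()].
#' @export
zero_error_model <- function() {
  dplyr::bind_rows(lapply(c("HR", "RR", "SPO2"), function(v) {
    tibble::tibble(
      variable = v, stage_id = ALL_STAGES,
      bias = 0, noise_sd = 0, artifact_rate = 0, artifact_magnitude_sd = 0,
      dropout_prob = 0
    )
  }))
}

validate_error_model <- function(m, what) {
  need <- c("variable", "stage_id", "bias", "noise_sd", "artifact_rate",
            "artifact_magnitude_sd", "dropout_prob")
  if (!all(need %in% names(m))) {
    abort_config(sprintf("%s error model lacks columns: %s", what,
                         paste(setdiff(need, names(m)), collapse = ", ")))
  }
  if (any(m$noise_sd < 0) || any(m$artifact_magnitude_sd < 0) ||
      any(m$artifact_rate < 0)) {
    abort_config(sprintf("%s error model: SDs and rates must be >= 0", what))
  }
  if (any(m$dropout_prob < 0 | m$dropout_prob > 1)) {
    abort_config(sprintf("%s error model: dropout_prob must be in [0, 1]", what))
  }
  m
}

#' Specify one synthetic session
#'
#' Encodes the simulated protocol: the seven consecutive movement
#' activities, then a stepwise desaturation through plateau targets
#' 95/90/87/85/83/80% (180-s plateaus joined by 60-s linear transitions),
#' with a participant baseline profile, per-stage physiological effects and
#' per-device error models. Everything downstream is deterministic given
#' `seed`.
#'
#' @param participant_id Participant label.
#' @param seed Integer seed driving truth wander, SpO2 jitter and all
#'   device-error draws for this session.
#' @param movement_schedule Tibble `stage_id`, `duration_s` for the seven
#'   movement stages, in protocol order.
#' @param hypoxia_targets Plateau SpO2 targets, percent, strictly
#'   decreasing; `NULL` to simulate a movement-only session.
#' @param plateau_s,transition_s Plateau hold and inter-plateau transition
#'   durations, seconds.
#' @param profile A [participant_profile()].
#' @param effects Stage-effect table, see [default_stage_effects()].
#' @param test_error,ref_error Device error models.
#' @param spo2_jitter_sd SD of plateau-level SpO2 jitter, percent.
#' @param hr_per_spo2 Linear HR rise per percent SpO2 below 90 (bpm/%),
#'   the hypoxic heart-rate response.
#' @return A `session_spec` list.
#' @export
session_spec <- function(participant_id = "sim-001", seed = 1,
                         movement_schedule = default_movement_schedule(),
                         hypoxia_targets = c(95, 90, 87, 85, 83, 80),
                         plateau_s = 180, transition_s = 60,
                         profile = participant_profile(),
                         effects = default_stage_effects(),
                         test_error = default_test_error_model(),
                         ref_error = default_ref_error_model(),
                         spo2_jitter_sd = 0.5, hr_per_spo2 = 0.4) {
  if (!identical(movement_schedule$stage_id, MOVEMENT_STAGES)) {
    abort_config("movement_schedule must list the seven movement stages in order")
  }
  if (any(movement_schedule$duration_s <= 40)) {
    abort_config("every stage duration must exceed the 40-s window length")
  }
  if (!is.null(hypoxia_targets)) {
    if (any(diff(hypoxia_targets) >= 0)) {
      abort_config("hypoxia_targets must be strictly decreasing")
    }
    if (plateau_s + transition_s <= 40) {
      abort_config("hypoxia plateaus must exceed the 40-s window length")
    }
  }
  validate_error_model(test_error, "test")
  validate_error_model(ref_error, "reference")
  structure(list(
    participant_id = participant_id, seed = as.integer(seed),
    movement_schedule = movement_schedule,
    hypoxia_targets = hypoxia_targets,
    plateau_s = plateau_s, transition_s = transition_s,
    profile = profile, effects = effects,
    test_error = test_error, ref_error = ref_error,
    spo2_jitter_sd = spo2_jitter_sd, hr_per_spo2 = hr_per_spo2
  ), class = "session_spec")
}

#' Default movement-phase schedule
#'
#' Seven consecutive activities: at rest (180 s), 20x sit-to-stand (120 s),
#' 2-minute tapping, 2-minute rubbing, drinking from a cup (90 s), turning
#' pages (120 s) and tablet use (180 s).
#' @return Tibble `stage_id`, `duration_s`.
#' @export
default_movement_schedule <- function() {
  tibble::tibble(
    stage_id = MOVEMENT_STAGES,
    duration_s = c(180, 120, 120, 120, 90, 120, 180)
  )
}

#' Generate dense ground truth for a session
#'
#' Builds 1-Hz HR, RR and SpO2 trajectories plus matching stage
#' annotations. HR and RR are baseline + stage shift + a bounded random
#' walk (clipped to 40-150 bpm and 4-31 rpm). SpO2 is 98% throughout
#' movement, then descends piecewise linearly to each plateau target with
#' small plateau jitter; HR rises linearly below 90% SpO2 (the hypoxic
#' response). Deterministic given `spec$seed`.
#'
#' @param spec A [session_spec()].
#' @return List with `truth` (tibble `t_s`, `HR`, `RR`, `SPO2`) and
#'   `annotations` ([stage_annotations()]).
#' @export
generate_truth <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  mv <- spec$movement_schedule
  mv_end <- cumsum(mv$duration_s)
  mv_start <- mv_end - mv$duration_s
  total_mv <- mv_end[length(mv_end)]

  has_hyp <- !is.null(spec$hypoxia_targets)
  n_plat <- if (has_hyp) length(spec$hypoxia_targets) else 0
  total_hyp <- n_plat * (spec$plateau_s + spec$transition_s)
  total <- total_mv + total_hyp

  ann <- if (has_hyp) {
    stage_annotations(
      c(mv$stage_id, "hypoxia"),
      c(rep("movement", nrow(mv)), "hypoxia"),
      c(mv_start, total_mv),
      c(mv_end, total)
    )
  } else {
    stage_annotations(mv$stage_id, rep("movement", nrow(mv)), mv_start, mv_end)
  }

  t_s <- 0:total
  stage_idx <- findInterval(t_s, ann$start_s)
  stage_at_t <- ann$stage_id[stage_idx]

  with_seed(spec$seed, {
    # SpO2 trajectory
    spo2 <- rep(98, length(t_s))
    if (has_hyp) {
      level_prev <- 98
      cursor <- total_mv
      for (k in seq_len(n_plat)) {
        target <- spec$hypoxia_targets[k]
        tr <- t_s >= cursor & t_s < cursor + spec$transition_s
        spo2[tr] <- level_prev + (t_s[tr] - cursor) / spec$transition_s *
          (target - level_prev)
        pl <- t_s >= cursor + spec$transition_s &
          t_s < cursor + spec$transition_s + spec$plateau_s
        spo2[pl] <- target + stats::rnorm(sum(pl), 0, spec$spo2_jitter_sd)
        cursor <- cursor + spec$transition_s + spec$plateau_s
        level_prev <- target
      }
      spo2[length(spo2)] <- level_prev
      spo2 <- pmin(100, pmax(50, spo2))
    }

    # Per-stage bounded random-walk wander
    wander <- function(col) {
      w <- numeric(length(t_s))
      for (i in seq_len(nrow(ann))) {
        idx <- which(stage_idx == i)
        sd_stage <- spec$effects[[col]][match(ann$stage_id[i], spec$effects$stage_id)]
        if (length(idx) && sd_stage > 0) {
          steps <- stats::rnorm(length(idx), 0, sd_stage / sqrt(length(idx)))
          w[idx] <- cumsum(steps) - steps[1]
        }
      }
      w
    }
    w_hr <- wander("wander_sd_hr")
    w_rr <- wander("wander_sd_rr")

    eff_row <- match(stage_at_t, spec$effects$stage_id)
    hr <- spec$profile$hr_baseline + spec$effects$hr_shift[eff_row] + w_hr +
      spec$hr_per_spo2 * pmax(0, 90 - spo2)
    rr <- spec$profile$rr_baseline + spec$effects$rr_shift[eff_row] + w_rr
    hr <- pmin(HR_BOUNDS[2], pmax(HR_BOUNDS[1], hr))
    rr <- pmin(RR_BOUNDS[2], pmax(RR_BOUNDS[1], rr))

    list(truth = tibble::tibble(t_s = as.numeric(t_s), HR = hr, RR = rr,
                                SPO2 = spo2),
         annotations = ann)
  })
}

#' Observe a truth trajectory through a device error model
#'
#' Samples the dense truth on the device's nominal grid, then applies the
#' stage-specific error model: additive bias, white Gaussian noise,
#' Poisson-timed artifact bursts (each lasting 5-15 s and adding zero-mean
#' Gaussian disturbance), and independent per-sample dropout. Deterministic
#' given `seed`.
#'
#' @param truth Truth tibble from [generate_truth()].
#' @param annotations Matching [stage_annotations()].
#' @param variable `"HR"`, `"RR"` or `"SPO2"`.
#' @param error_model Error-model tibble (rows for this variable).
#' @param nominal_interval_s Device sampling interval, seconds.
#' @param device_id Device label for the resulting recording.
#' @param seed Integer seed for this channel's error draws.
#' @return A [recording()].
#' @export
observe <- function(truth, annotations, variable, error_model,
                    nominal_interval_s, device_id, seed) {
  variable <- match.arg(variable, VARIABLES)
  em <- error_model[error_model$variable == variable, , drop = FALSE]
  if (nrow(em) == 0) {
    abort_config(sprintf("error model has no rows for variable %s", variable))
  }
  grid <- seq(0, max(truth$t_s), by = nominal_interval_s)
  vals <- stats::approx(truth$t_s, truth[[variable]], xout = grid)$y
  stage_idx <- findInterval(grid, annotations$start_s)
  stage_at_t <- annotations$stage_id[stage_idx]
  em_row <- match(stage_at_t, em$stage_id)
  if (any(is.na(em_row))) {
    abort_config("error model lacks rows for some annotated stages")
  }
  with_seed(seed, {
    vals <- vals + em$bias[em_row] +
      stats::rnorm(length(vals), 0, em$noise_sd[em_row])
    # artifact bursts, per stage
    for (i in seq_len(nrow(annotations))) {
      j <- match(annotations$stage_id[i], em$stage_id)
      rate <- em$artifact_rate[j]
      if (is.na(rate) || rate <= 0) next
      dur <- annotations$end_s[i] - annotations$start_s[i]
      n_burst <- stats::rpois(1, rate * dur / 60)
      if (n_burst == 0) next
      b_start <- stats::runif(n_burst, annotations$start_s[i], annotations$end_s[i])
      b_dur <- stats::runif(n_burst, 5, 15)
      for (b in seq_len(n_burst)) {
        hit <- grid >= b_start[b] & grid < b_start[b] + b_dur[b]
        vals[hit] <- vals[hit] +
          stats::rnorm(sum(hit), 0, em$artifact_magnitude_sd[j])
      }
    }
    keep <- stats::runif(length(grid)) >= em$dropout_prob[em_row]
    recording(grid[keep], vals[keep], device_id, variable,
              nominal_interval_s = nominal_interval_s)
  })
}

#' Simulate one complete session
#'
#' Generates ground truth, observes it through the test patch (HR/RR at
#' 4 s) and the reference monitor (HR/RR/SpO2 at 1 Hz), and assembles a
#' validated session. Channel seeds are derived deterministically from
#' `spec$seed`.
#'
#' @param spec A [session_spec()].
#' @return List with `session` (a `vital_session`) and `truth` (the dense
#'   ground truth and annotations).
#' @export
simulate_session <- function(spec) {
  gt <- generate_truth(spec)
  pid <- spec$participant_id
  recs <- list(
    test_HR = observe(gt$truth, gt$annotations, "HR", spec$test_error, 4,
                      paste0("patch-", pid), mix_seed(spec$seed, 1)),
    test_RR = observe(gt$truth, gt$annotations, "RR", spec$test_error, 4,
                      paste0("patch-", pid), mix_seed(spec$seed, 2)),
    ref_HR = observe(gt$truth, gt$annotations, "HR", spec$ref_error, 1,
                     paste0("monitor-", pid), mix_seed(spec$seed, 3)),
    ref_RR = observe(gt$truth, gt$annotations, "RR", spec$ref_error, 1,
                     paste0("monitor-", pid), mix_seed(spec$seed, 4))
  )
  if (!is.null(spec$hypoxia_targets)) {
    recs$ref_SPO2 <- observe(gt$truth, gt$annotations, "SPO2", spec$ref_error, 1,
                             paste0("monitor-", pid), mix_seed(spec$seed, 5))
  }
  list(session = assemble_session(pid, recs, gt$annotations), truth = gt)
}

#' Generate a synthetic cohort with a ground-truth ledger
#'
#' Draws per-participant baseline profiles from the population
#' distributions, derives an independent child seed per participant from
#' `master_seed`, simulates each session, and records every injected
#' parameter — biases, noise SDs, artifact and dropout settings, wander
#' SDs, baselines, and the analytic window-level difference SD from
#' [expected_window_sd()] — in a truth ledger so parameter-recovery tests
#' have exact targets.
#'
#' @param n_participants Number of participants (default 29, the scale of
#'   a typical validation cohort).
#' @param base_spec Template [session_spec()]; participant id, seed and
#'   profile are overridden per participant.
#' @param master_seed Integer master seed.
#' @return A `vital_cohort` list: `sessions` (list of `vital_session`),
#'   `ledger` (tibble), `master_seed`.
#' @export
generate_cohort <- function(n_participants = 29,
                            base_spec = session_spec(),
                            master_seed = 1) {
  stopifnot(n_participants >= 1)
  profiles <- with_seed(mix_seed(master_seed, 0), {
    hr <- rtruncnorm1(n_participants, 72.9, 11.9, HR_BOUNDS[1], HR_BOUNDS[2])
    rr <- rtruncnorm1(n_participants, 16.3, 3.6, RR_BOUNDS[1], RR_BOUNDS[2])
    list(hr = hr, rr = rr)
  })
  sessions <- vector("list", n_participants)
  ledgers <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    pid <- sprintf("sim-%03d", i)
    spec_i <- base_spec
    spec_i$participant_id <- pid
    spec_i$seed <- mix_seed(master_seed, i)
    spec_i$profile <- participant_profile(profiles$hr[i], profiles$rr[i])
    sim <- simulate_session(spec_i)
    sessions[[i]] <- sim$session

    te <- spec_i$test_error[spec_i$test_error$variable %in% c("HR", "RR"), ]
    re <- spec_i$ref_error
    ref_sd <- re$noise_sd[match(paste(te$variable, te$stage_id),
                                paste(re$variable, re$stage_id))]
    eff <- spec_i$effects
    eff_row <- match(te$stage_id, eff$stage_id)
    ledgers[[i]] <- tibble::tibble(
      participant_id = pid,
      seed = spec_i$seed,
      hr_baseline = profiles$hr[i],
      rr_baseline = profiles$rr[i],
      variable = te$variable,
      stage_id = te$stage_id,
      stage_shift = ifelse(te$variable == "HR", eff$hr_shift[eff_row],
                           eff$rr_shift[eff_row]),
      wander_sd = ifelse(te$variable == "HR", eff$wander_sd_hr[eff_row],
                         eff$wander_sd_rr[eff_row]),
      bias = te$bias,
      noise_sd = te$noise_sd,
      artifact_rate = te$artifact_rate,
      artifact_magnitude_sd = te$artifact_magnitude_sd,
      dropout_prob = te$dropout_prob,
      ref_noise_sd = ref_sd,
      ref_dropout_prob = re$dropout_prob[match(paste(te$variable, te$stage_id),
                                               paste(re$variable, re$stage_id))],
      expected_window_sd = expected_window_sd(te$noise_sd, ref_sd)
    )
  }
  structure(list(sessions = sessions,
                 ledger = dplyr::bind_rows(ledgers),
                 master_seed = as.integer(master_seed)),
            class = "vital_cohort")
}

#' @export
print.vital_cohort <- function(x, ...) {
  cat(sprintf("<vital_cohort> %d session(s), master seed %d\n",
              length(x$sessions), x$master_seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One directory per participant (channel CSVs, annotation CSV, YAML
#' manifest) plus `truth_ledger.csv` with every injected parameter.
#'
#' @param cohort A `vital_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$sessions) {
    write_session(s, file.path(dir, s$participant_id))
  }
  readr::write_csv(cohort$ledger, file.path(dir, "truth_ledger.csv"))
  invisible(dir)
}
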