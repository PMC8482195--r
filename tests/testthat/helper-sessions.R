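# Builders for tiny in-code fixtures, plus a cached default cohort shared
# by the heavier end-to-end tests.

.cache <- new.env(parent = emptyenv())

# Default 29-participant cohort under the study-protocol defaults.
default_cohort <- function() {
  if (is.null(.cache$cohort)) {
    .cache$cohort <- generate_cohort(29, session_spec(), master_seed = 101)
  }
  .cache$cohort
}

# Pipeline bundle over the default cohort (modest replicate count keeps the
# suite quick; CI width is not under test here).
default_bundle <- function() {
  if (is.null(.cache$bundle)) {
    .cache$bundle <- suppressMessages(run_pipeline(
      default_cohort()$sessions,
      boot = bootstrap_config(n_replicates = 500, seed = 11)
    ))
  }
  .cache$bundle
}

const_recording <- function(value, t, variable = "HR", interval = 1,
                            device = "dev") {
  recording(t, rep(value, length(t)), device, variable,
            nominal_interval_s = interval)
}

# A minimal movement-only session: constant signals on both devices.
constant_session <- function(value_hr = 70, value_rr = 15, duration = 120) {
  t_ref <- 0:duration
  t_test <- seq(0, duration, by = 4)
  ann <- stage_annotations("at_rest", "movement", 0, duration)
  assemble_session(
    "p1",
    list(
      test_HR = const_recording(value_hr, t_test, "HR", 4, "patch"),
      test_RR = const_recording(value_rr, t_test, "RR", 4, "patch"),
      ref_HR = const_recording(value_hr, t_ref, "HR", 1, "monitor"),
      ref_RR = const_recording(value_rr, t_ref, "RR", 1, "monitor")
    ),
    ann
  )
}

# Error-free, drift-free session spec: piecewise-constant truth, exact
# device observation. The pipeline must recover identically zero error.
zero_error_spec <- function(participant_id = "sim-001", seed = 1) {
  session_spec(
    participant_id = participant_id, seed = seed,
    effects = constant_stage_effects(),
    test_error = zero_error_model(),
    ref_error = zero_error_model(),
    hr_per_spo2 = 0
  )
}

write_csv_lines <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
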