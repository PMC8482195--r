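# Internal helpers: vocabulary, error signalling, seeded evaluation.

# Fixed stage vocabulary: seven movement activities plus the hypoxia phase.
MOVEMENT_STAGES <- c(
  "at_rest", "sts", "tapping", "rubbing", "drinking", "turning_pages", "tablet"
)
ALL_STAGES <- c(MOVEMENT_STAGES, "hypoxia")

VARIABLES <- c("HR", "RR", "SPO2")
UNITS <- c(HR = "bpm", RR = "rpm", SPO2 = "percent")

CHANNEL_ROLES <- c("test_HR", "test_RR", "ref_HR", "ref_RR", "ref_SPO2")
REQUIRED_CHANNELS <- c("test_HR", "test_RR", "ref_HR", "ref_RR")

#' Unit associated with a vital-sign variable
#'
#' @param variable One of `"HR"`, `"RR"`, `"SPO2"`.
#' @return `"bpm"`, `"rpm"` or `"percent"`.
#' @export
unit_for <- function(variable) {
  variable <- match.arg(variable, VARIABLES)
  unname(UNITS[[variable]])
}

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "vitalval_validation_error", ...)
}

abort_format <- function(msg, ...) {
  rlang::abort(msg, class = "vitalval_format_error", ...)
}

abort_completeness <- function(msg, ...) {
  rlang::abort(msg, class = "vitalval_completeness_error", ...)
}

abort_config <- function(msg, ...) {
  rlang::abort(msg, class = "vitalval_config_error", ...)
}

abort_insufficient <- function(msg, ...) {
  rlang::abort(msg, class = "vitalval_insufficient_data_error", ...)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Deterministic child-seed derivation (MINSTD-style congruential mixing).
# Keeps every intermediate below 2^53 so double arithmetic stays exact,
# and the result below 2^31 so it is a valid R integer seed.
mix_seed <- function(master_seed, index) {
  m <- 2147483647
  a <- master_seed %% m
  a <- (a * 48271) %% m
  a <- (a + index * 10007 + 1) %% m
  a <- (a * 48271) %% m
  as.integer(a)
}

# Variance of the median of k iid standard normals, as a fraction of the
# per-sample variance. Values for k = 10 and k = 40 were obtained by
# numerical integration of the joint density of the two central order
# statistics (relative tolerance 1e-10); other k fall back to the
# asymptotic pi / (2k).
median_var_factor <- function(k) {
  exact <- c(`10` = 0.1383266167, `40` = 0.03793415824)
  key <- as.character(k)
  if (key %in% names(exact)) unname(exact[[key]]) else pi / (2 * k)
}

# Display-style p-value, matching clinical reporting conventions.
format_p <- function(p) {
  ifelse(is.na(p), "NA", ifelse(p < 0.001, "<.001", sprintf("%.3f", p)))
}
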