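#' Windowing configuration
#'
#' Agreement is assessed on simultaneous medians over consecutive
#' non-overlapping windows, 40 s by default: the patch reports an estimate
#' every 4 s (10 points per median) and the reference at 1 Hz (40 points),
#' so each paired window compares a 10-point with a 40-point centered
#' median. Windows must lie wholly inside their stage interval, which for
#' `trim_s = window_s / 2` is the same as trimming window centers by 20 s
#' at each end of the stage.
#'
#' @param window_s Window length in seconds (> 0).
#' @param trim_s Center trim at each stage boundary, seconds; informational
#'   given the whole-window containment rule, kept explicit for reporting.
#' @param min_fraction Fraction in (0, 1] of a device's expected in-window
#'   sample count below which the window is excluded for that device. The
#'   default 0.5 keeps a window when at least 5 of 10 patch samples and 20
#'   of 40 reference samples are present; lower it towards 0 to keep any
#'   window with at least one sample on each device.
#' @return A `windowing_config` list.
#' @export
windowing_config <- function(window_s = 40, trim_s = window_s / 2,
                             min_fraction = 0.5) {
  if (!is.numeric(window_s) || window_s <= 0) {
    abort_config("`window_s` must be positive")
  }
  if (!is.numeric(trim_s) || trim_s < 0) {
    abort_config("`trim_s` must be nonnegative")
  }
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    abort_config("`min_fraction` must be in (0, 1]")
  }
  structure(list(window_s = as.numeric(window_s), trim_s = as.numeric(trim_s),
                 min_fraction = as.numeric(min_fraction)),
            class = "windowing_config")
}

#' Window grid for one stage interval
#'
#' Consecutive, non-overlapping windows of length `window_s`, the first
#' starting at the stage start; any window that would extend past the stage
#' end is discarded, so a stage of duration D yields `floor(D / window_s)`
#' windows and no window crosses a stage boundary.
#'
#' @param annotation A single stage interval: either a one-row
#'   [stage_annotations()] table or any list with `start_s` and `end_s`.
#' @param config A [windowing_config()].
#' @return Tibble with `window_start_s`, `window_end_s`, `center_s`; zero
#'   rows (with a message) when the stage is shorter than one window.
#' @examples
#' window_grid(list(start_s = 0, end_s = 130), windowing_config())
#' @export
window_grid <- function(annotation, config = windowing_config()) {
  start_s <- as.numeric(annotation$start_s)
  end_s <- as.numeric(annotation$end_s)
  stopifnot(length(start_s) == 1, length(end_s) == 1, end_s > start_s)
  w <- config$window_s
  n <- floor((end_s - start_s) / w)
  if (n < 1) {
    message(sprintf("window_grid: interval [%g, %g) shorter than %g s, skipped",
                    start_s, end_s, w))
    return(tibble::tibble(window_start_s = numeric(0),
                          window_end_s = numeric(0),
                          center_s = numeric(0)))
  }
  ws <- start_s + w * (seq_len(n) - 1)
  tibble::tibble(window_start_s = ws, window_end_s = ws + w,
                 center_s = ws + w / 2)
}

#' Median of a recording over a half-open window
#'
#' Takes the median of all samples with `t_s` in `[start_s, end_s)`. An
#' even sample count uses the midpoint of the two central order statistics;
#' an empty window yields an absent median (`NA`) with `n = 0`, not an
#' error.
#'
#' @param recording A [recording()].
#' @param start_s,end_s Window bounds in seconds (half-open).
#' @return List with `median` (value or `NA`) and `n` (sample count).
#' @export
median_in_window <- function(recording, start_s, end_s) {
  keep <- recording$t_s >= start_s & recording$t_s < end_s
  n <- sum(keep)
  list(median = if (n == 0) NA_real_ else stats::median(recording$value[keep]),
       n = as.integer(n))
}

#' Extract simultaneous paired median windows for a session
#'
#' For every window of every requested stage, computes the test-device and
#' reference-device medians over the same interval (plus the reference SpO2
#' median when that channel exists). A window is excluded when either rate
#' device has fewer than `min_fraction` times its expected in-window sample
#' count (expected = `window_s / nominal_interval_s`); no imputation is ever
#' performed. Exclusions are counted per stage and reported via
#' [exclusion_log()].
#'
#' @param session A `vital_session`.
#' @param variable `"HR"` or `"RR"`.
#' @param config A [windowing_config()].
#' @param stages Optional character vector restricting which stages to
#'   window; default all annotated stages.
#' @return A `paired_windows` tibble: `participant_id`, `variable`,
#'   `stage_id`, `phase`, `center_s`, `median_test`, `median_ref`,
#'   `n_test`, `n_ref`, `median_spo2`, `difference`
#'   (= `median_test - median_ref`), with the per-stage exclusion log as an
#'   attribute.
#' @export
extract_paired_windows <- function(session, variable, config = windowing_config(),
                                   stages = NULL) {
  stopifnot(inherits(session, "vital_session"))
  variable <- match.arg(variable, c("HR", "RR"))
  test_role <- paste0("test_", variable)
  ref_role <- paste0("ref_", variable)
  for (role in c(test_role, ref_role)) {
    if (!role %in% names(session$recordings)) {
      abort_completeness(sprintf("session %s lacks channel '%s'",
                                 session$participant_id, role))
    }
  }
  rec_test <- session$recordings[[test_role]]
  rec_ref <- session$recordings[[ref_role]]
  rec_spo2 <- session$recordings[["ref_SPO2"]]

  ann <- session$annotations
  if (!is.null(stages)) ann <- ann[ann$stage_id %in% stages, , drop = FALSE]

  exp_test <- config$window_s / attr(rec_test, "nominal_interval_s")
  exp_ref <- config$window_s / attr(rec_ref, "nominal_interval_s")
  need_test <- config$min_fraction * exp_test
  need_ref <- config$min_fraction * exp_ref

  rows <- vector("list", nrow(ann))
  excl <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    grid <- window_grid(ann[i, ], config)
    k <- nrow(grid)
    if (k == 0) {
      excl[[i]] <- tibble::tibble(stage_id = ann$stage_id[i], n_candidate = 0L,
                                  n_excluded = 0L, n_kept = 0L)
      next
    }
    med_t <- numeric(k); med_r <- numeric(k); med_s <- rep(NA_real_, k)
    n_t <- integer(k); n_r <- integer(k)
    for (j in seq_len(k)) {
      mt <- median_in_window(rec_test, grid$window_start_s[j], grid$window_end_s[j])
      mr <- median_in_window(rec_ref, grid$window_start_s[j], grid$window_end_s[j])
      med_t[j] <- mt$median; n_t[j] <- mt$n
      med_r[j] <- mr$median; n_r[j] <- mr$n
      if (!is.null(rec_spo2)) {
        ms <- median_in_window(rec_spo2, grid$window_start_s[j], grid$window_end_s[j])
        med_s[j] <- ms$median
      }
    }
    keep <- n_t >= need_test & n_r >= need_ref
    excl[[i]] <- tibble::tibble(stage_id = ann$stage_id[i],
                                n_candidate = k,
                                n_excluded = as.integer(sum(!keep)),
                                n_kept = as.integer(sum(keep)))
    rows[[i]] <- tibble::tibble(
      participant_id = session$participant_id,
      variable = variable,
      stage_id = ann$stage_id[i],
      phase = ann$phase[i],
      center_s = grid$center_s[keep],
      median_test = med_t[keep],
      median_ref = med_r[keep],
      n_test = n_t[keep],
      n_ref = n_r[keep],
      median_spo2 = med_s[keep],
      difference = med_t[keep] - med_r[keep]
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      participant_id = character(0), variable = character(0),
      stage_id = character(0), phase = character(0), center_s = numeric(0),
      median_test = numeric(0), median_ref = numeric(0),
      n_test = integer(0), n_ref = integer(0), median_spo2 = numeric(0),
      difference = numeric(0)
    )
  }
  log <- dplyr::bind_rows(excl)
  total_excluded <- sum(log$n_excluded)
  if (total_excluded > 0) {
    message(sprintf("extract_paired_windows: %s %s: excluded %d of %d window(s)",
                    session$participant_id, variable, total_excluded,
                    sum(log$n_candidate)))
  }
  attr(out, "exclusions") <- log
  class(out) <- c("paired_windows", class(out))
  out
}

#' Per-stage window exclusion log
#'
#' @param x A `paired_windows` table from [extract_paired_windows()].
#' @return Tibble with `stage_id`, `n_candidate`, `n_excluded`, `n_kept`.
#' @export
exclusion_log <- function(x) {
  attr(x, "exclusions")
}

#' Write a paired-window table to CSV
#'
#' @param x A `paired_windows` tibble (possibly row-bound across sessions).
#' @param path Output path. Absent SpO2 medians are written as empty fields.
#' @export
write_paired_windows <- function(x, path) {
  readr::write_csv(as.data.frame(x), path, na = "")
  invisible(path)
}
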