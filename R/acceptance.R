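# Clinical-acceptance evaluation and SpO2 subgroup stratification.

#' Clinical acceptance thresholds
#'
#' ANSI/AAMI-style accuracy limits for ambulatory rate monitors: the mean
#' absolute error must be within 5 beats per minute for HR and 3
#' respirations per minute for RR.
#'
#' @param hr_mae_max Maximum acceptable HR MAE, bpm (default 5).
#' @param rr_mae_max Maximum acceptable RR MAE, rpm (default 3).
#' @return An `acceptance_thresholds` list.
#' @export
acceptance_thresholds <- function(hr_mae_max = 5, rr_mae_max = 3) {
  if (!is.numeric(hr_mae_max) || hr_mae_max <= 0 ||
      !is.numeric(rr_mae_max) || rr_mae_max <= 0) {
    abort_config("thresholds must be strictly positive")
  }
  structure(list(hr_mae_max = hr_mae_max, rr_mae_max = rr_mae_max),
            class = "acceptance_thresholds")
}

#' SpO2 subgroup scheme
#'
#' Partitions the continuous SpO2 scale into normoxia (>= `normoxia_min`),
#' mild hypoxia (`severe_max` to < `normoxia_min`) and severe hypoxia
#' (< `severe_max`). Half-open intervals: a median of exactly 90 is
#' normoxia, exactly 85 is mild.
#'
#' @param normoxia_min Lower bound of normoxia, percent (default 90).
#' @param severe_max Upper bound (exclusive) of severe hypoxia, percent
#'   (default 85).
#' @return A `subgroup_scheme` list.
#' @export
subgroup_scheme <- function(normoxia_min = 90, severe_max = 85) {
  if (!(normoxia_min > severe_max) || severe_max <= 0 || normoxia_min > 100) {
    abort_config("cut points must be strictly decreasing within (0, 100]")
  }
  structure(list(normoxia_min = normoxia_min, severe_max = severe_max),
            class = "subgroup_scheme")
}

SUBGROUP_LEVELS <- c("normoxia", "mild", "severe")

#' Assign SpO2 medians to hypoxia subgroups
#'
#' @param spo2_median Numeric vector of windowed SpO2 medians in (0, 100];
#'   `NA` (absent SpO2) maps to `NA` and is excluded from subgroup analysis
#'   by callers.
#' @param scheme A [subgroup_scheme()].
#' @return Factor with levels `normoxia`, `mild`, `severe`.
#' @examples
#' assign_subgroup(c(92, 90, 87, 85, 84.9))
#' @export
assign_subgroup <- function(spo2_median, scheme = subgroup_scheme()) {
  x <- as.numeric(spo2_median)
  ok <- !is.na(x)
  if (any(x[ok] <= 0 | x[ok] > 100)) {
    abort_validation("SpO2 medians must lie in (0, 100]")
  }
  out <- rep(NA_character_, length(x))
  out[ok & x >= scheme$normoxia_min] <- "normoxia"
  out[ok & x < scheme$normoxia_min & x >= scheme$severe_max] <- "mild"
  out[ok & x < scheme$severe_max] <- "severe"
  factor(out, levels = SUBGROUP_LEVELS)
}

#' Assign hypoxia windows to protocol SpO2 target levels
#'
#' For per-level accuracy curves, windows are binned at the desaturation
#' protocol's plateau targets by nearest-target assignment within a
#' configurable half-width; windows between plateaus (transitions) stay
#' unassigned.
#'
#' @param spo2_median Numeric vector of windowed SpO2 medians.
#' @param targets Protocol plateau targets, percent.
#' @param half_width Maximum distance to the nearest target, percent.
#' @return Numeric vector of assigned targets (`NA` where unassigned).
#' @export
assign_spo2_level <- function(spo2_median, targets = c(95, 90, 87, 85, 83, 80),
                              half_width = 1.25) {
  vapply(as.numeric(spo2_median), function(v) {
    if (is.na(v)) return(NA_real_)
    dist <- abs(targets - v)
    i <- which.min(dist)
    if (dist[i] <= half_width) targets[i] else NA_real_
  }, numeric(1))
}

#' Evaluate clinical acceptance of agreement results
#'
#' A stratum is acceptable when its MAE is at or below the variable's
#' threshold (inclusive, per "within 5 bpm / 3 rpm"); whether the entire
#' bootstrap CI clears the threshold is reported alongside.
#'
#' @param results An `agreement_result` tibble (one row per stratum).
#' @param thresholds [acceptance_thresholds()].
#' @return Tibble of verdicts: `variable`, `stratum`, `mae`, `threshold`,
#'   `acceptable`, `ci_within`.
#' @export
evaluate_acceptance <- function(results, thresholds = acceptance_thresholds()) {
  if (any(is.na(results$mae))) abort_validation("results lack MAE values")
  thr <- ifelse(results$variable == "HR", thresholds$hr_mae_max,
                thresholds$rr_mae_max)
  tibble::tibble(
    variable = results$variable,
    stratum = results$stratum,
    mae = results$mae,
    threshold = thr,
    acceptable = results$mae <= thr,
    ci_within = !is.na(results$mae_ci_high) & results$mae_ci_high <= thr
  )
}

# Bootstrap CI for the difference of a statistic between two independent
# groups of differences (each group resampled independently).
boot_diff_ci <- function(d_a, d_b, statistic, config) {
  reps <- with_seed(config$seed, {
    ra <- boot_replicates_window(d_a, statistic, config$n_replicates)
    rb <- boot_replicates_window(d_b, statistic, config$n_replicates)
    ra - rb
  })
  percentile_interval(reps, config$ci_level)
}

#' Compare error metrics between SpO2 subgroups
#'
#' For every pair of subgroups and each of MAE and RMSE, computes a
#' percentile-bootstrap confidence interval of the between-group difference
#' by resampling each subgroup's windows independently with the configured
#' replicate count. A difference is flagged significant when its CI
#' excludes zero. Pairs involving a subgroup with fewer than 2 windows are
#' skipped with a message.
#'
#' @param windows A `paired_windows` table of hypoxia-phase windows (one
#'   variable) carrying `median_spo2`.
#' @param boot A [bootstrap_config()].
#' @param scheme A [subgroup_scheme()].
#' @return Tibble: `variable`, `stat`, `subgroup_a`, `subgroup_b`, `n_a`,
#'   `n_b`, `diff`, `ci_lo`, `ci_hi`, `significant`.
#' @export
compare_subgroups <- function(windows, boot = bootstrap_config(seed = 1),
                              scheme = subgroup_scheme()) {
  variable <- unique(windows$variable)
  if (length(variable) != 1) {
    abort_validation("windows must contain exactly one variable")
  }
  grp <- assign_subgroup(windows$median_spo2, scheme)
  n_unassigned <- sum(is.na(grp))
  if (n_unassigned > 0) {
    message(sprintf("compare_subgroups: %d window(s) without SpO2 median excluded",
                    n_unassigned))
  }
  groups <- split(windows$difference, grp)
  present <- names(groups)[vapply(groups, length, integer(1)) > 0]
  if (length(present) < 2) {
    abort_insufficient("need at least two non-empty subgroups to compare")
  }
  pairs <- utils::combn(present, 2, simplify = FALSE)
  rows <- list()
  for (pr in pairs) {
    d_a <- groups[[pr[1]]]
    d_b <- groups[[pr[2]]]
    if (length(d_a) < 2 || length(d_b) < 2) {
      message(sprintf("compare_subgroups: pair %s-%s skipped (subgroup with n < 2)",
                      pr[1], pr[2]))
      next
    }
    for (st in c("mae", "rmse")) {
      stat_fn <- switch(st, mae = stat_mae, rmse = stat_rmse)
      ci <- boot_diff_ci(d_a, d_b, st, boot)
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = variable, stat = st,
        subgroup_a = pr[1], subgroup_b = pr[2],
        n_a = length(d_a), n_b = length(d_b),
        diff = stat_fn(d_a) - stat_fn(d_b),
        ci_lo = unname(ci["low"]), ci_hi = unname(ci["high"]),
        significant = ci["low"] > 0 | ci["high"] < 0
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Export acceptance verdicts to CSV
#' @param verdicts Output of [evaluate_acceptance()].
#' @param path Output path.
#' @export
write_verdicts <- function(verdicts, path) {
  readr::write_csv(verdicts, path, na = "")
  invisible(path)
}

#' Export subgroup comparisons to CSV
#' @param comparisons Output of [compare_subgroups()].
#' @param path Output path.
#' @export
write_subgroup_comparisons <- function(comparisons, path) {
  readr::write_csv(comparisons, path, na = "")
  invisible(path)
}
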