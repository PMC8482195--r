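# Agreement metrics: MAE / RMSE with percentile-bootstrap CIs,
# Bland-Altman bias and limits of agreement, Pearson correlation.

stat_mae <- function(d) mean(abs(d))
stat_rmse <- function(d) sqrt(mean(d^2))

# Type-7 (linear interpolation of order statistics) percentile interval.
percentile_interval <- function(x, level) {
  alpha <- (1 - level) / 2
  xs <- sort(x)
  n <- length(xs)
  q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  }
  c(low = q(alpha), high = q(1 - alpha))
}

#' Point agreement metrics for a set of paired differences
#'
#' Computes the error summary used throughout the pipeline: mean absolute
#' error `mae = mean(|d|)`, root mean square error `rmse = sqrt(mean(d^2))`,
#' Bland-Altman mean bias `bias = mean(d)`, the sample SD of differences
#' (n - 1 denominator), and the 95% limits of agreement
#' `bias +/- 1.96 * sd_diff`. With a single difference only `mae` and
#' `bias` are defined; SD-based fields are `NA`.
#'
#' @param differences Numeric vector of test-minus-reference differences.
#' @param ref_values,test_values Optional paired raw values, used only for
#'   the descriptive means/SDs.
#' @return Named list: `n`, `mae`, `rmse`, `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `mean_ref`, `sd_ref`, `mean_test`, `sd_test`.
#' @examples
#' point_metrics(c(1, -1, 3))
#' @export
point_metrics <- function(differences, ref_values = NULL, test_values = NULL) {
  d <- as.numeric(differences)
  n <- length(d)
  if (n < 1 || any(!is.finite(d))) {
    abort_insufficient("`differences` must contain at least one finite value")
  }
  out <- list(
    n = n,
    mae = stat_mae(d),
    rmse = if (n >= 2) stat_rmse(d) else NA_real_,
    bias = mean(d),
    sd_diff = NA_real_, loa_low = NA_real_, loa_high = NA_real_,
    mean_ref = if (is.null(ref_values)) NA_real_ else mean(ref_values),
    sd_ref = if (is.null(ref_values) || n < 2) NA_real_ else stats::sd(ref_values),
    mean_test = if (is.null(test_values)) NA_real_ else mean(test_values),
    sd_test = if (is.null(test_values) || n < 2) NA_real_ else stats::sd(test_values)
  )
  if (n >= 2) {
    out$sd_diff <- stats::sd(d)
    out$loa_low <- out$bias - 1.96 * out$sd_diff
    out$loa_high <- out$bias + 1.96 * out$sd_diff
  }
  out
}

#' Bootstrap configuration
#'
#' @param n_replicates Number of bootstrap resamples (default 10000).
#' @param ci_level Confidence level in (0, 1).
#' @param seed Integer seed; required, so every interval is reproducible.
#' @param unit Resampling unit: `"window"` resamples pooled windows i.i.d.
#'   (the default, matching pooled per-stratum data points); `"participant"`
#'   resamples whole participants (cluster bootstrap) to respect
#'   within-participant autocorrelation.
#' @param method `"resample"` for ordinary Monte Carlo resampling;
#'   `"exhaustive"` enumerates all `n^n` equally likely resamples (tiny n
#'   only) and is used as an exact reference mode.
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(n_replicates = 10000, ci_level = 0.95, seed = NULL,
                             unit = c("window", "participant"),
                             method = c("resample", "exhaustive")) {
  unit <- match.arg(unit)
  method <- match.arg(method)
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    abort_config("`n_replicates` must be a positive integer")
  }
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1) {
    abort_config("`ci_level` must be in (0, 1)")
  }
  if (method == "resample" && (is.null(seed) || !is.numeric(seed))) {
    abort_config("`seed` must be set for resampling bootstrap")
  }
  structure(list(n_replicates = as.integer(n_replicates),
                 ci_level = as.numeric(ci_level),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 unit = unit, method = method),
            class = "bootstrap_config")
}

# Replicate statistics for i.i.d. window resampling, chunked so the index
# matrix never exceeds ~2e7 cells.
boot_replicates_window <- function(d, statistic, R) {
  n <- length(d)
  stat_col <- switch(statistic,
    mae = function(m, nc) .colMeans(abs(m), n, nc),
    rmse = function(m, nc) sqrt(.colMeans(m^2, n, nc))
  )
  out <- numeric(R)
  chunk <- max(1L, min(R, as.integer(2e7 / n)))
  done <- 0L
  while (done < R) {
    r <- min(chunk, R - done)
    idx <- sample.int(n, n * r, replace = TRUE)
    m <- matrix(d[idx], nrow = n, ncol = r)
    out[done + seq_len(r)] <- stat_col(m, r)
    done <- done + r
  }
  out
}

boot_replicates_participant <- function(d, statistic, R, group_ids) {
  stat_fn <- switch(statistic, mae = stat_mae, rmse = stat_rmse)
  groups <- split(seq_along(d), group_ids)
  G <- length(groups)
  vapply(seq_len(R), function(r) {
    take <- sample.int(G, G, replace = TRUE)
    stat_fn(d[unlist(groups[take], use.names = FALSE)])
  }, numeric(1))
}

# All n^n equally likely resample statistics, enumerated exactly.
exhaustive_replicates <- function(d, statistic) {
  n <- length(d)
  total <- n^n
  if (total > 2e6) {
    abort_config(sprintf(
      "exhaustive enumeration of %d^%d resamples is infeasible", n, n))
  }
  stat_fn <- switch(statistic,
    mae = function(m) rowMeans(abs(m)),
    rmse = function(m) sqrt(rowMeans(m^2))
  )
  r <- seq_len(total) - 1
  idx <- vapply(seq_len(n) - 1, function(j) (r %/% n^j) %% n + 1, numeric(total))
  stat_fn(matrix(d[idx], nrow = total, ncol = n))
}

#' Percentile bootstrap confidence interval for MAE or RMSE
#'
#' Draws `n_replicates` resamples with replacement at the configured unit
#' (pooled windows, or whole participants for a cluster bootstrap),
#' recomputes the statistic on each, and returns the central
#' `ci_level` percentile interval. Identical seed and inputs always give
#' identical intervals. In `"exhaustive"` mode all `n^n` equally likely
#' resamples are enumerated instead of sampled, giving an exact reference
#' answer for very small n.
#'
#' @param differences Numeric vector of paired differences (n >= 2).
#' @param statistic `"mae"` or `"rmse"`.
#' @param config A [bootstrap_config()].
#' @param group_ids Participant labels parallel to `differences`; required
#'   when `config$unit == "participant"`.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(differences, statistic = c("mae", "rmse"),
                         config = bootstrap_config(seed = 1),
                         group_ids = NULL) {
  statistic <- match.arg(statistic)
  d <- as.numeric(differences)
  if (length(d) < 2) abort_insufficient("bootstrap requires n >= 2 differences")
  if (config$method == "exhaustive") {
    reps <- exhaustive_replicates(d, statistic)
    return(percentile_interval(reps, config$ci_level))
  }
  if (config$unit == "participant") {
    if (is.null(group_ids)) {
      abort_config("unit = 'participant' requires `group_ids`")
    }
    if (length(group_ids) != length(d)) {
      abort_config("`group_ids` must be parallel to `differences`")
    }
    reps <- with_seed(config$seed,
      boot_replicates_participant(d, statistic, config$n_replicates, group_ids))
  } else {
    reps <- with_seed(config$seed,
      boot_replicates_window(d, statistic, config$n_replicates))
  }
  percentile_interval(reps, config$ci_level)
}

#' Pearson correlation between reference and test values
#'
#' Sample Pearson r with the usual two-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom (as
#' computed by [stats::cor.test()]). Constant input is a hard error rather
#' than a silent `NA`.
#'
#' @param ref_values,test_values Paired numeric vectors, length >= 3.
#' @return List with `r` and `p_value`.
#' @export
pearson_cor <- function(ref_values, test_values) {
  x <- as.numeric(ref_values)
  y <- as.numeric(test_values)
  if (length(x) != length(y)) abort_validation("inputs must have equal length")
  if (length(x) < 3) abort_insufficient("Pearson correlation requires n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("correlation undefined: constant input sequence",
                 class = "vitalval_undefined_correlation_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Full agreement analysis for one stratum
#'
#' Bundles [point_metrics()], bootstrap CIs for both MAE and RMSE, and
#' [pearson_cor()] into one result row for a stratum (a movement stage, an
#' SpO2 subgroup, or an overall phase). An undefined correlation (constant
#' signal) is flagged as `NA` with a warning instead of aborting the run.
#'
#' @param windows A `paired_windows` table (all rows one variable), or any
#'   data frame with `difference`, `median_ref`, `median_test` and
#'   optionally `participant_id`.
#' @param stratum Stratum label recorded in the output.
#' @param boot A [bootstrap_config()].
#' @return One-row `agreement_result` tibble with columns `variable`,
#'   `stratum`, `n_windows`, descriptive means/SDs, `mae`/`rmse` with CI
#'   bounds, `bias`, `sd_diff`, `loa_low`, `loa_high`, `pearson_r`,
#'   `p_value`.
#' @export
analyze_stratum <- function(windows, stratum = "overall",
                            boot = bootstrap_config(seed = 1)) {
  if (nrow(windows) == 0) abort_insufficient("no windows in stratum")
  variable <- unique(windows$variable)
  if (length(variable) > 1) {
    abort_validation("windows mix variables; analyze one variable at a time")
  }
  if (length(variable) == 0) variable <- NA_character_
  d <- windows$difference
  pm <- point_metrics(d, windows$median_ref, windows$median_test)
  group_ids <- if (boot$unit == "participant") windows$participant_id else NULL
  if (pm$n >= 2) {
    mae_ci <- bootstrap_ci(d, "mae", boot, group_ids)
    rmse_ci <- bootstrap_ci(d, "rmse", boot, group_ids)
  } else {
    mae_ci <- rmse_ci <- c(low = NA_real_, high = NA_real_)
  }
  corr <- if (pm$n >= 3) {
    tryCatch(pearson_cor(windows$median_ref, windows$median_test),
             vitalval_undefined_correlation_error = function(e) {
               warning(sprintf("stratum '%s': %s", stratum, conditionMessage(e)),
                       call. = FALSE)
               list(r = NA_real_, p_value = NA_real_)
             })
  } else {
    list(r = NA_real_, p_value = NA_real_)
  }
  out <- tibble::tibble(
    variable = variable, stratum = stratum, n_windows = pm$n,
    mean_ref = pm$mean_ref, sd_ref = pm$sd_ref,
    mean_test = pm$mean_test, sd_test = pm$sd_test,
    mae = pm$mae, mae_ci_low = unname(mae_ci["low"]),
    mae_ci_high = unname(mae_ci["high"]),
    rmse = pm$rmse, rmse_ci_low = unname(rmse_ci["low"]),
    rmse_ci_high = unname(rmse_ci["high"]),
    bias = pm$bias, sd_diff = pm$sd_diff,
    loa_low = pm$loa_low, loa_high = pm$loa_high,
    pearson_r = corr$r, p_value = corr$p_value
  )
  class(out) <- c("agreement_result", class(out))
  out
}

#' Export agreement results to CSV
#'
#' Columns mirror a device-validation summary table: descriptive means and
#' SDs for both devices, r, MAE and RMSE with CI bounds, and mean bias with
#' the limits of agreement.
#'
#' @param results An `agreement_result` tibble (one or more rows).
#' @param path Output path.
#' @export
write_agreement_results <- function(results, path) {
  out <- tibble::tibble(
    variable = results$variable, stratum = results$stratum,
    n = results$n_windows,
    ref_mean = results$mean_ref, ref_sd = results$sd_ref,
    test_mean = results$mean_test, test_sd = results$sd_test,
    r = results$pearson_r,
    mae = results$mae, mae_lo = results$mae_ci_low, mae_hi = results$mae_ci_high,
    rmse = results$rmse, rmse_lo = results$rmse_ci_low,
    rmse_hi = results$rmse_ci_high,
    bias = results$bias, loa_lo = results$loa_low, loa_hi = results$loa_high,
    p = results$p_value
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Human-readable summary table
#'
#' Formats agreement results the way validation studies print them:
#' `MAE (CI low to CI high)`, `bias (LoA low to LoA high)`, p-values below
#' 0.001 shown as `<.001`.
#'
#' @param results An `agreement_result` tibble.
#' @return Tibble of display strings.
#' @export
format_results_table <- function(results) {
  f <- function(x) sprintf("%.2f", x)
  tibble::tibble(
    variable = results$variable,
    stratum = results$stratum,
    n = results$n_windows,
    ref = sprintf("%s (%s)", f(results$mean_ref), f(results$sd_ref)),
    test = sprintf("%s (%s)", f(results$mean_test), f(results$sd_test)),
    r = sprintf("%.2f", results$pearson_r),
    mae = sprintf("%s (%s to %s)", f(results$mae), f(results$mae_ci_low),
                  f(results$mae_ci_high)),
    rmse = sprintf("%s (%s to %s)", f(results$rmse), f(results$rmse_ci_low),
                   f(results$rmse_ci_high)),
    bias_loa = sprintf("%s (%s to %s)", f(results$bias), f(results$loa_low),
                       f(results$loa_high)),
    p = format_p(results$p_value)
  )
}
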