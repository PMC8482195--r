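# Figure analogs: per-stratum scatter and Bland-Altman plots, and
# per-phase accuracy/bias summary panels with clinical threshold lines.

#' Scatter plot of test versus reference medians
#'
#' @param windows `paired_windows` rows for one stratum.
#' @param title Optional plot title.
#' @return A ggplot object with the identity line.
#' @export
plot_scatter <- function(windows, title = NULL) {
  ggplot2::ggplot(windows,
                  ggplot2::aes(x = .data$median_ref, y = .data$median_test)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::labs(x = "Reference 40-s median", y = "Patch 40-s median",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot for one stratum
#'
#' Differences against paired means, with horizontal lines at the mean
#' bias and the 95% limits of agreement.
#'
#' @param windows `paired_windows` rows for one stratum.
#' @param result Optional one-row `agreement_result` supplying bias/LoA;
#'   computed from `windows` when absent.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(windows, result = NULL, title = NULL) {
  if (is.null(result)) {
    pm <- point_metrics(windows$difference, windows$median_ref,
                        windows$median_test)
    bias <- pm$bias; loa <- c(pm$loa_low, pm$loa_high)
  } else {
    bias <- result$bias; loa <- c(result$loa_low, result$loa_high)
  }
  df <- tibble::tibble(
    mean_val = (windows$median_test + windows$median_ref) / 2,
    difference = windows$difference
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_val, y = .data$difference)) +
    ggplot2::geom_hline(yintercept = bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = loa, colour = "steelblue",
                        linetype = "dashed", na.rm = TRUE) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::labs(x = "Mean of devices", y = "Patch - reference",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Accuracy and bias summary panels for a set of strata
#'
#' Three stacked panels — MAE with CI, RMSE with CI, and bias with limits
#' of agreement — per stratum and variable, with horizontal reference
#' lines at the clinical acceptance thresholds (5 bpm / 3 rpm).
#'
#' @param results `agreement_result` rows to display.
#' @param thresholds [acceptance_thresholds()].
#' @return A patchwork object of three ggplots.
#' @export
plot_phase_summary <- function(results, thresholds = acceptance_thresholds()) {
  df <- results
  df$stratum <- factor(df$stratum, levels = unique(df$stratum))
  thr <- tibble::tibble(variable = c("HR", "RR"),
                        threshold = c(thresholds$hr_mae_max,
                                      thresholds$rr_mae_max))
  thr <- thr[thr$variable %in% df$variable, , drop = FALSE]
  base <- function(y, lo, hi, lab, with_thr) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum,
                                          colour = .data$variable)) +
      ggplot2::geom_pointrange(ggplot2::aes(y = .data[[y]], ymin = .data[[lo]],
                                            ymax = .data[[hi]]),
                               position = ggplot2::position_dodge(width = 0.4),
                               na.rm = TRUE) +
      ggplot2::scale_colour_manual(values = c(HR = "firebrick", RR = "steelblue")) +
      ggplot2::labs(x = NULL, y = lab) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
    if (with_thr && nrow(thr)) {
      p <- p + ggplot2::geom_hline(data = thr,
                                   ggplot2::aes(yintercept = .data$threshold,
                                                colour = .data$variable),
                                   linetype = "dotted")
    }
    p
  }
  patchwork::wrap_plots(
    base("mae", "mae_ci_low", "mae_ci_high", "MAE (95% CI)", TRUE),
    base("rmse", "rmse_ci_low", "rmse_ci_high", "RMSE (95% CI)", TRUE),
    base("bias", "loa_low", "loa_high", "Bias (95% LoA)", FALSE),
    ncol = 1
  )
}

#' Render the full figure set for a pipeline bundle
#'
#' Per (variable, stratum): one figure file combining the scatter and
#' Bland-Altman panels. Per phase (movement, hypoxia): one summary figure
#' with MAE/RMSE/bias panels and threshold lines. Every figure's plotted
#' data are co-exported as CSV so figures are auditable without image
#' parsing. Strata with fewer than 2 windows are skipped with a message.
#'
#' @param bundle A `vitalval_bundle` from [run_pipeline()].
#' @param out_dir Output directory.
#' @param width,height Figure size in inches.
#' @return Character vector of figure paths written, invisibly.
#' @export
render_reports <- function(bundle, out_dir, width = 8, height = 4.5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  res <- bundle$results
  for (i in seq_len(nrow(res))) {
    v <- res$variable[i]; st <- res$stratum[i]
    w <- stratum_windows(bundle$windows, v, st, bundle$config$scheme)
    if (nrow(w) < 2) {
      message(sprintf("render_reports: stratum %s/%s has n < 2, plot skipped",
                      v, st))
      next
    }
    ttl <- sprintf("%s - %s", v, st)
    fig <- patchwork::wrap_plots(plot_scatter(w, ttl),
                                 plot_bland_altman(w, res[i, ], ttl), ncol = 2)
    path <- file.path(out_dir, sprintf("fig_%s_%s.pdf", v, st))
    ggplot2::ggsave(path, fig, width = width, height = height)
    readr::write_csv(
      tibble::tibble(median_ref = w$median_ref, median_test = w$median_test,
                     difference = w$difference),
      file.path(out_dir, sprintf("fig_%s_%s_data.csv", v, st)))
    written <- c(written, path)
  }
  phases <- list(movement = res[res$stratum %in% MOVEMENT_STAGES, ],
                 hypoxia = res[!res$stratum %in% MOVEMENT_STAGES, ])
  for (ph in names(phases)) {
    pr <- phases[[ph]]
    if (nrow(pr) == 0) next
    path <- file.path(out_dir, sprintf("summary_%s.pdf", ph))
    ggplot2::ggsave(path, plot_phase_summary(pr, bundle$config$thresholds),
                    width = width, height = 3 * height)
    readr::write_csv(pr, file.path(out_dir, sprintf("summary_%s_data.csv", ph)))
    written <- c(written, path)
  }
  invisible(written)
}

# Windows belonging to a result stratum (stage, hypoxia phase, or SpO2
# subgroup).
stratum_windows <- function(windows, variable, stratum, scheme) {
  w <- windows[windows$variable == variable, , drop = FALSE]
  if (stratum %in% c(ALL_STAGES)) {
    return(w[w$stage_id == stratum, , drop = FALSE])
  }
  wh <- w[w$stage_id == "hypoxia", , drop = FALSE]
  grp <- assign_subgroup(wh$median_spo2, scheme)
  wh[!is.na(grp) & grp == stratum, , drop = FALSE]
}
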