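# End-to-end pipeline: sessions -> paired windows -> agreement results ->
# acceptance verdicts and SpO2 subgroup comparisons.

#' Run the full validation pipeline over a set of sessions
#'
#' For each variable, windows every session, pools the paired windows
#' across participants, and computes one agreement result per stratum: each
#' movement stage, the hypoxia phase overall, and (when SpO2 medians are
#' available) the normoxia / mild / severe hypoxia subgroups. Acceptance
#' verdicts and between-subgroup comparisons are attached. Session-level
#' errors are recorded and the run continues; an unacceptable MAE is a
#' result, not a failure.
#'
#' Each stratum's bootstrap uses a child seed derived from `boot$seed`, so
#' results are reproducible end to end and independent across strata.
#'
#' @param sessions A `vital_session` or list of them.
#' @param variables Variables to analyze, subset of `c("HR", "RR")`.
#' @param windowing A [windowing_config()].
#' @param boot A [bootstrap_config()].
#' @param thresholds [acceptance_thresholds()].
#' @param scheme [subgroup_scheme()].
#' @param out_dir Optional directory; when given, all export CSVs are
#'   written there via [write_bundle()].
#' @return A `vitalval_bundle` list: `windows`, `results`, `verdicts`,
#'   `subgroup_comparisons`, `exclusions`, `failures`.
#' @export
run_pipeline <- function(sessions, variables = c("HR", "RR"),
                         windowing = windowing_config(),
                         boot = bootstrap_config(seed = 1),
                         thresholds = acceptance_thresholds(),
                         scheme = subgroup_scheme(),
                         out_dir = NULL) {
  if (inherits(sessions, "vital_session")) sessions <- list(sessions)
  if (length(sessions) == 0) abort_config("no sessions supplied")
  variables <- match.arg(variables, c("HR", "RR"), several.ok = TRUE)

  windows <- list()
  exclusions <- list()
  failures <- list()
  for (s in sessions) {
    for (v in variables) {
      res <- tryCatch(extract_paired_windows(s, v, windowing), error = identity)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <- tibble::tibble(
          participant_id = s$participant_id, variable = v,
          error = conditionMessage(res))
        next
      }
      ex <- exclusion_log(res)
      ex$participant_id <- s$participant_id
      ex$variable <- v
      windows[[length(windows) + 1]] <- res
      exclusions[[length(exclusions) + 1]] <- ex
    }
  }
  windows <- dplyr::bind_rows(windows)
  exclusions <- dplyr::bind_rows(exclusions)
  failures <- dplyr::bind_rows(failures)
  if (nrow(windows) == 0) abort_insufficient("no windows extracted from any session")

  results <- list()
  comparisons <- list()
  k <- 0L
  stratum_boot <- function() {
    k <<- k + 1L
    b <- boot
    b$seed <- mix_seed(boot$seed, k)
    b
  }
  for (v in intersect(variables, unique(windows$variable))) {
    wv <- windows[windows$variable == v, , drop = FALSE]
    for (st in intersect(MOVEMENT_STAGES, unique(wv$stage_id))) {
      wst <- wv[wv$stage_id == st, , drop = FALSE]
      if (nrow(wst) < 2) next
      results[[length(results) + 1]] <- analyze_stratum(wst, st, stratum_boot())
    }
    wh <- wv[wv$stage_id == "hypoxia", , drop = FALSE]
    if (nrow(wh) >= 2) {
      results[[length(results) + 1]] <- analyze_stratum(wh, "hypoxia",
                                                        stratum_boot())
      grp <- assign_subgroup(wh$median_spo2, scheme)
      for (g in levels(grp)) {
        wg <- wh[!is.na(grp) & grp == g, , drop = FALSE]
        if (nrow(wg) < 2) next
        results[[length(results) + 1]] <- analyze_stratum(wg, g, stratum_boot())
      }
      cmp <- tryCatch(compare_subgroups(wh, stratum_boot(), scheme),
                      vitalval_insufficient_data_error = function(e) NULL)
      if (!is.null(cmp)) comparisons[[length(comparisons) + 1]] <- cmp
    }
  }
  results <- dplyr::bind_rows(results)
  comparisons <- dplyr::bind_rows(comparisons)
  verdicts <- evaluate_acceptance(results, thresholds)

  bundle <- structure(list(
    windows = windows, results = results, verdicts = verdicts,
    subgroup_comparisons = comparisons, exclusions = exclusions,
    failures = failures,
    config = list(variables = variables, windowing = windowing, boot = boot,
                  thresholds = thresholds, scheme = scheme)
  ), class = "vitalval_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.vitalval_bundle <- function(x, ...) {
  cat(sprintf("<vitalval_bundle> %d windows, %d strata, %d failure(s)\n",
              nrow(x$windows), nrow(x$results), nrow(x$failures)))
  print(format_results_table(x$results))
  invisible(x)
}

#' Write all pipeline export CSVs
#'
#' Emits `paired_windows.csv`, `agreement_results.csv`, `verdicts.csv`,
#' `subgroup_comparisons.csv` and `exclusions.csv`. Outputs are
#' deterministic: identical inputs and configuration reproduce
#' byte-identical files.
#'
#' @param bundle A `vitalval_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_paired_windows(bundle$windows, file.path(dir, "paired_windows.csv"))
  write_agreement_results(bundle$results, file.path(dir, "agreement_results.csv"))
  write_verdicts(bundle$verdicts, file.path(dir, "verdicts.csv"))
  if (nrow(bundle$subgroup_comparisons) > 0) {
    write_subgroup_comparisons(bundle$subgroup_comparisons,
                               file.path(dir, "subgroup_comparisons.csv"))
  }
  readr::write_csv(bundle$exclusions, file.path(dir, "exclusions.csv"))
  if (nrow(bundle$failures) > 0) {
    readr::write_csv(bundle$failures, file.path(dir, "failures.csv"))
  }
  invisible(dir)
}

#' Read a pipeline run configuration from YAML
#'
#' The file must carry `schema_version: 1`; unknown top-level keys are
#' rejected (fail-loud). Recognized keys: `sessions` (list of session
#' manifest paths, resolved relative to the config file), `output_dir`,
#' `variables`, `seed`, `windowing`, `bootstrap`, `thresholds`,
#' `subgroups`.
#'
#' @param path Path to the YAML config.
#' @return A `run_config` list ready for [run_pipeline_file()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  allowed <- c("schema_version", "sessions", "output_dir", "variables", "seed",
               "windowing", "bootstrap", "thresholds", "subgroups")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    abort_config(sprintf("unknown config key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  if (!identical(cfg$schema_version, 1L) && !identical(cfg$schema_version, 1)) {
    abort_config("config must declare schema_version: 1")
  }
  if (is.null(cfg$sessions) || length(cfg$sessions) == 0) {
    abort_config("config lists no sessions")
  }
  if (is.null(cfg$seed)) abort_config("config must set a seed")
  base <- dirname(path)
  paths <- vapply(cfg$sessions, function(p) {
    fp <- if (startsWith(p, "/")) p else file.path(base, p)
    if (!file.exists(fp)) abort_config(sprintf("session manifest not found: %s", p))
    fp
  }, character(1))
  w <- do.call(windowing_config, cfg$windowing %||% list())
  b_args <- cfg$bootstrap %||% list()
  if (is.null(b_args$seed)) b_args$seed <- cfg$seed
  b <- do.call(bootstrap_config, b_args)
  thr <- do.call(acceptance_thresholds, cfg$thresholds %||% list())
  sch <- do.call(subgroup_scheme, cfg$subgroups %||% list())
  structure(list(
    session_paths = paths,
    output_dir = if (is.null(cfg$output_dir)) NULL else
      (if (startsWith(cfg$output_dir, "/")) cfg$output_dir
       else file.path(base, cfg$output_dir)),
    variables = cfg$variables %||% c("HR", "RR"),
    windowing = w, boot = b, thresholds = thr, scheme = sch
  ), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the pipeline from a YAML configuration
#'
#' @param config_path Path accepted by [read_run_config()].
#' @return The `vitalval_bundle`, invisibly; exports are written to the
#'   configured output directory when one is set.
#' @export
run_pipeline_file <- function(config_path) {
  cfg <- read_run_config(config_path)
  sessions <- lapply(cfg$session_paths, read_session)
  invisible(run_pipeline(sessions, cfg$variables, cfg$windowing, cfg$boot,
                         cfg$thresholds, cfg$scheme, out_dir = cfg$output_dir))
}
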