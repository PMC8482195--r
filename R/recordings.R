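#' Construct a device recording
#'
#' A recording is one device channel's timestamped samples on the session
#' clock: decimal seconds from session start, paired with finite values.
#' The test patch reports instantaneous HR and RR estimates every 4 seconds;
#' the reference monitor reports HR, RR and SpO2 at 1 Hz.
#'
#' @param t_s Numeric vector of timestamps, seconds since session start,
#'   strictly increasing.
#' @param value Numeric vector of finite sample values, same length as `t_s`.
#' @param device_id Label identifying the physical device.
#' @param variable One of `"HR"`, `"RR"`, `"SPO2"`.
#' @param unit Measurement unit; must match the variable (`HR` is `bpm`,
#'   `RR` is `rpm`, `SPO2` is `percent`). Defaults to the matching unit.
#' @param nominal_interval_s Nominal sampling interval in seconds (4 for
#'   patch channels, 1 for reference channels).
#' @param n_dropped Count of rows discarded during parsing (bookkeeping).
#' @return A `vital_recording`: a tibble with columns `t_s` and `value` and
#'   metadata attributes.
#' @examples
#' recording(0:5, rep(70, 6), "ref-ecg", "HR", nominal_interval_s = 1)
#' @export
recording <- function(t_s, value, device_id, variable,
                      unit = unit_for(variable), nominal_interval_s,
                      n_dropped = 0L) {
  variable <- match.arg(variable, VARIABLES)
  out <- tibble::tibble(t_s = as.numeric(t_s), value = as.numeric(value))
  attr(out, "device_id") <- as.character(device_id)
  attr(out, "variable") <- variable
  attr(out, "unit") <- unit
  attr(out, "nominal_interval_s") <- as.numeric(nominal_interval_s)
  attr(out, "n_dropped") <- as.integer(n_dropped)
  class(out) <- c("vital_recording", class(out))
  validate_recording(out)
}

validate_recording <- function(x) {
  iv <- attr(x, "nominal_interval_s")
  if (!is.numeric(iv) || length(iv) != 1 || !is.finite(iv) || iv <= 0) {
    abort_validation("`nominal_interval_s` must be a single positive number")
  }
  variable <- attr(x, "variable")
  if (!identical(attr(x, "unit"), unit_for(variable))) {
    abort_validation(sprintf(
      "unit '%s' does not match variable '%s' (expected '%s')",
      attr(x, "unit"), variable, unit_for(variable)
    ))
  }
  if (nrow(x) > 0) {
    if (any(!is.finite(x$t_s)) || any(!is.finite(x$value))) {
      abort_validation("timestamps and values must all be finite")
    }
    if (nrow(x) > 1 && any(diff(x$t_s) <= 0)) {
      first_bad <- which(diff(x$t_s) <= 0)[1] + 1L
      abort_validation(sprintf(
        "timestamps must be strictly increasing; first offending row: %d (t_s = %g)",
        first_bad, x$t_s[first_bad]
      ))
    }
  }
  x
}

#' @export
print.vital_recording <- function(x, ...) {
  cat(sprintf(
    "<vital_recording> %s %s [%s], %d samples every %g s nominal, span %s s\n",
    attr(x, "device_id"), attr(x, "variable"), attr(x, "unit"), nrow(x),
    attr(x, "nominal_interval_s"),
    if (nrow(x)) sprintf("%.1f-%.1f", min(x$t_s), max(x$t_s)) else "-"
  ))
  if (attr(x, "n_dropped") > 0) {
    cat(sprintf("  (%d unparseable/non-finite rows dropped on read)\n",
                attr(x, "n_dropped")))
  }
  invisible(x)
}

#' Read a recording from a two-column CSV
#'
#' The file must have a header `t_s,value`. Rows whose value is non-numeric
#' or non-finite (device dropouts) are dropped and counted, not treated as
#' errors; structural problems (wrong header, unsorted timestamps) are.
#'
#' @inheritParams recording
#' @param path Path to the CSV file.
#' @return A validated [recording()]; the number of dropped rows is
#'   available as `attr(x, "n_dropped")` and reported via [message()].
#' @export
read_recording <- function(path, device_id, variable,
                           unit = unit_for(variable), nominal_interval_s) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", strip.white = TRUE),
    error = function(e) abort_format(sprintf("unparseable CSV '%s': %s",
                                             path, conditionMessage(e)))
  )
  if (!identical(names(raw), c("t_s", "value"))) {
    abort_format(sprintf(
      "'%s': expected header 't_s,value', got '%s'",
      path, paste(names(raw), collapse = ",")
    ))
  }
  t_s <- suppressWarnings(as.numeric(raw$t_s))
  value <- suppressWarnings(as.numeric(raw$value))
  keep <- is.finite(t_s) & is.finite(value)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("read_recording: dropped %d non-numeric/non-finite row(s) from %s",
                    n_dropped, path))
  }
  recording(t_s[keep], value[keep], device_id, variable, unit,
            nominal_interval_s, n_dropped = n_dropped)
}

#' Write a recording to CSV
#'
#' Timestamps and values are written with 3 decimal places, which exceeds
#' both devices' reporting resolution and makes write-then-read round trips
#' exact.
#'
#' @param x A [recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(x, path) {
  stopifnot(inherits(x, "vital_recording"))
  lines <- c("t_s,value",
             sprintf("%.3f,%.3f", x$t_s, x$value))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Construct stage annotations
#'
#' Stage annotations carve a session into labeled intervals: the seven
#' movement activities (at rest, sit-to-stand, tapping, rubbing, drinking,
#' turning pages, tablet) and the controlled-hypoxia phase. Unknown labels
#' are rejected so downstream stratification stays well-defined.
#'
#' @param stage_id Character vector of stage labels.
#' @param phase `"movement"` or `"hypoxia"` per stage.
#' @param start_s,end_s Interval bounds in seconds since session start.
#' @return A `vital_annotations` tibble sorted by `start_s`.
#' @export
stage_annotations <- function(stage_id, phase, start_s, end_s) {
  out <- tibble::tibble(
    stage_id = as.character(stage_id),
    phase = as.character(phase),
    start_s = as.numeric(start_s),
    end_s = as.numeric(end_s)
  )
  out <- out[order(out$start_s), , drop = FALSE]
  class(out) <- c("vital_annotations", class(out))
  validate_annotations(out)
}

validate_annotations <- function(x) {
  unknown <- setdiff(x$stage_id, ALL_STAGES)
  if (length(unknown)) {
    abort_validation(sprintf("unknown stage_id(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  bad_phase <- x$phase[!x$phase %in% c("movement", "hypoxia")]
  if (length(bad_phase)) {
    abort_validation(sprintf("unknown phase(s): %s",
                             paste(unique(bad_phase), collapse = ", ")))
  }
  expected_phase <- ifelse(x$stage_id == "hypoxia", "hypoxia", "movement")
  if (any(x$phase != expected_phase)) {
    abort_validation("stage_id and phase are inconsistent")
  }
  if (any(x$end_s <= x$start_s)) {
    abort_validation("each annotation must satisfy end_s > start_s")
  }
  for (ph in unique(x$phase)) {
    xi <- x[x$phase == ph, , drop = FALSE]
    if (nrow(xi) > 1) {
      xi <- xi[order(xi$start_s), , drop = FALSE]
      if (any(xi$start_s[-1] < xi$end_s[-nrow(xi)])) {
        abort_validation(sprintf("overlapping intervals within phase '%s'", ph))
      }
    }
  }
  x
}

#' Read stage annotations from CSV
#'
#' @param path CSV with header `stage_id,phase,start_s,end_s`.
#' @return Validated [stage_annotations()], sorted by start time.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  raw <- tryCatch(
    utils::read.csv(path, strip.white = TRUE),
    error = function(e) abort_format(sprintf("unparseable CSV '%s': %s",
                                             path, conditionMessage(e)))
  )
  if (!identical(names(raw), c("stage_id", "phase", "start_s", "end_s"))) {
    abort_format(sprintf(
      "'%s': expected header 'stage_id,phase,start_s,end_s', got '%s'",
      path, paste(names(raw), collapse = ",")
    ))
  }
  stage_annotations(raw$stage_id, raw$phase, raw$start_s, raw$end_s)
}

#' Write stage annotations to CSV
#'
#' @param x [stage_annotations()].
#' @param path Output path.
#' @export
write_annotations <- function(x, path) {
  stopifnot(inherits(x, "vital_annotations"))
  lines <- c("stage_id,phase,start_s,end_s",
             sprintf("%s,%s,%.3f,%.3f", x$stage_id, x$phase, x$start_s, x$end_s))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Assemble a validated session
#'
#' A session bundles one participant's channels and stage annotations.
#' Channels are never resampled: original timestamps are preserved. At
#' minimum the four rate channels must be present (`test_HR`, `test_RR`,
#' `ref_HR`, `ref_RR`); a reference SpO2 channel (`ref_SPO2`) is required
#' whenever a hypoxia annotation is present, because hypoxia windows are
#' later stratified by their SpO2 medians.
#'
#' @param participant_id Participant label.
#' @param recordings Named list of [recording()] objects; names must be
#'   drawn from `test_HR`, `test_RR`, `ref_HR`, `ref_RR`, `ref_SPO2`.
#' @param annotations [stage_annotations()] for the session.
#' @return A `vital_session` object (list with `participant_id`,
#'   `recordings`, `annotations`).
#' @export
assemble_session <- function(participant_id, recordings, annotations) {
  if (!inherits(annotations, "vital_annotations")) {
    annotations <- validate_annotations(annotations)
  }
  if (is.null(names(recordings)) || any(names(recordings) == "")) {
    abort_validation("`recordings` must be a fully named list")
  }
  unknown <- setdiff(names(recordings), CHANNEL_ROLES)
  if (length(unknown)) {
    abort_validation(sprintf("unknown channel role(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(REQUIRED_CHANNELS, names(recordings))
  if (any(annotations$phase == "hypoxia") && !"ref_SPO2" %in% names(recordings)) {
    missing <- c(missing, "ref_SPO2")
  }
  if (length(missing)) {
    abort_completeness(sprintf("missing required channel(s): %s",
                               paste(missing, collapse = ", ")))
  }
  for (role in names(recordings)) {
    rec <- recordings[[role]]
    if (!inherits(rec, "vital_recording")) {
      abort_validation(sprintf("channel '%s' is not a vital_recording", role))
    }
    want_var <- sub("^(test|ref)_", "", role)
    if (!identical(attr(rec, "variable"), want_var)) {
      abort_validation(sprintf("channel '%s' carries variable '%s'",
                               role, attr(rec, "variable")))
    }
  }
  spans <- vapply(recordings, function(r) {
    if (nrow(r) == 0) c(NA_real_, NA_real_) else range(r$t_s)
  }, numeric(2))
  t_min <- min(spans[1, ], na.rm = TRUE)
  t_max <- max(spans[2, ], na.rm = TRUE)
  if (any(annotations$start_s < t_min) || any(annotations$end_s > t_max)) {
    abort_validation(sprintf(
      "annotation interval extends outside recorded span [%.3f, %.3f]",
      t_min, t_max
    ))
  }
  structure(
    list(participant_id = as.character(participant_id),
         recordings = recordings,
         annotations = annotations),
    class = "vital_session"
  )
}

#' @export
print.vital_session <- function(x, ...) {
  cat(sprintf("<vital_session> participant %s: %d channel(s), %d annotation(s)\n",
              x$participant_id, length(x$recordings), nrow(x$annotations)))
  for (role in names(x$recordings)) {
    r <- x$recordings[[role]]
    cat(sprintf("  %-9s %5d samples @ %g s\n", role, nrow(r),
                attr(r, "nominal_interval_s")))
  }
  invisible(x)
}

#' Write a session to a directory
#'
#' Emits one CSV per channel, an annotation CSV, and a YAML manifest
#' (`session.yaml`) mapping channel roles to files so the session can be
#' reloaded with [read_session()].
#'
#' @param session A `vital_session`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "vital_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  channels <- list()
  for (role in names(session$recordings)) {
    rec <- session$recordings[[role]]
    fname <- paste0(role, ".csv")
    write_recording(rec, file.path(dir, fname))
    channels[[role]] <- list(
      path = fname,
      device_id = attr(rec, "device_id"),
      variable = attr(rec, "variable"),
      unit = attr(rec, "unit"),
      nominal_interval_s = attr(rec, "nominal_interval_s")
    )
  }
  write_annotations(session$annotations, file.path(dir, "annotations.csv"))
  manifest <- list(
    participant_id = session$participant_id,
    channels = channels,
    annotations = "annotations.csv"
  )
  manifest_path <- file.path(dir, "session.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest_path)
}

#' Read a session from its YAML manifest
#'
#' @param manifest_path Path to a `session.yaml` written by
#'   [write_session()]; file paths inside it are resolved relative to the
#'   manifest's directory.
#' @return A validated `vital_session`.
#' @export
read_session <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    abort_format(sprintf("manifest not found: %s", manifest_path))
  }
  m <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  if (is.null(m$participant_id) || is.null(m$channels) || is.null(m$annotations)) {
    abort_format("manifest must contain participant_id, channels, annotations")
  }
  recs <- lapply(m$channels, function(ch) {
    read_recording(file.path(base, ch$path), ch$device_id, ch$variable,
                   ch$unit, ch$nominal_interval_s)
  })
  names(recs) <- names(m$channels)
  ann <- read_annotations(file.path(base, m$annotations))
  assemble_session(m$participant_id, recs, ann)
}
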