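#' Read a gaze-sample table
#'
#' Reads the canonical gaze CSV: a header row followed by one row per
#' sample, with columns `time_ms` and, per recorded eye, `xL_px`, `yL_px`,
#' `blankL` and/or `xR_px`, `yR_px`, `blankR`. `blank*` is 0/1 and marks
#' samples excluded by the tracker as blink or saccade; rows with non-finite
#' coordinates are additionally forced to blank, so blank samples may carry
#' arbitrary coordinate values and must never be used un-interpolated.
#'
#' @param path Path to a gaze CSV file.
#' @param screen A [screen_geometry()]; supplies the sampling rate.
#' @return A `gaze_recording`: a tibble with a `time_ms` column and per-eye
#'   coordinate/blank columns, with attributes `sampling_rate_hz` and
#'   `eyes` (subset of `c("left", "right")`).
#' @export
read_gaze_table <- function(path, screen) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_gaze_recording(dat, screen$sampling_rate_hz)
}

#' Validate a data frame as a gaze recording
#'
#' @param dat Data frame with column `time_ms` and per-eye columns as in
#'   [read_gaze_table()].
#' @param sampling_rate_hz Nominal sampling rate in Hz.
#' @return A validated `gaze_recording` tibble.
#' @export
as_gaze_recording <- function(dat, sampling_rate_hz) {
  if (!"time_ms" %in% names(dat)) {
    stop("gaze table is missing mandatory column 'time_ms'", call. = FALSE)
  }
  eyes <- character(0)
  if (all(c("xL_px", "yL_px", "blankL") %in% names(dat))) eyes <- c(eyes, "left")
  if (all(c("xR_px", "yR_px", "blankR") %in% names(dat))) eyes <- c(eyes, "right")
  if (length(eyes) == 0) {
    stop("gaze table must contain complete columns for at least one eye ",
         "(xL_px/yL_px/blankL or xR_px/yR_px/blankR)", call. = FALSE)
  }
  if (anyNA(dat$time_ms) || any(diff(dat$time_ms) <= 0)) {
    stop("gaze timestamps must be finite and strictly increasing",
         call. = FALSE)
  }
  dat <- tibble::as_tibble(dat)
  # non-finite coordinates imply blank regardless of the vendor flag
  if ("left" %in% eyes) {
    dat$blankL <- as.integer(dat$blankL != 0 |
                               !is.finite(dat$xL_px) | !is.finite(dat$yL_px))
  }
  if ("right" %in% eyes) {
    dat$blankR <- as.integer(dat$blankR != 0 |
                               !is.finite(dat$xR_px) | !is.finite(dat$yR_px))
  }
  structure(dat, sampling_rate_hz = sampling_rate_hz, eyes = eyes,
            class = c("gaze_recording", class(dat)))
}

#' Select the analysis eye of a binocular recording
#'
#' Picks the eye with the fewer blank samples; ties are broken toward the
#' left eye. Monocular recordings pass through unchanged (renamed to the
#' monocular layout).
#'
#' @param rec A `gaze_recording` from [read_gaze_table()].
#' @return A monocular `gaze_recording` tibble with columns `time_ms`,
#'   `x_px`, `y_px`, `blank` and attribute `eye`.
#' @export
select_eye <- function(rec) {
  eyes <- attr(rec, "eyes")
  if (is.null(eyes)) stop("not a gaze_recording", call. = FALSE)
  counts <- c(left = if ("left" %in% eyes) sum(rec$blankL) else Inf,
              right = if ("right" %in% eyes) sum(rec$blankR) else Inf)
  # ties broken toward the left eye: which.min picks the first minimum
  eye <- names(counts)[which.min(counts)]
  cols <- if (eye == "left") c("xL_px", "yL_px", "blankL") else
    c("xR_px", "yR_px", "blankR")
  out <- tibble::tibble(
    time_ms = rec$time_ms,
    x_px = rec[[cols[1]]],
    y_px = rec[[cols[2]]],
    blank = as.integer(rec[[cols[3]]])
  )
  if (all(out$blank == 1)) {
    stop("every sample of every available eye is blank", call. = FALSE)
  }
  structure(out, sampling_rate_hz = attr(rec, "sampling_rate_hz"), eye = eye,
            class = c("gaze_recording", class(out)))
}

#' Read a trial-event table
#'
#' The events CSV has columns `trial_id`, `condition`, `cs_onset_ms`,
#' `soa_s`, `cs_duration_s`. Conditions come from the closed set
#' `CSplus_USplus` (reinforced), `CSplus_USminus` (non-reinforced CS+),
#' `CSminus`. Onsets must be strictly increasing and the CS-US interval
#' (SOA) must not exceed the CS duration.
#'
#' @param path Path to an events CSV file.
#' @return A validated tibble of trial events.
#' @export
read_events_table <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_events(dat)
}

#' @rdname read_events_table
#' @param events Data frame of trial events to validate.
#' @export
validate_events <- function(events) {
  need <- c("trial_id", "condition", "cs_onset_ms", "soa_s", "cs_duration_s")
  miss <- setdiff(need, names(events))
  if (length(miss) > 0) {
    stop("events table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(diff(events$cs_onset_ms) <= 0)) {
    stop("CS onsets must be strictly increasing", call. = FALSE)
  }
  bad <- setdiff(unique(events$condition), condition_levels())
  if (length(bad) > 0) {
    stop("unknown condition labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(events$soa_s > events$cs_duration_s)) {
    stop("soa_s must not exceed cs_duration_s", call. = FALSE)
  }
  tibble::as_tibble(events)
}

#' Condition labels of the delay-conditioning design
#'
#' @return Character vector: reinforced CS+ (`CSplus_USplus`),
#'   non-reinforced CS+ (`CSplus_USminus`), and CS- (`CSminus`). Only the
#'   latter two enter statistics; reinforced trials are excluded because
#'   interpolation lets responses to the aversive event leak backwards in
#'   time.
#' @export
condition_levels <- function() {
  c("CSplus_USplus", "CSplus_USminus", "CSminus")
}

#' @rdname condition_levels
#' @export
analyzed_conditions <- function() {
  c("CSplus_USminus", "CSminus")
}

#' Read a fixation-event table
#'
#' Columns: `trial_id`, `onset_ms`, `duration_ms`, `x_mm`, `y_mm`.
#' Fixations are taken as parsed by the tracker (or generated); the package
#' does not re-detect them.
#'
#' @param path Path to a fixation CSV file.
#' @return A tibble of fixation events.
#' @export
read_fixations_table <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("onset_ms", "duration_ms", "x_mm", "y_mm")
  miss <- setdiff(need, names(dat))
  if (length(miss) > 0) {
    stop("fixation table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(dat$duration_ms <= 0)) {
    stop("fixation durations must be strictly positive", call. = FALSE)
  }
  tibble::as_tibble(dat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
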