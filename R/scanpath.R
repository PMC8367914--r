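#' Per-trial scanpath length in a window before anticipated US onset
#'
#' Integrates scan speed (equivalently, sums the per-step great-circle
#' arcs) over the final `window_s` seconds of the CS-US interval. For
#' non-reinforced trials the anchor is the *anticipated* US onset,
#' `cs_onset + soa`. A step whose interval straddles the window start is
#' assigned by its later-sample timestamp; at typical sampling rates the
#' bias is at most one sample and identical across conditions.
#'
#' @param speed A `scan_speed_series` for one participant.
#' @param events Trial events for the same recording.
#' @param window_s Window length in seconds, in `(0, soa]`. Defaults to the
#'   2-s window that maximizes the CS+/CS- effect size.
#' @return A tibble `trial_id`, `condition`, `window_s`, `length_deg`.
#' @export
scanpath_lengths <- function(speed, events, window_s = 2) {
  if (any(window_s <= 0) || any(window_s > events$soa_s + 1e-9)) {
    stop("window_s must lie in (0, soa]", call. = FALSE)
  }
  soa_ms <- events$soa_s * 1000
  epochs <- epoch_trials(speed, events,
                         window_ms = c(0, max(soa_ms)))
  # keep only each trial's own [soa - window, soa) stretch
  ep <- dplyr::left_join(epochs,
                         events[, c("trial_id", "soa_s")], by = "trial_id")
  keep <- ep$t_rel_ms >= (ep$soa_s * 1000 - window_s * 1000) &
    ep$t_rel_ms < ep$soa_s * 1000
  ep <- ep[keep, , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(ep, .data$trial_id, .data$condition),
    length_deg = sum(.data$arc_deg), .groups = "drop")
  # trials whose window contained no samples get length 0 only if absent
  out <- dplyr::left_join(events[, c("trial_id", "condition")],
                          out, by = c("trial_id", "condition"))
  out$length_deg[is.na(out$length_deg)] <- 0
  out$window_s <- window_s
  out[, c("trial_id", "condition", "window_s", "length_deg")]
}

#' Participant-by-condition mean scanpath length
#'
#' Averages per-trial lengths over the retained (non-reinforced) trials of
#' each condition within participants. Reinforced `CSplus_USplus` trials
#' are never included. Participants missing a whole condition are dropped
#' with a warning.
#'
#' @param trials A tibble of per-trial lengths with columns `participant`,
#'   `condition`, `length_deg` (e.g. row-bound output of
#'   [scanpath_lengths()] with a `participant` column added).
#' @return A tibble `participant`, `condition`, `mean_length_deg` with one
#'   row per retained participant and analyzed condition.
#' @export
condition_means <- function(trials) {
  stopifnot(all(c("participant", "condition", "length_deg") %in%
                  names(trials)))
  keep <- trials$condition %in% analyzed_conditions()
  out <- dplyr::summarise(
    dplyr::group_by(trials[keep, ], .data$participant, .data$condition),
    mean_length_deg = mean(.data$length_deg), .groups = "drop")
  n_cond <- table(out$participant)
  incomplete <- names(n_cond)[n_cond < length(analyzed_conditions())]
  if (length(incomplete) > 0) {
    warning("dropping participant(s) with an empty condition: ",
            paste(incomplete, collapse = ", "))
    out <- out[!out$participant %in% incomplete, , drop = FALSE]
  }
  out
}

#' Paired CS+ minus CS- differences of a participant-by-condition table
#'
#' @param means Output of [condition_means()] (or any tibble with columns
#'   `participant`, `condition`, and a value column).
#' @param value Name of the value column.
#' @return Named numeric vector of per-participant `CSplus_USminus -
#'   CSminus` differences.
#' @export
paired_differences <- function(means, value = "mean_length_deg") {
  wide <- tidyr::pivot_wider(means[, c("participant", "condition", value)],
                             names_from = "condition",
                             values_from = dplyr::all_of(value))
  stopifnot(all(analyzed_conditions() %in% names(wide)))
  d <- wide$CSplus_USminus - wide$CSminus
  names(d) <- wide$participant
  d
}

#' Window sweep: retrodictive validity across scanpath windows
#'
#' Recomputes the scanpath-length statistic for every window in `windows`
#' (by default 0.5-s steps up to the SOA), contrasts CS+ against CS-, and
#' reports the absolute Hedge's g and the log Bayes factor of each window
#' relative to the full CS-US interval as reference model (whose LBF is 0
#' by construction).
#'
#' @param cohort A list with one element per participant, each a list with
#'   `speed` (a `scan_speed_series`) and `events`.
#' @param soa_s The CS-US interval in seconds (must match the events).
#' @param windows Window lengths in seconds; default `seq(0.5, soa_s, 0.5)`.
#' @return A tibble `window_s`, `df`, `lbf`, `abs_g`, ordered from the
#'   full-interval reference downward.
#' @export
window_sweep <- function(cohort, soa_s, windows = NULL) {
  if (is.null(windows)) windows <- seq(0.5, soa_s, by = 0.5)
  windows <- sort(windows, decreasing = TRUE)
  if (max(windows) < soa_s) windows <- c(soa_s, windows)
  per_window <- lapply(windows, function(w) {
    means <- condition_means(cohort_trial_lengths(cohort, w))
    means$value <- means$mean_length_deg
    means
  })
  names(per_window) <- sprintf("%.1f", windows)
  ref_name <- sprintf("%.1f", soa_s)
  cmp <- aic_lbf(per_window, reference = ref_name, value = "value")
  gs <- vapply(per_window, function(m) hedges_g(paired_differences(m)),
               numeric(1))
  n <- length(unique(per_window[[1]]$participant))
  tibble::tibble(window_s = windows, df = n - 1,
                 lbf = unname(cmp$lbf[match(sprintf("%.1f", windows),
                                            cmp$candidate)]),
                 abs_g = unname(abs(gs)))
}

#' Per-trial lengths for a whole cohort at one window
#'
#' @param cohort As in [window_sweep()].
#' @param window_s Window length in seconds.
#' @return Tibble `participant`, `trial_id`, `condition`, `window_s`,
#'   `length_deg`.
#' @export
cohort_trial_lengths <- function(cohort, window_s) {
  dplyr::bind_rows(lapply(names(cohort), function(id) {
    p <- cohort[[id]]
    res <- scanpath_lengths(p$speed, p$events, window_s)
    res$participant <- id
    res
  }))
}
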