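#' Preprocess one participant's recording into a scan-speed series
#'
#' Eye selection (fewer missing samples), linear interpolation of blank
#' stretches, pixel-to-mm conversion, spherical transform, and per-step
#' great-circle scan speed — the full kinematic chain in the canonical
#' order.
#'
#' @param gaze A binocular (or monocular) `gaze_recording`.
#' @param screen A [screen_geometry()].
#' @return A `scan_speed_series`.
#' @export
preprocess_gaze <- function(gaze, screen) {
  mono <- select_eye(gaze)
  filled <- interpolate_blanks(mono)
  scan_speed_series(filled, screen)
}

#' Grand-mean condition-difference scan-speed series of a cohort
#'
#' Epochs each participant's scan speed over `[epoch_s[1], epoch_s[2])`
#' relative to CS onset, averages within condition and participant, then
#' across participants, and returns the smoothed CS- minus CS+ difference
#' used to fit the response function.
#'
#' @param cohort Named list of participants with `speed` and `events`.
#' @param epoch_s Epoch bounds relative to CS onset (s); default CS onset
#'   to SOA + 2 s.
#' @param soa_s CS-US interval (s).
#' @param span Smoothing span in samples (odd); default approximately 1 s
#'   at the recording rate.
#' @return A tibble `t_s` (relative to CS onset), `diff` (smoothed CS-
#'   minus CS+ grand-mean scan speed).
#' @export
grand_mean_difference <- function(cohort, soa_s, epoch_s = NULL,
                                  span = NULL) {
  if (is.null(epoch_s)) epoch_s <- c(0, soa_s + 2)
  per_part <- lapply(cohort, function(p) {
    ep <- epoch_trials(p$speed, p$events, window_ms = epoch_s * 1000)
    ep <- ep[ep$condition %in% analyzed_conditions(), , drop = FALSE]
    # trial onsets need not sit on the sample grid: bin relative times
    # onto the nominal grid so trials can be averaged point-wise
    dt <- stats::median(diff(p$speed$t_ms))
    ep$t_rel_ms <- (floor((ep$t_rel_ms - epoch_s[1] * 1000) / dt) + 1) *
      dt + epoch_s[1] * 1000
    dplyr::summarise(dplyr::group_by(ep, .data$condition, .data$t_rel_ms),
                     v = mean(.data$v_deg_s), .groups = "drop")
  })
  all <- dplyr::bind_rows(per_part, .id = "participant")
  gm <- dplyr::summarise(dplyr::group_by(all, .data$condition,
                                         .data$t_rel_ms),
                         v = mean(.data$v), .groups = "drop")
  wide <- tidyr::pivot_wider(gm, names_from = "condition",
                             values_from = "v")
  wide <- wide[order(wide$t_rel_ms), ]
  d <- wide$CSminus - wide$CSplus_USminus
  if (is.null(span)) {
    rate <- 1000 / stats::median(diff(wide$t_rel_ms))
    span <- 2 * floor(rate / 2) + 1
  }
  span <- min(span, 2 * floor((length(d) - 1) / 2) + 1)
  tibble::tibble(t_s = wide$t_rel_ms / 1000,
                 diff = smooth_for_viz(d, span))
}

#' Run the full scanpath analysis pipeline on a cohort
#'
#' Preprocesses every participant, computes per-trial scanpath lengths in
#' the analysis window, participant-by-condition means, the group
#' contrast (paired t, exact-J Hedge's g, BCa bootstrap CI, sign-based
#' classification accuracy), split-half reliability, and optionally the
#' window sweep and the GLM response-amplitude contrast.
#'
#' @param cohort Named list of participants, each with `gaze`, `events`,
#'   and optionally `fixations` (e.g. from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param screen A [screen_geometry()].
#' @param window_s Analysis window before anticipated US onset (s);
#'   default 2.
#' @param sweep Logical: also run the 0.5-s-step window sweep.
#' @param glm Logical: also run the GLM contrast.
#' @param rf_params Response-function parameters for the GLM (named:
#'   `t0`, `k`, `mu`). If `NULL` and `glm = TRUE`, the function is fitted
#'   to the cohort's grand-mean difference series.
#' @param glm_shift_s Rightward shift of the response function in the GLM
#'   design (s).
#' @param seed Integer seed for bootstrap and reliability resampling.
#' @param n_boot Bootstrap replicates for the CI.
#' @param n_rep Split-half repetitions.
#' @return A list of class `threatgaze_report` with elements
#'   `trial_lengths`, `condition_means`, `contrast`, `reliability`,
#'   `exclusions`, and optionally `sweep`, `rf`, `glm`.
#' @export
run_pipeline <- function(cohort, screen, window_s = 2, sweep = FALSE,
                         glm = FALSE, rf_params = NULL, glm_shift_s = 0,
                         seed = 1L, n_boot = 2000, n_rep = 1000) {
  proc <- lapply(cohort, function(p) {
    list(speed = preprocess_gaze(p$gaze, screen), events = p$events)
  })
  soa_s <- proc[[1]]$events$soa_s[1]
  trials <- cohort_trial_lengths(proc, window_s)
  n_usplus <- sum(trials$condition == "CSplus_USplus")
  means <- condition_means(trials)
  d <- paired_differences(means)
  contrast <- contrast_summary(d, n_boot = n_boot, seed = seed)
  analyzed <- trials[trials$condition %in% analyzed_conditions(), ]
  rel <- split_half_reliability(analyzed, n_rep = n_rep, seed = seed + 1)
  report <- list(
    window_s = window_s,
    trial_lengths = trials,
    condition_means = means,
    contrast = contrast,
    reliability = list(mean_r = rel$mean_r, n_rep = rel$n_rep),
    exclusions = list(us_plus_trials = n_usplus)
  )
  if (sweep) report$sweep <- window_sweep(proc, soa_s)
  if (glm) {
    if (is.null(rf_params)) {
      gmd <- grand_mean_difference(proc, soa_s)
      fit <- fit_rf(gmd$t_s, gmd$diff)
      rf_params <- fit$params
      report$rf <- fit
    }
    betas <- lapply(proc, function(p)
      glm_contrast(p$speed, p$events, rf_params, shift_s = glm_shift_s))
    gd <- vapply(betas, `[[`, numeric(1), "contrast")
    report$glm <- list(params = rf_params,
                       contrast = contrast_summary(gd, n_boot = n_boot,
                                                   seed = seed + 2),
                       beta = lapply(betas, `[[`, "beta"))
  }
  class(report) <- "threatgaze_report"
  report
}

#' @export
print.threatgaze_report <- function(x, ...) {
  ct <- x$contrast
  cat(sprintf("Scanpath length, %.1f-s window before anticipated US onset\n",
              x$window_s))
  cat(sprintf("  n = %d, t(%d) = %.2f, p = %.4g, g = %.2f [%.2f, %.2f]\n",
              ct$n, ct$df, ct$t, ct$p, ct$g, ct$ci_lo, ct$ci_hi))
  cat(sprintf("  classification accuracy = %.2f, split-half r = %.2f\n",
              ct$accuracy, x$reliability$mean_r))
  cat(sprintf("  excluded reinforced (US+) trials: %d\n",
              x$exclusions$us_plus_trials))
  if (!is.null(x$sweep)) {
    cat("Window sweep (reference = full CS-US interval):\n")
    print(as.data.frame(x$sweep), row.names = FALSE, digits = 3)
  }
  if (!is.null(x$glm)) {
    g <- x$glm$contrast
    cat(sprintf(
      "GLM response contrast: t(%d) = %.2f, p = %.4g, g = %.2f\n",
      g$df, g$t, g$p, g$g))
  }
  invisible(x)
}

#' Write a pipeline report as TSV files
#'
#' @param report A `threatgaze_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$trial_lengths,
                   file.path(dir, "trial_lengths.tsv"), progress = FALSE)
  readr::write_tsv(report$condition_means,
                   file.path(dir, "condition_means.tsv"), progress = FALSE)
  ct <- report$contrast
  ct$reliability_r <- report$reliability$mean_r
  readr::write_tsv(ct, file.path(dir, "contrast.tsv"), progress = FALSE)
  if (!is.null(report$sweep)) {
    readr::write_tsv(report$sweep, file.path(dir, "window_sweep.tsv"),
                     progress = FALSE)
  }
  if (!is.null(report$glm)) {
    readr::write_tsv(report$glm$contrast,
                     file.path(dir, "glm_contrast.tsv"), progress = FALSE)
    yaml::write_yaml(as.list(report$glm$params),
                     file.path(dir, "rf_params.yaml"))
  }
  invisible(dir)
}
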