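#' Configuration for the synthetic gaze generator
#'
#' Describes a delay threat-conditioning session as sampled by a 500-Hz
#' binocular tracker: trials of the three conditions in random order,
#' gaze alternating between center-biased fixations and main-sequence
#' saccades (saccade samples are emitted but flagged blank, mimicking the
#' tracker's exclusion of saccade stretches so that downstream
#' interpolation is consequential), occasional blinks masked as missing,
#' and per-sample oculomotor jitter.
#'
#' The conditioning effect is modeled on the observed mechanism: during
#' the final `effect_window_s` seconds before anticipated US onset of CS+
#' trials, fixation durations are multiplied by `csplus_fix_mult` (> 1:
#' fewer saccades) and the center-bias spread by `csplus_center_shrink`
#' (< 1: tighter around center), both jointly producing shorter CS+
#' scanpaths. Per-participant effect strength varies with
#' `between_sd` (SD of a multiplicative lognormal factor on the
#' fixation-duration effect).
#'
#' Defaults emulate the confirmatory visual-CS design: 3.5-s CS-US
#' interval, 4-s CS, 16/16/32 trials, 500 Hz, effect confined to the
#' final 2 s of the anticipation window.
#'
#' @param seed Integer seed.
#' @param n_participants Number of participants.
#' @param n_trials Named counts per condition.
#' @param soa_s CS-US interval (s).
#' @param cs_duration_s CS duration (s).
#' @param iti_s Range (length 2) of inter-trial intervals (s), drawn
#'   uniformly.
#' @param sampling_rate_hz Tracker sampling rate.
#' @param fix_mean_iti_ms,fix_mean_cs_ms Mean fixation duration during ITI
#'   (fixation cross shown) and during CS, in ms.
#' @param fix_shape Gamma shape of fixation durations.
#' @param center_sd_iti_mm,center_sd_cs_mm SD of the isotropic Gaussian
#'   center bias of fixation targets (truncated at the screen edges), mm.
#' @param csplus_fix_mult Fixation-duration multiplier in the CS+ effect
#'   window (1 = no effect).
#' @param csplus_center_shrink Center-bias SD multiplier in the CS+ effect
#'   window.
#' @param effect_window_s Length of the CS+ effect window before
#'   anticipated US onset (s).
#' @param between_sd SD of the per-participant lognormal factor on the
#'   fixation-duration effect.
#' @param saccade_a_ms,saccade_b_ms_deg Main-sequence intercept (ms) and
#'   slope (ms/deg): saccade duration = a + b * amplitude.
#' @param blink_rate_hz Blink rate (per second).
#' @param blink_dur_ms Range (length 2) of blink durations (ms).
#' @param jitter_sd_deg SD of per-sample isotropic gaze jitter (deg).
#' @param eye_noise_px SD of independent per-eye pixel noise.
#' @param screen A [screen_geometry()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_participants = 35,
                       n_trials = c(CSplus_USplus = 16, CSplus_USminus = 16,
                                    CSminus = 32),
                       soa_s = 3.5,
                       cs_duration_s = 4,
                       iti_s = c(2, 3),
                       sampling_rate_hz = 500,
                       fix_mean_iti_ms = 450,
                       fix_mean_cs_ms = 280,
                       fix_shape = 4,
                       center_sd_iti_mm = 12,
                       center_sd_cs_mm = 60,
                       csplus_fix_mult = 1.3,
                       csplus_center_shrink = 0.7,
                       effect_window_s = 2,
                       between_sd = 0.15,
                       saccade_a_ms = 21,
                       saccade_b_ms_deg = 2.2,
                       blink_rate_hz = 0.25,
                       blink_dur_ms = c(100, 300),
                       jitter_sd_deg = 0.02,
                       eye_noise_px = 0.5,
                       screen = screen_geometry(1152, 864, 156.21, 113.445,
                                                700, sampling_rate_hz)) {
  cfg <- as.list(environment())
  # YAML-parsed configs arrive as lists; normalize to named vectors
  cfg$n_trials <- n_trials <- unlist(n_trials)
  cfg$iti_s <- iti_s <- unlist(iti_s)
  cfg$blink_dur_ms <- blink_dur_ms <- unlist(blink_dur_ms)
  stopifnot(all(n_trials >= 0), soa_s > 0, cs_duration_s >= soa_s,
            sampling_rate_hz > 0, fix_shape > 0,
            all(c(fix_mean_iti_ms, fix_mean_cs_ms) > 0),
            csplus_fix_mult > 0, csplus_center_shrink > 0,
            effect_window_s <= soa_s)
  cfg$screen$sampling_rate_hz <- sampling_rate_hz
  structure(cfg, class = "sim_config")
}

# draw a fixation target: isotropic Gaussian around center, truncated to
# the screen with a small margin
draw_target <- function(sd_mm, screen) {
  mx <- screen$half_width_mm * 0.98
  my <- screen$half_height_mm * 0.98
  c(max(-mx, min(mx, stats::rnorm(1, 0, sd_mm))),
    max(-my, min(my, stats::rnorm(1, 0, sd_mm))))
}

# angular amplitude (deg) of a displacement on the screen; scalar-fast
# version of the pixels-to-spherical-to-arc chain
amplitude_deg <- function(p_from, p_to, screen) {
  d <- screen$distance_mm
  th1 <- atan2(d, p_from[1]) * 180 / pi
  ph1 <- atan(p_from[2] / sqrt(p_from[1]^2 + d^2)) * 180 / pi
  th2 <- atan2(d, p_to[1]) * 180 / pi
  ph2 <- atan(p_to[2] / sqrt(p_to[1]^2 + d^2)) * 180 / pi
  central_angle(th1, ph1, th2, ph2)
}

#' Simulate the event schedule of one participant
#'
#' @param cfg A [sim_config()].
#' @return A trial-event tibble (validated).
#' @export
simulate_schedule <- function(cfg) {
  conds <- sample(rep(names(cfg$n_trials), cfg$n_trials))
  n <- length(conds)
  iti <- stats::runif(n, cfg$iti_s[1], cfg$iti_s[2])
  trial_span <- cfg$cs_duration_s + iti
  onsets <- (cumsum(c(cfg$iti_s[2], trial_span))[seq_len(n)]) * 1000
  validate_events(tibble::tibble(
    trial_id = seq_len(n), condition = conds, cs_onset_ms = onsets,
    soa_s = cfg$soa_s, cs_duration_s = cfg$cs_duration_s))
}

#' Simulate one participant's gaze recording
#'
#' Generates a continuous fixation/saccade/blink process over the whole
#' session, samples it on the tracker grid, and returns the binocular
#' recording together with the ground-truth fixation events and the
#' participant's true effect multipliers.
#'
#' @param cfg A [sim_config()].
#' @param events Trial events from [simulate_schedule()].
#' @param fix_mult Participant-level fixation-duration effect multiplier
#'   (drawn by [simulate_cohort()]).
#' @return A list with `gaze` (binocular `gaze_recording`), `fixations`
#'   (truth tibble), `events`.
#' @export
simulate_participant_gaze <- function(cfg, events, fix_mult = NULL) {
  if (is.null(fix_mult)) fix_mult <- cfg$csplus_fix_mult
  scr <- cfg$screen
  t_end_ms <- max(events$cs_onset_ms) + cfg$cs_duration_s * 1000 +
    cfg$iti_s[2] * 1000
  # CS and CS+ effect intervals
  cs_lo <- events$cs_onset_ms
  cs_hi <- events$cs_onset_ms + events$cs_duration_s * 1000
  is_plus <- grepl("^CSplus", events$condition)
  eff_lo <- events$cs_onset_ms[is_plus] +
    (cfg$soa_s - cfg$effect_window_s) * 1000
  eff_hi <- events$cs_onset_ms[is_plus] + cfg$soa_s * 1000
  phase_at <- function(t) {
    if (any(t >= eff_lo & t < eff_hi)) "effect"
    else if (any(t >= cs_lo & t < cs_hi)) "cs"
    else "iti"
  }
  # build alternating fixation/saccade segment list
  seg_t0 <- seg_t1 <- seg_x0 <- seg_y0 <- seg_x1 <- seg_y1 <- numeric(0)
  seg_sacc <- logical(0)
  fix_onset <- fix_dur <- fix_x <- fix_y <- numeric(0)
  cur_t <- 0
  pos <- draw_target(cfg$center_sd_iti_mm, scr)
  while (cur_t < t_end_ms) {
    ph <- phase_at(cur_t)
    mean_ms <- switch(ph,
      iti = cfg$fix_mean_iti_ms,
      cs = cfg$fix_mean_cs_ms,
      effect = cfg$fix_mean_cs_ms * fix_mult)
    dur <- stats::rgamma(1, shape = cfg$fix_shape,
                         scale = mean_ms / cfg$fix_shape)
    # a fixation straddling the start of a CS+ effect window has its
    # in-window remainder lengthened, so the saccade-rate change is
    # aligned with the window rather than lagging it by one fixation
    if (ph != "effect") {
      cross <- eff_lo[eff_lo > cur_t & eff_lo <= cur_t + dur]
      if (length(cross) > 0) {
        dur <- (cross[1] - cur_t) + fix_mult * (cur_t + dur - cross[1])
      }
    }
    dur <- max(dur, 40) # physiological floor
    fix_onset <- c(fix_onset, cur_t); fix_dur <- c(fix_dur, dur)
    fix_x <- c(fix_x, pos[1]); fix_y <- c(fix_y, pos[2])
    seg_t0 <- c(seg_t0, cur_t); seg_t1 <- c(seg_t1, cur_t + dur)
    seg_x0 <- c(seg_x0, pos[1]); seg_y0 <- c(seg_y0, pos[2])
    seg_x1 <- c(seg_x1, pos[1]); seg_y1 <- c(seg_y1, pos[2])
    seg_sacc <- c(seg_sacc, FALSE)
    cur_t <- cur_t + dur
    # saccade to the next target
    ph <- phase_at(cur_t)
    sd_mm <- switch(ph,
      iti = cfg$center_sd_iti_mm,
      cs = cfg$center_sd_cs_mm,
      effect = cfg$center_sd_cs_mm * cfg$csplus_center_shrink)
    nxt <- draw_target(sd_mm, scr)
    amp <- amplitude_deg(pos, nxt, scr)
    sdur <- cfg$saccade_a_ms + cfg$saccade_b_ms_deg * amp
    seg_t0 <- c(seg_t0, cur_t); seg_t1 <- c(seg_t1, cur_t + sdur)
    seg_x0 <- c(seg_x0, pos[1]); seg_y0 <- c(seg_y0, pos[2])
    seg_x1 <- c(seg_x1, nxt[1]); seg_y1 <- c(seg_y1, nxt[2])
    seg_sacc <- c(seg_sacc, TRUE)
    cur_t <- cur_t + sdur
    pos <- nxt
  }
  # sample on the tracker grid
  dt_ms <- 1000 / cfg$sampling_rate_hz
  t_ms <- seq(0, t_end_ms, by = dt_ms)
  i <- findInterval(t_ms, seg_t0)
  i[i < 1] <- 1
  frac <- (t_ms - seg_t0[i]) / pmax(seg_t1[i] - seg_t0[i], 1e-9)
  frac <- pmin(pmax(frac, 0), 1)
  x_mm <- seg_x0[i] + frac * (seg_x1[i] - seg_x0[i])
  y_mm <- seg_y0[i] + frac * (seg_y1[i] - seg_y0[i])
  blank <- seg_sacc[i]
  # oculomotor jitter (tremor/drift), in mm via the small-angle tangent
  jit_mm <- tan(cfg$jitter_sd_deg * pi / 180) * scr$distance_mm
  x_mm <- x_mm + stats::rnorm(length(t_ms), 0, jit_mm)
  y_mm <- y_mm + stats::rnorm(length(t_ms), 0, jit_mm)
  # blinks: Poisson onsets, masked as missing
  n_blink <- stats::rpois(1, cfg$blink_rate_hz * t_end_ms / 1000)
  if (n_blink > 0) {
    b_on <- stats::runif(n_blink, 0, t_end_ms)
    b_dur <- stats::runif(n_blink, cfg$blink_dur_ms[1], cfg$blink_dur_ms[2])
    for (b in seq_len(n_blink)) {
      blank <- blank | (t_ms >= b_on[b] & t_ms < b_on[b] + b_dur[b])
    }
  }
  px <- mm_to_pixels(x_mm, y_mm, scr)
  mk_eye <- function() {
    list(x = px$x_px + stats::rnorm(length(t_ms), 0, cfg$eye_noise_px),
         y = px$y_px + stats::rnorm(length(t_ms), 0, cfg$eye_noise_px))
  }
  left <- mk_eye(); right <- mk_eye()
  xl <- left$x; yl <- left$y; xr <- right$x; yr <- right$y
  xl[blank] <- NA; yl[blank] <- NA; xr[blank] <- NA; yr[blank] <- NA
  gaze <- as_gaze_recording(tibble::tibble(
    time_ms = t_ms,
    xL_px = xl, yL_px = yl, blankL = as.integer(blank),
    xR_px = xr, yR_px = yr, blankR = as.integer(blank)),
    cfg$sampling_rate_hz)
  fixations <- tibble::tibble(onset_ms = fix_onset, duration_ms = fix_dur,
                              x_mm = fix_x, y_mm = fix_y)
  list(gaze = gaze, fixations = fixations, events = events)
}

#' Simulate a full cohort
#'
#' Draws per-participant effect multipliers, simulates every participant's
#' schedule and recording, and returns an in-memory bundle together with
#' the ground truth needed for recovery tests. Output is a deterministic
#' function of the config (including its seed).
#'
#' @param cfg A [sim_config()].
#' @return A named list (one element per participant `P01`, `P02`, ...),
#'   each with `gaze`, `events`, `fixations`; plus attribute `truth`, a
#'   tibble of per-participant true effect multipliers.
#' @export
simulate_cohort <- function(cfg) {
  set.seed(cfg$seed)
  ids <- sprintf("P%02d", seq_len(cfg$n_participants))
  mults <- cfg$csplus_fix_mult *
    exp(stats::rnorm(cfg$n_participants, 0, cfg$between_sd))
  out <- lapply(seq_along(ids), function(i) {
    ev <- simulate_schedule(cfg)
    simulate_participant_gaze(cfg, ev, fix_mult = mults[i])
  })
  names(out) <- ids
  attr(out, "truth") <- tibble::tibble(participant = ids,
                                       fix_mult = mults)
  attr(out, "config") <- cfg
  out
}

#' Write a simulated cohort to disk
#'
#' Writes, per participant, the canonical gaze, events and fixation CSVs,
#' plus a screen config YAML and a ground-truth YAML for the cohort.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- attr(cohort, "config")
  write_screen_config(cfg$screen, file.path(dir, "screen.yaml"))
  for (id in names(cohort)) {
    p <- cohort[[id]]
    readr::write_csv(tibble::as_tibble(p$gaze),
                     file.path(dir, paste0(id, "_gaze.csv")),
                     progress = FALSE)
    readr::write_csv(p$events, file.path(dir, paste0(id, "_events.csv")),
                     progress = FALSE)
    readr::write_csv(p$fixations,
                     file.path(dir, paste0(id, "_fixations.csv")),
                     progress = FALSE)
  }
  truth <- attr(cohort, "truth")
  yaml::write_yaml(list(participant = truth$participant,
                        fix_mult = truth$fix_mult),
                   file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Load a cohort previously written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return A cohort bundle in the in-memory layout of [simulate_cohort()].
#' @export
read_cohort <- function(dir) {
  screen <- read_screen_config(file.path(dir, "screen.yaml"))
  files <- list.files(dir, pattern = "_gaze\\.csv$")
  ids <- sub("_gaze\\.csv$", "", files)
  out <- lapply(ids, function(id) {
    list(gaze = read_gaze_table(file.path(dir, paste0(id, "_gaze.csv")),
                                screen),
         events = read_events_table(file.path(dir,
                                              paste0(id, "_events.csv"))),
         fixations = read_fixations_table(
           file.path(dir, paste0(id, "_fixations.csv"))))
  })
  names(out) <- ids
  attr(out, "screen") <- screen
  out
}
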