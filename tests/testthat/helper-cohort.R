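# shared fixtures, all generated in code

paper_screen <- function(rate = 500) {
  screen_geometry(1152, 864, 156.21, 113.445, 700, rate)
}

# small, fast cohort config for end-to-end tests
tiny_cfg <- function(seed = 1, n = 6, trials = c(CSplus_USplus = 2,
                                                 CSplus_USminus = 4,
                                                 CSminus = 4), ...) {
  sim_config(seed = seed, n_participants = n, n_trials = trials,
             sampling_rate_hz = 250, iti_s = c(1.5, 2), ...)
}

# preprocess a simulated cohort into {speed, events} per participant
preprocess_cohort <- function(cohort, screen) {
  lapply(cohort, function(p) {
    list(speed = preprocess_gaze(p$gaze, screen), events = p$events)
  })
}

# hand-rolled monocular recording on a uniform grid
make_mono <- function(t_ms, x_px, y_px, blank = 0L, rate = 500) {
  structure(
    tibble::tibble(time_ms = t_ms, x_px = x_px, y_px = y_px,
                   blank = as.integer(rep_len(blank, length(t_ms)))),
    sampling_rate_hz = rate, eye = "left",
    class = c("gaze_recording", class(tibble::tibble())))
}

# independent arc oracle: arccos of the dot product of unit gaze vectors
arc_oracle_deg <- function(th1, ph1, th2, ph2) {
  v <- function(th, ph) {
    th <- th * pi / 180; ph <- ph * pi / 180
    cbind(cos(ph) * cos(th), cos(ph) * sin(th), sin(ph))
  }
  d <- rowSums(v(th1, ph1) * v(th2, ph2))
  acos(pmin(pmax(d, -1), 1)) * 180 / pi
}

# random on-screen spherical points for geometry property tests
random_onscreen_spherical <- function(n, screen) {
  x <- stats::runif(n, -screen$half_width_mm, screen$half_width_mm)
  y <- stats::runif(n, -screen$half_height_mm, screen$half_height_mm)
  to_spherical(tibble::tibble(x_mm = x, y_mm = y,
                              z_mm = screen$distance_mm))
}
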