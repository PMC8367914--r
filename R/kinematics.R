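#' Linearly interpolate blank gaze stretches
#'
#' Blank samples (blinks, saccades, dropouts) are replaced by linear
#' interpolation of each pixel coordinate against time, matching the
#' exclude-then-interpolate treatment applied before any angular
#' computation. Blank stretches at the start or end of the record, where no
#' bracketing samples exist, are filled by holding the nearest valid value;
#' this keeps the trial usable while injecting zero artificial motion.
#'
#' @param rec A monocular `gaze_recording` (see [select_eye()]).
#' @return The recording with interpolated coordinates and no blanks; the
#'   original flags are kept in a `was_blank` column.
#' @export
interpolate_blanks <- function(rec) {
  stopifnot(all(c("time_ms", "x_px", "y_px", "blank") %in% names(rec)))
  ok <- rec$blank == 0
  if (sum(ok) < 2) {
    stop("need at least two non-blank samples to interpolate", call. = FALSE)
  }
  out <- rec
  if (any(!ok)) {
    for (col in c("x_px", "y_px")) {
      out[[col]] <- stats::approx(rec$time_ms[ok], rec[[col]][ok],
                                  xout = rec$time_ms, method = "linear",
                                  rule = 2)$y
    }
  }
  out$was_blank <- rec$blank
  out$blank <- 0L
  attributes(out)[c("sampling_rate_hz", "eye")] <-
    attributes(rec)[c("sampling_rate_hz", "eye")]
  out
}

#' Gaze direction in spherical coordinates
#'
#' Projects screen-plane gaze points `(x_mm, y_mm, z_mm)` (nasion at the
#' origin, `z` the viewing distance) onto direction angles. The azimuth
#' `theta` is the counterclockwise angle in the horizontal x-z plane from
#' the positive x axis, with `theta = 90` degrees for straight-ahead gaze;
#' the elevation `phi` is the angle from the x-z plane,
#' `phi = arctan(y / sqrt(x^2 + z^2))`. Radial distance carries no
#' information about gaze direction and is discarded.
#'
#' `theta` is computed with the two-argument arctangent `atan2(z, x)`,
#' which equals the piecewise `arctan(z/x)` definition on both half-planes
#' and gives `theta = 90` degrees at `x = 0` without a special case.
#'
#' @param planar A tibble from [pixels_to_mm()] (columns `x_mm`, `y_mm`,
#'   `z_mm` with `z_mm > 0`).
#' @return A tibble with `theta_deg` in (0, 180) and `phi_deg` in (-90, 90).
#' @export
to_spherical <- function(planar) {
  stopifnot(all(c("x_mm", "y_mm", "z_mm") %in% names(planar)))
  if (any(planar$z_mm <= 0)) {
    stop("viewing distance z_mm must be strictly positive", call. = FALSE)
  }
  tibble::tibble(
    theta_deg = atan2(planar$z_mm, planar$x_mm) * 180 / pi,
    phi_deg = atan(planar$y_mm / sqrt(planar$x_mm^2 + planar$z_mm^2)) *
      180 / pi
  )
}

#' Great-circle central angle between gaze directions
#'
#' Computes the central angle between pairs of gaze directions with the
#' Haversine formula,
#' `a = sin^2(dphi/2) + cos(phi1) cos(phi2) sin^2(dtheta/2)`,
#' `angle = 2 atan(sqrt(a) / sqrt(1 - a))`,
#' which is numerically stable for the small angles typical of adjacent
#' gaze samples. `a` is clamped to `[0, 1 - 1e-12]` with a warning before
#' the second step; near-antipodal pairs cannot arise for on-screen gaze.
#'
#' @param theta1,phi1,theta2,phi2 Numeric vectors of azimuth/elevation in
#'   degrees (recycled to a common length).
#' @return Central angles in degrees, in `[0, 180)`.
#' @export
central_angle <- function(theta1, phi1, theta2, phi2) {
  t1 <- theta1 * pi / 180; p1 <- phi1 * pi / 180
  t2 <- theta2 * pi / 180; p2 <- phi2 * pi / 180
  a <- sin((p2 - p1) / 2)^2 + cos(p1) * cos(p2) * sin((t2 - t1) / 2)^2
  if (any(a >= 1 - 1e-12)) {
    warning("near-antipodal gaze pair: Haversine intermediate clamped")
    a <- pmin(a, 1 - 1e-12)
  }
  a <- pmax(a, 0)
  2 * atan2(sqrt(a), sqrt(1 - a)) * 180 / pi
}

#' Scan speed series of a gap-free recording
#'
#' For each pair of adjacent samples, converts pixels to physical
#' coordinates, then to spherical angles, and computes the great-circle arc
#' between them; dividing by the inter-sample interval gives the angular
#' scan speed in degrees per second. Each step is assigned to the later
#' sample's timestamp, which makes windowed sums over half-open windows
#' exactly additive. No filtering is applied.
#'
#' @param rec A gap-free monocular `gaze_recording` (see
#'   [interpolate_blanks()]).
#' @param screen A [screen_geometry()].
#' @return A `scan_speed_series` tibble with columns `t_ms` (later-sample
#'   timestamps), `arc_deg` (per-step central angle) and `v_deg_s`; length
#'   is one less than the number of samples.
#' @export
scan_speed_series <- function(rec, screen) {
  n <- nrow(rec)
  if (n < 2) stop("need at least two samples", call. = FALSE)
  dt_s <- diff(rec$time_ms) / 1000
  if (any(dt_s <= 0)) stop("non-positive inter-sample interval", call. = FALSE)
  planar <- pixels_to_mm(rec$x_px, rec$y_px, screen)
  sph <- to_spherical(planar)
  arc <- central_angle(sph$theta_deg[-n], sph$phi_deg[-n],
                       sph$theta_deg[-1], sph$phi_deg[-1])
  structure(
    tibble::tibble(t_ms = rec$time_ms[-1], arc_deg = arc,
                   v_deg_s = arc / dt_s),
    sampling_rate_hz = attr(rec, "sampling_rate_hz"),
    class = c("scan_speed_series", class(tibble::tibble()))
  )
}

#' Epoch a scan-speed series into trial segments
#'
#' Cuts a continuous per-participant scan-speed series into per-trial
#' segments over a window stated relative to CS onset. Assignment uses
#' half-open intervals `[t_start, t_end)` on the later-sample timestamps,
#' so partitioning a window partitions its arcs.
#'
#' @param speed A `scan_speed_series` from [scan_speed_series()].
#' @param events A trial-event tibble (see [read_events_table()]).
#' @param window_ms Numeric length-2: start and end of the window in ms
#'   relative to each trial's CS onset.
#' @return A tibble with one row per speed sample in any trial window:
#'   `trial_id`, `condition`, `t_rel_ms` (time from CS onset), `arc_deg`,
#'   `v_deg_s`.
#' @export
epoch_trials <- function(speed, events, window_ms) {
  stopifnot(length(window_ms) == 2, window_ms[1] < window_ms[2])
  lo <- events$cs_onset_ms + window_ms[1]
  hi <- events$cs_onset_ms + window_ms[2]
  t0 <- min(speed$t_ms); t1 <- max(speed$t_ms)
  out_of_range <- lo < t0 | hi > t1 + 1e-9
  if (any(out_of_range)) {
    stop("trial window exceeds recording bounds for trial(s): ",
         paste(events$trial_id[out_of_range], collapse = ", "),
         call. = FALSE)
  }
  segs <- lapply(seq_len(nrow(events)), function(i) {
    keep <- speed$t_ms >= lo[i] & speed$t_ms < hi[i]
    tibble::tibble(
      trial_id = events$trial_id[i],
      condition = events$condition[i],
      t_rel_ms = speed$t_ms[keep] - events$cs_onset_ms[i],
      arc_deg = speed$arc_deg[keep],
      v_deg_s = speed$v_deg_s[keep]
    )
  })
  dplyr::bind_rows(segs)
}

#' Centered moving-average smoothing (visualization only)
#'
#' Moving average with an odd span and shrinking symmetric windows at the
#' edges (the first and last points are untouched, the second uses three
#' points, and so on). Used only for plotting and for developing the
#' response function; the windowed scanpath statistic always uses raw
#' speeds.
#'
#' @param x Numeric series.
#' @param span Odd window length in samples (e.g. 501 at 500 Hz, about 1 s).
#' @return The smoothed series, same length as `x`.
#' @export
smooth_for_viz <- function(x, span) {
  if (span %% 2 == 0) stop("span must be odd", call. = FALSE)
  n <- length(x)
  if (span > n) stop("span exceeds series length", call. = FALSE)
  if (span == 1) return(x)
  half <- (span - 1) / 2
  cs <- cumsum(c(0, x))
  k <- pmin(half, seq_len(n) - 1, n - seq_len(n))
  lo <- seq_len(n) - k
  hi <- seq_len(n) + k
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
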