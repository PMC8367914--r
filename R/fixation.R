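#' Fixations within the CS-US anticipation window
#'
#' Retains fixations whose onset falls in `[cs_onset, cs_onset + soa)` of
#' any analyzed (non-reinforced) trial and labels them with the trial's
#' condition. A fixation spanning the anticipated US onset is kept with its
#' duration truncated at the window end rather than excluded, so late
#' fixations are not systematically lost.
#'
#' @param fixations Tibble of fixation events (`onset_ms`, `duration_ms`,
#'   `x_mm`, `y_mm`; see [read_fixations_table()]).
#' @param events Trial-event tibble.
#' @param conditions Conditions to retain (default: the analyzed,
#'   non-reinforced ones).
#' @return The retained fixations with `trial_id`, `condition` and
#'   truncated `duration_ms`.
#' @export
fixations_in_window <- function(fixations, events,
                                conditions = analyzed_conditions()) {
  ev <- events[events$condition %in% conditions, , drop = FALSE]
  out <- lapply(seq_len(nrow(ev)), function(i) {
    lo <- ev$cs_onset_ms[i]
    hi <- ev$cs_onset_ms[i] + ev$soa_s[i] * 1000
    keep <- fixations$onset_ms >= lo & fixations$onset_ms < hi
    f <- fixations[keep, , drop = FALSE]
    f$duration_ms <- pmin(f$duration_ms, hi - f$onset_ms)
    f$trial_id <- ev$trial_id[i]
    f$condition <- ev$condition[i]
    f
  })
  dplyr::bind_rows(out)
}

#' Euclidean distance of fixation points from screen center
#'
#' @param fixations Tibble with `x_mm`, `y_mm` in screen-centered
#'   coordinates.
#' @return Numeric vector of distances (mm).
#' @export
center_distances <- function(fixations) {
  sqrt(fixations$x_mm^2 + fixations$y_mm^2)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares two empirical distributions (fixation durations or center
#' distances, pooled across participants within condition) with the
#' two-sided two-sample KS test: `D` is the exact supremum distance
#' between the empirical CDFs and `p` the asymptotic two-sided p value.
#'
#' @param sample1,sample2 Numeric vectors (non-empty).
#' @return A list with `D`, `p`, `n1`, `n2`.
#' @export
ks_compare <- function(sample1, sample2) {
  if (length(sample1) < 1 || length(sample2) < 1) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  res <- suppressWarnings(
    stats::ks.test(sample1, sample2, alternative = "two.sided",
                   exact = FALSE))
  list(D = unname(res$statistic), p = res$p.value,
       n1 = length(sample1), n2 = length(sample2))
}

#' Fixation heat map on a fixed grid over the screen
#'
#' Bins fixation coordinates on a 64 x 48 grid spanning the physical
#' screen extents. Binning is presentation-only and does not feed any
#' statistic.
#'
#' @param fixations Tibble with `x_mm`, `y_mm`.
#' @param screen A [screen_geometry()].
#' @param nx,ny Grid dimensions.
#' @return An `ny` x `nx` count matrix (rows run from top of screen down).
#' @export
fixation_heatmap <- function(fixations, screen, nx = 64, ny = 48) {
  bx <- seq(-screen$half_width_mm, screen$half_width_mm, length.out = nx + 1)
  by <- seq(-screen$half_height_mm, screen$half_height_mm,
            length.out = ny + 1)
  ix <- findInterval(pmin(pmax(fixations$x_mm, bx[1]), bx[nx + 1]), bx,
                     rightmost.closed = TRUE)
  iy <- findInterval(pmin(pmax(fixations$y_mm, by[1]), by[ny + 1]), by,
                     rightmost.closed = TRUE)
  m <- matrix(0L, nrow = ny, ncol = nx)
  for (i in seq_along(ix)) {
    r <- ny - iy[i] + 1
    m[r, ix[i]] <- m[r, ix[i]] + 1L
  }
  m
}
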