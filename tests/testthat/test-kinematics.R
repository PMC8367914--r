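test_that("blank stretches are linearly interpolated, edges held", {
  rec <- make_mono(t_ms = seq(0, 10, by = 2),
                   x_px = c(10, 0, 0, 0, 0, 20),
                   y_px = c(5, 0, 0, 0, 0, 5),
                   blank = c(0L, 1L, 1L, 1L, 1L, 0L))
  out <- interpolate_blanks(rec)
  expect_equal(out$x_px, c(10, 12, 14, 16, 18, 20))
  expect_equal(out$y_px, rep(5, 6))
  expect_equal(out$blank, rep(0L, 6))
  # identity when nothing is blank
  clean <- make_mono(seq(0, 8, 2), 1:5, 5:1)
  expect_equal(interpolate_blanks(clean)$x_px, 1:5)
  # leading/trailing blanks held at nearest valid value
  edge <- make_mono(seq(0, 8, 2), c(0, 7, 8, 9, 0), c(0, 1, 1, 1, 0),
                    blank = c(1L, 0L, 0L, 0L, 1L))
  filled <- interpolate_blanks(edge)
  expect_equal(filled$x_px, c(7, 7, 8, 9, 9))
  # fewer than two valid samples is an error
  expect_error(interpolate_blanks(
    make_mono(seq(0, 8, 2), 1:5, 1:5, blank = c(0L, 1L, 1L, 1L, 1L))),
    "two non-blank")
})

test_that("spherical transform matches the printed identities", {
  # straight-ahead gaze
  ctr <- to_spherical(tibble::tibble(x_mm = 0, y_mm = 0, z_mm = 700))
  expect_equal(ctr$theta_deg, 90)
  expect_equal(ctr$phi_deg, 0)
  # 45 degrees in the horizontal plane
  diag <- to_spherical(tibble::tibble(x_mm = 700, y_mm = 0, z_mm = 700))
  expect_equal(diag$theta_deg, 45)
  # screen corner, independent arithmetic oracle
  corner <- to_spherical(tibble::tibble(x_mm = 156.21, y_mm = -113.445,
                                        z_mm = 700))
  expect_equal(corner$theta_deg, 77.42016, tolerance = 1e-6)
  expect_equal(corner$phi_deg, -8.988219, tolerance = 1e-6)
  expect_error(to_spherical(tibble::tibble(x_mm = 0, y_mm = 0, z_mm = -1)),
               "positive")
})

test_that("Haversine central angle agrees with the arccos-dot oracle", {
  expect_equal(central_angle(90, 0, 90, 0), 0)
  expect_equal(central_angle(90, 0, 90, 10), 10) # meridian arc
  expect_equal(central_angle(77.42016, -8.988219, 90, 0), 15.41869,
               tolerance = 1e-6)
  scr <- paper_screen()
  set.seed(7)
  p1 <- random_onscreen_spherical(20000, scr)
  p2 <- random_onscreen_spherical(20000, scr)
  got <- central_angle(p1$theta_deg, p1$phi_deg, p2$theta_deg, p2$phi_deg)
  want <- arc_oracle_deg(p1$theta_deg, p1$phi_deg, p2$theta_deg, p2$phi_deg)
  expect_lt(max(abs(got - want)), 1e-9)
  # symmetry
  expect_equal(central_angle(p2$theta_deg, p2$phi_deg,
                             p1$theta_deg, p1$phi_deg), got)
})

test_that("central angle obeys the triangle inequality on-screen", {
  scr <- paper_screen()
  set.seed(8)
  a <- random_onscreen_spherical(2000, scr)
  b <- random_onscreen_spherical(2000, scr)
  c <- random_onscreen_spherical(2000, scr)
  ac <- central_angle(a$theta_deg, a$phi_deg, c$theta_deg, c$phi_deg)
  ab <- central_angle(a$theta_deg, a$phi_deg, b$theta_deg, b$phi_deg)
  bc <- central_angle(b$theta_deg, b$phi_deg, c$theta_deg, c$phi_deg)
  expect_true(all(ac <= ab + bc + 1e-12))
})

test_that("scan speed is arc over time with later-sample alignment", {
  scr <- paper_screen()
  # stationary gaze -> zero speed
  still <- make_mono(seq(0, 20, 2), rep(600, 11), rep(400, 11))
  s <- scan_speed_series(still, scr)
  expect_equal(nrow(s), 10)
  expect_true(all(s$v_deg_s == 0))
  expect_equal(s$t_ms, seq(2, 20, 2)) # later-sample timestamps
  # known arc over 2 ms: 0.02 deg -> 10 deg/s
  expect_equal(0.02 / 0.002, 10)
  # horizontal path: integrated arc equals summed |dtheta|
  x <- seq(100, 900, length.out = 201)
  horiz <- make_mono(seq(0, 400, 2), x, rep(432, 201))
  sp <- scan_speed_series(horiz, scr)
  sph <- to_spherical(pixels_to_mm(x, rep(432, 201), scr))
  expect_equal(sum(sp$arc_deg), sum(abs(diff(sph$theta_deg))),
               tolerance = 1e-9)
  # constant time offset leaves speeds unchanged
  shifted <- make_mono(seq(1000, 1400, 2), x, rep(432, 201))
  expect_equal(scan_speed_series(shifted, scr)$v_deg_s, sp$v_deg_s)
  # x -> -x reflection (theta -> 180 - theta) leaves speeds unchanged
  mirror <- make_mono(seq(0, 400, 2), 1152 - x, rep(432, 201))
  expect_equal(scan_speed_series(mirror, scr)$v_deg_s, sp$v_deg_s,
               tolerance = 1e-9)
})

test_that("a synthetic 10-degree saccade yields about 250 deg/s mean speed", {
  scr <- paper_screen()
  # 10 deg amplitude along the horizontal meridian, executed over 40 ms
  th0 <- 90; th1 <- 100
  x0_mm <- scr$distance_mm / tan(th0 * pi / 180 + 1e-12)
  x1_mm <- scr$distance_mm / tan(th1 * pi / 180)
  t_ms <- seq(0, 40, by = 2)
  x_mm <- seq(x0_mm, x1_mm, length.out = length(t_ms))
  px <- mm_to_pixels(x_mm, rep(0, length(t_ms)), scr)
  rec <- make_mono(t_ms, px$x_px, px$y_px)
  sp <- scan_speed_series(rec, scr)
  total_arc <- sum(sp$arc_deg)
  expect_equal(total_arc, 10, tolerance = 0.01)
  expect_equal(total_arc / 0.040, 250, tolerance = 0.01)
})

test_that("epoching uses half-open windows indexed by trial", {
  scr <- paper_screen()
  n <- 2501 # 5 s at 500 Hz
  rec <- make_mono(seq(0, by = 2, length.out = n), rep(500, n), rep(400, n))
  sp <- scan_speed_series(rec, scr)
  ev <- validate_events(tibble::tibble(
    trial_id = 1:2, condition = c("CSplus_USminus", "CSminus"),
    cs_onset_ms = c(500, 3000), soa_s = 1, cs_duration_s = 1.5))
  ep <- epoch_trials(sp, ev, window_ms = c(0, 1000))
  expect_equal(sum(ep$trial_id == 1), 500) # 1 s at 500 Hz, half-open
  expect_equal(sum(ep$trial_id == 2), 500)
  expect_true(all(ep$t_rel_ms >= 0 & ep$t_rel_ms < 1000))
  # disjoint trials give disjoint segments
  expect_equal(nrow(ep), 1000)
  # window past the end of the recording errors and names the trial
  expect_error(epoch_trials(sp, ev, window_ms = c(0, 3000)), "2")
})

test_that("moving-average smoothing shrinks symmetrically at edges", {
  expect_equal(smooth_for_viz(rep(3, 100), 11), rep(3, 100))
  x <- rnorm(50)
  expect_equal(smooth_for_viz(x, 1), x)
  expect_error(smooth_for_viz(x, 10), "odd")
  # impulse of height 501 -> plateau of height 1 across the center window
  imp <- rep(0, 2001)
  imp[1001] <- 501
  sm <- smooth_for_viz(imp, 501)
  expect_equal(sm[1001], 1)
  expect_equal(sm[1001 + 250], 1)
  expect_equal(sm[1001 - 250], 1)
  expect_equal(sm[1001 + 251], 0)
  # edge windows shrink symmetrically: second point averages 3 samples
  y <- c(1, 2, 6, 2, 1)
  expect_equal(smooth_for_viz(y, 5), c(1, 3, 12 / 5, 3, 1))
})
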