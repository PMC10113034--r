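test_that("coefficient of variation follows the printed formula", {
  expect_equal(coefficient_of_variation(rep(5, 10)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), 100 * sqrt(2) / 2)
  x <- runif(20, 1, 4)
  expect_equal(coefficient_of_variation(x), coefficient_of_variation(7 * x))
  expect_true(is.na(coefficient_of_variation(3)))
  expect_true(is.na(coefficient_of_variation(c(-1, 1))))
})

straight_to_odour <- function(n = 200, fps = 10, bl = 4) {
  sp <- array(NA_real_, c(n, 12, 2))
  u <- (0:11) / 11
  for (f in seq_len(n)) {
    sp[f, , 1] <- (f - 1) * 0.2 + u * bl
    sp[f, , 2] <- 20
  }
  track_record(sp, fps)
}

test_that("attribute record covers the catalogue with correct trivials", {
  tr <- straight_to_odour()
  stim <- stimulus_context(c(1000, 20))   # far ahead on the crawl line
  att <- compute_attributes(tr, stimulus = stim)
  expect_true(all(rf_attribute_names() %in% colnames(att)))
  expect_equal(att$bending_angle, 0, tolerance = 1e-6)
  expect_equal(att$bearing_angle, 0, tolerance = 1e-6)
  expect_equal(att$heading_angle, 0, tolerance = 1e-6)
  expect_equal(att$abs_bearing_angle, 0, tolerance = 1e-6)
  expect_equal(att$hc_rate, 0)
  expect_equal(att$body_length_mm, 4, tolerance = 1e-6)
  # unit coherence: bl attributes equal mm attributes over body length
  expect_equal(att$midpoint_speed_bl,
               att$midpoint_speed_mm / att$body_length_mm)

  # hc rate with injected events: 6 HCs in a 60 s track -> 0.1 /s
  tr2 <- straight_to_odour(n = 600)
  ev <- detect_events(tr2)
  ev$hcs <- data.frame(start_frame = seq(50, 550, by = 100),
                       end_frame = seq(55, 555, by = 100),
                       side = "left", hc_angle_deg = 20)
  att2 <- compute_attributes(tr2, events = ev)
  expect_equal(att2$hc_rate, 0.1)
  expect_equal(att2$abs_hc_angle, 20)
  expect_equal(att2$cv_abs_hc_angle, 0)
})

test_that("HC rate modulation follows the toward/away definition", {
  # the track crawls past the odour source: toward for the first half,
  # away for the second, with one HC in each half
  n <- 400
  tr <- straight_to_odour(n = n)     # tail x = 0.2 * (frame - 1)
  ev <- detect_events(tr)
  odour_x <- 0.2 * (n / 2)           # bearing flips sign mid-track
  ev$hcs <- data.frame(start_frame = c(50, 250), end_frame = c(55, 255),
                       side = "left", hc_angle_deg = 20)
  att <- compute_attributes(tr, events = ev,
                            stimulus = stimulus_context(c(odour_x, 20)))
  # equal counts over (nearly) equal times: modulation ~ 0
  expect_lt(abs(att$hc_rate_modulation), 0.05)

  # both HCs while heading toward: rate_away = 0 -> modulation -1
  ev$hcs$start_frame <- c(50, 120); ev$hcs$end_frame <- c(55, 125)
  att2 <- compute_attributes(tr, events = ev,
                             stimulus = stimulus_context(c(odour_x, 20)))
  expect_equal(att2$hc_rate_modulation, -1)
  # and both while heading away -> +1
  ev$hcs$start_frame <- c(250, 320); ev$hcs$end_frame <- c(255, 325)
  att3 <- compute_attributes(tr, events = ev,
                             stimulus = stimulus_context(c(odour_x, 20)))
  expect_equal(att3$hc_rate_modulation, 1)
})

test_that("IS cycle identity holds on simulated tracks", {
  p <- larva_params(hc_rate_hz = 0, rng_seed = 8)
  gt <- simulate_track(p, 40, 16, c(0, 0), 0)
  ev <- detect_events(as_track_record(gt))
  att <- compute_attributes(as_track_record(gt), events = ev)
  expect_equal(att$is_speed_bl * att$is_interval, att$is_distance_bl,
               tolerance = 0.05)
  expect_equal(att$is_distance_bl,
               att$is_distance_mm / att$body_length_mm, tolerance = 1e-6)
})

test_that("mirroring negates signed attributes and fixes absolutes", {
  p <- larva_params(hc_rate_hz = 0.08, hc_amplitude_deg = 40, rng_seed = 13)
  gt <- simulate_track(p, 60, 16, c(0, 0), 20)
  tr <- as_track_record(gt)
  trm <- tr; trm$spine[, , 2] <- -trm$spine[, , 2]
  a <- compute_attributes(tr); am <- compute_attributes(trm)
  for (nm in c("bending_angle", "hv_angular_speed", "tv_angular_speed",
               "is_angle", "hc_angle"))
    expect_equal(am[[nm]], -a[[nm]], tolerance = 1e-6, label = nm)
  for (nm in c("abs_bending_angle", "abs_hv_angular_speed", "abs_is_angle",
               "abs_hc_angle", "is_interval", "distance_travelled_bl",
               "tail_forward_velocity"))
    expect_equal(am[[nm]], a[[nm]], tolerance = 1e-6, label = nm)
})

test_that("calibration scaling moves mm attributes and fixes bl ones", {
  # period incommensurate with the frame grid: exactly tied crest samples
  # would otherwise break ties differently after rescaling
  p <- larva_params(hc_rate_hz = 0, peristaltic_period_s = 0.93, rng_seed = 8)
  gt <- simulate_track(p, 30, 16, c(0, 0), 0)
  tr <- as_track_record(gt)
  k <- 1.7
  trs <- tr; trs$spine <- trs$spine * k   # same video, rescaled calibration
  a <- compute_attributes(tr); as_ <- compute_attributes(trs)
  expect_equal(as_$body_length_mm, k * a$body_length_mm, tolerance = 1e-6)
  expect_equal(as_$midpoint_speed_mm, k * a$midpoint_speed_mm,
               tolerance = 1e-6)
  expect_equal(as_$midpoint_speed_bl, a$midpoint_speed_bl, tolerance = 1e-6)
  expect_equal(as_$is_distance_bl, a$is_distance_bl, tolerance = 1e-4)
  expect_equal(as_$distance_travelled_bl, a$distance_travelled_bl,
               tolerance = 1e-6)
})

test_that("delta values difference interval means", {
  x <- c(rep(3, 50), rep(5, 50))
  expect_equal(delta_values(x, fps = 10, during = c(5, 10), before = c(0, 5)), 2)
  expect_equal(delta_values(x, fps = 10, during = c(0, 5), before = c(0, 5)), 0)
  expect_equal(delta_values(rep(4, 100), 10, c(6, 9), c(1, 3)), 0)
})

test_that("peak values contrast the centre window with its flanks", {
  fps <- 10
  x <- rep(0, 300); x[101:200] <- 10   # 10 s pulse centred on t = 15 s
  expect_equal(peak_values(x, fps, switch_s = 15), 10, tolerance = 0.2,
               ignore_attr = TRUE)
  expect_equal(peak_values(rep(7, 300), fps, 15), 0, ignore_attr = TRUE)
  # triangular pulse: oracle = direct window means
  tt <- (0:299) / fps
  tri <- pmax(0, 1 - abs(tt - 15) / 5)
  oracle <- mean(tri[tt >= 10 & tt < 20]) -
    mean(tri[(tt >= 5 & tt < 10) | (tt >= 20 & tt < 25)])
  expect_equal(peak_values(tri, fps, 15), oracle, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(attr(peak_values(tri, fps, 3), "truncated"))
})

test_that("binned series pool animals with confidence intervals", {
  fps <- 10
  tracks <- list(rep(2, 100), rep(2, 100), rep(2, 100))
  b <- bin_series(tracks, fps, bin_s = 2)
  expect_true(all(b$mean == 2))
  expect_true(all(b$ci_hi - b$ci_lo < 1e-9))
  expect_true(all(b$n == 3))

  # switch alignment: both animals land their switch in bin 0
  tr2 <- list(c(rep(0, 300), rep(9, 100)), c(rep(0, 400), rep(9, 200)))
  b2 <- bin_series(tr2, fps, bin_s = 2, align = "to_switch",
                   switch_s = c(30, 40))
  bin0 <- b2[b2$bin_start_s == 0, ]
  expect_equal(bin0$mean, 9)
  expect_equal(bin0$n, 2)
  # animals without a switch are dropped
  b3 <- bin_series(tr2, fps, bin_s = 2, align = "to_switch",
                   switch_s = c(30, NA))
  expect_true(all(b3$n <= 1))

  # HC-rate bins: 1 HC frame among 20 frames -> 0.05
  hc <- list(c(rep(FALSE, 19), TRUE))
  bh <- bin_series(hc, fps = 10, bin_s = 2, hc_rate = TRUE)
  expect_equal(bh$mean, 0.05)
})

test_that("orientation change histogram brackets reorientations", {
  fps <- 10
  mk <- function(turn_deg) {
    n <- 300
    sp <- array(NA_real_, c(n, 12, 2)); u <- (0:11) / 11
    for (f in seq_len(n)) {
      th <- if (f > 150) turn_deg * pi / 180 else 0
      dir <- c(cos(th), -sin(th))
      sp[f, , 1] <- 10 + u * 4 * dir[1]
      sp[f, , 2] <- 10 + u * 4 * dir[2]
    }
    smooth_and_differentiate(track_record(sp, fps))
  }
  h0 <- orientation_change_histogram(list(mk(0)), list(15))
  expect_equal(h0$pct[1], 100)
  # 110 deg turn sits mid-bracket, away from the smoothing-blurred boundary
  h100 <- orientation_change_histogram(list(mk(110)), list(15))
  expect_equal(h100$pct[h100$bracket_lo == 100], 100)
  expect_equal(sum(h100$pct), 100)
  # truncated windows are skipped
  htr <- orientation_change_histogram(list(mk(110)), list(2))
  expect_equal(sum(htr$count), 0)
})
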