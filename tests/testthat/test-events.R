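# build a track whose 12 spine points follow a prescribed rigid motion
rigid_track <- function(n, fps, pos_fun, angle_fun = function(t) 0, bl = 4) {
  sp <- array(NA_real_, c(n, 12, 2))
  u <- (0:11) / 11
  for (f in seq_len(n)) {
    t <- (f - 1) / fps
    th <- angle_fun(t) * pi / 180
    dir <- c(cos(th), -sin(th))    # left-positive heading
    tailp <- pos_fun(t)
    sp[f, , 1] <- tailp[1] + u * bl * dir[1]
    sp[f, , 2] <- tailp[2] + u * bl * dir[2]
  }
  track_record(sp, fps)
}

# minimal hand-built motion series for detector unit tests
fake_series <- function(tail_fwd_mm, fps = 10, bl = 4,
                        hv_speed = NULL, tv_speed = NULL, bending = NULL,
                        midpoint = NULL) {
  n <- length(tail_fwd_mm)
  structure(list(
    n = n, fps = fps, bl_mm = bl, valid = rep(TRUE, n),
    t = (seq_len(n) - 1) / fps,
    tail_fwd_mm = tail_fwd_mm, tail_fwd_bl = tail_fwd_mm / bl,
    hv_angular_speed = hv_speed %||% rep(0, n),
    tv_angular_speed = tv_speed %||% rep(0, n),
    bending = bending %||% rep(0, n),
    midpoint = midpoint %||% cbind(cumsum(tail_fwd_mm) / fps, rep(0, n))),
    class = "motion_series")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("velocities project displacement on the body vectors", {
  fps <- 10
  # translation along the body axis at 2 mm/s
  tr <- rigid_track(60, fps, function(t) c(2 * t, 10))
  s <- smooth_and_differentiate(tr)
  core <- 10:50
  expect_equal(mean(s$tail_fwd_mm[core]), 2, tolerance = 0.01)
  expect_equal(mean(s$head_fwd_mm[core]), 2, tolerance = 0.01)
  expect_equal(mean(s$mid_speed_mm[core]), 2, tolerance = 0.01)
  expect_equal(mean(s$tail_fwd_bl[core]), 0.5, tolerance = 0.01)

  # motion perpendicular to the body axis: zero forward velocity
  tr2 <- rigid_track(60, fps, function(t) c(10, 5 + 2 * t))
  s2 <- smooth_and_differentiate(tr2)
  expect_equal(mean(abs(s2$tail_fwd_mm[core])), 0, tolerance = 0.01)

  # rigid rotation at 100 deg/s to the right
  tr3 <- rigid_track(60, fps, function(t) c(10, 10),
                     angle_fun = function(t) -100 * t)
  s3 <- smooth_and_differentiate(tr3)
  expect_equal(mean(s3$hv_angular_speed[core]), 100, tolerance = 0.02)
  expect_equal(mean(s3$tv_angular_speed[core]), 100, tolerance = 0.02)

  # too-short track flagged
  expect_equal(smooth_and_differentiate(rigid_track(2, fps, function(t) c(0, 0)))$n, 0)
})

test_that("head casts honour threshold and both discard rules", {
  fps <- 10; n <- 100
  hv <- rep(0, n); hv[31:40] <- 40          # +40 deg/s for 1 s -> right HC
  bend <- cumsum(-hv / fps)                 # consistent bending trace
  s <- fake_series(rep(2, n), fps, hv_speed = hv, bending = bend)
  hcs <- detect_head_casts(s, steps = data.frame(frame = integer(0)))
  expect_equal(nrow(hcs), 1)
  expect_equal(hcs$side, "right")
  expect_equal(hcs$start_frame, 31)
  expect_equal(hcs$hc_angle_deg, bend[40] - bend[31])

  # discard rule 1: TV angular speed beyond 45 deg/s inside
  tv <- rep(0, n); tv[35] <- 50
  s1 <- fake_series(rep(2, n), fps, hv_speed = hv, tv_speed = tv)
  expect_equal(nrow(detect_head_casts(s1, data.frame(frame = integer(0)))), 0)

  # discard rule 2: two steps inside the candidate
  s2 <- fake_series(rep(2, n), fps, hv_speed = hv)
  expect_equal(nrow(detect_head_casts(s2, data.frame(frame = c(33, 37)))), 0)
  expect_equal(nrow(detect_head_casts(s2, data.frame(frame = 35))), 1)

  # below threshold: +30 deg/s sustained is no HC
  s3 <- fake_series(rep(2, n), fps, hv_speed = rep(30, n))
  expect_equal(nrow(detect_head_casts(s3, data.frame(frame = integer(0)))), 0)

  # left HC at negative angular speed
  s4 <- fake_series(rep(2, n), fps, hv_speed = -hv)
  expect_equal(detect_head_casts(s4, data.frame(frame = integer(0)))$side, "left")
})

test_that("run mask excludes 1.5 s around each HC and merges windows", {
  fps <- 10
  mask <- classify_runs(data.frame(start_frame = 101, end_frame = 111),
                        200, fps)
  # exclusion covers [10 - 1.5, 11 + 1.5] s = frames 86..126
  expect_true(all(!mask[86:126]))
  expect_true(all(mask[1:85]))
  expect_true(all(mask[127:200]))

  expect_true(all(classify_runs(data.frame(start_frame = integer(0),
                                           end_frame = integer(0)),
                                50, fps)))

  # two HCs 1 s apart merge into one exclusion window
  mask2 <- classify_runs(data.frame(start_frame = c(50, 70),
                                    end_frame = c(55, 75)), 200, fps)
  expect_true(all(!mask2[35:90]))
})

test_that("steps are run-restricted local maxima above the speed floor", {
  fps <- 10; t <- seq(0, 10 - 1 / fps, by = 1 / fps)
  v <- 0.6 + 0.6 * sin(2 * pi * t)    # crests of 1.2 mm/s once per second
  s <- fake_series(v, fps)
  steps <- detect_steps(s, rep(TRUE, length(v)))
  expect_equal(nrow(steps), 10)
  cyc <- attr(steps, "cycles")
  expect_equal(mean(cyc$interval_s), 1, tolerance = 1e-9)
  expect_true(all(steps$tail_fwd_mm_s > 1.15))  # crest samples near 1.2

  # constant sub-floor speed: no steps
  expect_equal(nrow(detect_steps(fake_series(rep(0.3, 50), fps),
                                 rep(TRUE, 50))), 0)

  # crests below the 0.6 mm/s floor are discarded
  v2 <- 0.25 + 0.25 * sin(2 * pi * t)
  expect_equal(nrow(detect_steps(fake_series(v2, fps), rep(TRUE, 100))), 0)

  # plateau maxima count once, at the first plateau frame
  v3 <- c(0.5, 0.8, 1.2, 1.2, 0.8, 0.5, 0.5)
  st3 <- detect_steps(fake_series(v3, fps), rep(TRUE, 7))
  expect_equal(st3$frame, 3)

  # steps never inside excluded frames
  run <- rep(TRUE, length(v)); run[25:45] <- FALSE
  st4 <- detect_steps(fake_series(v, fps), run)
  expect_false(any(st4$frame %in% 25:45))
})

test_that("stumble cycles are W-shaped inter-step periods", {
  fps <- 10
  # one clean sinusoid cycle: normal
  t <- seq(0, 3 - 1 / fps, by = 1 / fps)
  v <- 0.7 + 0.5 * sin(2 * pi * t)
  s <- fake_series(v, fps)
  steps <- detect_steps(s, rep(TRUE, length(v)))
  cyc <- classify_stepping(attr(steps, "cycles"), s)
  expect_true(all(cyc$class == "normal"))

  # W-shaped velocity between two steps: stumble (middle crest below floor)
  vw <- c(0.4, 1.2, 0.4, 0.5, 0.4, 1.2, 0.4)
  sw <- fake_series(vw, fps)
  stw <- detect_steps(sw, rep(TRUE, 7))
  expect_equal(stw$frame, c(2, 6))
  cw <- classify_stepping(attr(stw, "cycles"), sw)
  expect_equal(cw$class, "stumble")

  # alternating stumbler: every second cycle W-shaped -> ratio exactly 0.5
  v5 <- c(0.4)
  for (k in 1:11) v5 <- c(v5, 1.2, if (k %% 2) c(0.4, 0.5, 0.4) else 0.4)
  s5 <- fake_series(v5, fps)
  st5 <- detect_steps(s5, rep(TRUE, length(v5)))
  c5 <- classify_stepping(attr(st5, "cycles"), s5)
  expect_equal(nrow(c5), 10)
  expect_equal(mean(c5$class == "normal"), 0.5)
})

test_that("switch detection uses persistence with hysteresis", {
  fps <- 10
  # step change +1 -> -1 bl/s at t = 30 s, sustained
  v <- c(rep(4, 300), rep(-4, 200)) # mm/s; bl = 4 -> +-1 bl/s
  sw <- detect_switches(fake_series(v, fps))
  expect_equal(sw$direction, "to_backward")
  expect_equal(sw$time_s, 30)

  # a 0.2 s negative blip with 1 s persistence: no event
  v2 <- rep(4, 300); v2[100:101] <- -4
  expect_equal(nrow(detect_switches(fake_series(v2, fps))), 0)

  # never negative: empty
  expect_equal(nrow(detect_switches(fake_series(rep(2, 100), fps))), 0)

  # alternation: backward then forward
  v3 <- c(rep(4, 100), rep(-4, 100), rep(4, 100))
  sw3 <- detect_switches(fake_series(v3, fps))
  expect_equal(sw3$direction, c("to_backward", "to_forward"))
})

test_that("event recovery matches simulator ground truth", {
  # step count within +-1 and IS interval within 5% on an HC-free track
  for (per in c(0.8, 1.0)) {
    p <- larva_params(peristaltic_period_s = per, hc_rate_hz = 0, rng_seed = 5)
    gt <- simulate_track(p, 40, 16, c(0, 0), 0)
    ev <- detect_events(as_track_record(gt))
    expect_lte(abs(nrow(ev$steps) - length(gt$steps)), 1)
    expect_lt(abs(mean(ev$cycles$interval_s) - per) / per, 0.05)
  }
  # HC count recovered exactly above threshold, missed entirely below
  p_hi <- larva_params(hc_rate_hz = 0.08, hc_amplitude_deg = 40, rng_seed = 21)
  gt_hi <- simulate_track(p_hi, 60, 16, c(0, 0), 0)
  ev_hi <- detect_events(as_track_record(gt_hi))
  expect_equal(nrow(ev_hi$hcs), nrow(gt_hi$hcs))
  expect_equal(ev_hi$hcs$side, gt_hi$hcs$side)
  p_lo <- larva_params(hc_rate_hz = 0.08, hc_amplitude_deg = 8, rng_seed = 21)
  ev_lo <- detect_events(as_track_record(simulate_track(p_lo, 60, 16, c(0, 0), 0)))
  expect_equal(nrow(ev_lo$hcs), 0)
  # no step inside any HC exclusion zone
  mask <- classify_runs(ev_hi$hcs, ev_hi$series$n, 16)
  expect_true(all(mask[ev_hi$steps$frame]))
})

test_that("mirroring a track swaps HC sides and negates bending", {
  p <- larva_params(hc_rate_hz = 0.08, hc_amplitude_deg = 40, rng_seed = 33)
  gt <- simulate_track(p, 60, 16, c(0, 0), 15)
  tr <- as_track_record(gt)
  trm <- tr
  trm$spine[, , 2] <- -trm$spine[, , 2]
  ev <- detect_events(tr); evm <- detect_events(trm)
  expect_equal(nrow(ev$hcs), nrow(evm$hcs))
  expect_equal(evm$hcs$side,
               ifelse(ev$hcs$side == "left", "right", "left"))
  expect_equal(evm$hcs$hc_angle_deg, -ev$hcs$hc_angle_deg, tolerance = 1e-8)
  expect_equal(evm$series$bending, -ev$series$bending, tolerance = 1e-8)
})
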