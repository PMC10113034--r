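#' Event-detection configuration
#'
#' Defaults are the published detection constants: head casts are intervals
#' where the head-vector angular speed exceeds +/-35 deg/s, discarded when
#' the tail-vector angular speed exceeds 45 deg/s inside the interval or when
#' two or more steps fall inside; steps are local maxima of the tail forward
#' velocity of at least 0.6 mm/s; runs exclude 1.5 s on either side of each
#' head cast; spine positions are smoothed with a 0.3 s window.
#'
#' @param hc_threshold_deg_s head-cast detection threshold on HV angular speed
#' @param tv_discard_deg_s discard threshold on TV angular speed inside a HC
#' @param step_min_speed_mm_s minimum tail forward speed of a step (mm/s,
#'   applied before body-length normalisation)
#' @param run_exclusion_s exclusion window around each HC
#' @param smooth_window_s boxcar smoothing window for spine positions
#' @param switch_persistence_s minimum duration of a velocity sign change to
#'   count as a forward/backward switch
#' @param switch_speed_floor_bl_s velocity magnitude floor for switches (bl/s)
#' @return an `event_config` list
#' @export
event_config <- function(hc_threshold_deg_s = 35,
                         tv_discard_deg_s = 45,
                         step_min_speed_mm_s = 0.6,
                         run_exclusion_s = 1.5,
                         smooth_window_s = 0.3,
                         switch_persistence_s = 1.0,
                         switch_speed_floor_bl_s = 0.1) {
  cfg <- list(hc_threshold_deg_s = hc_threshold_deg_s,
              tv_discard_deg_s = tv_discard_deg_s,
              step_min_speed_mm_s = step_min_speed_mm_s,
              run_exclusion_s = run_exclusion_s,
              smooth_window_s = smooth_window_s,
              switch_persistence_s = switch_persistence_s,
              switch_speed_floor_bl_s = switch_speed_floor_bl_s)
  if (any(vapply(cfg, function(v) v <= 0, TRUE)))
    stop("all event_config values must be positive")
  structure(cfg, class = "event_config")
}

#' Build a track record from an oriented spine time series
#'
#' The minimal analysable unit: a per-frame series of 12 spine points (mm,
#' tail tip first, head tip last). Tracker output provides these directly;
#' simulator ground truth or external CSV spine series can be wrapped too.
#'
#' @param spine `n x 12 x 2` array of spine points in mm (may contain NA
#'   frames, e.g. during unresolved collisions)
#' @param fps frame rate
#' @param id identity label
#' @param start_frame frame index of the first row in the source video
#' @return a `track_record`
#' @export
track_record <- function(spine, fps, id = "larva1", start_frame = 1L) {
  stopifnot(length(dim(spine)) == 3, dim(spine)[2] == 12, dim(spine)[3] == 2)
  structure(list(id = id, spine = spine, fps = fps,
                 start_frame = as.integer(start_frame),
                 duration_frames = dim(spine)[1]),
            class = "track_record")
}

#' @export
print.track_record <- function(x, ...) {
  cat(sprintf("<track_record %s> %d frames @ %g fps (%.1f s), %d valid\n",
              x$id, x$duration_frames, x$fps, x$duration_frames / x$fps,
              sum(stats::complete.cases(x$spine[, 1, ]))))
  invisible(x)
}

#' @rdname track_record
#' @param gt a `larva_ground_truth` from [simulate_track()]
#' @export
as_track_record <- function(gt, id = "larva1") {
  track_record(gt$spine, gt$fps, id = id)
}

#' Smoothed kinematic time series of a track
#'
#' Smooths spine positions with a centred boxcar (width `round(0.3 s * fps)`
#' frames, forced odd) and derives the per-frame motion quantities: midpoint
#' speed (spine point 6), head/tail forward velocities (displacement of spine
#' points 11/2 projected on the head/tail vector), head- and tail-vector
#' angles, angular speeds and accelerations, and the bending angle. Signs
#' follow the attribute-table conventions: bending positive = bent to the
#' left; angular speeds positive = vector turning to the animal's right.
#' Distances come in mm and in individual body lengths (bl); the bl unit is
#' the track's mean body length.
#'
#' @param track a [track_record()]
#' @param cfg an [event_config()]
#' @return a `motion_series` (list of per-frame vectors plus metadata)
#' @export
smooth_and_differentiate <- function(track, cfg = event_config()) {
  fps <- track$fps
  n <- track$duration_frames
  w <- round(cfg$smooth_window_s * fps)
  if (w %% 2 == 0) w <- w + 1
  empty <- structure(list(n = 0, fps = fps, flag = "too_short"),
                     class = "motion_series")
  if (n <= w) return(empty)
  sp <- track$spine
  for (j in 1:12) for (k in 1:2) sp[, j, k] <- boxcar_smooth(sp[, j, k], w)

  bl_frame <- rowSums(vapply(1:11, function(j)
    sqrt(rowSums((sp[, j + 1, ] - sp[, j, ])^2)), numeric(n)))
  bl_mm <- mean(bl_frame, na.rm = TRUE)

  hv <- sp[, 11, ] - sp[, 9, ]
  tv <- sp[, 6, ] - sp[, 2, ]
  mid <- sp[, 6, ]
  headp <- sp[, 11, ]
  tailp <- sp[, 2, ]

  cdiff <- function(x) {     # central difference, one-sided at the ends
    n <- length(x)
    d <- numeric(n)
    if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
    d[1] <- x[2] - x[1]; d[n] <- x[n] - x[n - 1]
    d
  }
  unitize <- function(v) v / pmax(sqrt(rowSums(v^2)), 1e-12)
  uhv <- unitize(hv); utv <- unitize(tv)

  head_fwd_mm <- (cdiff(headp[, 1]) * uhv[, 1] + cdiff(headp[, 2]) * uhv[, 2]) * fps
  tail_fwd_mm <- (cdiff(tailp[, 1]) * utv[, 1] + cdiff(tailp[, 2]) * utv[, 2]) * fps
  mid_speed_mm <- sqrt(cdiff(mid[, 1])^2 + cdiff(mid[, 2])^2) * fps

  hv_ang <- unwrap_deg(vec_angle_left(hv[, 1], hv[, 2]))
  tv_ang <- unwrap_deg(vec_angle_left(tv[, 1], tv[, 2]))
  # positive angular speed = turning to the right = left-angle decreasing
  hv_speed <- -cdiff(hv_ang) * fps
  tv_speed <- -cdiff(tv_ang) * fps
  hv_acc <- cdiff(hv_speed) * fps
  tv_acc <- cdiff(tv_speed) * fps

  mh <- sp[, 11, ] - mid    # middle -> head
  bend <- signed_angle_left(tv[, 1], tv[, 2], mh[, 1], mh[, 2])

  valid <- stats::complete.cases(sp[, 1, ]) & stats::complete.cases(sp[, 12, ])
  structure(list(
    n = n, fps = fps, bl_mm = bl_mm, valid = valid, spine_smooth = sp,
    t = (seq_len(n) - 1) / fps,
    midpoint = mid, head_point = headp, tail_point = tailp,
    head_vector = hv, tail_vector = tv,
    mid_speed_mm = mid_speed_mm, mid_speed_bl = mid_speed_mm / bl_mm,
    head_fwd_mm = head_fwd_mm, head_fwd_bl = head_fwd_mm / bl_mm,
    tail_fwd_mm = tail_fwd_mm, tail_fwd_bl = tail_fwd_mm / bl_mm,
    hv_angle = hv_ang, tv_angle = tv_ang,
    hv_angular_speed = hv_speed, tv_angular_speed = tv_speed,
    hv_angular_accel = hv_acc, tv_angular_accel = tv_acc,
    bending = bend, body_length_frame = bl_frame, flag = NULL),
    class = "motion_series")
}

# strict local maxima with plateau-first tie rule: a plateau of equal values
# counts once, at its first frame
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  out <- integer(0)
  i <- 2
  while (i <= n - 1) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1
      if (j <= n - 1 && x[j + 1] < x[i]) out <- c(out, i)
      i <- j + 1
    } else i <- i + 1
  }
  out
}

local_minima <- function(x) local_maxima(-x)

#' Detect lateral head casts
#'
#' Candidate head casts are maximal intervals where the HV angular speed
#' stays beyond the +/- threshold; a candidate is discarded when the TV
#' angular speed exceeds its own threshold anywhere inside (the posterior
#' body is reorienting, not the head) or when two or more steps fall inside.
#' The HC angle is the bending-angle change over the interval.
#'
#' @param series a [smooth_and_differentiate()] result
#' @param steps data.frame of provisional steps (see [detect_steps()]); when
#'   NULL, provisional unrestricted steps are computed internally for the
#'   two-step discard rule
#' @param cfg an [event_config()]
#' @return data.frame: `start_frame`, `end_frame`, `side`, `hc_angle_deg`
#' @export
detect_head_casts <- function(series, steps = NULL, cfg = event_config()) {
  empty <- data.frame(start_frame = integer(0), end_frame = integer(0),
                      side = character(0), hc_angle_deg = numeric(0))
  if (series$n == 0) return(empty)
  if (is.null(steps))
    steps <- detect_steps(series, run_mask = rep(TRUE, series$n), cfg = cfg,
                          cycles = FALSE)
  w <- series$hv_angular_speed
  thr <- cfg$hc_threshold_deg_s
  lab <- ifelse(!is.finite(w), 0L, ifelse(w > thr, 1L, ifelse(w < -thr, -1L, 0L)))
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != 0L
  out <- empty
  for (k in which(keep)) {
    s <- starts[k]; e <- ends[k]
    if (any(abs(series$tv_angular_speed[s:e]) > cfg$tv_discard_deg_s,
            na.rm = TRUE)) next
    if (sum(steps$frame >= s & steps$frame <= e) >= 2) next
    out <- rbind(out, data.frame(
      start_frame = s, end_frame = e,
      # positive angular speed = head moving right
      side = if (r$values[k] > 0) "right" else "left",
      hc_angle_deg = series$bending[e] - series$bending[s]))
  }
  out
}

#' Per-frame run mask
#'
#' A larva is in a run whenever it is not head casting; a window of
#' `run_exclusion_s` before and after each HC is excluded as well.
#'
#' @param hcs data.frame from [detect_head_casts()]
#' @param n_frames,fps track geometry
#' @param cfg an [event_config()]
#' @return logical vector of length `n_frames`
#' @export
classify_runs <- function(hcs, n_frames, fps, cfg = event_config()) {
  mask <- rep(TRUE, n_frames)
  pad <- cfg$run_exclusion_s * fps
  for (k in seq_len(nrow(hcs))) {
    lo <- max(1, floor(hcs$start_frame[k] - pad))
    hi <- min(n_frames, ceiling(hcs$end_frame[k] + pad))
    mask[lo:hi] <- FALSE
  }
  mask
}

#' Detect peristaltic steps and inter-step cycles
#'
#' A step is a strict local maximum of the tail forward velocity during a
#' run; maxima below the absolute speed floor (mm/s) are discarded. Pairs of
#' consecutive steps with only run frames between them form inter-step (IS)
#' cycles carrying the midpoint path distance, the interval and the average
#' midpoint speed.
#'
#' @param series a [smooth_and_differentiate()] result
#' @param run_mask logical per-frame run indicator (see [classify_runs()])
#' @param cfg an [event_config()]
#' @param cycles also compute IS cycles (attribute `cycles`)
#' @return data.frame of steps (`frame`, `time_s`, `tail_fwd_mm_s`); when
#'   `cycles = TRUE`, attribute `"cycles"` holds the IS-cycle data.frame
#' @export
detect_steps <- function(series, run_mask = NULL, cfg = event_config(),
                         cycles = TRUE) {
  empty <- data.frame(frame = integer(0), time_s = numeric(0),
                      tail_fwd_mm_s = numeric(0))
  if (series$n == 0) {
    if (cycles) attr(empty, "cycles") <- empty_cycles()
    return(empty)
  }
  if (is.null(run_mask)) run_mask <- rep(TRUE, series$n)
  v <- series$tail_fwd_mm
  cand <- local_maxima(v)
  cand <- cand[v[cand] >= cfg$step_min_speed_mm_s & run_mask[cand]]
  steps <- data.frame(frame = cand, time_s = (cand - 1) / series$fps,
                      tail_fwd_mm_s = v[cand])
  if (cycles) attr(steps, "cycles") <- make_cycles(steps, series, run_mask)
  steps
}

empty_cycles <- function() {
  data.frame(start_frame = integer(0), end_frame = integer(0),
             interval_s = numeric(0), distance_mm = numeric(0),
             distance_bl = numeric(0), speed_mm_s = numeric(0),
             speed_bl_s = numeric(0))
}

make_cycles <- function(steps, series, run_mask) {
  if (nrow(steps) < 2) return(empty_cycles())
  out <- empty_cycles()
  mid <- series$midpoint
  stepd <- c(0, sqrt(rowSums(diff(mid)^2)))  # stepd[f] = path from f-1 to f
  for (k in 2:nrow(steps)) {
    s <- steps$frame[k - 1]; e <- steps$frame[k]
    if (!all(run_mask[s:e])) next   # cycle must not straddle a non-run gap
    dist_mm <- sum(stepd[(s + 1):e])
    int_s <- (e - s) / series$fps
    out <- rbind(out, data.frame(
      start_frame = s, end_frame = e, interval_s = int_s,
      distance_mm = dist_mm, distance_bl = dist_mm / series$bl_mm,
      speed_mm_s = dist_mm / int_s, speed_bl_s = dist_mm / int_s / series$bl_mm))
  }
  out
}

#' Classify IS cycles as normal or stumble stepping
#'
#' A cycle with a single interior local minimum of the tail forward velocity
#' is normal stepping; two or more interior minima mark a stumble cycle (a
#' small spurious crest between two true steps).
#'
#' @param cycles IS-cycle data.frame (attribute of [detect_steps()])
#' @param series the matching motion series
#' @return the cycles data.frame with a `class` column (`normal`/`stumble`)
#' @export
classify_stepping <- function(cycles, series) {
  if (!nrow(cycles)) { cycles$class <- character(0); return(cycles) }
  v <- series$tail_fwd_mm
  cycles$class <- vapply(seq_len(nrow(cycles)), function(k) {
    s <- cycles$start_frame[k]; e <- cycles$end_frame[k]
    if (e - s < 2) return("normal")
    # local_minima never reports the first/last sample, so all hits are
    # strictly inside the cycle
    if (length(local_minima(v[s:e])) >= 2) "stumble" else "normal"
  }, character(1))
  cycles
}

#' Detect switches between forward and backward crawling
#'
#' A switch to backward crawling is flagged at the first frame where the
#' tail forward velocity drops below `-switch_speed_floor_bl_s`, provided the
#' velocity does not exceed `+switch_speed_floor_bl_s` again within
#' `switch_persistence_s` (hysteresis: the peristaltic oscillation crosses
#' zero within every cycle, so an episode only ends when the velocity crosses
#' the opposite floor). The switch back to forward crawling is symmetric, and
#' events alternate by construction (state machine starting forward).
#'
#' @param series a [smooth_and_differentiate()] result
#' @param cfg an [event_config()]
#' @return data.frame: `frame`, `time_s`, `direction`
#' @export
detect_switches <- function(series, cfg = event_config()) {
  out <- data.frame(frame = integer(0), time_s = numeric(0),
                    direction = character(0))
  if (series$n == 0) return(out)
  v <- series$tail_fwd_bl
  n <- series$n
  need <- max(1, round(cfg$switch_persistence_s * series$fps))
  floorv <- cfg$switch_speed_floor_bl_s
  lab <- ifelse(!is.finite(v), 0L, ifelse(v < -floorv, -1L,
                                          ifelse(v > floorv, 1L, 0L)))
  state <- 1L   # assume forward crawling at track start
  cursor <- 1L
  repeat {
    onset <- which(lab == -state)
    onset <- onset[onset >= cursor]
    if (!length(onset)) break
    s <- onset[1]
    offs <- which(lab == state)
    offs <- offs[offs > s]
    e <- if (length(offs)) offs[1] else n + 1L
    if (e - s >= need) {
      out <- rbind(out, data.frame(
        frame = s, time_s = (s - 1) / series$fps,
        direction = if (state == 1L) "to_backward" else "to_forward"))
      state <- -state
    }
    if (e > n) break
    cursor <- e
  }
  out
}

#' Full event detection for one track
#'
#' Runs the event-detector chain in the published order: motion series,
#' provisional steps (for the HC discard rule), head casts, run mask, final
#' steps restricted to runs, stepping-cycle classification and
#' forward/backward switches.
#'
#' @param track a [track_record()]
#' @param cfg an [event_config()]
#' @return a `larva_events` list: `series`, `hcs`, `run_mask`, `steps`,
#'   `cycles`, `switches`
#' @export
detect_events <- function(track, cfg = event_config()) {
  series <- smooth_and_differentiate(track, cfg)
  if (series$n == 0)
    return(structure(list(series = series, hcs = NULL, run_mask = logical(0),
                          steps = NULL, cycles = NULL, switches = NULL,
                          flag = "too_short"), class = "larva_events"))
  provisional <- detect_steps(series, run_mask = rep(TRUE, series$n),
                              cfg = cfg, cycles = FALSE)
  hcs <- detect_head_casts(series, provisional, cfg)
  run_mask <- classify_runs(hcs, series$n, series$fps, cfg)
  steps <- detect_steps(series, run_mask, cfg)
  cycles <- classify_stepping(attr(steps, "cycles"), series)
  switches <- detect_switches(series, cfg)
  structure(list(series = series, hcs = hcs, run_mask = run_mask,
                 steps = steps, cycles = cycles, switches = switches,
                 flag = NULL), class = "larva_events")
}
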