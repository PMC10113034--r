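#' Coefficient of variation
#'
#' `100 * s(x) / mean(x)` with the sample (n-1) standard deviation, the
#' within- or across-individual variability measure used throughout the
#' attribute catalogue.
#'
#' @param x numeric samples
#' @return CV in percent; `NA` for fewer than 2 samples or a zero mean
#' @export
coefficient_of_variation <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  if (abs(m) < 1e-12) return(NA_real_)
  100 * sd(x) / m
}

#' Stimulus (odour) context
#'
#' @param odour_mm `c(x, y)` odour-source position in mm
#' @param near_far_cutoff_mm distance separating near/far analysis bands
#' @param orientation_cutoff_deg absolute bearing below which a larva counts
#'   as oriented towards the source
#' @export
stimulus_context <- function(odour_mm, near_far_cutoff_mm = 60,
                             orientation_cutoff_deg = 90) {
  stopifnot(length(odour_mm) == 2, near_far_cutoff_mm > 0,
            orientation_cutoff_deg > 0)
  structure(list(odour_mm = odour_mm,
                 near_far_cutoff_mm = near_far_cutoff_mm,
                 orientation_cutoff_deg = orientation_cutoff_deg),
            class = "stimulus_context")
}

# per-frame bearing/heading angles w.r.t. the odour source, right-positive
# (positive = odour on the animal's right)
odour_angles <- function(series, stimulus) {
  o <- stimulus$odour_mm
  to_od_tail <- cbind(o[1] - series$tail_point[, 1], o[2] - series$tail_point[, 2])
  tv <- series$tail_vector
  bearing <- -signed_angle_left(tv[, 1], tv[, 2], to_od_tail[, 1], to_od_tail[, 2])
  s9 <- series$spine_smooth[, 9, ]
  to_od_9 <- cbind(o[1] - s9[, 1], o[2] - s9[, 2])
  hv <- series$head_vector
  heading <- -signed_angle_left(hv[, 1], hv[, 2], to_od_9[, 1], to_od_9[, 2])
  list(bearing = bearing, heading = heading,
       dist_mm = sqrt(rowSums((cbind(o[1], o[2])[rep(1, series$n), ] -
                                 series$midpoint)^2)))
}

#' Per-larva behavioural attribute record
#'
#' Computes the attribute catalogue for one track: the 30 random-forest
#' attributes (bending, angular speed/acceleration, inter-step and head-cast
#' statistics, forward velocities, distances, with their within-individual
#' CVs), the non-forest basics (midpoint speeds, mm-valued IS attributes,
#' body length), and, when a stimulus is given, the odour-related set
#' (bearing/heading, HC rate modulation, HC reorientation, IS speed
#' modulation, distance from source). Scalars are means across the
#' observation period; distances and speeds are reported in individual body
#' lengths unless the mm variant is part of the catalogue.
#'
#' @param track a [track_record()]
#' @param events a [detect_events()] result for the same track (computed on
#'   the fly when NULL)
#' @param stimulus optional [stimulus_context()]
#' @param cfg an [event_config()]
#' @param reorientation_order `"before_minus_after"` (positive = towards the
#'   odour, the table's stated interpretation) or `"after_minus_before"`
#' @return one-row data.frame of attributes
#' @export
compute_attributes <- function(track, events = NULL, stimulus = NULL,
                               cfg = event_config(),
                               reorientation_order = c("before_minus_after",
                                                       "after_minus_before")) {
  reorientation_order <- match.arg(reorientation_order)
  if (is.null(events)) events <- detect_events(track, cfg)
  s <- events$series
  if (s$n == 0) stop("track too short for attribute computation")
  ok <- s$valid
  dur_s <- s$n / s$fps
  hcs <- events$hcs
  cyc <- events$cycles
  steps <- events$steps
  bl <- s$bl_mm

  mean_ok <- function(x) mean(x[ok & is.finite(x)])
  cv_ok <- function(x) coefficient_of_variation(x[ok])

  # inter-step angle: head-vector angle change (left-positive) per cycle
  is_angle <- if (nrow(steps) >= 2)
    diff(s$hv_angle[steps$frame]) else numeric(0)

  path <- sqrt(rowSums(diff(s$midpoint)^2))
  disp <- sqrt(rowSums((s$midpoint - matrix(s$midpoint[1, ], s$n, 2,
                                            byrow = TRUE))^2))

  out <- data.frame(
    id = track$id,
    # --- bending / head-cast block (random forest) ---
    bending_angle = mean_ok(s$bending),
    abs_bending_angle = mean_ok(abs(s$bending)),
    cv_abs_bending_angle = cv_ok(abs(s$bending)),
    hv_angular_speed = mean_ok(s$hv_angular_speed),
    abs_hv_angular_speed = mean_ok(abs(s$hv_angular_speed)),
    cv_abs_hv_angular_speed = cv_ok(abs(s$hv_angular_speed)),
    hv_angular_acceleration = mean_ok(s$hv_angular_accel),
    tv_angular_speed = mean_ok(s$tv_angular_speed),
    abs_tv_angular_speed = mean_ok(abs(s$tv_angular_speed)),
    cv_abs_tv_angular_speed = cv_ok(abs(s$tv_angular_speed)),
    tv_angular_acceleration = mean_ok(s$tv_angular_accel),
    is_angle = if (length(is_angle)) mean(is_angle) else NA_real_,
    abs_is_angle = if (length(is_angle)) mean(abs(is_angle)) else NA_real_,
    cv_abs_is_angle = coefficient_of_variation(abs(is_angle)),
    hc_rate = nrow(hcs) / dur_s,
    hc_angle = if (nrow(hcs)) mean(hcs$hc_angle_deg) else NA_real_,
    abs_hc_angle = if (nrow(hcs)) mean(abs(hcs$hc_angle_deg)) else NA_real_,
    cv_abs_hc_angle = coefficient_of_variation(abs(hcs$hc_angle_deg)),
    # --- speed block (random forest) ---
    head_forward_velocity = mean_ok(s$head_fwd_bl),
    cv_head_forward_velocity = cv_ok(s$head_fwd_bl),
    tail_forward_velocity = mean_ok(s$tail_fwd_bl),
    cv_tail_forward_velocity = cv_ok(s$tail_fwd_bl),
    is_distance_bl = if (nrow(cyc)) mean(cyc$distance_bl) else NA_real_,
    cv_is_distance = coefficient_of_variation(cyc$distance_bl),
    is_interval = if (nrow(cyc)) mean(cyc$interval_s) else NA_real_,
    cv_is_interval = coefficient_of_variation(cyc$interval_s),
    is_speed_bl = if (nrow(cyc)) mean(cyc$speed_bl_s) else NA_real_,
    cv_is_speed = coefficient_of_variation(cyc$speed_bl_s),
    distance_travelled_bl = sum(path[ok[-1] & ok[-s$n]]) / bl,
    distance_from_start_bl = max(disp[ok]) / bl,
    # --- non-forest basics ---
    midpoint_speed_mm = mean_ok(s$mid_speed_mm),
    midpoint_speed_bl = mean_ok(s$mid_speed_bl),
    cv_midpoint_speed = cv_ok(s$mid_speed_mm),
    is_distance_mm = if (nrow(cyc)) mean(cyc$distance_mm) else NA_real_,
    is_speed_mm = if (nrow(cyc)) mean(cyc$speed_mm_s) else NA_real_,
    body_length_mm = bl,
    stringsAsFactors = FALSE)

  if (!is.null(stimulus)) {
    oa <- odour_angles(s, stimulus)
    cutoff <- stimulus$orientation_cutoff_deg
    toward <- abs(oa$bearing) < cutoff
    away <- abs(oa$bearing) > cutoff
    time_toward <- sum(toward & ok) / s$fps
    time_away <- sum(away & ok) / s$fps
    hc_toward <- if (nrow(hcs)) sum(toward[hcs$start_frame]) else 0
    hc_away <- if (nrow(hcs)) sum(away[hcs$start_frame]) else 0
    r_t <- if (time_toward > 0) hc_toward / time_toward else NA_real_
    r_a <- if (time_away > 0) hc_away / time_away else NA_real_
    hc_mod <- if (is.finite(r_t) && is.finite(r_a) && (r_t + r_a) > 0)
      (r_a - r_t) / (r_a + r_t) else NA_real_
    cyc_toward <- if (nrow(cyc)) toward[cyc$start_frame] else logical(0)
    sp_t <- if (any(cyc_toward)) mean(cyc$speed_bl_s[cyc_toward]) else NA_real_
    sp_a <- if (any(!cyc_toward)) mean(cyc$speed_bl_s[!cyc_toward]) else NA_real_
    is_mod <- if (is.finite(sp_t) && is.finite(sp_a) && (sp_t + sp_a) != 0)
      (sp_t - sp_a) / (sp_t + sp_a) else NA_real_
    reor <- if (nrow(hcs)) {
      d <- abs(oa$heading[hcs$start_frame]) - abs(oa$heading[hcs$end_frame])
      if (reorientation_order == "after_minus_before") d <- -d
      mean(d)
    } else NA_real_
    out <- cbind(out, data.frame(
      bearing_angle = mean_ok(oa$bearing),
      abs_bearing_angle = mean_ok(abs(oa$bearing)),
      heading_angle = mean_ok(oa$heading),
      abs_heading_angle = mean_ok(abs(oa$heading)),
      hc_rate_modulation = hc_mod,
      hc_reorientation = reor,
      is_speed_modulation = is_mod,
      distance_from_odour_mm = mean_ok(oa$dist_mm)))
  }
  out
}

#' The 30 random-forest attribute names
#' @export
rf_attribute_names <- function() c(
  "bending_angle", "abs_bending_angle", "cv_abs_bending_angle",
  "hv_angular_speed", "abs_hv_angular_speed", "cv_abs_hv_angular_speed",
  "hv_angular_acceleration", "tv_angular_speed", "abs_tv_angular_speed",
  "cv_abs_tv_angular_speed", "tv_angular_acceleration",
  "is_angle", "abs_is_angle", "cv_abs_is_angle",
  "hc_rate", "hc_angle", "abs_hc_angle", "cv_abs_hc_angle",
  "head_forward_velocity", "cv_head_forward_velocity",
  "tail_forward_velocity", "cv_tail_forward_velocity",
  "is_distance_bl", "cv_is_distance", "is_interval", "cv_is_interval",
  "is_speed_bl", "cv_is_speed", "distance_travelled_bl",
  "distance_from_start_bl")

# named per-frame attribute series (for delta/peak/bin computations)
attribute_series <- function(series, name) {
  map <- list(
    bending_angle = series$bending,
    abs_bending_angle = abs(series$bending),
    hv_angular_speed = series$hv_angular_speed,
    abs_hv_angular_speed = abs(series$hv_angular_speed),
    tv_angular_speed = series$tv_angular_speed,
    abs_tv_angular_speed = abs(series$tv_angular_speed),
    midpoint_speed_mm = series$mid_speed_mm,
    midpoint_speed_bl = series$mid_speed_bl,
    tail_forward_velocity = series$tail_fwd_bl,
    head_forward_velocity = series$head_fwd_bl)
  if (is.null(map[[name]])) stop("no per-frame series for attribute ", name)
  map[[name]]
}

#' Difference of an attribute between two time intervals
#'
#' The stimulation-response measure: mean of the attribute during one
#' interval minus its mean during a reference interval (e.g. 30 s of light
#' stimulation minus the 30 s before).
#'
#' @param x per-frame numeric series, or a `motion_series` plus `attribute`
#' @param fps frame rate of the series
#' @param during,before `c(start_s, end_s)` intervals (start inclusive,
#'   end exclusive)
#' @param attribute attribute name when `x` is a `motion_series`
#' @return the delta; `NA` if either interval has no finite frames
#' @export
delta_values <- function(x, fps, during, before, attribute = NULL) {
  if (inherits(x, "motion_series")) {
    fps <- x$fps
    x <- attribute_series(x, attribute)
  }
  t <- (seq_along(x) - 1) / fps
  m <- function(iv) {
    v <- x[t >= iv[1] & t < iv[2]]
    v <- v[is.finite(v)]
    if (!length(v)) NA_real_ else mean(v)
  }
  m(during) - m(before)
}

#' Peak value of an attribute around a switching point
#'
#' Mean of the attribute in the 10 s window centred on the switch minus its
#' mean in the two 5 s flanks, quantifying a local peak at the switch.
#'
#' @inheritParams delta_values
#' @param switch_s time of the switch event in seconds
#' @param half_window_s half width of the central window (default 5 s)
#' @return the peak value, with attribute `"truncated"` flagging windows cut
#'   short by the track ends
#' @export
peak_values <- function(x, fps, switch_s, half_window_s = 5,
                        attribute = NULL) {
  if (inherits(x, "motion_series")) {
    fps <- x$fps
    x <- attribute_series(x, attribute)
  }
  t <- (seq_along(x) - 1) / fps
  h <- half_window_s
  centre <- t >= switch_s - h & t < switch_s + h
  flank <- (t >= switch_s - 2 * h & t < switch_s - h) |
           (t >= switch_s + h & t < switch_s + 2 * h)
  truncated <- switch_s - 2 * h < 0 || switch_s + 2 * h > max(t)
  v1 <- x[centre]; v1 <- v1[is.finite(v1)]
  v2 <- x[flank];  v2 <- v2[is.finite(v2)]
  out <- if (!length(v1) || !length(v2)) NA_real_ else mean(v1) - mean(v2)
  attr(out, "truncated") <- truncated
  out
}

#' Binned group time series with confidence intervals
#'
#' Pools an attribute across animals in fixed time bins: per bin the mean of
#' the per-animal bin means and a normal-approximation 95% confidence
#' interval (mean +/- 1.96 SEM across animals). For the head-cast rate the
#' bin value is the pooled fraction of HC frames among all frames in the
#' bin. With `align = "to_switch"` each animal's clock is shifted so its
#' switch event is time zero, and animals without a switch are dropped.
#'
#' @param tracks list of per-animal per-frame numeric vectors (or logical HC
#'   indicators for `hc_rate = TRUE`)
#' @param fps common frame rate
#' @param bin_s bin width in seconds
#' @param align `"clock"` or `"to_switch"`
#' @param switch_s per-animal switch times (seconds), used for `to_switch`
#' @param hc_rate treat inputs as per-frame HC indicators
#' @return data.frame: `bin_start_s`, `bin_mid_s`, `mean`, `ci_lo`, `ci_hi`,
#'   `n` (animals contributing); empty bins are absent
#' @export
bin_series <- function(tracks, fps, bin_s = 2,
                       align = c("clock", "to_switch"), switch_s = NULL,
                       hc_rate = FALSE) {
  align <- match.arg(align)
  if (!length(tracks)) stop("at least one track required")
  offs <- rep(0, length(tracks))
  if (align == "to_switch") {
    if (is.null(switch_s)) stop("switch_s required for to_switch alignment")
    keep <- is.finite(switch_s)
    tracks <- tracks[keep]
    offs <- -switch_s[keep]
    if (!length(tracks)) stop("no animal performed the switch")
  }
  per <- lapply(seq_along(tracks), function(i) {
    v <- tracks[[i]]
    t <- (seq_along(v) - 1) / fps + offs[i]
    data.frame(bin = floor(t / bin_s), v = as.numeric(v))
  })
  allbins <- sort(unique(unlist(lapply(per, function(d) unique(d$bin)))))
  rows <- lapply(allbins, function(b) {
    if (hc_rate) {
      vals <- unlist(lapply(per, function(d) d$v[d$bin == b]))
      vals <- vals[is.finite(vals)]
      if (!length(vals)) return(NULL)
      n_anim <- sum(vapply(per, function(d) any(d$bin == b), TRUE))
      data.frame(bin_start_s = b * bin_s, bin_mid_s = (b + 0.5) * bin_s,
                 mean = mean(vals), ci_lo = NA_real_, ci_hi = NA_real_,
                 n = n_anim)
    } else {
      means <- vapply(per, function(d) {
        vv <- d$v[d$bin == b & is.finite(d$v)]
        if (!length(vv)) NA_real_ else mean(vv)
      }, numeric(1))
      means <- means[is.finite(means)]
      if (!length(means)) return(NULL)
      sem <- if (length(means) > 1) sd(means) / sqrt(length(means)) else 0
      data.frame(bin_start_s = b * bin_s, bin_mid_s = (b + 0.5) * bin_s,
                 mean = mean(means), ci_lo = mean(means) - 1.96 * sem,
                 ci_hi = mean(means) + 1.96 * sem, n = length(means))
    }
  })
  do.call(rbind, rows)
}

#' Histogram of body-orientation change across a switch
#'
#' For every switch with a full window on both sides, the mean tail-vector
#' direction over the 10 s before is compared with the 10 s after; the
#' absolute angle between the two (0-180 deg) is tallied in 20 deg brackets
#' and reported as the percentage of switches per bracket.
#'
#' @param series_list list of `motion_series`, one per animal
#' @param switch_list list of per-animal switch-time vectors (seconds)
#' @param window_s comparison window on each side
#' @param bracket_deg histogram bracket width
#' @return data.frame: `bracket_lo`, `bracket_hi`, `count`, `pct`
#' @export
orientation_change_histogram <- function(series_list, switch_list,
                                         window_s = 10, bracket_deg = 20) {
  angles <- c()
  for (i in seq_along(series_list)) {
    s <- series_list[[i]]
    for (sw in switch_list[[i]]) {
      if (sw - window_s < 0 || sw + window_s > (s$n - 1) / s$fps) next
      pre <- s$t >= sw - window_s & s$t < sw
      post <- s$t > sw & s$t <= sw + window_s
      mdir <- function(sel) {
        v <- s$tail_vector[sel, , drop = FALSE]
        u <- v / pmax(sqrt(rowSums(v^2)), 1e-12)
        colMeans(u)
      }
      a <- mdir(pre); b <- mdir(post)
      angles <- c(angles, abs(signed_angle_left(a[1], a[2], b[1], b[2])))
    }
  }
  lo <- seq(0, 180 - bracket_deg, by = bracket_deg)
  cnt <- vapply(lo, function(l)
    sum(angles >= l & (angles < l + bracket_deg | l + bracket_deg == 180)),
    numeric(1))
  data.frame(bracket_lo = lo, bracket_hi = lo + bracket_deg, count = cnt,
             pct = if (length(angles)) 100 * cnt / length(angles) else 0 * cnt)
}
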