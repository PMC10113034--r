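#' Kinematic parameters of a simulated larva
#'
#' The simulator reproduces the kinematic signatures the event detectors look
#' for: a peristaltic oscillation of the axial (tail-forward) velocity,
#' lateral head casts realised as angular excursions of the anterior body,
#' and optional backward-crawling episodes with negative axial velocity.
#'
#' @param body_length_mm body length in mm (> 0)
#' @param peristaltic_period_s duration of one peristaltic cycle in seconds
#' @param stride_bl distance covered per cycle, in body lengths
#' @param hc_rate_hz expected number of head casts per second (Poisson)
#' @param hc_amplitude_deg angular excursion of one head cast; the outward
#'   sweep lasts 0.5 s, so the head-vector angular speed during a cast is
#'   `hc_amplitude_deg / 0.5` deg/s
#' @param backward_episodes list of `c(start_s, end_s)` intervals with
#'   negative axial velocity; must be non-overlapping
#' @param rng_seed integer seed making the track reproducible
#' @return a `larva_params` object
#' @export
larva_params <- function(body_length_mm = 4,
                         peristaltic_period_s = 1,
                         stride_bl = 0.35,
                         hc_rate_hz = 0.1,
                         hc_amplitude_deg = 40,
                         backward_episodes = list(),
                         rng_seed = 1L) {
  stopifnot(body_length_mm > 0, peristaltic_period_s > 0, stride_bl > 0,
            hc_rate_hz >= 0)
  eps <- backward_episodes
  if (length(eps)) {
    m <- do.call(rbind, eps)
    if (any(m[, 2] <= m[, 1])) stop("backward episode must have end > start")
    if (nrow(m) > 1) {
      m <- m[order(m[, 1]), , drop = FALSE]
      if (any(m[-1, 1] < m[-nrow(m), 2]))
        stop("backward episodes must not overlap")
    }
  }
  structure(list(body_length_mm = body_length_mm,
                 peristaltic_period_s = peristaltic_period_s,
                 stride_bl = stride_bl,
                 hc_rate_hz = hc_rate_hz,
                 hc_amplitude_deg = hc_amplitude_deg,
                 backward_episodes = backward_episodes,
                 rng_seed = as.integer(rng_seed)),
            class = "larva_params")
}

# head-cast phase profile: outward sweep of fixed duration, followed by a
# slow relaxation (25 deg/s, below the 35 deg/s detection threshold) during
# which half of the excursion is converted into a permanent heading change
HC_SWEEP_S <- 0.5
HC_RELAX_RATE <- 25
HC_GAP_S <- 0.4

hc_footprint_s <- function(amp) HC_SWEEP_S + abs(amp) / HC_RELAX_RATE + HC_GAP_S

#' Simulate the ground-truth track of a single larva
#'
#' Produces per-frame true spine points (12, tail tip to head tip, in mm with
#' raster orientation: x right, y down) plus event lists: peristaltic step
#' times, head-cast intervals with side, and forward/backward switch times.
#'
#' @param params a [larva_params()] object
#' @param duration_s scene duration in seconds (> 0)
#' @param fps frame rate, at least 8
#' @param start_mm `c(x, y)` initial tail position in mm
#' @param heading_deg initial heading (left-positive world angle; 0 = +x)
#' @return a `larva_ground_truth` object: `t` (frame times), `spine` (an
#'   `n_frames x 12 x 2` array, mm), `steps` (step times, s), `hcs`
#'   (data.frame start_s/end_s/side/hc_angle_deg), `switches`, `params`
#' @export
simulate_track <- function(params, duration_s, fps,
                           start_mm = c(20, 20), heading_deg = 0) {
  if (!inherits(params, "larva_params")) stop("params must be larva_params")
  if (duration_s <= 0) stop("duration_s must be positive")
  if (fps < 8) stop("fps must be at least 8")
  eps <- params$backward_episodes
  if (length(eps) && any(vapply(eps, max, 0) > duration_s))
    stop("backward episodes must lie within the scene duration")

  n <- as.integer(round(duration_s * fps))
  t <- (seq_len(n) - 1) / fps
  bl <- params$body_length_mm
  period <- params$peristaltic_period_s
  v0 <- params$stride_bl * bl / period   # mean axial speed, mm/s

  dir <- rep(1, n)
  for (ep in eps) dir[t >= ep[1] & t < ep[2]] <- -1
  # axial speed oscillates between 0 and 2*v0; crests are the true steps
  v <- dir * v0 * (1 - cos(2 * pi * t / period))

  # true step times: crests of the tail forward velocity on forward stretches
  crest <- period * (seq_len(ceiling(duration_s / period) + 1) - 0.5)
  crest <- crest[crest < duration_s]
  fw <- vapply(crest, function(ts) {
    !length(eps) || all(vapply(eps, function(e) ts < e[1] || ts >= e[2], TRUE))
  }, TRUE)
  steps <- crest[fw]

  # head casts: Poisson count, placed uniformly subject to a minimum gap
  hcs <- with_seed(params$rng_seed, {
    amp <- params$hc_amplitude_deg
    foot <- hc_footprint_s(amp)
    k <- if (params$hc_rate_hz > 0) rpois(1, params$hc_rate_hz * duration_s) else 0L
    onsets <- numeric(0)
    if (k > 0) {
      for (try in 1:500) {
        cand <- sort(runif(k, 0.5, max(0.6, duration_s - foot - 0.5)))
        if (k == 1 || all(diff(cand) >= foot)) { onsets <- cand; break }
      }
      if (!length(onsets)) { # fall back: greedy thinning keeps as many as fit
        cand <- sort(runif(k, 0.5, max(0.6, duration_s - foot - 0.5)))
        keep <- cand[1]
        for (x in cand[-1]) if (x - keep[length(keep)] >= foot) keep <- c(keep, x)
        onsets <- keep
      }
    }
    side <- if (length(onsets)) sample(c(-1, 1), length(onsets), replace = TRUE) else numeric(0)
    data.frame(start_s = onsets, end_s = onsets + HC_SWEEP_S,
               side = ifelse(side > 0, "left", "right"),
               hc_angle_deg = side * abs(amp))
  })

  # bending angle profile and permanent heading turns contributed by HCs
  beta <- numeric(n)     # head deflection, left-positive degrees
  dhead <- numeric(n)    # heading increment per frame, degrees
  if (nrow(hcs)) {
    for (i in seq_len(nrow(hcs))) {
      a <- hcs$hc_angle_deg[i]
      t0 <- hcs$start_s[i]
      relax <- abs(a) / HC_RELAX_RATE
      sweep <- t >= t0 & t < t0 + HC_SWEEP_S
      beta[sweep] <- beta[sweep] + a * (t[sweep] - t0) / HC_SWEEP_S
      rel <- t >= t0 + HC_SWEEP_S & t < t0 + HC_SWEEP_S + relax
      frac <- (t[rel] - t0 - HC_SWEEP_S) / relax
      beta[rel] <- beta[rel] + a * (1 - frac)
      dhead[rel] <- dhead[rel] + (a / 2) / (relax * fps)
    }
  }
  heading <- heading_deg + cumsum(dhead)

  # tail path: integrate axial velocity along the heading
  s_inc <- v / fps
  ux <- cos(heading * pi / 180)
  uy <- -sin(heading * pi / 180)       # left-positive angle in raster coords
  tailx <- start_mm[1] + cumsum(s_inc * ux) - s_inc[1] * ux[1]
  taily <- start_mm[2] + cumsum(s_inc * uy) - s_inc[1] * uy[1]

  # straight body along the heading; anterior 3 points rotated about point 9
  u <- (seq_len(12) - 1) / 11
  spine <- array(NA_real_, c(n, 12, 2))
  for (f in seq_len(n)) {
    base <- cbind(tailx[f] + u * bl * ux[f], taily[f] + u * bl * uy[f])
    if (beta[f] != 0) {
      pivot <- base[9, ]
      ant <- sweep(base[10:12, , drop = FALSE], 2, pivot)
      base[10:12, ] <- sweep(rot_left(ant, beta[f]), 2, pivot, `+`)
    }
    spine[f, , ] <- base
  }

  switches <- data.frame(time_s = numeric(0), direction = character(0))
  if (length(eps)) {
    for (ep in eps) {
      switches <- rbind(switches,
        data.frame(time_s = c(ep[1], ep[2]),
                   direction = c("to_backward", "to_forward")))
    }
    switches <- switches[switches$time_s <= duration_s, ]
    switches <- switches[order(switches$time_s), ]
  }

  structure(list(t = t, fps = fps, duration_s = duration_s, spine = spine,
                 head_index = 12L, steps = steps, hcs = hcs,
                 switches = switches, axial_velocity = v,
                 heading_deg = heading, bending_deg = beta, params = params),
            class = "larva_ground_truth")
}

# per-spine-point rendering half-width (mm): tapered capsule, sharp tips
spine_halfwidth <- function(bl, width_frac = 0.2) {
  u <- (seq_len(12) - 1) / 11
  (width_frac * bl / 2) * sqrt(pmax(0, 4 * u * (1 - u)))
}

#' Render simulated larvae into a synthetic scene
#'
#' Each larva is drawn as a tapered capsule along its true spine (11 segments
#' joining the 12 spine points, zero width at the tips). The anterior fifth
#' of the body is drawn slightly darker, mimicking the pigmented mouth hooks
#' that make real larval heads the darker end. Background is uniform with
#' additive Gaussian noise; frames are generated lazily and are bit-identical
#' for a fixed seed.
#'
#' @param tracks list of [simulate_track()] results (same fps and duration)
#' @param arena_mm `c(width, height)` of the arena in mm
#' @param mm_per_px calibration (default 0.1 mm/px gives > 30 px per larva)
#' @param noise_sd Gaussian noise standard deviation in grey levels
#' @param polarity `"dark"` (dark larvae on light background) or `"light"`
#' @param seed seed for the per-frame noise
#' @return a `larva_scene`, which is also a [frame_sequence()]; ground truth
#'   is in `$ground_truth` (per-larva truths plus `$collisions`)
#' @export
render_scene <- function(tracks, arena_mm = c(40, 40), mm_per_px = 0.1,
                         noise_sd = 2, polarity = c("dark", "light"),
                         seed = 1L) {
  polarity <- match.arg(polarity)
  if (length(unique(vapply(tracks, function(g) g$fps, 0))) != 1)
    stop("all tracks must share one fps")
  if (length(unique(vapply(tracks, function(g) nrow(g$spine), 0))) != 1)
    stop("all tracks must share one duration")
  fps <- tracks[[1]]$fps
  n <- dim(tracks[[1]]$spine)[1]
  for (g in tracks) {
    xs <- g$spine[, , 1]; ys <- g$spine[, , 2]
    if (min(xs) < 1 || min(ys) < 1 ||
        max(xs) > arena_mm[1] - 1 || max(ys) > arena_mm[2] - 1)
      stop("true spine leaves the arena; enlarge arena_mm or shorten track")
  }
  nr <- round(arena_mm[2] / mm_per_px)
  nc <- round(arena_mm[1] / mm_per_px)
  bg <- if (polarity == "dark") 200 else 50
  body <- if (polarity == "dark") 70 else 190
  head_delta <- -40   # head end darker in both polarities
  take <- if (polarity == "dark") -1L else 1L

  widths <- lapply(tracks, function(g)
    spine_halfwidth(g$params$body_length_mm) / mm_per_px)
  u <- (seq_len(12) - 1) / 11
  # darkening ramps over the anterior third (mouth hooks / anterior gut),
  # wide enough to register in a 10 px brightness probe at the head end
  intens <- body + head_delta * pmax(0, (u - 0.65) / 0.35)

  dense_idx <- seq(1, 12, length.out = 45)
  densify <- function(v) approx(seq_len(12), v, xout = dense_idx)$y

  frame_fun <- function(i) {
    img <- with_seed(seed * 1000003L %% 2147483647L + i, {
      matrix(bg + (if (noise_sd > 0) rnorm(nr * nc, 0, noise_sd) else 0), nr, nc)
    })
    for (k in seq_along(tracks)) {
      sp <- tracks[[k]]$spine[i, , ]
      pts <- mm_to_px(sp, mm_per_px)
      dpts <- cbind(densify(pts[, 1]), densify(pts[, 2]))
      hw <- densify(widths[[k]])
      iv <- densify(intens)
      .render_polyline(img, dpts, hw, iv, take)
    }
    pmin(pmax(img, 0), 255)
  }

  scene <- frame_sequence(frame_fun, n_frames = n, fps = fps,
                          mm_per_px = mm_per_px)
  scene$polarity <- polarity
  scene$noise_sd <- noise_sd
  scene$arena_mm <- arena_mm
  scene$seed <- seed
  scene$ground_truth <- list(
    larvae = tracks,
    collisions = find_true_collisions(tracks, mm_per_px))
  class(scene) <- c("larva_scene", class(scene))
  scene
}

# ground-truth collision events: frame intervals during which the rendered
# silhouettes of two or more larvae overlap (capsule-distance test on the
# true spines), merged into participant sets by connected components
find_true_collisions <- function(tracks, mm_per_px) {
  n <- dim(tracks[[1]]$spine)[1]
  K <- length(tracks)
  if (K < 2) return(data.frame())
  hw <- lapply(tracks, function(g) spine_halfwidth(g$params$body_length_mm))
  dense_idx <- seq(1, 12, length.out = 30)
  over <- vector("list", n)
  for (f in seq_len(n)) {
    pairs <- NULL
    for (a in seq_len(K - 1)) for (b in (a + 1):K) {
      sa <- tracks[[a]]$spine[f, , ]; sb <- tracks[[b]]$spine[f, , ]
      if (sum((colMeans(sa) - colMeans(sb))^2) >
          (tracks[[a]]$params$body_length_mm + tracks[[b]]$params$body_length_mm)^2 / 2)
        next
      pa <- cbind(approx(1:12, sa[, 1], xout = dense_idx)$y,
                  approx(1:12, sa[, 2], xout = dense_idx)$y)
      pb <- cbind(approx(1:12, sb[, 1], xout = dense_idx)$y,
                  approx(1:12, sb[, 2], xout = dense_idx)$y)
      wa <- approx(1:12, hw[[a]], xout = dense_idx)$y
      wb <- approx(1:12, hw[[b]], xout = dense_idx)$y
      d2 <- outer(pa[, 1], pb[, 1], `-`)^2 + outer(pa[, 2], pb[, 2], `-`)^2
      lim <- outer(wa, wb, `+`)
      if (any(d2 <= lim^2)) pairs <- rbind(pairs, c(a, b))
    }
    if (!is.null(pairs)) over[[f]] <- pairs
  }
  # merge per-frame overlap pair sets into events over contiguous frames
  events <- list()
  active <- list()   # open events: list(participants, start)
  for (f in seq_len(n)) {
    pairs <- over[[f]]
    groups <- list()
    if (!is.null(pairs)) {
      ids <- sort(unique(as.vector(pairs)))
      parent <- stats::setNames(ids, ids)
      findp <- function(i) { while (parent[[as.character(i)]] != i) i <- parent[[as.character(i)]]; i }
      for (r in seq_len(nrow(pairs))) {
        ra <- findp(pairs[r, 1]); rb <- findp(pairs[r, 2])
        if (ra != rb) parent[[as.character(ra)]] <- rb
      }
      roots <- vapply(ids, findp, 0)
      groups <- split(ids, roots)
    }
    still <- rep(FALSE, length(active))
    for (g in groups) {
      matched <- FALSE
      for (j in seq_along(active)) {
        if (length(intersect(active[[j]]$participants, g))) {
          active[[j]]$participants <- union(active[[j]]$participants, g)
          active[[j]]$end <- f
          still[j] <- TRUE
          matched <- TRUE
          break
        }
      }
      if (!matched) {
        active[[length(active) + 1]] <- list(participants = g, start = f, end = f)
        still <- c(still, TRUE)
      }
    }
    for (j in rev(which(!still))) {
      events[[length(events) + 1]] <- active[[j]]
      active[[j]] <- NULL
    }
  }
  for (j in seq_along(active)) events[[length(events) + 1]] <- active[[j]]
  if (!length(events)) return(data.frame())
  # merge events with identical participant sets separated by brief gaps
  # (grazing contacts flicker at pixel resolution)
  gap <- round(0.5 * tracks[[1]]$fps)
  events <- events[order(vapply(events, function(e) e$start, 0))]
  merged <- list(events[[1]])
  for (e in events[-1]) {
    last <- merged[[length(merged)]]
    if (identical(sort(e$participants), sort(last$participants)) &&
        e$start - last$end <= gap) {
      merged[[length(merged)]]$end <- max(last$end, e$end)
    } else merged[[length(merged) + 1]] <- e
  }
  events <- merged
  data.frame(
    start_frame = vapply(events, function(e) e$start, 0),
    end_frame = vapply(events, function(e) e$end, 0),
    n_participants = vapply(events, function(e) length(e$participants), 0),
    participants = I(lapply(events, function(e) sort(e$participants))))
}

#' Canonical collision scenarios
#'
#' Small, deterministic scenes each containing exactly one collision of a
#' requested class, used to exercise the two collision-resolution routes:
#' `ephemeral_2` (two larvae crossing for < 8 s, shape-model territory),
#' `long_2_distinct_sizes` / `long_2_identical` (shallow-angle encounters
#' lasting >= 8 s, statistical territory; the former with a >= 25% body-length
#' difference), `triple` and `quadruple` (the latter is refused by design).
#'
#' @param kind scenario class
#' @param seed integer seed
#' @param noise_sd rendering noise (grey levels)
#' @return a `larva_scene`
#' @export
make_collision_scenario <- function(kind = c("ephemeral_2",
                                             "long_2_distinct_sizes",
                                             "long_2_identical",
                                             "triple", "quadruple"),
                                    seed = 1L, noise_sd = 1.5) {
  kind <- match.arg(kind)
  fps <- 16
  # constant mean speed of 0.8 mm/s regardless of body length, so that
  # differently sized larvae can stay in contact for a programmed duration
  quiet <- function(bl, seed2) larva_params(body_length_mm = bl,
                                            stride_bl = 0.8 / bl,
                                            hc_rate_hz = 0, rng_seed = seed2)
  arena <- c(40, 40)
  if (kind == "ephemeral_2") {
    dur <- 30
    # perpendicular crossing at the arena centre around t = 15 s; silhouette
    # overlap lasts about 6 s (< 8 s, shape-model territory)
    t1 <- simulate_track(quiet(4, seed), dur, fps,
                         start_mm = c(8, 20), heading_deg = 0)
    t2 <- simulate_track(quiet(4, seed + 1), dur, fps,
                         start_mm = c(20, 8), heading_deg = -90)
    tracks <- list(t1, t2)
  } else if (kind %in% c("long_2_distinct_sizes", "long_2_identical")) {
    dur <- 60
    arena <- c(60, 60)
    bl2 <- if (kind == "long_2_distinct_sizes") 3 else 4
    # shallow-angle (10 deg) encounter: transverse closing speed ~0.14 mm/s
    # keeps the silhouettes merged for roughly 10 s (>= 8 s, statistical).
    # the identical-size pair is laid out mirror-symmetrically about the
    # contact line so neither larva acquires a raster-specific signature
    t1 <- simulate_track(quiet(4, seed), dur, fps,
                         start_mm = c(5, 30), heading_deg = 0)
    if (kind == "long_2_identical")
      t1 <- simulate_track(quiet(4, seed), dur, fps,
                           start_mm = c(5.5, 28.5), heading_deg = -5)
    t2 <- simulate_track(quiet(bl2, seed + 1), dur, fps,
                         start_mm = c(5.5, if (kind == "long_2_identical")
                                            31.5 else 33),
                         heading_deg = if (kind == "long_2_identical") 5 else 10)
    tracks <- list(t1, t2)
  } else if (kind == "triple") {
    dur <- 25
    ctr <- c(20, 20); R <- 8
    tracks <- lapply(0:2, function(k) {
      phi <- 120 * k
      pos <- ctr + R * c(cos(phi * pi / 180), -sin(phi * pi / 180))
      simulate_track(quiet(4, seed + k), dur, fps, pos, phi + 180)
    })
  } else {
    dur <- 25
    t1 <- simulate_track(quiet(4, seed), dur, fps, c(12, 20), 0)
    t2 <- simulate_track(quiet(4, seed + 1), dur, fps, c(28, 20.3), 180)
    t3 <- simulate_track(quiet(4, seed + 2), dur, fps, c(20.3, 12), -90)
    t4 <- simulate_track(quiet(4, seed + 3), dur, fps, c(19.8, 28), 90)
    tracks <- list(t1, t2, t3, t4)
  }
  render_scene(tracks, arena_mm = arena, noise_sd = noise_sd, seed = seed)
}

#' Six-larva scene with four programmed pairwise collisions
#'
#' A 3-minute benchmark scene: six straight-crawling larvae (0.3 mm/s) whose
#' path crossings are timed so that two collisions are ephemeral (about 6 s,
#' shape-model territory) and two last well beyond 8 s with body-length
#' differences of at least 25% (statistical territory). Two larvae take part
#' in two collisions each, exercising identity chaining. Frame rate is a
#' free parameter of the acquisition (the default keeps rendering cheap).
#'
#' @param fps frame rate (>= 8)
#' @param seed scene seed (noise and any stochastic kinematics)
#' @param duration_s scene length
#' @param noise_sd rendering noise
#' @return a `larva_scene`
#' @export
make_multi_collision_scene <- function(fps = 12, seed = 1L, duration_s = 180,
                                       noise_sd = 1.5) {
  quiet <- function(bl, seed2) larva_params(body_length_mm = bl,
                                            stride_bl = 0.3 / bl,
                                            hc_rate_hz = 0, rng_seed = seed2)
  lay <- list( # body length, start, heading
    A = list(4.0, c(8, 20), 0),       # ephemeral with B (~40 s), C (~125 s)
    B = list(4.0, c(20.2, 4), -90),
    C = list(4.0, c(45.8, 61.6), 90), # long with D (~55-65 s), then meets A
    D = list(3.0, c(64.7, 41.6), 180),
    E = list(4.5, c(38.3, 6), -90),   # long with F (~65-75 s)
    F = list(3.2, c(61.2, 30.4), 180))
  tracks <- lapply(seq_along(lay), function(i)
    simulate_track(quiet(lay[[i]][[1]], seed + i), duration_s, fps,
                   start_mm = lay[[i]][[2]], heading_deg = lay[[i]][[3]]))
  render_scene(tracks, arena_mm = c(70, 70), noise_sd = noise_sd, seed = seed)
}

#' Write a scene to disk as a PGM stack plus JSON ground truth
#'
#' @param scene a `larva_scene`
#' @param dir output directory (created if missing)
#' @param every write every k-th frame (thinning for quick inspection)
#' @export
write_scene <- function(scene, dir, every = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- seq(1, scene$n_frames, by = every)
  for (i in idx)
    write_pgm(scene$frame(i), file.path(dir, sprintf("frame%06d.pgm", i)))
  gt <- scene$ground_truth
  out <- list(
    fps = scene$fps, mm_per_px = scene$mm_per_px, polarity = scene$polarity,
    n_frames = scene$n_frames,
    larvae = lapply(gt$larvae, function(g) list(
      body_length_mm = g$params$body_length_mm,
      steps = g$steps, hcs = g$hcs, switches = g$switches)),
    collisions = gt$collisions)
  jsonlite::write_json(out, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
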