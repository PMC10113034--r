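# Shared fixture builders. Everything is generated in code; no binary data.

with_seed <- larvatrack:::with_seed

# synthetic attribute records for cohort/forest tests: 30 standard-normal
# features, optionally shifting one feature by `shift` SD
fake_record <- function(seed, shift = 0) {
  set.seed(seed)
  vals <- as.list(rnorm(30))
  names(vals) <- rf_attribute_names()
  vals$is_speed_bl <- vals$is_speed_bl + shift
  as.data.frame(vals)
}

two_class_table <- function(n_per = 20, shift = 5, seed = 1) {
  recs <- c(lapply(seq_len(n_per), function(i) fake_record(seed * 1000 + i, 0)),
            lapply(seq_len(n_per), function(i)
              fake_record(seed * 2000 + i, shift)))
  cohort_table(recs, rep(c("ctrl", "mut"), each = n_per))
}

# memoized expensive fixtures (shared across test files within one run)
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

ephemeral_state <- function() {
  cached_fixture("eph", {
    sc <- make_collision_scenario("ephemeral_2", seed = 1)
    list(scene = sc, state = track_pipeline(sc, track_config()))
  })
}

# a quiet (no head cast) simulated larva with a given mean speed
quiet_params <- function(bl = 4, speed = 0.8, seed = 1L, ...) {
  larva_params(body_length_mm = bl, stride_bl = speed / bl, hc_rate_hz = 0,
               rng_seed = seed, ...)
}

# straight capsule boundary polygon (analytic, sub-pixel): a rectangle of
# length L and width 2*r capped with semicircles, sampled densely
capsule_polygon <- function(L = 40, r = 4, cx = 50, cy = 50, n_side = 60,
                            n_cap = 40) {
  xs <- seq(-L / 2, L / 2, length.out = n_side)
  top <- cbind(xs, -r)
  th <- seq(-pi / 2, pi / 2, length.out = n_cap)
  cap_r <- cbind(L / 2 + r * cos(th), r * sin(th))
  bot <- cbind(rev(xs), r)
  th2 <- seq(pi / 2, 3 * pi / 2, length.out = n_cap)
  cap_l <- cbind(-L / 2 + r * cos(th2), r * sin(th2))
  pts <- rbind(top, cap_r, bot, cap_l)
  pts <- pts[!duplicated(round(pts, 9)), ]
  cbind(pts[, 1] + cx, pts[, 2] + cy)
}

# capsule bent along a circular arc of given angular extent (degrees):
# centreline is an arc of length L on a circle of radius R = L / phi,
# boundary offset by r on each side, semicircular end caps
bent_capsule_polygon <- function(L = 40, r = 4, arc_deg = 90, cx = 50,
                                 cy = 50, n = 80) {
  phi <- arc_deg * pi / 180
  R <- L / phi
  pt <- function(th, rad) cbind(rad * sin(th), rad * cos(th))
  th <- seq(0, phi, length.out = n)
  inner <- pt(th, R - r)
  outer <- pt(rev(th), R + r)
  e1 <- c(R * sin(phi), R * cos(phi))
  n1 <- c(sin(phi), cos(phi)); t1 <- c(cos(phi), -sin(phi))
  tc <- seq(0, pi, length.out = 30)
  cap_far <- cbind(e1[1] + r * (-cos(tc) * n1[1] + sin(tc) * t1[1]),
                   e1[2] + r * (-cos(tc) * n1[2] + sin(tc) * t1[2]))
  e0 <- c(0, R)
  n0 <- c(0, 1); t0 <- c(1, 0)
  cap_near <- cbind(e0[1] + r * (cos(tc) * n0[1] - sin(tc) * t0[1]),
                    e0[2] + r * (cos(tc) * n0[2] - sin(tc) * t0[2]))
  pts <- rbind(inner, cap_far, outer, cap_near)
  pts <- pts[!duplicated(round(pts, 9)), ]
  cbind(pts[, 1] + cx, pts[, 2] + cy - R + L / 2)
}

# rasterize a polygon into a logical mask (point-in-polygon per pixel centre)
polygon_mask <- function(poly, nr, nc) {
  inside <- matrix(FALSE, nr, nc)
  xs <- poly[, 1]; ys <- poly[, 2]
  n <- nrow(poly)
  for (row in seq_len(nr)) {
    py <- row
    # horizontal-ray crossing counts per row, vectorised over columns
    cross <- c()
    j <- n
    for (i in seq_len(n)) {
      if ((ys[i] > py) != (ys[j] > py)) {
        x_at <- xs[i] + (py - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
        cross <- c(cross, x_at)
      }
      j <- i
    }
    if (length(cross)) {
      cross <- sort(cross)
      for (k in seq(1, length(cross) - 1, by = 2)) {
        lo <- ceiling(cross[k]); hi <- floor(cross[k + 1])
        if (lo <= hi) inside[row, max(1, lo):min(nc, hi)] <- TRUE
      }
    }
  }
  inside
}

# independent flood-fill component labelling (oracle for extract_blobs)
flood_fill_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0]) next
    nxt <- nxt + 1L
    stack <- list(c(r0, c0))
    while (length(stack)) {
      rc <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      r <- rc[1]; c <- rc[2]
      if (r < 1 || r > nr || c < 1 || c > nc) next
      if (!mask[r, c] || lab[r, c]) next
      lab[r, c] <- nxt
      for (dr in -1:1) for (dc in -1:1)
        if (dr || dc) stack[[length(stack) + 1]] <- c(r + dr, c + dc)
    }
  }
  lab
}

# exhaustive integer minimisation oracle for the collision-graph counts.
# a variable that appears in no balance constraint only has x_i >= lb_i and
# a positive objective coefficient, so it equals lb_i in every optimum;
# enumeration (components up to 6) runs over the constrained variables only
brute_force_counts <- function(graph, max_count = 6) {
  nodes <- graph$nodes
  n <- length(nodes)
  lb <- vapply(nodes, function(nd)
    max(length(nd$parents), length(nd$children), 1L), 0L)
  internal <- Filter(function(nd) length(nd$parents) && length(nd$children),
                     nodes)
  free <- sort(unique(unlist(lapply(internal, function(nd)
    c(nd$parents, nd$children)))))
  x <- lb
  if (!length(free)) return(list(x = x, value = sum(x)))
  nf <- length(free)
  pos <- integer(n); pos[free] <- seq_len(nf)
  # constraints become checkable once their last involved variable is set
  cons <- lapply(internal, function(nd)
    list(p = pos[nd$parents], c = pos[nd$children],
         last = max(pos[c(nd$parents, nd$children)])))
  by_last <- lapply(seq_len(nf), function(k)
    Filter(function(cn) cn$last == k, cons))
  xa <- integer(nf)
  best <- NULL; best_val <- sum(lb[-free]) + Inf
  base <- sum(lb[-free])
  lbf <- lb[free]
  rest_lb <- rev(cumsum(rev(lbf)))      # lower bound on unassigned tail
  recurse <- function(k, partial) {
    if (partial + (if (k <= nf) rest_lb[k] else 0) >= best_val) return()
    if (k > nf) {
      best_val <<- partial; best <<- xa
      return()
    }
    for (v in lbf[k]:max_count) {
      xa[k] <<- v
      ok <- TRUE
      for (cn in by_last[[k]]) {
        if (sum(xa[cn$p]) != sum(xa[cn$c])) { ok <- FALSE; break }
      }
      if (ok) recurse(k + 1L, partial + v)
    }
  }
  recurse(1L, base)
  if (is.null(best)) return(list(x = NULL, value = Inf))
  x[free] <- best
  list(x = x, value = best_val)
}

# random small collision DAG in layered (time-ordered) form
random_collision_graph <- function(n_nodes = 8, seed = 1) {
  set.seed(seed)
  nodes <- lapply(seq_len(n_nodes), function(i)
    list(id = i, start_frame = i, end_frame = i, blob_idx = 1L,
         parents = integer(0), children = integer(0)))
  for (i in seq_len(n_nodes)) {
    if (i == 1) next
    nparents <- sample(0:min(3, i - 1), 1, prob = c(4, 2, 1, 1)[1:(min(3, i - 1) + 1)])
    if (nparents > 0) {
      ps <- sample(seq_len(i - 1), nparents)
      nodes[[i]]$parents <- ps
      for (p in ps) nodes[[p]]$children <- c(nodes[[p]]$children, i)
    }
  }
  structure(list(nodes = nodes, n_frames = n_nodes),
            class = "collision_graph")
}

# feature histories (length/width/area/perimeter) for statistical resolution:
# correlated size features around a scale parameter
make_size_features <- function(scale, n_frames = 45, sd = 0.05, seed = 1) {
  set.seed(seed)
  len <- rnorm(n_frames, scale, sd)
  cbind(len = len,
        wid = 0.2 * len + rnorm(n_frames, 0, sd / 4),
        area = 0.16 * len^2 + rnorm(n_frames, 0, sd / 2),
        per = 2.2 * len + rnorm(n_frames, 0, sd / 2))
}
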