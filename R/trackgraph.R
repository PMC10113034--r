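#' Match blobs between consecutive frames by pixel overlap
#'
#' Builds the bipartite pixel-overlap graph between the blobs of two
#' consecutive frames and classifies each connected component into the five
#' match categories: `one_one` (clean continuation), `one_one_partial`
#' (continuation whose overlap is less than half of the smaller blob),
#' `one_N` (split), `N_one` (merge) and `N_M`.
#'
#' @param prev,curr lists of blobs from [extract_blobs()] for frames t-1, t
#' @return list of matches: each holds `old` / `new` (blob indices),
#'   `category` and the overlap submatrix
#' @export
match_blobs <- function(prev, curr) {
  if (!length(prev) || !length(curr)) return(list())
  ov <- .overlap_counts(lapply(prev, `[[`, "pixels"),
                        lapply(curr, `[[`, "pixels"))
  # connected components of the bipartite nonzero-overlap graph
  np <- length(prev); nc <- length(curr)
  comp_old <- rep(0L, np); comp_new <- rep(0L, nc)
  ncomp <- 0L
  for (i in seq_len(np)) {
    if (comp_old[i] || all(ov[i, ] == 0)) next
    ncomp <- ncomp + 1L
    qo <- i
    while (length(qo)) {
      o <- qo[1]; qo <- qo[-1]
      if (comp_old[o]) next
      comp_old[o] <- ncomp
      for (j in which(ov[o, ] > 0)) {
        if (!comp_new[j]) {
          comp_new[j] <- ncomp
          qo <- c(qo, which(ov[, j] > 0))
        }
      }
    }
  }
  out <- list()
  for (k in seq_len(ncomp)) {
    old <- which(comp_old == k); new <- which(comp_new == k)
    cat_ <- if (length(old) == 1 && length(new) == 1) {
      small <- min(prev[[old]]$area_px, curr[[new]]$area_px)
      if (ov[old, new] < 0.5 * small) "one_one_partial" else "one_one"
    } else if (length(old) == 1) "one_N"
    else if (length(new) == 1) "N_one"
    else "N_M"
    out[[k]] <- list(old = old, new = new, category = cat_,
                     overlap = ov[old, new, drop = FALSE])
  }
  out
}

#' Build the collision graph over a whole blob stream
#'
#' Nodes are maximal blob lifetimes (chains of `one_one` continuations);
#' merges and splits close the involved nodes and open new ones, recording
#' parent/child edges. The resulting directed acyclic graph is the input of
#' the larva-count optimisation.
#'
#' @param blobs_by_frame list (per frame) of blob lists from [extract_blobs()]
#' @return a `collision_graph`: `nodes` (list with `id`, `start_frame`,
#'   `end_frame`, `blob_idx` per frame, `parents`, `children`) and `n_frames`
#' @export
build_collision_graph <- function(blobs_by_frame) {
  n_frames <- length(blobs_by_frame)
  nodes <- list()
  new_node <- function(start, blob_idx) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, start_frame = start, end_frame = start,
                         blob_idx = c(blob_idx), parents = integer(0),
                         children = integer(0))
    id
  }
  active <- if (length(blobs_by_frame[[1]]))
    vapply(seq_along(blobs_by_frame[[1]]), function(j) new_node(1L, j), 0L)
  else integer(0)
  for (t in seq_len(n_frames)[-1]) {
    prev <- blobs_by_frame[[t - 1]]; curr <- blobs_by_frame[[t]]
    matches <- match_blobs(prev, curr)
    nxt <- rep(NA_integer_, length(curr))
    matched_new <- logical(length(curr))
    for (m in matches) {
      if (length(m$old) == 1 && length(m$new) == 1) {
        id <- active[m$old]
        nodes[[id]]$end_frame <- t
        nodes[[id]]$blob_idx <- c(nodes[[id]]$blob_idx, m$new)
        nxt[m$new] <- id
      } else {
        pids <- active[m$old]
        for (j in m$new) {
          cid <- new_node(t, j)
          nodes[[cid]]$parents <- pids
          for (p in pids)
            nodes[[p]]$children <- union(nodes[[p]]$children, cid)
          nxt[j] <- cid
        }
      }
      matched_new[m$new] <- TRUE
    }
    for (j in which(!matched_new)) nxt[j] <- new_node(t, j)  # appeared
    active <- nxt
  }
  structure(list(nodes = nodes, n_frames = n_frames),
            class = "collision_graph")
}

#' @export
print.collision_graph <- function(x, ...) {
  ne <- sum(vapply(x$nodes, function(nd) length(nd$children), 0))
  cat(sprintf("<collision_graph> %d nodes, %d edges over %d frames\n",
              length(x$nodes), ne, x$n_frames))
  invisible(x)
}

#' Solve per-node larva counts by linear programming
#'
#' Minimises the total larva count over the collision graph subject to (1)
#' each node holding at least `max(|parents|, |children|, 1)` larvae and (2)
#' flow balance at every internal node: the counts of its parents sum to the
#' counts of its children. The constraint matrix is totally unimodular, so
#' the LP relaxation (solved with the simplex method) is guaranteed to have
#' an integral optimum; the solution is asserted integral to 1e-6 and
#' rounded.
#'
#' @param graph a [build_collision_graph()] result
#' @return integer vector of larva counts per node
#' @export
solve_larva_counts <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0) return(integer(0))
  lb <- vapply(nodes, function(nd)
    max(length(nd$parents), length(nd$children), 1L), 0L)
  eq <- NULL
  for (nd in nodes) {
    if (length(nd$parents) && length(nd$children)) {
      row <- numeric(n)
      row[nd$parents] <- row[nd$parents] + 1
      row[nd$children] <- row[nd$children] - 1
      eq <- rbind(eq, row)
    }
  }
  if (is.null(eq)) return(as.integer(lb))
  # substitute x = lb + u (u >= 0) to fold the lower bounds away, leaving an
  # equality-only standard-form LP
  rhs <- as.numeric(-eq %*% lb)
  sol <- lp_solve_min(rep(1, n), eq, rhs)
  if (sol$status != "optimal")
    stop("larva-count LP ", sol$status, "; malformed collision graph?")
  x <- lb + sol$x
  if (any(abs(x - round(x)) > 1e-6))
    stop("LP solution unexpectedly non-integral; totally unimodular ",
         "constraint matrix violated")
  as.integer(round(x))
}

# ---- subtracks -------------------------------------------------------------

#' Split a single-larva node into subtracks and assign its head end
#'
#' Within one single-larva blob lifetime, per-frame poses are first aligned
#' so the two endpoints form continuous trajectories; the track is split
#' wherever a pose is invalid or an endpoint jumps farther than
#' `max_jump_bl` body lengths between frames. Per subtrack, three head votes
#' are computed over the whole subtrack: lower mean image brightness in a
#' disc around the endpoint, larger total distance covered, and net motion
#' away from the previous-frame centroid. The majority assigns the head,
#' which is mapped onto spine index 12; full ties yield `ambiguous`.
#'
#' @param poses list of `larva_pose` per frame of the node
#' @param blobs list of the node's blobs (same length; used for patches)
#' @param mm_per_px calibration
#' @param fps frame rate
#' @param start_frame video frame of the first pose
#' @param max_jump_bl endpoint-continuity bound (body lengths/frame)
#' @param brightness_radius_px radius of the brightness-vote disc
#' @return list of subtracks: `frames`, `spine` (oriented, mm),
#'   `pose_extras` (length/width/area/perimeter), `head_end`, `votes`
#' @export
split_and_orient_subtracks <- function(poses, blobs, mm_per_px, fps,
                                       start_frame = 1L, max_jump_bl = 0.5,
                                       brightness_radius_px = 10) {
  n <- length(poses)
  valid <- vapply(poses, function(p) isTRUE(p$valid), TRUE)
  # orientation-align consecutive poses and find split points
  spines <- vector("list", n)
  breaks <- logical(n)   # TRUE = subtrack must start here
  breaks[1] <- TRUE
  bl_ref <- median(vapply(poses[valid], function(p) p$body_length_mm, 0))
  prev <- NULL
  for (f in seq_len(n)) {
    if (!valid[f]) { breaks[f] <- TRUE; prev <- NULL; next }
    sp <- poses[[f]]$spine
    if (!is.null(prev)) {
      d_keep <- sqrt(sum((sp[1, ] - prev[1, ])^2)) +
                sqrt(sum((sp[12, ] - prev[12, ])^2))
      d_flip <- sqrt(sum((sp[1, ] - prev[12, ])^2)) +
                sqrt(sum((sp[12, ] - prev[1, ])^2))
      if (d_flip < d_keep) sp <- sp[12:1, ]
      jump <- max(sqrt(sum((sp[1, ] - prev[1, ])^2)),
                  sqrt(sum((sp[12, ] - prev[12, ])^2)))
      if (jump > max_jump_bl * bl_ref) breaks[f] <- TRUE
    } else if (f > 1) breaks[f] <- TRUE
    spines[[f]] <- sp
    prev <- sp
  }
  # carve into subtracks of consecutive valid frames
  subs <- list()
  f <- 1
  while (f <= n) {
    if (!valid[f]) { f <- f + 1; next }
    g <- f
    while (g + 1 <= n && valid[g + 1] && !breaks[g + 1]) g <- g + 1
    subs[[length(subs) + 1]] <- f:g
    f <- g + 1
  }
  lapply(subs, function(idx) {
    sp <- array(NA_real_, c(length(idx), 12, 2))
    for (k in seq_along(idx)) sp[k, , ] <- spines[[idx[k]]]
    votes <- head_votes(sp, blobs[idx], mm_per_px, brightness_radius_px)
    head_end <- if (votes$head_A > votes$head_B) "A"
                else if (votes$head_B > votes$head_A) "B" else "ambiguous"
    if (head_end == "A") sp <- sp[, 12:1, , drop = FALSE]
    extras <- data.frame(
      body_length_mm = vapply(poses[idx], `[[`, 0, "body_length_mm"),
      width_mm = vapply(poses[idx], `[[`, 0, "width_mm"),
      area_mm2 = vapply(poses[idx], `[[`, 0, "area_mm2"),
      perimeter_mm = vapply(poses[idx], `[[`, 0, "perimeter_mm"))
    list(frames = start_frame + idx - 1L, spine = sp, pose_extras = extras,
         head_end = head_end, votes = votes)
  })
}

# the three endpoint head/tail votes; endpoint A = spine row 1, B = row 12
head_votes <- function(spine, blobs, mm_per_px, radius_px) {
  nf <- dim(spine)[1]
  eA <- spine[, 1, , drop = FALSE][, 1, ]
  eB <- spine[, 12, , drop = FALSE][, 1, ]
  if (nf == 1) { eA <- matrix(eA, 1); eB <- matrix(eB, 1) }
  bright <- function(e_mm) {
    vals <- c()
    for (f in seq_len(nf)) {
      b <- blobs[[f]]
      if (is.null(b$patch)) next
      px <- mm_to_px(matrix(e_mm[f, ], 1), mm_per_px)
      cx <- px[1] - b$patch_offset[1]; cy <- px[2] - b$patch_offset[2]
      nr <- nrow(b$patch); nc2 <- ncol(b$patch)
      r0 <- max(1, floor(cy - radius_px)); r1 <- min(nr, ceiling(cy + radius_px))
      c0 <- max(1, floor(cx - radius_px)); c1 <- min(nc2, ceiling(cx + radius_px))
      if (r0 > r1 || c0 > c1) next
      rows <- r0:r1; cols <- c0:c1
      dd <- outer((rows - cy)^2, (cols - cx)^2, `+`)
      sel <- dd <= radius_px^2
      if (any(sel)) vals <- c(vals, mean(b$patch[rows, cols][sel]))
    }
    if (length(vals)) mean(vals) else NA_real_
  }
  brA <- bright(eA); brB <- bright(eB)
  distA <- if (nf > 1) sum(sqrt(rowSums(diff(eA)^2))) else 0
  distB <- if (nf > 1) sum(sqrt(rowSums(diff(eB)^2))) else 0
  centroid <- do.call(rbind, lapply(blobs, function(b)
    px_to_mm(matrix(b$centroid, 1), mm_per_px)))
  away <- function(e) {
    if (nf < 2) return(0)
    sum(sqrt(rowSums((e[-1, , drop = FALSE] - centroid[-nf, , drop = FALSE])^2)) -
        sqrt(rowSums((e[-nf, , drop = FALSE] - centroid[-nf, , drop = FALSE])^2)))
  }
  awA <- away(eA); awB <- away(eB)
  vA <- 0L; vB <- 0L
  # brightness differences within ~2 grey levels are measurement noise
  # (true head darkening is an order of magnitude larger): no vote
  if (is.finite(brA) && is.finite(brB) && abs(brA - brB) > 2) {
    if (brA < brB) vA <- vA + 1L else vB <- vB + 1L
  }
  if (distA != distB) { if (distA > distB) vA <- vA + 1L else vB <- vB + 1L }
  if (awA != awB) { if (awA > awB) vA <- vA + 1L else vB <- vB + 1L }
  list(head_A = vA, head_B = vB,
       brightness = c(A = brA, B = brB),
       distance = c(A = distA, B = distB),
       away = c(A = awA, B = awB))
}
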