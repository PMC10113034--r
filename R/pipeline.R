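#' Tracking configuration
#'
#' @param polarity `"dark"` or `"light"` larvae
#' @param roi optional region of interest
#' @param min_area_px minimum blob area; when `NULL`, 25% of the median blob
#'   area observed on a probe frame (speckle filter that scales with larva
#'   size)
#' @param resolution `"full"` (shape model + statistical) or `"none"`
#' @param ephemeral_max_s maximum duration handled by the shape model
#' @param min_stable_frames single-larva nodes shorter than this adjacent to
#'   a collision are absorbed into the collision event (suppresses
#'   merge/split flicker at contact boundaries); default `0.5 s * fps`
#' @param stat_max_frames,stat_min_frames,stat_margin statistical-resolution
#'   sample cap, minimum history and p-value dominance factor
#' @param max_jump_bl endpoint-continuity bound for subtrack splitting
#' @param brightness_radius_px disc radius of the brightness head vote
#' @param background optional precomputed [build_background()] model (e.g.
#'   from an empty-dish recording); when NULL the model is estimated from
#'   the central third of the video itself
#' @export
track_config <- function(polarity = "dark", roi = NULL, min_area_px = NULL,
                         resolution = c("full", "none"),
                         ephemeral_max_s = 8, min_stable_frames = NULL,
                         stat_max_frames = 45, stat_min_frames = 10,
                         stat_margin = 1000, max_jump_bl = 0.5,
                         brightness_radius_px = 10, background = NULL) {
  structure(list(polarity = polarity, roi = roi, min_area_px = min_area_px,
                 background = background,
                 resolution = match.arg(resolution),
                 ephemeral_max_s = ephemeral_max_s,
                 min_stable_frames = min_stable_frames,
                 stat_max_frames = stat_max_frames,
                 stat_min_frames = stat_min_frames,
                 stat_margin = stat_margin, max_jump_bl = max_jump_bl,
                 brightness_radius_px = brightness_radius_px),
            class = "track_config")
}

#' Run tracking phases 1-2: segmentation, graph, counts, poses, subtracks
#'
#' The expensive image-processing part of [track_scene()], separated so the
#' collision-resolution phase can be finalized more than once (e.g. with and
#' without resolution) from one pass over the frames.
#'
#' @param frames a [frame_sequence()]
#' @param config a [track_config()]
#' @param verbose print per-phase progress
#' @return a `tracking_state` for [finalize_tracks()]
#' @export
track_pipeline <- function(frames, config = track_config(), verbose = FALSE) {
  bg <- config$background %||% build_background(frames)
  n <- frames$n_frames
  blobs_by_frame <- vector("list", n)
  min_area <- config$min_area_px
  for (i in seq_len(n)) {
    f <- frames$frame(i)
    mask <- segment_frame(f, bg, config$polarity, config$roi)
    if (is.null(min_area)) {
      probe <- extract_blobs(mask, 5, i)
      if (length(probe)) {
        min_area <- 0.25 * median(vapply(probe, `[[`, 0, "area_px"))
        if (verbose) message("auto min_area_px = ", round(min_area, 1))
      }
    }
    blobs_by_frame[[i]] <- extract_blobs(mask, min_area %||% 5, i, f)
    if (verbose && i %% 500 == 0) message("segmented frame ", i, "/", n)
  }
  graph <- build_collision_graph(blobs_by_frame)
  counts <- solve_larva_counts(graph)
  if (verbose) message(length(graph$nodes), " nodes, counts solved")

  node_poses <- vector("list", length(graph$nodes))
  node_subtracks <- vector("list", length(graph$nodes))
  for (id in seq_along(graph$nodes)) {
    if (counts[id] != 1L) next
    nd <- graph$nodes[[id]]
    fr <- nd$start_frame:nd$end_frame
    blobs <- lapply(seq_along(fr), function(k)
      blobs_by_frame[[fr[k]]][[nd$blob_idx[k]]])
    node_poses[[id]] <- lapply(blobs, blob_pose, mm_per_px = frames$mm_per_px)
    node_subtracks[[id]] <- split_and_orient_subtracks(
      node_poses[[id]], blobs, frames$mm_per_px, frames$fps,
      start_frame = nd$start_frame, max_jump_bl = config$max_jump_bl,
      brightness_radius_px = config$brightness_radius_px)
  }
  structure(list(fps = frames$fps, mm_per_px = frames$mm_per_px,
                 n_frames = n, background = bg,
                 blobs_by_frame = blobs_by_frame, graph = graph,
                 counts = counts, node_poses = node_poses,
                 node_subtracks = node_subtracks, config = config),
            class = "tracking_state")
}

# collision complexes: connected groups of multi-larva nodes plus unstable
# (shorter than min_stable_frames) single-larva nodes attached to them
find_collision_complexes <- function(graph, counts, min_stable) {
  nodes <- graph$nodes
  len <- vapply(nodes, function(nd) nd$end_frame - nd$start_frame + 1L, 0L)
  in_complex <- counts >= 2L | (counts == 1L & len < min_stable &
    (vapply(nodes, function(nd) length(nd$parents) > 0 ||
              length(nd$children) > 0, TRUE)))
  ids <- which(in_complex)
  if (!length(ids)) return(list())
  comp <- stats::setNames(ids, ids)
  findr <- function(i) { while (comp[[as.character(i)]] != i) i <- comp[[as.character(i)]]; i }
  for (id in ids) {
    for (nb in c(nodes[[id]]$parents, nodes[[id]]$children)) {
      if (in_complex[nb]) {
        a <- findr(id); b <- findr(nb)
        if (a != b) comp[[as.character(a)]] <- b
      }
    }
  }
  split(ids, vapply(ids, findr, 0))
}

# build collision events from complexes
collision_events <- function(graph, counts, min_stable) {
  nodes <- graph$nodes
  complexes <- find_collision_complexes(graph, counts, min_stable)
  lapply(complexes, function(members) {
    inside <- rep(FALSE, length(nodes)); inside[members] <- TRUE
    in_nodes <- sort(unique(unlist(lapply(members, function(id)
      nodes[[id]]$parents[!inside[nodes[[id]]$parents] &
                            counts[nodes[[id]]$parents] == 1L]))))
    out_nodes <- sort(unique(unlist(lapply(members, function(id)
      nodes[[id]]$children[!inside[nodes[[id]]$children] &
                             counts[nodes[[id]]$children] == 1L]))))
    span <- c(min(vapply(nodes[members], `[[`, 0L, "start_frame")),
              max(vapply(nodes[members], `[[`, 0L, "end_frame")))
    n_larvae <- max(counts[members], length(in_nodes), length(out_nodes))
    kind <- if (n_larvae >= 4) "oversized"
    else if (length(in_nodes) != length(out_nodes) ||
             length(in_nodes) == 0) "asymmetric"
    else if (length(in_nodes) == 2) "symmetric_2"
    else if (length(in_nodes) == 3) "symmetric_3"
    else "asymmetric"
    list(members = members, in_nodes = in_nodes, out_nodes = out_nodes,
         start_frame = span[1], end_frame = span[2], n_larvae = n_larvae,
         kind = kind)
  })
}

# size-feature history (length/width/area/perimeter per valid frame) of a node
node_features <- function(state, id) {
  poses <- state$node_poses[[id]]
  ok <- vapply(poses, function(p) isTRUE(p$valid), TRUE)
  do.call(rbind, lapply(poses[ok], function(p)
    c(len = p$body_length_mm, wid = p$width_mm, area = p$area_mm2,
      per = p$perimeter_mm)))
}

#' Finalize tracking: resolve collisions and assemble track records
#'
#' @param state a [track_pipeline()] result
#' @param resolution `"full"` or `"none"` (overrides the config)
#' @return a `larva_tracking`: `records` (list of [track_record()]),
#'   `events` (collision events with resolution outcomes), `counts`,
#'   `graph`, `stats` (incl. `frac_frames_in_long_tracks`)
#' @export
finalize_tracks <- function(state, resolution = NULL) {
  cfg <- state$config
  if (!is.null(resolution)) cfg$resolution <- resolution
  graph <- state$graph
  counts <- state$counts
  nodes <- graph$nodes
  min_stable <- cfg$min_stable_frames %||% max(2L, round(0.5 * state$fps))
  events <- collision_events(graph, counts, min_stable)

  # identity union-find over stable single-larva nodes
  parent <- seq_along(nodes)
  findr <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  link <- function(a, b) { ra <- findr(a); rb <- findr(b)
                           if (ra != rb) parent[ra] <<- rb }

  if (cfg$resolution == "full") {
    for (e in seq_along(events)) {
      ev <- events[[e]]
      res <- resolve_event(state, ev, cfg)
      events[[e]]$resolution <- res
      if (isTRUE(res$resolved)) {
        for (i in seq_along(ev$in_nodes))
          link(ev$in_nodes[i], ev$out_nodes[res$mapping[i]])
      }
    }
  }

  len <- vapply(nodes, function(nd) nd$end_frame - nd$start_frame + 1L, 0L)
  in_any_complex <- rep(FALSE, length(nodes))
  for (ev in events) in_any_complex[ev$members] <- TRUE
  keep <- counts == 1L & !in_any_complex
  roots <- vapply(which(keep), findr, 0L)
  groups <- split(which(keep), roots)

  records <- lapply(seq_along(groups), function(g) {
    ids <- groups[[g]]
    f0 <- min(vapply(nodes[ids], `[[`, 0L, "start_frame"))
    f1 <- max(vapply(nodes[ids], `[[`, 0L, "end_frame"))
    sp <- array(NA_real_, c(f1 - f0 + 1L, 12, 2))
    for (id in ids) {
      for (st in state$node_subtracks[[id]]) {
        rows <- st$frames - f0 + 1L
        sp[rows, , ] <- st$spine
      }
    }
    rec <- track_record(sp, state$fps, id = paste0("track", g),
                        start_frame = f0)
    attr(rec, "nodes") <- ids
    rec
  })

  n_frames <- state$n_frames
  covered <- vapply(records, function(r) sum(is.finite(r$spine[, 1, 1])), 0)
  span <- vapply(records, function(r) r$duration_frames, 0)
  frac_long <- if (sum(covered) > 0)
    sum(covered[span >= n_frames / 2]) / sum(covered) else NA_real_

  structure(list(records = records, events = events, counts = counts,
                 graph = graph, resolution = cfg$resolution,
                 stats = list(
                   n_records = length(records),
                   n_events = length(events),
                   n_resolved = sum(vapply(events, function(e)
                     isTRUE(e$resolution$resolved), TRUE)),
                   frac_frames_in_long_tracks = frac_long)),
            class = "larva_tracking")
}

# dispatch one collision event to the appropriate resolution route
resolve_event <- function(state, ev, cfg) {
  unres <- function(reason, refused = FALSE)
    structure(list(resolved = FALSE, mapping = NULL, refused = refused,
                   method = "none", evidence = list(reason = reason)),
              class = "assignment_result")
  if (ev$kind == "oversized") return(unres("oversized: 4+ larvae", TRUE))
  if (ev$kind == "asymmetric") return(unres("asymmetric participant sets"))
  span_s <- (ev$end_frame - ev$start_frame + 1) / state$fps
  core <- ev$members[state$counts[ev$members] >= 2L]
  if (ev$kind == "symmetric_2" && span_s < cfg$ephemeral_max_s &&
      length(core) == 1) {
    entry <- lapply(ev$in_nodes, function(id) {
      poses <- state$node_poses[[id]]
      ok <- which(vapply(poses, function(p) isTRUE(p$valid), TRUE))
      if (!length(ok)) return(NULL)
      poses[[max(ok)]]
    })
    if (!any(vapply(entry, is.null, TRUE))) {
      nd <- state$graph$nodes[[core]]
      fr <- nd$start_frame:nd$end_frame
      cblobs <- lapply(seq_along(fr), function(k)
        state$blobs_by_frame[[fr[k]]][[nd$blob_idx[k]]])
      exit_px <- do.call(rbind, lapply(ev$out_nodes, function(id) {
        ndo <- state$graph$nodes[[id]]
        state$blobs_by_frame[[ndo$start_frame]][[ndo$blob_idx[1]]]$centroid
      }))
      res <- resolve_shape_model(entry, cblobs, exit_px, state$mm_per_px)
      if (isTRUE(res$resolved)) return(res)
      # fall through to the statistical route on a failed geometric fit
    }
  }
  fin <- lapply(ev$in_nodes, function(id) node_features(state, id))
  fout <- lapply(ev$out_nodes, function(id) node_features(state, id))
  if (any(vapply(fin, is.null, TRUE)) || any(vapply(fout, is.null, TRUE)))
    return(unres("missing pose history"))
  resolve_statistical(fin, fout, max_frames = cfg$stat_max_frames,
                      min_frames = cfg$stat_min_frames,
                      margin = cfg$stat_margin)
}

#' Track a scene end to end
#'
#' @inheritParams track_pipeline
#' @return a `larva_tracking` (see [finalize_tracks()])
#' @export
track_scene <- function(frames, config = track_config(), verbose = FALSE) {
  finalize_tracks(track_pipeline(frames, config, verbose))
}

#' @export
print.larva_tracking <- function(x, ...) {
  cat(sprintf(paste0("<larva_tracking> %d records, %d collision events ",
                     "(%d resolved), long-track fraction %.3f\n"),
              x$stats$n_records, x$stats$n_events, x$stats$n_resolved,
              x$stats$frac_frames_in_long_tracks))
  invisible(x)
}

#' Match track records to simulator ground truth
#'
#' For every record, each valid frame's spine midpoint is matched to the
#' nearest true larva; the record's identity is the majority match and its
#' purity the fraction of frames agreeing with it.
#'
#' @param tracking a `larva_tracking`
#' @param scene the `larva_scene` that produced it
#' @return data.frame: `record`, `gt_id`, `purity`, `covered_frames`
#' @export
match_records_to_truth <- function(tracking, scene) {
  gts <- scene$ground_truth$larvae
  rows <- lapply(seq_along(tracking$records), function(r) {
    rec <- tracking$records[[r]]
    ok <- which(is.finite(rec$spine[, 6, 1]))
    if (!length(ok)) return(NULL)
    frames <- rec$start_frame + ok - 1L
    best <- vapply(seq_along(ok), function(k) {
      mid <- rec$spine[ok[k], 6, ]
      d <- vapply(gts, function(g)
        sum((g$spine[frames[k], 6, ] - mid)^2), 0)
      which.min(d)
    }, 0L)
    tab <- table(best)
    data.frame(record = r,
               gt_id = as.integer(names(tab)[which.max(tab)]),
               purity = max(tab) / length(best),
               covered_frames = length(best))
  })
  do.call(rbind, rows)
}
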