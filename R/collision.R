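# Collision resolution: a geometric shape-model route for ephemeral 2-larva
# collisions and a statistical re-identification route (PCA + Mann-Whitney
# U-tests with a factor-1000 p-value margin) for longer or asymmetric cases.

#' Five-link larva shape model state
#'
#' Orientation plus four joint angles over five equal-length segments whose
#' total length and width are frozen at collision entry. Used to follow a
#' larva through an ephemeral collision by fitting the model silhouette to
#' the residual contour each frame.
#'
#' @param spine_px 12 x 2 spine in pixel coordinates (entry pose)
#' @param width_px body width in pixels (entry pose)
#' @return a `shape_model_state`: `anchor`, `orientation`, `joints` (4),
#'   `seg_len`, `halfwidth`, `chain` (6 x 2)
#' @export
shape_model_from_pose <- function(spine_px, width_px) {
  pts <- resample_polyline(spine_px, 6)
  segs <- diff(pts)
  ang <- atan2(segs[, 2], segs[, 1])
  joints <- diff(ang)
  joints <- atan2(sin(joints), cos(joints))   # wrap to (-pi, pi]
  seg_len <- mean(sqrt(rowSums(segs^2)))
  structure(list(anchor = pts[1, ], orientation = ang[1],
                 joints = pmin(pi / 2, pmax(-pi / 2, joints)),
                 seg_len = seg_len, halfwidth = width_px / 2,
                 chain = pts), class = "shape_model_state")
}

shape_model_chain <- function(state) {
  th <- state$orientation + cumsum(c(0, state$joints))
  matrix(c(state$anchor[1] + cumsum(c(0, state$seg_len * cos(th))),
           state$anchor[2] + cumsum(c(0, state$seg_len * sin(th)))),
         ncol = 2)
}

# one grid-search update of a shape model against residual pixels
shape_model_fit <- function(state, res_xy, orient_deg = 15, orient_step = 3,
                            joint_deg = 20, joint_step = 5,
                            max_pixels = 150) {
  if (nrow(res_xy) == 0) return(list(state = state, score = 0, coverage = 0))
  if (nrow(res_xy) > max_pixels) {
    keep <- round(seq(1, nrow(res_xy), length.out = max_pixels))
    res_sub <- res_xy[keep, , drop = FALSE]
  } else res_sub <- res_xy
  # re-anchor: translate so the model chain centroid tracks the residual
  chain <- shape_model_chain(state)
  shift <- colMeans(res_sub) - colMeans(chain)
  anchor <- state$anchor + shift
  dO <- seq(-orient_deg, orient_deg, by = orient_step) * pi / 180
  dJ <- seq(-joint_deg, joint_deg, by = joint_step) * pi / 180
  fit <- .shape_fit_search(res_sub[, 1], res_sub[, 2], anchor[1], anchor[2],
                           state$orientation, state$joints, state$seg_len,
                           state$halfwidth, dO, dJ)
  state$anchor <- anchor
  state$orientation <- fit$orientation
  state$joints <- fit$joints
  state$chain <- fit$chain
  list(state = state, score = fit$score,
       coverage = fit$score / nrow(res_sub))
}

#' Resolve an ephemeral two-larva collision with the shape model
#'
#' Each participant's model is initialised from its pose one frame before
#' the collision. Per collision frame, the residual contour of a participant
#' is the merged blob minus the previous-frame silhouettes of its
#' counterparts; a brute-force grid search over orientation (+/-15 deg in
#' 3 deg steps) and the four joint angles (+/-20 deg in 5 deg steps) around
#' the previous state maximises the overlap with the residual. On exit,
#' model centroids are matched to the outgoing blobs by nearest distance.
#'
#' @param entry_poses list (per participant) of `larva_pose` one frame
#'   before the collision (pixel-space spine via `spine_px`, plus width)
#' @param collision_blobs list (per collision frame) of the merged blob
#' @param exit_centroids_px matrix (participants x 2) of the outgoing blob
#'   or subtrack centroids, in pixels
#' @param mm_per_px calibration
#' @param fit_floor minimum residual coverage counting as a successful frame
#' @param max_fail_frac unresolved when more than this fraction of frames
#'   fall below the floor
#' @return an `assignment_result`: `resolved`, `mapping` (in -> out),
#'   `method = "shape_model"`, `evidence`
#' @export
resolve_shape_model <- function(entry_poses, collision_blobs,
                                exit_centroids_px, mm_per_px,
                                fit_floor = 0.5, max_fail_frac = 0.25) {
  k <- length(entry_poses)
  states <- lapply(entry_poses, function(p)
    shape_model_from_pose(mm_to_px(p$spine, mm_per_px),
                          p$width_mm / mm_per_px))
  nfr <- length(collision_blobs)
  fails <- 0L
  scores <- numeric(0)
  for (f in seq_len(nfr)) {
    b <- collision_blobs[[f]]
    pix <- cbind((b$pixels - 1L) %/% nrow_of(b) + 1L,
                 (b$pixels - 1L) %% nrow_of(b) + 1L)  # (col=x, row=y)
    prev_chains <- lapply(states, identity)
    for (i in seq_len(k)) {
      inside_other <- rep(FALSE, nrow(pix))
      for (j in seq_len(k)) {
        if (j == i) next
        inside_other <- inside_other |
          .points_in_capsule(pix, prev_chains[[j]]$chain,
                             rep(prev_chains[[j]]$halfwidth, 6))
      }
      res <- pix[!inside_other, , drop = FALSE]
      fit <- shape_model_fit(states[[i]], res)
      states[[i]] <- fit$state
      scores <- c(scores, fit$coverage)
      if (fit$coverage < fit_floor) fails <- fails + 1L
    }
  }
  centroids <- do.call(rbind, lapply(states, function(s)
    colMeans(shape_model_chain(s))))
  mapping <- best_bijection_by_distance(centroids, exit_centroids_px)
  resolved <- fails <= max_fail_frac * (nfr * k)
  structure(list(resolved = resolved, mapping = if (resolved) mapping else NULL,
                 method = "shape_model",
                 evidence = list(mean_coverage = mean(scores),
                                 fail_frac = fails / max(1, nfr * k),
                                 final_states = states)),
            class = "assignment_result")
}

nrow_of <- function(blob) blob$img_nrow

# minimal-total-distance bijection for small k (exhaustive over permutations)
best_bijection_by_distance <- function(from_xy, to_xy) {
  k <- nrow(from_xy)
  perms <- all_permutations(k)
  cost <- vapply(perms, function(p)
    sum(sqrt(rowSums((from_xy - to_xy[p, , drop = FALSE])^2))), 0)
  perms[[which.min(cost)]]
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1)) {
    for (pos in 0:(k - 1)) {
      out[[length(out) + 1]] <- append(p, k, after = pos)
    }
  }
  out
}

# ---- statistical route -----------------------------------------------------

# joint z-scoring + first principal component of the four size features
# (body length, width, area, perimeter) pooled over all participants
collision_pc1 <- function(feature_list) {
  all <- do.call(rbind, feature_list)
  keep <- apply(all, 2, function(col) sd(col) > 1e-12)
  if (!any(keep)) return(lapply(feature_list, function(f) rep(0, nrow(f))))
  z <- scale(all[, keep, drop = FALSE])
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  sc <- z %*% pc$rotation[, 1]
  var_expl <- pc$sdev[1]^2 / sum(pc$sdev^2)
  idx <- cumsum(vapply(feature_list, nrow, 0L))
  lo <- c(1, head(idx, -1) + 1)
  out <- lapply(seq_along(feature_list), function(i) sc[lo[i]:idx[i]])
  attr(out, "var_explained") <- var_expl
  out
}

#' Resolve a collision by statistical re-identification
#'
#' Size features (body length, width, area, perimeter) of every participant
#' are z-scored jointly and projected on their first principal component.
#' For every logically consistent in-to-out bijection, two-sided
#' Mann-Whitney U-tests are run between matched participants on equal-size
#' samples: the smallest participant frame count, capped at `max_frames`
#' (ingoing larvae contribute their last frames before the collision,
#' outgoing their first frames after it). The event is resolved iff every
#' p-value of one bijection exceeds every p-value of each competing
#' bijection by at least `margin` (the factor-1000 rule). Events with four
#' or more larvae are refused outright.
#'
#' @param features_in,features_out lists (per participant) of data frames or
#'   matrices with columns body length, width, area, perimeter, one row per
#'   frame, ordered in time
#' @param max_frames sample-size cap per side
#' @param min_frames minimum history required of every participant
#' @param margin p-value dominance factor required for resolution
#' @return an `assignment_result` with `method = "statistical"`; `mapping[i]`
#'   is the out-participant matched to in-participant `i`
#' @export
resolve_statistical <- function(features_in, features_out, max_frames = 45,
                                min_frames = 10, margin = 1000) {
  k <- length(features_in)
  if (k != length(features_out))
    stop("statistical resolution needs equal in/out participant counts")
  if (k >= 4)
    return(structure(list(resolved = FALSE, mapping = NULL,
                          method = "statistical", refused = TRUE,
                          evidence = list(reason = "oversized: 4+ larvae")),
                     class = "assignment_result"))
  counts <- c(vapply(features_in, nrow, 0L), vapply(features_out, nrow, 0L))
  if (any(counts < min_frames))
    return(structure(list(resolved = FALSE, mapping = NULL,
                          method = "statistical", refused = FALSE,
                          evidence = list(reason = "insufficient history")),
                     class = "assignment_result"))
  m <- min(min(counts), max_frames)
  trimmed <- c(lapply(features_in, function(f) utils::tail(as.matrix(f), m)),
               lapply(features_out, function(f) utils::head(as.matrix(f), m)))
  pc <- collision_pc1(trimmed)
  pin <- pc[seq_len(k)]
  pout <- pc[k + seq_len(k)]
  perms <- all_permutations(k)
  pvals <- lapply(perms, function(p)
    vapply(seq_len(k), function(i)
      suppressWarnings(wilcox.test(pin[[i]], pout[[p[i]]],
                                   exact = FALSE, correct = TRUE)$p.value),
      0))
  best <- which.max(vapply(pvals, min, 0))
  # two larvae: the literal published rule (both p-values of the winning
  # assignment exceed both of the other by the margin). three larvae: every
  # competing bijection must be refuted, i.e. contain at least one pair
  # whose p-value is a margin below the winner's weakest pair -- with six
  # bijections every competitor shares a correct pair with the winner, so
  # comparing against the competitor's *largest* p would never resolve
  dominated <- all(vapply(seq_along(perms)[-best], function(j) {
    ref <- if (k == 2) max(pvals[[j]]) else min(pvals[[j]])
    min(pvals[[best]]) >= margin * ref
  }, TRUE))
  structure(list(resolved = dominated,
                 mapping = if (dominated) perms[[best]] else NULL,
                 method = "statistical", refused = FALSE,
                 evidence = list(p_values = pvals, permutations = perms,
                                 best = best,
                                 var_explained = attr(pc, "var_explained"))),
            class = "assignment_result")
}

#' Statistically re-identify a reappeared larva against a lost pool
#'
#' When a larva re-enters the arena (e.g. from the Petri-dish wall), its
#' size-feature distribution is compared by U-tests with every larva
#' previously lost there, plus pairwise tests among the pool members
#' themselves. The reappeared larva is assigned to its best match iff that
#' p-value exceeds all other computed p-values (pool matches and
#' within-pool tests) by the factor-1000 margin.
#'
#' @param pool_features list (per lost larva) of feature histories
#' @param reappeared_features feature history of the re-entering larva
#' @inheritParams resolve_statistical
#' @return an `assignment_result`; `mapping` is the pool index matched
#' @export
resolve_asymmetric <- function(pool_features, reappeared_features,
                               max_frames = 45, min_frames = 10,
                               margin = 1000) {
  np <- length(pool_features)
  if (np == 0)
    return(structure(list(resolved = FALSE, mapping = NULL,
                          method = "statistical", refused = FALSE,
                          evidence = list(reason = "empty pool")),
                     class = "assignment_result"))
  counts <- c(vapply(pool_features, nrow, 0L), nrow(reappeared_features))
  if (any(counts < min_frames))
    return(structure(list(resolved = FALSE, mapping = NULL,
                          method = "statistical", refused = FALSE,
                          evidence = list(reason = "insufficient history")),
                     class = "assignment_result"))
  m <- min(min(counts), max_frames)
  trimmed <- c(lapply(pool_features, function(f) utils::tail(as.matrix(f), m)),
               list(utils::head(as.matrix(reappeared_features), m)))
  pc <- collision_pc1(trimmed)
  pool_pc <- pc[seq_len(np)]
  re_pc <- pc[[np + 1]]
  p_match <- vapply(pool_pc, function(x)
    suppressWarnings(wilcox.test(x, re_pc, exact = FALSE)$p.value), 0)
  p_pool <- c()
  if (np > 1) {
    for (i in seq_len(np - 1)) for (j in (i + 1):np)
      p_pool <- c(p_pool, suppressWarnings(
        wilcox.test(pool_pc[[i]], pool_pc[[j]], exact = FALSE)$p.value))
  }
  best <- which.max(p_match)
  others <- c(p_match[-best], p_pool)
  resolved <- !length(others) || p_match[best] >= margin * max(others)
  structure(list(resolved = resolved,
                 mapping = if (resolved) best else NULL,
                 method = "statistical", refused = FALSE,
                 evidence = list(p_match = p_match, p_pool = p_pool)),
            class = "assignment_result")
}
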