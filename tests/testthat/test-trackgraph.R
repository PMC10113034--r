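blob_from_mask <- function(mask, frame = 1L) extract_blobs(mask, frame_index = frame)

sq_mask <- function(nr, nc, r, c, h = 4, w = 4) {
  m <- matrix(FALSE, nr, nc); m[r:(r + h - 1), c:(c + w - 1)] <- TRUE; m
}

test_that("match_blobs classifies the five overlap categories", {
  a <- blob_from_mask(sq_mask(20, 20, 3, 3))
  expect_equal(match_blobs(a, a)[[1]]$category, "one_one")

  # shifted so the single-single overlap is below half the smaller area
  b <- blob_from_mask(sq_mask(20, 20, 3, 6))   # overlap 4 px of 16
  expect_equal(match_blobs(a, b)[[1]]$category, "one_one_partial")

  # two old blobs merging into one new
  m_old <- sq_mask(20, 20, 3, 3) | sq_mask(20, 20, 3, 12)
  old2 <- blob_from_mask(m_old)
  merged <- blob_from_mask(sq_mask(20, 20, 3, 3, 4, 14))
  mm <- match_blobs(old2, merged)
  expect_equal(mm[[1]]$category, "N_one")
  expect_length(mm[[1]]$old, 2)

  # split: one old overlapping two new
  ms <- match_blobs(merged, old2)
  expect_equal(ms[[1]]$category, "one_N")

  # N-M: two horizontal old bars, two vertical new bars, cross overlaps
  oldh <- blob_from_mask(sq_mask(20, 20, 3, 2, 2, 16) |
                           sq_mask(20, 20, 9, 2, 2, 16))
  newv <- blob_from_mask(sq_mask(20, 20, 2, 4, 10, 2) |
                           sq_mask(20, 20, 2, 14, 10, 2))
  nm <- match_blobs(oldh, newv)
  expect_equal(nm[[1]]$category, "N_M")
  expect_length(nm[[1]]$old, 2); expect_length(nm[[1]]$new, 2)
})

test_that("collision graph has isolated nodes without collisions", {
  frames <- lapply(1:5, function(i)
    blob_from_mask(sq_mask(20, 40, 3, 3 + i) |
                     sq_mask(20, 40, 12, 30 - i), i))
  g <- build_collision_graph(frames)
  expect_length(g$nodes, 2)
  expect_true(all(vapply(g$nodes, function(nd)
    length(nd$parents) + length(nd$children), 0) == 0))
  expect_equal(vapply(g$nodes, `[[`, 0L, "end_frame"), c(5L, 5L))
})

test_that("a merge and split builds the 2-1-2 graph and counts", {
  seqs <- list(
    blob_from_mask(sq_mask(20, 20, 2, 2) | sq_mask(20, 20, 12, 2), 1),
    blob_from_mask(sq_mask(20, 20, 2, 2, 14, 4), 2),    # merged, spans both
    blob_from_mask(sq_mask(20, 20, 2, 2) | sq_mask(20, 20, 12, 2), 3))
  g <- build_collision_graph(seqs)
  expect_length(g$nodes, 5)
  merged <- which(vapply(g$nodes, function(nd) length(nd$parents) == 2, TRUE))
  expect_length(merged, 1)
  expect_length(g$nodes[[merged]]$children, 2)
  x <- solve_larva_counts(g)
  expect_equal(x[merged], 2L)
  expect_equal(sum(x == 1L), 4)
})

test_that("isolated nodes get count one", {
  g <- build_collision_graph(list(blob_from_mask(sq_mask(10, 10, 2, 2))))
  expect_equal(solve_larva_counts(g), 1L)
})

test_that("LP counts equal exhaustive integer minimisation on random DAGs", {
  for (s in 1:12) {
    g <- random_collision_graph(n_nodes = sample(4:9, 1), seed = s)
    lp <- solve_larva_counts(g)
    bf <- brute_force_counts(g)
    expect_equal(sum(lp), bf$value, info = paste("seed", s))
    # and the LP solution itself is feasible
    for (nd in g$nodes) {
      expect_gte(lp[nd$id], max(length(nd$parents), length(nd$children), 1))
      if (length(nd$parents) && length(nd$children))
        expect_equal(sum(lp[nd$parents]), sum(lp[nd$children]))
    }
  }
})

test_that("count conservation holds across frame cuts on a tracked scene", {
  fix <- ephemeral_state()
  g <- fix$state$graph; x <- fix$state$counts
  for (f in c(10, floor(fix$scene$n_frames / 2), fix$scene$n_frames - 10)) {
    alive <- vapply(g$nodes, function(nd)
      nd$start_frame <= f && nd$end_frame >= f, TRUE)
    expect_equal(sum(x[alive]), 2)
  }
})

test_that("head voting orients a crawling larva by majority", {
  gt <- simulate_track(quiet_params(seed = 2), 8, 16, c(6, 10), 0)
  sc <- render_scene(list(gt), arena_mm = c(30, 20), noise_sd = 1, seed = 4)
  clean_bg <- build_background(frame_sequence(list(matrix(200, sc$dim[1],
                                                          sc$dim[2])),
                                              fps = 16, mm_per_px = 0.1))
  st <- track_pipeline(sc, track_config(background = clean_bg))
  expect_equal(st$counts, 1L)
  subs <- st$node_subtracks[[1]]
  expect_gte(length(subs), 1)
  main <- subs[[which.max(vapply(subs, function(s) length(s$frames), 0))]]
  expect_true(main$head_end %in% c("A", "B"))
  expect_gte(max(main$votes$head_A, main$votes$head_B), 2)
  # oriented spine must put index 12 at the true head (leading, darker end)
  f <- main$frames[round(length(main$frames) / 2)]
  k <- which(main$frames == f)
  d_head <- sqrt(sum((main$spine[k, 12, ] - gt$spine[f, 12, ])^2))
  d_tail <- sqrt(sum((main$spine[k, 12, ] - gt$spine[f, 1, ])^2))
  expect_lt(d_head, d_tail)
})

test_that("a static symmetric blob yields an ambiguous head", {
  # symmetric capsule, no motion, uniform brightness
  mask <- polygon_mask(capsule_polygon(L = 30, r = 4, cx = 40, cy = 20), 40, 80)
  frame <- matrix(200, 40, 80); frame[mask] <- 70
  blobs <- extract_blobs(mask, frame_index = 1, frame = frame)
  poses <- list(larvatrack:::blob_pose(blobs[[1]], 0.1))
  subs <- split_and_orient_subtracks(poses, blobs, 0.1, 16)
  expect_equal(subs[[1]]$head_end, "ambiguous")
})

test_that("darkened head pixels win the brightness vote", {
  mask <- polygon_mask(capsule_polygon(L = 30, r = 4, cx = 40, cy = 20), 40, 80)
  frame <- matrix(200, 40, 80); frame[mask] <- 70
  frame[, 48:80][mask[, 48:80]] <- 40   # darken one end
  blobs <- extract_blobs(mask, frame_index = 1, frame = frame)
  poses <- list(larvatrack:::blob_pose(blobs[[1]], 0.1))
  subs <- split_and_orient_subtracks(poses, blobs, 0.1, 16)
  v <- subs[[1]]$votes
  dark_is_A <- v$brightness["A"] < v$brightness["B"]
  expect_equal(unname(if (dark_is_A) v$head_A else v$head_B), 1L)
  # the darker end ends up at spine index 12
  sp <- subs[[1]]$spine[1, , ]
  expect_gt(sp[12, 1], sp[1, 1])  # head (dark, right side) at high x
})
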