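#' Reconstruct a smooth 200-point contour from a blob boundary
#'
#' Fits periodic parametric cubic smoothing splines (one per coordinate,
#' against the chord-length parameter, with the boundary replicated one
#' period to each side to enforce periodicity) to the raw staircase boundary
#' polygon, then resamples the smooth closed curve to 200 points equidistant
#' in arc length. Signed curvature is computed from the spline derivatives;
#' its sign is normalised so that convex regions (the body tips) are
#' positive, regardless of traversal orientation.
#'
#' @param x a `larva_blob` or an n x 2 boundary polygon (ordered, closed)
#' @param df_frac smoothing-spline degrees of freedom as a fraction of the
#'   number of boundary vertices (controls staircase suppression)
#' @return a `larva_contour`: `points` (200 x 2), `curvature` (length 200,
#'   convex-positive), `ok` flag
#' @export
reconstruct_contour <- function(x, df_frac = 0.5) {
  pts <- if (inherits(x, "larva_blob")) x$contour else x
  if (is.null(dim(pts)) || nrow(pts) < 8)
    return(structure(list(points = NULL, curvature = NULL, ok = FALSE),
                     class = "larva_contour"))
  # drop consecutive duplicates, keep the polygon open (no repeated closer)
  if (all(pts[1, ] == pts[nrow(pts), ])) pts <- pts[-nrow(pts), , drop = FALSE]
  d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), ])^2))
  if (sum(d) <= 0)
    return(structure(list(points = NULL, curvature = NULL, ok = FALSE),
                     class = "larva_contour"))
  n <- nrow(pts)
  seg <- sqrt(rowSums((pts[c(2:n, 1), ] - pts)^2))
  tpar <- c(0, cumsum(seg))          # length n + 1; tpar[n+1] = period
  L <- tpar[n + 1]
  tt <- tpar[seq_len(n)]
  # replicate one period either side for a periodic fit
  t3 <- c(tt - L, tt, tt + L)
  x3 <- rep(pts[, 1], 3)
  y3 <- rep(pts[, 2], 3)
  df <- max(8, min(3 * n - 4, round(df_frac * 3 * n)))
  fx <- try(smooth.spline(t3, x3, df = df), silent = TRUE)
  fy <- try(smooth.spline(t3, y3, df = df), silent = TRUE)
  if (inherits(fx, "try-error") || inherits(fy, "try-error"))
    return(structure(list(points = NULL, curvature = NULL, ok = FALSE),
                     class = "larva_contour"))
  # dense evaluation of the central period, then equal-arc resampling
  td <- seq(0, L, length.out = 601)[-601]
  px <- predict(fx, td)$y;  py <- predict(fy, td)$y
  dx <- predict(fx, td, deriv = 1)$y;  dy <- predict(fy, td, deriv = 1)$y
  ddx <- predict(fx, td, deriv = 2)$y; ddy <- predict(fy, td, deriv = 2)$y
  kappa <- (dx * ddy - dy * ddx) / pmax(1e-12, (dx^2 + dy^2)^1.5)
  s <- c(0, cumsum(sqrt(diff(px)^2 + diff(py)^2)))
  starg <- seq(0, s[length(s)], length.out = 201)[-201]
  p200 <- cbind(approx(s, px, xout = starg)$y, approx(s, py, xout = starg)$y)
  k200 <- approx(s, kappa, xout = starg)$y
  # convex-positive: total turning of a simple closed curve is +/- 2*pi, so
  # the traversal orientation is the sign of the mean curvature
  if (mean(k200) < 0) k200 <- -k200
  structure(list(points = p200, curvature = k200, ok = TRUE),
            class = "larva_contour")
}

#' Locate the two body endpoints on a reconstructed contour
#'
#' After several passes of a small cyclic moving-average filter over the
#' curvature profile, the two largest local curvature maxima that are at
#' least `min_sep` contour positions apart (an elongated body cannot have
#' adjacent ends) are returned. Near-circular blobs without two distinct
#' maxima yield a failure flag.
#'
#' @param contour a [reconstruct_contour()] result
#' @param min_sep minimum cyclic index separation between the endpoints
#' @param smooth_k,smooth_passes moving-average kernel width and passes
#' @return list `(a, b, ok)` with 1-based contour indices
#' @export
find_endpoints <- function(contour, min_sep = 30, smooth_k = 5,
                           smooth_passes = 3) {
  fail <- list(a = NA, b = NA, ok = FALSE)
  if (!isTRUE(contour$ok)) return(fail)
  k <- cyclic_smooth(contour$curvature, smooth_k, smooth_passes)
  n <- length(k)
  # near-circular blobs (including curled larvae) have no meaningful body
  # ends: require clear elongation of the outline (principal-axis variance
  # ratio), otherwise raster staircase ripples fake curvature maxima
  ev <- eigen(stats::cov(contour$points), symmetric = TRUE,
              only.values = TRUE)$values
  if (ev[1] < 1.5 * ev[2]) return(fail)
  prev <- k[c(n, 1:(n - 1))]
  nxt <- k[c(2:n, 1)]
  locmax <- which(k > prev & k >= nxt)
  if (length(locmax) < 2) return(fail)
  # a rounded end is a curvature *plateau* (a capsule cap has constant
  # curvature): centre the endpoint within the contiguous region holding at
  # least 90% of the peak value, otherwise the tip lands on the cap edge
  centre_peak <- function(i0) {
    thr <- 0.9 * k[i0]
    lo <- 0
    while (lo < n - 1 && k[(i0 - lo - 2) %% n + 1] >= thr) lo <- lo + 1
    hi <- 0
    while (hi < n - 1 && k[(i0 + hi) %% n + 1] >= thr) hi <- hi + 1
    (i0 - 1 + round((hi - lo) / 2)) %% n + 1
  }
  cyc_dist <- function(i, j) { d <- abs(i - j); min(d, n - d) }
  ord <- locmax[order(k[locmax], decreasing = TRUE)]
  a <- centre_peak(ord[1])
  b <- NA
  for (cand in ord[-1]) {
    cc <- centre_peak(cand)
    if (cyc_dist(a, cc) >= min_sep) { b <- cc; break }
  }
  if (is.na(b)) return(fail)
  list(a = min(a, b), b = max(a, b), ok = TRUE)
}

#' Compute a larva pose (spine, contour, shape metrics) from a contour
#'
#' The spine is built as the midline of arc-paired contour points: both
#' contour arcs between the endpoints are parameterised by normalised arc
#' length, paired at equal fractions, and the pair midpoints are resampled to
#' 12 points equidistant along the spine. The orientation (which end is
#' index 1 vs 12) is arbitrary here and fixed later by head/tail voting.
#'
#' @param contour a [reconstruct_contour()] result
#' @param endpoints a [find_endpoints()] result
#' @param mm_per_px spatial calibration
#' @return a `larva_pose`: `spine` (12 x 2, mm), `contour24` (24 x 2, mm),
#'   `body_length_mm`, `width_mm` (maximum arc-pair distance),
#'   `area_mm2`, `perimeter_mm`, `head_vector`, `tail_vector`, `valid`
#' @export
compute_pose <- function(contour, endpoints, mm_per_px) {
  bad <- structure(list(spine = NULL, contour24 = NULL,
                        body_length_mm = NA_real_, width_mm = NA_real_,
                        area_mm2 = NA_real_, perimeter_mm = NA_real_,
                        head_vector = c(NA, NA), tail_vector = c(NA, NA),
                        valid = FALSE), class = "larva_pose")
  if (!isTRUE(contour$ok) || !isTRUE(endpoints$ok)) return(bad)
  p <- contour$points
  n <- nrow(p)
  a <- endpoints$a; b <- endpoints$b
  arc1 <- p[a:b, , drop = FALSE]
  arc2 <- p[c(b:n, 1:a), , drop = FALSE]   # other way round the cycle
  m <- 101
  q1 <- resample_polyline(arc1, m)
  q2 <- resample_polyline(arc2[rev(seq_len(nrow(arc2))), , drop = FALSE], m)
  mid <- (q1 + q2) / 2
  widths <- sqrt(rowSums((q1 - q2)^2))
  spine_px <- resample_polyline(mid, 12)
  if (anyNA(spine_px)) return(bad)
  spine <- px_to_mm(spine_px, mm_per_px)
  blen <- sum(sqrt(rowSums(diff(spine)^2)))
  if (!is.finite(blen) || blen <= 0) return(bad)
  c24 <- px_to_mm(resample_polyline(rbind(p, p[1, ]), 25)[-25, , drop = FALSE],
                  mm_per_px)
  pm <- px_to_mm(p, mm_per_px)
  area <- abs(sum(pm[, 1] * pm[c(2:n, 1), 2] - pm[c(2:n, 1), 1] * pm[, 2])) / 2
  perim <- sum(sqrt(rowSums((pm[c(2:n, 1), ] - pm)^2)))
  structure(list(spine = spine, contour24 = c24,
                 body_length_mm = blen,
                 width_mm = max(widths) * mm_per_px,
                 area_mm2 = area, perimeter_mm = perim,
                 head_vector = spine[11, ] - spine[9, ],
                 tail_vector = spine[6, ] - spine[2, ],
                 valid = TRUE), class = "larva_pose")
}

# one-call helper: blob -> pose
blob_pose <- function(blob, mm_per_px, ...) {
  ct <- reconstruct_contour(blob, ...)
  ep <- find_endpoints(ct)
  compute_pose(ct, ep, mm_per_px)
}
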