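# Shared geometry and RNG helpers. Coordinates are raster style throughout:
# x grows rightwards (columns), y grows downwards (rows). "Left of heading"
# is defined with the y-flip folded in, so that a larva viewed on screen
# turning to its own left gets positive left-angles regardless of the raster
# orientation.

# signed angle (degrees) from vector a to vector b, positive = b is to the
# LEFT of a (counterclockwise once the raster y-flip is folded in)
signed_angle_left <- function(ax, ay, bx, by) {
  atan2(ay * bx - ax * by, ax * bx + ay * by) * 180 / pi
}

# orientation angle (degrees, left-positive world) of a raster vector
vec_angle_left <- function(vx, vy) atan2(-vy, vx) * 180 / pi

# rotate raster vector(s) by `deg` to the LEFT
rot_left <- function(xy, deg) {
  th <- deg * pi / 180
  # left rotation in raster coords = clockwise in matrix terms
  cbind(cos(th) * xy[, 1] + sin(th) * xy[, 2],
        -sin(th) * xy[, 1] + cos(th) * xy[, 2])
}

# unwrap an angle series (degrees) so consecutive frames never jump by >180
unwrap_deg <- function(theta) {
  if (length(theta) < 2) return(theta)
  d <- diff(theta)
  d <- d - 360 * round(d / 360)
  theta[1] + c(0, cumsum(d))
}

wrap180 <- function(theta) {
  w <- (theta + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

# cumulative chord length of an n x 2 polyline
arc_length <- function(pts) {
  d <- sqrt(rowSums(diff(pts)^2))
  c(0, cumsum(d))
}

# resample an open polyline to n points equidistant in arc length
resample_polyline <- function(pts, n) {
  s <- arc_length(pts)
  L <- s[length(s)]
  if (L <= 0) return(matrix(rep(pts[1, ], each = n), ncol = 2))
  keep <- c(TRUE, diff(s) > 0)
  s <- s[keep]; pts <- pts[keep, , drop = FALSE]
  target <- seq(0, L, length.out = n)
  cbind(approx(s, pts[, 1], xout = target)$y,
        approx(s, pts[, 2], xout = target)$y)
}

# run a block with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# moving-average smoothing with a centred boxcar; edges use shrunken windows
boxcar_smooth <- function(x, w) {
  n <- length(x)
  if (w <= 1 || n == 0) return(x)
  half <- (w - 1) / 2
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# circular (cyclic) moving average, `passes` repetitions of a `k`-point kernel
cyclic_smooth <- function(x, k = 5, passes = 3) {
  n <- length(x)
  half <- (k - 1) / 2
  for (p in seq_len(passes)) {
    xp <- c(tail(x, half), x, head(x, half))
    x <- vapply(seq_len(n), function(i) mean(xp[i:(i + k - 1)]), numeric(1))
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
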