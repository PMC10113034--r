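#' Background model from equidistant frames of the central video third
#'
#' The background is the pixel-wise mean of up to 100 equidistantly spaced
#' frames taken from the central third of the sequence, which makes the model
#' robust against changes at the start or end of a recording. Sequences with
#' fewer than 300 frames contribute all frames of their central third.
#'
#' @param frames a [frame_sequence()]
#' @return a `larva_background`: `mean_image`, `n_frames_used`, `frames_used`
#' @export
build_background <- function(frames) {
  n <- frames$n_frames
  if (n < 1) stop("empty frame sequence")
  lo <- floor(n / 3) + 1
  hi <- max(lo, floor(2 * n / 3))
  central <- lo:hi
  idx <- if (length(central) <= 100 || n < 300) central else
    unique(round(seq(lo, hi, length.out = 100)))
  acc <- NULL
  for (i in idx) {
    f <- frames$frame(i)
    acc <- if (is.null(acc)) f else acc + f
  }
  structure(list(mean_image = acc / length(idx),
                 n_frames_used = length(idx), frames_used = idx),
            class = "larva_background")
}

#' Otsu's threshold from a 256-bin histogram
#'
#' Selects the integer threshold that minimises the intensity variance within
#' the two classes (equivalently, maximises the between-class variance).
#' Plateaus of equally optimal thresholds are resolved to their midpoint, so
#' a histogram with two well-separated modes yields a threshold strictly
#' between them.
#'
#' @param values integer-valued intensities in `[0, 255]`
#' @return the threshold; foreground is `values > threshold`
#' @export
otsu_threshold <- function(values) {
  h <- as.numeric(tabulate(as.integer(values) + 1L, nbins = 256L))
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h)
  m0 <- cumsum(h * lev)
  mu <- m0[256]
  w1 <- n - w0
  # between-class variance for threshold t = lev (foreground > t)
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 256)
  bcv[valid] <- (mu * w0[valid] - n * m0[valid])^2 /
    (as.numeric(w0[valid]) * w1[valid])
  best <- which(bcv == max(bcv))
  lev[floor(mean(best))]
}

#' Segment one frame against the background model
#'
#' Computes the signed difference image (background minus frame for dark
#' larvae on a light background, the reverse for inverted polarity), clamps
#' it at zero and thresholds it with Otsu's method computed on the region of
#' interest only. A constant difference image (no foreground present) yields
#' an empty mask flagged as degenerate rather than an error.
#'
#' @param frame numeric matrix
#' @param bg a [build_background()] model
#' @param polarity `"dark"` or `"light"` objects
#' @param roi optional [roi_rect()] / [roi_circle()]
#' @return logical mask with attributes `threshold` and `degenerate`
#' @export
segment_frame <- function(frame, bg, polarity = c("dark", "light"),
                          roi = NULL) {
  polarity <- match.arg(polarity)
  if (!all(dim(frame) == dim(bg$mean_image)))
    stop("frame and background dimensions differ")
  d <- if (polarity == "dark") bg$mean_image - frame else frame - bg$mean_image
  d <- pmax(0, pmin(255, round(d)))
  rmask <- roi_mask(roi, dim(frame))
  vals <- d[rmask]
  if (max(vals) == min(vals)) {
    mask <- matrix(FALSE, nrow(frame), ncol(frame))
    attr(mask, "threshold") <- NA_integer_
    attr(mask, "degenerate") <- TRUE
    return(mask)
  }
  thr <- otsu_threshold(vals)
  mask <- d > thr & rmask
  attr(mask, "threshold") <- thr
  attr(mask, "degenerate") <- FALSE
  mask
}

#' Extract blobs (8-connected foreground components)
#'
#' @param mask logical matrix from [segment_frame()]
#' @param min_area_px minimum component area kept (speckle filter)
#' @param frame_index frame number recorded on each blob
#' @param frame optional original frame; when given, an intensity patch
#'   around each blob (bounding box + `patch_margin`) is stored for later
#'   brightness-based head/tail voting and shape-model fitting
#' @param patch_margin margin of the stored patch in pixels
#' @return list of `larva_blob`: `frame`, `pixels` (sorted linear indices),
#'   `area_px`, `centroid` (x, y), `bbox` (x0, y0, x1, y1), `contour`
#'   (n x 2 boundary polygon), optionally `patch` + `patch_offset`
#' @export
extract_blobs <- function(mask, min_area_px = 0, frame_index = NA_integer_,
                          frame = NULL, patch_margin = 12L) {
  lab <- .cc_label(mask)
  npix <- tabulate(lab[lab > 0L])
  keep <- which(npix >= max(1, min_area_px))
  nr <- nrow(mask)
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    k <- keep[j]
    pix <- which(lab == k)
    rows <- (pix - 1L) %% nr + 1L
    cols <- (pix - 1L) %/% nr + 1L
    bbox <- c(min(cols), min(rows), max(cols), max(rows))
    b <- list(frame = frame_index, pixels = pix, area_px = length(pix),
              centroid = c(mean(cols), mean(rows)), bbox = bbox,
              contour = .trace_boundary(lab, k), img_nrow = nr)
    if (!is.null(frame)) {
      r0 <- max(1, bbox[2] - patch_margin); r1 <- min(nr, bbox[4] + patch_margin)
      c0 <- max(1, bbox[1] - patch_margin); c1 <- min(ncol(mask), bbox[3] + patch_margin)
      b$patch <- frame[r0:r1, c0:c1, drop = FALSE]
      b$patch_offset <- c(c0 - 1L, r0 - 1L)  # add to patch (x, y) for image coords
    }
    class(b) <- "larva_blob"
    out[[j]] <- b
  }
  out
}
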