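#' Calibrated frame sequences
#'
#' A frame sequence is the common input container of the imaging pipeline: a
#' stack of greyscale frames (values 0-255) plus acquisition metadata. Frames
#' can be held in memory (a list of matrices) or produced lazily by a
#' generator function, which keeps multi-minute synthetic scenes within a
#' small memory footprint.
#'
#' @param x a list of numeric matrices (all the same dimension), or a
#'   function `f(i)` returning frame `i` as a numeric matrix
#' @param n_frames number of frames; required when `x` is a function
#' @param fps acquisition rate in frames per second
#' @param mm_per_px spatial calibration in millimetres per pixel
#' @param roi optional region of interest, see [roi_rect()] / [roi_circle()]
#' @return an object of class `frame_sequence` with elements `frame(i)`,
#'   `n_frames`, `dim`, `fps`, `mm_per_px`, `roi`
#' @export
frame_sequence <- function(x, n_frames = NULL, fps, mm_per_px, roi = NULL) {
  if (is.function(x)) {
    if (is.null(n_frames)) stop("n_frames is required for a generator")
    f1 <- x(1L)
    seq <- list(frame = x, n_frames = as.integer(n_frames), dim = dim(f1))
  } else if (is.list(x)) {
    if (length(x) == 0) stop("empty frame list")
    seq <- list(frame = function(i) x[[i]], n_frames = length(x),
                dim = dim(x[[1]]))
  } else stop("x must be a list of matrices or a generator function")
  seq$fps <- fps
  seq$mm_per_px <- mm_per_px
  seq$roi <- roi
  class(seq) <- "frame_sequence"
  seq
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames of %dx%d px, %.3g fps, %.3g mm/px\n",
              x$n_frames, x$dim[1], x$dim[2], x$fps, x$mm_per_px))
  invisible(x)
}

#' Rectangular / circular regions of interest
#'
#' Regions of interest restrict segmentation to the arena (e.g. the Petri
#' dish area) so that dish walls do not dominate the threshold histogram.
#' Coordinates are in pixels, `x` = column, `y` = row.
#'
#' @param x0,y0,x1,y1 rectangle corners (inclusive)
#' @export
roi_rect <- function(x0, y0, x1, y1) {
  structure(list(shape = "rect", x0 = x0, y0 = y0, x1 = x1, y1 = y1),
            class = "larva_roi")
}

#' @param cx,cy,r circle centre and radius in pixels
#' @rdname roi_rect
#' @export
roi_circle <- function(cx, cy, r) {
  structure(list(shape = "circle", cx = cx, cy = cy, r = r),
            class = "larva_roi")
}

# logical matrix marking ROI membership for an image of dimension `dm`
roi_mask <- function(roi, dm) {
  if (is.null(roi)) return(matrix(TRUE, dm[1], dm[2]))
  col <- matrix(rep(seq_len(dm[2]), each = dm[1]), dm[1], dm[2])
  row <- matrix(rep(seq_len(dm[1]), dm[2]), dm[1], dm[2])
  if (roi$shape == "rect") {
    col >= roi$x0 & col <= roi$x1 & row >= roi$y0 & row <= roi$y1
  } else {
    (col - roi$cx)^2 + (row - roi$cy)^2 <= roi$r^2
  }
}

# mm <-> px mapping shared by the renderer and the pose converter: the point
# (0, 0) mm sits at the outer corner of pixel (1, 1), whose centre is 0.5 px
mm_to_px <- function(xy_mm, mm_per_px) xy_mm / mm_per_px + 0.5
px_to_mm <- function(xy_px, mm_per_px) (xy_px - 0.5) * mm_per_px

#' Read and write plain (ASCII) PGM images
#'
#' Text-format portable graymaps are used as the on-disk frame format: they
#' are human-readable, diffable and need no codec. `read_frames_dir()` loads
#' a lexicographically sorted stack of `.pgm` (and, if the `png` package is
#' installed, `.png`) frames as a [frame_sequence()].
#'
#' @param path file path
#' @param img numeric matrix with values in 0..maxval
#' @param maxval maximum grey value written to the header
#' @return `read_pgm()` returns a numeric matrix
#' @export
read_pgm <- function(path) {
  tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (tok[1] != "P2") stop("only ASCII (P2) PGM supported")
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname read_pgm
#' @export
write_pgm <- function(img, path, maxval = 255) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  apply(round(img), 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

#' @rdname read_pgm
#' @param dir directory holding one image file per frame
#' @inheritParams frame_sequence
#' @export
read_frames_dir <- function(dir, fps, mm_per_px, roi = NULL) {
  files <- sort(list.files(dir, pattern = "\\.(pgm|png)$", full.names = TRUE))
  if (length(files) == 0) stop("no .pgm/.png frames in ", dir)
  read1 <- function(f) {
    if (grepl("\\.pgm$", f)) return(read_pgm(f))
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading png frames requires the png package")
    g <- png::readPNG(f)
    if (length(dim(g)) == 3) g <- 0.299 * g[, , 1] + 0.587 * g[, , 2] + 0.114 * g[, , 3]
    g * 255
  }
  frame_sequence(lapply(files, read1), fps = fps, mm_per_px = mm_per_px,
                 roi = roi)
}
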