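#' Thermal frame stack
#'
#' An ordered sequence of 2-D absolute-temperature images (degC) at a known
#' frame rate — the raw measurement object of a thermal recording.
#'
#' @param frames list of numeric H x W matrices (degC), all the same shape,
#'   all finite.
#' @param fs frame rate (Hz), > 0.
#' @param t0_s time of the first frame (s), default 0.
#' @return a `thermal_frame_stack`.
#' @export
thermal_frame_stack <- function(frames, fs, t0_s = 0) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("frames must be a non-empty list of matrices")
  dims <- vapply(frames, function(f) {
    if (!is.matrix(f) || !is.numeric(f)) stop("each frame must be a numeric matrix")
    dim(f)
  }, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
    stop("ragged frame shapes at frame(s): ", paste(bad, collapse = ", "))
  }
  if (!all(vapply(frames, function(f) all(is.finite(f)), logical(1))))
    stop("all temperatures must be finite")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  structure(list(frames = frames, fs = fs, t0_s = t0_s),
            class = "thermal_frame_stack")
}

#' @export
print.thermal_frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("thermal_frame_stack: %d frames of %dx%d px @ %g Hz (%.1f s)\n",
              length(x$frames), d[1], d[2], x$fs, length(x$frames) / x$fs))
  invisible(x)
}

#' Rectangular region of interest
#'
#' Pixel coordinates are 0-based with x along columns and y along rows; the
#' box covers `width` columns starting at `x0` and `height` rows starting at
#' `y0` (inclusive counts). This convention is used throughout the package.
#'
#' @param label ROI name.
#' @param x0,y0 top-left corner, 0-based integers.
#' @param width,height box extent in pixels, >= 1.
#' @return a `roi_box`.
#' @export
roi_box <- function(label, x0, y0, width, height) {
  if (width < 1 || height < 1) stop("width and height must be >= 1")
  if (x0 < 0 || y0 < 0) stop("x0 and y0 must be >= 0")
  structure(list(label = as.character(label),
                 x0 = as.integer(round(x0)), y0 = as.integer(round(y0)),
                 width = as.integer(round(width)), height = as.integer(round(height))),
            class = "roi_box")
}

# 1-based row/col index ranges of a box at integer offset (dx, dy).
box_rows <- function(box, dy = 0L) (box$y0 + dy + 1L):(box$y0 + dy + box$height)
box_cols <- function(box, dx = 0L) (box$x0 + dx + 1L):(box$x0 + dx + box$width)

box_inside <- function(box, dim_hw, dx = 0L, dy = 0L) {
  box$x0 + dx >= 0 && box$y0 + dy >= 0 &&
    box$x0 + dx + box$width <= dim_hw[2] && box$y0 + dy + box$height <= dim_hw[1]
}

check_box_inside <- function(box, dim_hw) {
  if (!box_inside(box, dim_hw))
    stop(sprintf("ROI '%s' (x0=%d, y0=%d, %dx%d) exceeds the %dx%d image",
                 box$label, box$x0, box$y0, box$width, box$height,
                 dim_hw[1], dim_hw[2]))
  invisible(box)
}
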