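#' Tracker settings
#'
#' @param search_px half-width of the square search window around the
#'   previous position, pixels (default 10).
#' @param refresh_every refresh the template from the tracked box every this
#'   many frames (default 50); keeps the template current under slow
#'   appearance change while bounding drift accumulation.
#' @param min_score normalized cross-correlation below this marks the frame
#'   low-confidence; the previous position is held (default 0.5).
#' @return a `track_settings` list.
#' @export
track_settings <- function(search_px = 10L, refresh_every = 50L,
                           min_score = 0.5) {
  if (search_px < 1) stop("search_px must be >= 1")
  list(search_px = as.integer(search_px),
       refresh_every = as.integer(refresh_every), min_score = min_score)
}

# Pearson correlation of a candidate patch against a pre-centred template.
# Returns NA when either side has zero variance (featureless image).
ncc_score <- function(patch, tc, tnorm) {
  p <- patch - mean(patch)
  pn <- sqrt(sum(p * p))
  if (pn == 0 || tnorm == 0) return(NA_real_)
  sum(p * tc) / (pn * tnorm)
}

#' Track an ROI across a thermal frame stack
#'
#' Frame-to-frame normalized cross-correlation template matching: on each
#' frame the template is correlated at every integer offset within
#' `search_px` of the previous position and the best-scoring position wins.
#' Frames whose best score falls below `min_score` (including featureless,
#' zero-variance frames) keep the previous position and are flagged. The
#' template is refreshed from the tracked box every `refresh_every` frames.
#'
#' @param stack a [thermal_frame_stack()].
#' @param initial a [roi_box()] valid on frame 1.
#' @param settings a [track_settings()].
#' @return a `roi_track`: list with `label`, `positions` data.frame
#'   `(frame, x, y)` (top-left, 0-based), `score`, `flagged`.
#' @export
track_roi <- function(stack, initial, settings = track_settings()) {
  stopifnot(inherits(stack, "thermal_frame_stack"), inherits(initial, "roi_box"))
  hw <- dim(stack$frames[[1]])
  check_box_inside(initial, hw)
  n <- length(stack$frames)
  s <- settings$search_px
  x <- y <- integer(n)
  score <- numeric(n)
  flagged <- logical(n)
  x[1] <- initial$x0; y[1] <- initial$y0; score[1] <- 1
  tmpl <- stack$frames[[1]][box_rows(initial), box_cols(initial), drop = FALSE]
  tc <- tmpl - mean(tmpl); tnorm <- sqrt(sum(tc * tc))
  flagged[1] <- tnorm == 0
  box <- initial
  for (i in seq_len(n)[-1]) {
    f <- stack$frames[[i]]
    best <- -Inf; bx <- x[i - 1]; by <- y[i - 1]
    any_valid <- FALSE
    for (dy in -s:s) {
      yy <- y[i - 1] + dy
      if (yy < 0 || yy + box$height > hw[1]) next
      rows <- (yy + 1L):(yy + box$height)
      for (dx in -s:s) {
        xx <- x[i - 1] + dx
        if (xx < 0 || xx + box$width > hw[2]) next
        sc <- ncc_score(f[rows, (xx + 1L):(xx + box$width), drop = FALSE],
                        tc, tnorm)
        if (is.na(sc)) next
        any_valid <- TRUE
        if (sc > best) { best <- sc; bx <- xx; by <- yy }
      }
    }
    if (!any_valid || best < settings$min_score) {
      x[i] <- x[i - 1]; y[i] <- y[i - 1]
      score[i] <- if (any_valid) best else NA_real_
      flagged[i] <- TRUE
    } else {
      x[i] <- bx; y[i] <- by; score[i] <- best
    }
    if (settings$refresh_every > 0 && i %% settings$refresh_every == 0L &&
        !flagged[i]) {
      tmpl <- f[(y[i] + 1L):(y[i] + box$height),
                (x[i] + 1L):(x[i] + box$width), drop = FALSE]
      tc <- tmpl - mean(tmpl); tnorm <- sqrt(sum(tc * tc))
    }
  }
  structure(list(label = initial$label,
                 positions = data.frame(frame = seq_len(n), x = x, y = y),
                 width = box$width, height = box$height,
                 score = score, flagged = flagged),
            class = "roi_track")
}

#' Static (no-tracking) track for an ROI
#'
#' @param stack a [thermal_frame_stack()].
#' @param box a [roi_box()].
#' @return a `roi_track` holding `box` on every frame.
#' @export
static_track <- function(stack, box) {
  check_box_inside(box, dim(stack$frames[[1]]))
  n <- length(stack$frames)
  structure(list(label = box$label,
                 positions = data.frame(frame = seq_len(n),
                                        x = rep(box$x0, n), y = rep(box$y0, n)),
                 width = box$width, height = box$height,
                 score = rep(1, n), flagged = rep(FALSE, n)),
            class = "roi_track")
}

#' Extract the per-frame ROI mean-temperature trace
#'
#' `values[i]` is the arithmetic mean of the pixels inside the tracked box
#' on frame i — the \eqn{T_{ROI}(t)} signal all downstream features are
#' computed from.
#'
#' @param stack a [thermal_frame_stack()].
#' @param track a `roi_track` (from [track_roi()] or [static_track()]) with
#'   one position per frame.
#' @return a [roi_trace()] of length `length(stack$frames)`.
#' @export
extract_trace <- function(stack, track) {
  stopifnot(inherits(stack, "thermal_frame_stack"), inherits(track, "roi_track"))
  n <- length(stack$frames)
  if (nrow(track$positions) != n)
    stop("track has ", nrow(track$positions), " positions for ", n, " frames")
  v <- vapply(seq_len(n), function(i) {
    p <- track$positions[i, ]
    mean(stack$frames[[i]][(p$y + 1L):(p$y + track$height),
                           (p$x + 1L):(p$x + track$width)])
  }, numeric(1))
  roi_trace(v, fs = stack$fs, label = track$label, t0_s = stack$t0_s)
}

#' Track all ROIs and extract their traces
#'
#' @param stack a [thermal_frame_stack()].
#' @param rois list of [roi_box()].
#' @param track logical: run the tracker (default) or hold boxes static.
#' @param settings a [track_settings()].
#' @return named list of [roi_trace()]; each carries its `roi_track` as
#'   attribute `"track"`.
#' @export
extract_traces <- function(stack, rois, track = TRUE,
                           settings = track_settings()) {
  out <- list()
  for (b in rois) {
    tk <- if (track) track_roi(stack, b, settings) else static_track(stack, b)
    tr <- extract_trace(stack, tk)
    attr(tr, "track") <- tk
    out[[b$label]] <- tr
  }
  out
}
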