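#' Scene layout for synthetic thermal video
#'
#' Describes where each ROI patch sits in the image, its spatial profile and
#' its motion. Patches are rectangles over an ambient-temperature
#' background, either uniform or Gaussian-edged (warm centre fading towards
#' the box edge). The profile is normalised to mean 1 over its support box,
#' so the mean of in-ROI pixels always equals the injected trace value
#' before pixel noise.
#'
#' Motion paths are quantised to integer pixels per frame; the quantised
#' path is stored as ground truth, giving the tracker an exact reference.
#'
#' @param image_hw image size as `c(height, width)` in pixels.
#' @param rois list of [roi_box()] patches; must not overlap at any frame.
#' @param profiles named character vector (by ROI label): `"uniform"` or
#'   `"gaussian"`. Default `"gaussian"` for all (gives the tracker texture).
#' @param motions named list (by ROI label) of motion specs:
#'   `list(type = "none")`, `list(type = "drift", dx = , dy = )` (total
#'   displacement in px over the video, linear) or
#'   `list(type = "sine", amp_px = , freq_hz = , axis = "x"|"y")`.
#' @return a `scene_layout`.
#' @export
scene_layout <- function(image_hw, rois, profiles = NULL, motions = NULL) {
  stopifnot(length(image_hw) == 2L, all(image_hw >= 1))
  labels <- vapply(rois, function(b) b$label, character(1))
  if (anyDuplicated(labels)) stop("duplicate ROI labels in layout")
  for (b in rois) check_box_inside(b, image_hw)
  if (is.null(profiles)) profiles <- stats::setNames(rep("gaussian", length(rois)), labels)
  if (is.null(motions)) motions <- stats::setNames(
    rep(list(list(type = "none")), length(rois)), labels)
  structure(list(image_hw = as.integer(image_hw), rois = rois,
                 labels = labels, profiles = profiles, motions = motions),
            class = "scene_layout")
}

# Spatial profile of a patch, normalised to mean 1 over the box.
patch_profile <- function(box, kind) {
  if (kind == "uniform") return(matrix(1, box$height, box$width))
  ry <- (seq_len(box$height) - (box$height + 1) / 2) / (box$height / 2)
  rx <- (seq_len(box$width) - (box$width + 1) / 2) / (box$width / 2)
  g <- exp(-outer(ry^2, rx^2, "+") / 0.5)
  g / mean(g)
}

# Integer displacement path (n frames) for one motion spec.
motion_path <- function(motion, n, fs) {
  t <- (seq_len(n) - 1L) / fs
  frac <- if (n > 1L) (seq_len(n) - 1L) / (n - 1L) else 0
  dx <- dy <- numeric(n)
  type <- motion$type %||% "none"
  if (type == "drift") {
    dx <- (motion$dx %||% 0) * frac
    dy <- (motion$dy %||% 0) * frac
  } else if (type == "sine") {
    s <- (motion$amp_px %||% 0) * sin(2 * pi * (motion$freq_hz %||% 0.05) * t)
    if ((motion$axis %||% "x") == "x") dx <- s else dy <- s
  } else if (type != "none") stop("unknown motion type: ", type)
  data.frame(frame = seq_len(n), dx = as.integer(round(dx)), dy = as.integer(round(dy)))
}

#' Render synthetic thermal frames from ROI traces
#'
#' Each frame is an ambient-temperature background with one patch per ROI
#' whose in-box pixel mean equals that ROI's trace value at the frame time
#' (before pixel noise), plus i.i.d. Gaussian pixel noise at the sensor
#' NETD scale.
#'
#' @param traces named list of [roi_trace()] (names = ROI labels present in
#'   `layout`); all the same length and sampling rate.
#' @param layout a [scene_layout()].
#' @param ambient_temp background temperature, degC (default 24, room).
#' @param noise_sd per-pixel Gaussian noise SD, degC (default 0.03, NETD).
#' @param seed integer, reproducibility.
#' @return list with `stack` (a [thermal_frame_stack()]) and `truth`: per-ROI
#'   data.frames `(frame, x, y)` of the ground-truth top-left box positions.
#' @export
synthesize_frames <- function(traces, layout, ambient_temp = 24,
                              noise_sd = 0.03, seed = 1) {
  stopifnot(inherits(layout, "scene_layout"))
  if (!all(names(traces) %in% layout$labels))
    stop("traces present without a layout ROI: ",
         paste(setdiff(names(traces), layout$labels), collapse = ", "))
  ns <- vapply(traces, function(tr) length(tr$values), integer(1))
  fss <- vapply(traces, function(tr) tr$fs, numeric(1))
  if (length(unique(ns)) != 1L || length(unique(fss)) != 1L)
    stop("all traces must share length and sampling rate")
  n <- ns[[1]]; fs <- fss[[1]]
  hw <- layout$image_hw

  labels <- names(traces)
  boxes <- stats::setNames(layout$rois, layout$labels)[labels]
  profs <- lapply(labels, function(l) patch_profile(boxes[[l]], layout$profiles[[l]]))
  names(profs) <- labels
  paths <- lapply(labels, function(l) motion_path(layout$motions[[l]], n, fs))
  names(paths) <- labels

  # bounds + overlap audit over all frames
  for (l in labels) {
    p <- paths[[l]]
    ok <- vapply(seq_len(n), function(i)
      box_inside(boxes[[l]], hw, p$dx[i], p$dy[i]), logical(1))
    if (!all(ok))
      stop(sprintf("ROI '%s' leaves the frame bounds at frame %d", l, which(!ok)[1]))
  }
  if (length(labels) > 1L) {
    corners <- lapply(labels, function(l) {
      b <- boxes[[l]]; p <- paths[[l]]
      cbind(b$x0 + p$dx, b$x0 + p$dx + b$width, b$y0 + p$dy, b$y0 + p$dy + b$height)
    })
    pairs <- utils::combn(seq_along(labels), 2)
    for (k in seq_len(ncol(pairs))) {
      a <- corners[[pairs[1, k]]]; b <- corners[[pairs[2, k]]]
      hit <- a[, 1] < b[, 2] & b[, 1] < a[, 2] & a[, 3] < b[, 4] & b[, 3] < a[, 4]
      if (any(hit))
        stop(sprintf("ROIs '%s' and '%s' overlap at frame %d",
                     labels[pairs[1, k]], labels[pairs[2, k]], which(hit)[1]))
    }
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as_seed(seed))
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    f <- matrix(ambient_temp, hw[1], hw[2])
    for (l in labels) {
      b <- boxes[[l]]; p <- paths[[l]]
      rows <- box_rows(b, p$dy[i]); cols <- box_cols(b, p$dx[i])
      f[rows, cols] <- ambient_temp +
        (traces[[l]]$values[i] - ambient_temp) * profs[[l]]
    }
    if (noise_sd > 0) f <- f + matrix(stats::rnorm(length(f), 0, noise_sd), hw[1], hw[2])
    frames[[i]] <- f
  }
  truth <- lapply(labels, function(l) {
    b <- boxes[[l]]; p <- paths[[l]]
    data.frame(frame = p$frame, x = b$x0 + p$dx, y = b$y0 + p$dy)
  })
  names(truth) <- labels
  list(stack = thermal_frame_stack(frames, fs, t0_s = traces[[1]]$t0_s),
       truth = truth)
}
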