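#' Write a thermal frame stack to disk
#'
#' Two dialects. `"tiff"`: one multi-frame 32-bit float TIFF; since float
#' TIFF samples are stored in \[0, 1\], temperatures are affinely encoded as
#' `(T - offset) / scale` with the encoding recorded in the sidecar
#' (decoding error ~3e-6 degC from float32 quantisation). `"csv_dir"`: one
#' plain CSV matrix per frame (`frame_000000.csv`, zero-padded acquisition
#' order), written at full precision — the lossless dialect. Both carry a
#' JSON sidecar with `fs_hz`, `t0_s`, `units` and, optionally, the
#' ground-truth ROI paths of a synthetic scene.
#'
#' @param stack a [thermal_frame_stack()].
#' @param path output file (`.tif`) or directory, by dialect.
#' @param format `"tiff"` or `"csv_dir"`.
#' @param truth optional list of per-ROI ground-truth path data.frames (from
#'   [synthesize_frames()]), stored in the sidecar.
#' @param encode_offset,encode_scale TIFF encoding, degC; defaults cover
#'   0-80 degC (float32 quantisation ~5e-6 degC).
#' @return invisibly, the sidecar path.
#' @export
write_frame_stack <- function(stack, path, format = c("tiff", "csv_dir"),
                              truth = NULL, encode_offset = 0,
                              encode_scale = 80) {
  format <- match.arg(format)
  stopifnot(inherits(stack, "thermal_frame_stack"))
  meta <- list(fs_hz = stack$fs, t0_s = stack$t0_s, units = "degC",
               n_frames = length(stack$frames),
               shape_hw = dim(stack$frames[[1]]), format = format)
  if (!is.null(truth)) meta$roi_ground_truth_paths <- truth
  if (format == "tiff") {
    meta$encoding <- list(offset = encode_offset, scale = encode_scale)
    enc <- lapply(stack$frames, function(f) (f - encode_offset) / encode_scale)
    rng <- range(unlist(lapply(enc, range)))
    if (rng[1] < 0 || rng[2] > 1)
      stop("temperatures outside the TIFF encoding range [",
           encode_offset, ", ", encode_offset + encode_scale, "] degC")
    tiff::writeTIFF(enc, path, bits.per.sample = 32L, compression = "none",
                    reduce = FALSE)
    sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (i in seq_along(stack$frames)) {
      f <- stack$frames[[i]]
      lines <- apply(f, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
      writeLines(lines, file.path(path, sprintf("frame_%06d.csv", i - 1L)))
    }
    sidecar <- file.path(path, "metadata.json")
  }
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a thermal frame stack
#'
#' Units are verified against the sidecar: anything other than `"degC"` is
#' an error (no silent conversion).
#'
#' @param path `.tif` file or CSV directory, as written by
#'   [write_frame_stack()].
#' @param format `"tiff"` or `"csv_dir"`.
#' @return a [thermal_frame_stack()]; ground-truth ROI paths, if present in
#'   the sidecar, are attached as attribute `"truth"`.
#' @export
read_frame_stack <- function(path, format = c("tiff", "csv_dir")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such path: ", path)
  sidecar <- if (format == "tiff")
    paste0(tools::file_path_sans_ext(path), ".json")
  else file.path(path, "metadata.json")
  if (!file.exists(sidecar))
    stop("missing sidecar metadata file: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$units) || !identical(meta$units, "degC"))
    stop("sidecar declares units '", meta$units %||% "<missing>",
         "'; this reader accepts degC only (no silent conversion)")
  if (format == "tiff") {
    enc <- tiff::readTIFF(path, all = TRUE)
    off <- meta$encoding$offset %||% 0
    sc <- meta$encoding$scale %||% 1
    frames <- lapply(enc, function(f) f * sc + off)
  } else {
    files <- sort(list.files(path, pattern = "^frame_[0-9]+\\.csv$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("no frame_*.csv files in ", path)
    frames <- lapply(files, function(f)
      as.matrix(data.table::fread(f, header = FALSE)))
    frames <- lapply(frames, function(m) {
      dimnames(m) <- NULL
      storage.mode(m) <- "double"
      m
    })
  }
  stack <- thermal_frame_stack(frames, fs = as.numeric(meta$fs_hz),
                               t0_s = as.numeric(meta$t0_s %||% 0))
  if (!is.null(meta$roi_ground_truth_paths))
    attr(stack, "truth") <- meta$roi_ground_truth_paths
  stack
}

#' Write / read tidy trace CSV
#'
#' Long format `(subject_id, t_s, label, temp_C)`; single-subject writes may
#' omit `subject_id`.
#'
#' @param traces either a named list of [roi_trace()] (one subject) or a
#'   list by subject of such lists.
#' @param path CSV file.
#' @return `write_traces`: invisibly, `path`. `read_traces`: list by subject
#'   of named lists of [roi_trace()] (sampling rate recovered from `t_s`).
#' @export
write_traces <- function(traces, path) {
  if (length(traces) && inherits(traces[[1]], "roi_trace"))
    traces <- list(S01 = traces)
  rows <- list()
  for (sid in names(traces)) for (tr in traces[[sid]]) {
    rows[[paste(sid, tr$label)]] <- data.frame(
      subject_id = sid, t_s = trace_times(tr), label = tr$label,
      temp_C = tr$values)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  if (!all(c("t_s", "label", "temp_C") %in% names(d)))
    stop("traces CSV needs columns t_s, label, temp_C")
  if (is.null(d$subject_id)) d$subject_id <- "S01"
  out <- list()
  for (sid in unique(d$subject_id)) {
    ds <- d[d$subject_id == sid, ]
    out[[sid]] <- list()
    for (l in unique(ds$label)) {
      dl <- ds[ds$label == l, ]
      dl <- dl[order(dl$t_s), ]
      fs <- 1 / stats::median(diff(dl$t_s))
      out[[sid]][[l]] <- roi_trace(dl$temp_C, fs = fs, label = l,
                                   t0_s = dl$t_s[1])
    }
  }
  out
}

#' Read ROI box definitions (YAML or JSON)
#'
#' Expects a list of records with `label`, `x0`, `y0`, `width`, `height`
#' (0-based pixel coordinates, inclusive extents).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return list of [roi_box()].
#' @export
read_roi_boxes <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r)
    roi_box(r$label, r$x0, r$y0, r$width, r$height))
}

#' Read a session timeline (YAML or JSON)
#'
#' Accepts either explicit `phases: [{label, start_s, end_s}, ...]` or the
#' compact form `{set_durations_s, baseline_s, rest_s, recovery_s}` passed
#' to [make_default_timeline()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a [session_timeline()].
#' @export
read_timeline <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  timeline_from_config(raw)
}

timeline_from_config <- function(raw) {
  if (!is.null(raw$phases)) {
    ph <- raw$phases
    if (!is.data.frame(ph))
      ph <- do.call(rbind, lapply(ph, function(p)
        data.frame(label = p$label, start_s = p$start_s, end_s = p$end_s)))
    session_timeline(ph)
  } else if (!is.null(raw$set_durations_s)) {
    make_default_timeline(unlist(raw$set_durations_s),
                          baseline_s = raw$baseline_s %||% 300,
                          rest_s = raw$rest_s %||% 180,
                          recovery_s = raw$recovery_s %||% 300)
  } else stop("timeline needs either 'phases' or 'set_durations_s'")
}

#' Read per-subject RPE values from CSV
#'
#' @param path CSV with columns `subject_id`, `rpe` and optionally `set`.
#' @return data.frame `(subject_id, set, rpe)`, `set` defaulting to 3.
#' @export
read_rpe <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  if (!all(c("subject_id", "rpe") %in% names(d)))
    stop("RPE CSV needs columns subject_id, rpe")
  if (!all(d$rpe %in% 1:10)) stop("RPE values must be integers in 1..10")
  if (is.null(d$set)) d$set <- 3L
  d[, c("subject_id", "set", "rpe")]
}
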