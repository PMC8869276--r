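#' Time-domain feature: pre/post temperature change of one ROI
#'
#' \eqn{\Delta T_{ROI}} is the mean of \eqn{T_{ROI}} over the last 10 s of
#' the recording minus its mean over the 10-s window running from 20 s to
#' 10 s before the first repetition. Windows are half-open `[start, end)`,
#' so each holds exactly `round(10 * fs)` samples.
#'
#' @param trace a [roi_trace()].
#' @param timeline a [session_timeline()].
#' @return \eqn{\Delta T_{ROI}} in degC.
#' @export
delta_t_roi <- function(trace, timeline) {
  w <- analysis_windows(timeline)
  i_base <- window_indices(trace, w$dt_baseline, "dt_baseline window")
  i_final <- window_indices(trace, w$dt_final, "dt_final window")
  mean(trace$values[i_final]) - mean(trace$values[i_base])
}

#' Frequency-domain features: per-band PSD change of one ROI
#'
#' Estimates the PSD over the 5-min window ending at the first repetition
#' (pre) and the 5-min window ending the recording (post), integrates each
#' over the vasomotion bands, and differences them:
#' `delta_psd[b] = band_power(post, b) - band_power(pre, b)`.
#'
#' @param trace a [roi_trace()].
#' @param timeline a [session_timeline()].
#' @param bands data.frame of bands (default [vasomotion_bands()]).
#' @param settings a [psd_settings()].
#' @return data.frame `(band, power_pre, power_post, delta_psd,
#'   resolution_limited)`; band powers in degC^2.
#' @export
delta_psd <- function(trace, timeline, bands = vasomotion_bands(),
                      settings = psd_settings()) {
  w <- analysis_windows(timeline, psd_window_s = settings$window_s %||% 300)
  i_pre <- window_indices(trace, w$psd_pre, "psd_pre window")
  i_post <- window_indices(trace, w$psd_post, "psd_post window")
  psd_pre <- estimate_psd(trace$values[i_pre], trace$fs, settings)
  psd_post <- estimate_psd(trace$values[i_post], trace$fs, settings)
  rows <- lapply(seq_len(nrow(bands)), function(k) {
    b <- bands[k, , drop = FALSE]
    p0 <- band_power(psd_pre, b); p1 <- band_power(psd_post, b)
    data.frame(band = b$label, power_pre = as.numeric(p0),
               power_post = as.numeric(p1),
               delta_psd = as.numeric(p1) - as.numeric(p0),
               resolution_limited = isTRUE(attr(p0, "resolution_limited")) ||
                 isTRUE(attr(p1, "resolution_limited")))
  })
  do.call(rbind, rows)
}

#' Assemble the subject x ROI feature table
#'
#' One row per subject and ROI carrying \eqn{\Delta T_{ROI}}, the five
#' per-band \eqn{\Delta PSD} values and the subject's RPE. Subjects whose
#' timeline cannot support the analysis windows are excluded with a logged
#' reason (attribute `"excluded"` and a warning), never silently.
#'
#' @param traces list by subject of named lists of [roi_trace()] (4 ROIs).
#' @param timeline a [session_timeline()], or a list of them by subject.
#' @param rpe data.frame `(subject_id, set, rpe)` or `(subject_id, rpe)`.
#' @param rpe_agg how to reduce per-set RPE to one value per subject:
#'   `"last"` (default), `"mean"` or `"max"`.
#' @param bands,settings passed to [delta_psd()].
#' @return a `feature_table` data.frame: `subject_id`, `roi`, `delta_t_C`,
#'   `dpsd_<band>` x5, `rpe`, `resolution_limited`; excluded subjects in
#'   `attr(, "excluded")`.
#' @export
compute_feature_table <- function(traces, timeline, rpe,
                                  rpe_agg = c("last", "mean", "max"),
                                  bands = vasomotion_bands(),
                                  settings = psd_settings()) {
  rpe_agg <- match.arg(rpe_agg)
  if (!is.null(rpe$set)) rpe <- rpe_aggregate(rpe, rpe_agg)
  per_subject_tl <- inherits(timeline, "session_timeline") == FALSE
  rows <- list(); excluded <- character()
  for (sid in names(traces)) {
    tl <- if (per_subject_tl) timeline[[sid]] else timeline
    problems <- check_windows(tl, psd_window_s = settings$window_s %||% 300)
    if (length(problems) > 0) {
      excluded <- c(excluded, sprintf("%s: %s", sid, paste(problems, collapse = "; ")))
      next
    }
    r <- rpe$rpe[rpe$subject_id == sid]
    if (length(r) != 1L) {
      excluded <- c(excluded, sprintf("%s: no unique RPE value", sid))
      next
    }
    for (tr in traces[[sid]]) {
      key <- paste(sid, tr$label, sep = "|")
      if (!is.null(rows[[key]]))
        stop("duplicate subject x ROI cell: ", sid, " / ", tr$label)
      dt <- delta_t_roi(tr, tl)
      dp <- delta_psd(tr, tl, bands = bands, settings = settings)
      row <- data.frame(subject_id = sid, roi = tr$label, delta_t_C = dt)
      for (k in seq_len(nrow(dp)))
        row[[paste0("dpsd_", dp$band[k])]] <- dp$delta_psd[k]
      row$rpe <- r
      row$resolution_limited <- any(dp$resolution_limited)
      rows[[key]] <- row
    }
  }
  out <- if (length(rows) == 0)
    data.frame(subject_id = character(), roi = character())
  else do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (length(excluded) > 0)
    warning("excluded subject(s): ", paste(excluded, collapse = " | "))
  attr(out, "excluded") <- excluded
  class(out) <- c("feature_table", class(out))
  out
}

#' Write / read a feature table CSV
#' @param ft a feature table from [compute_feature_table()].
#' @param path CSV file.
#' @return `write_feature_table`: invisibly `path`; `read_feature_table`:
#'   the feature table.
#' @export
write_feature_table <- function(ft, path) {
  data.table::fwrite(as.data.frame(ft), path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- as.data.frame(data.table::fread(path))
  class(out) <- c("feature_table", class(out))
  out
}
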