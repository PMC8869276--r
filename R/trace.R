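#' ROI temperature trace
#'
#' The per-frame mean temperature of one region of interest,
#' \eqn{T_{ROI}(t)}, sampled at the acquisition rate.
#'
#' @param values numeric vector of temperatures (degC), finite.
#' @param fs sampling rate (Hz), > 0.
#' @param label ROI label.
#' @param t0_s time of the first sample (s), default 0.
#' @return a `roi_trace` object.
#' @export
roi_trace <- function(values, fs, label = "ROI", t0_s = 0) {
  if (!is.numeric(values) || length(values) < 1L)
    stop("values must be a non-empty numeric vector")
  if (any(!is.finite(values))) stop("trace values must be finite")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  structure(list(values = as.numeric(values), fs = fs,
                 label = as.character(label), t0_s = t0_s),
            class = "roi_trace")
}

#' @export
print.roi_trace <- function(x, ...) {
  cat(sprintf("roi_trace '%s': %d samples @ %g Hz (%.1f s), %.2f-%.2f degC\n",
              x$label, length(x$values), x$fs, length(x$values) / x$fs,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Sample times of a trace (s)
#' @param trace a [roi_trace()].
#' @return numeric vector, same length as the trace.
#' @export
trace_times <- function(trace) {
  trace$t0_s + (seq_along(trace$values) - 1L) / trace$fs
}

# Indices of samples with t in [window[1], window[2]); errors (naming the
# window) if the window does not lie inside the trace.
window_indices <- function(trace, window, name = "window") {
  t <- trace_times(trace)
  n <- length(t)
  t_end <- trace$t0_s + n / trace$fs
  if (window[1] < trace$t0_s - 1e-9 || window[2] > t_end + 1e-9)
    stop(sprintf("%s [%.1f, %.1f) s falls outside the trace [%.1f, %.1f) s",
                 name, window[1], window[2], trace$t0_s, t_end))
  which(t >= window[1] - 1e-9 & t < window[2] - 1e-9)
}
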