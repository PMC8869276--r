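#' Session timeline
#'
#' A `session_timeline` holds the labelled phase boundaries of one recording
#' session: an acclimation baseline, alternating exercise sets and interset
#' rests, and a final recovery. All analysis windows (the 10-s windows of
#' \eqn{\Delta T_{ROI}} and the 5-min pre/post windows of \eqn{\Delta PSD})
#' are anchored to it.
#'
#' @param phases data.frame with columns `label`, `start_s`, `end_s`. Labels
#'   must be `baseline`, `recovery`, or start with `set`/`rest`. Phases must
#'   be contiguous, non-overlapping and strictly increasing.
#' @return A `session_timeline`: list with `phases` (data.frame),
#'   `first_rep_s` (start of the first set) and `end_s`.
#' @seealso [make_default_timeline()], [analysis_windows()]
#' @export
session_timeline <- function(phases) {
  stopifnot(is.data.frame(phases),
            all(c("label", "start_s", "end_s") %in% names(phases)))
  phases <- phases[, c("label", "start_s", "end_s")]
  phases$label <- as.character(phases$label)
  ok <- phases$label %in% c("baseline", "recovery") |
    grepl("^set", phases$label) | grepl("^rest", phases$label)
  if (!all(ok))
    stop("unknown phase label(s): ", paste(unique(phases$label[!ok]), collapse = ", "))
  if (any(phases$end_s <= phases$start_s))
    stop("phases must have strictly positive duration")
  if (nrow(phases) > 1 &&
      any(abs(phases$start_s[-1] - phases$end_s[-nrow(phases)]) > 1e-9))
    stop("phases must be contiguous and non-overlapping")
  set_idx <- grep("^set", phases$label)
  if (length(set_idx) == 0L) stop("timeline needs at least one set phase")
  out <- structure(list(
    phases      = phases,
    first_rep_s = phases$start_s[set_idx[1]],
    end_s       = phases$end_s[nrow(phases)]
  ), class = "session_timeline")
  out
}

#' Build the standard three-set session timeline
#'
#' Phases are baseline, set1, rest, set2, rest, set3, recovery — the
#' three-sets-to-exhaustion knee-extension protocol with a 3-min interset
#' rest and 5-min acclimation/recovery epochs.
#'
#' @param set_durations_s numeric vector of 3 set durations (s). Sets run to
#'   concentric failure, so durations differ between sets and subjects.
#' @param baseline_s baseline (acclimation) duration in seconds, default 300.
#' @param rest_s interset rest in seconds, default 180.
#' @param recovery_s post-exercise recovery in seconds, default 300.
#' @return a [session_timeline()].
#' @examples
#' tl <- make_default_timeline(c(60, 50, 40))
#' tl$end_s        # 1110
#' tl$first_rep_s  # 300
#' @export
make_default_timeline <- function(set_durations_s, baseline_s = 300,
                                  rest_s = 180, recovery_s = 300) {
  if (length(set_durations_s) != 3L)
    stop("set_durations_s must have length 3")
  durs <- c(baseline_s, set_durations_s[1], rest_s, set_durations_s[2],
            rest_s, set_durations_s[3], recovery_s)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("all durations must be positive and finite")
  labels <- c("baseline", "set1", "rest1", "set2", "rest2", "set3", "recovery")
  ends <- cumsum(durs)
  session_timeline(data.frame(label = labels,
                              start_s = c(0, ends[-length(ends)]),
                              end_s = ends))
}

#' @export
print.session_timeline <- function(x, ...) {
  cat("session_timeline:", x$end_s, "s, first repetition at", x$first_rep_s, "s\n")
  print(x$phases, row.names = FALSE)
  invisible(x)
}

#' Analysis windows anchored to a timeline
#'
#' The two 10-s windows of \eqn{\Delta T_{ROI}} (from 20 s to 10 s before the
#' first repetition, and the last 10 s of the recording) and the two 5-min
#' windows over which the pre/post PSDs are estimated.
#'
#' @param timeline a [session_timeline()].
#' @param psd_window_s PSD window length in seconds (default 300).
#' @return list of `(start, end)` pairs: `dt_baseline`, `dt_final`,
#'   `psd_pre`, `psd_post`. Windows are half-open `[start, end)`.
#' @export
analysis_windows <- function(timeline, psd_window_s = 300) {
  stopifnot(inherits(timeline, "session_timeline"))
  fr <- timeline$first_rep_s
  en <- timeline$end_s
  list(dt_baseline = c(fr - 20, fr - 10),
       dt_final    = c(en - 10, en),
       psd_pre     = c(fr - psd_window_s, fr),
       psd_post    = c(en - psd_window_s, en))
}

#' Check that a timeline can support all analysis windows
#'
#' @param timeline a [session_timeline()].
#' @param t0_s time of the first sample (s), default 0.
#' @param psd_window_s PSD window length (s), default 300.
#' @return character vector of problems; empty when all windows fit.
#' @export
check_windows <- function(timeline, t0_s = 0, psd_window_s = 300) {
  w <- analysis_windows(timeline, psd_window_s)
  problems <- character()
  for (nm in names(w)) {
    if (w[[nm]][1] < t0_s - 1e-9)
      problems <- c(problems, sprintf(
        "window %s starts at %.1f s, before the recording (t0 = %.1f s)",
        nm, w[[nm]][1], t0_s))
  }
  rec <- timeline$phases[timeline$phases$label == "recovery", ]
  if (nrow(rec) == 1L && (rec$end_s - rec$start_s) < psd_window_s - 1e-9)
    problems <- c(problems, sprintf(
      "recovery phase (%.0f s) is shorter than the %.0f-s post PSD window",
      rec$end_s - rec$start_s, psd_window_s))
  problems
}
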