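#' Band-limited oscillator
#'
#' One sinusoidal component of a synthetic ROI signal, placed strictly
#' inside a vasomotion band. The default frequency is the band's geometric
#' centre (see [band_centre()]).
#'
#' @param band_label one of the five vasomotion band labels.
#' @param amplitude peak amplitude in degC, >= 0. A sinusoid of amplitude A
#'   contributes A^2/2 degC^2 of band power.
#' @param frequency Hz; must lie strictly inside the band. Default: band
#'   geometric centre.
#' @param phase radians, default 0.
#' @return a `band_oscillator` object.
#' @export
band_oscillator <- function(band_label, amplitude, frequency = NULL, phase = 0) {
  band <- band_by_label(band_label)
  if (is.null(frequency)) frequency <- band_centre(band)
  if (frequency <= band$f_lo || frequency >= band$f_hi)
    stop(sprintf("frequency %g Hz not strictly inside %s band (%g-%g Hz)",
                 frequency, band_label, band$f_lo, band$f_hi))
  if (amplitude < 0) stop("amplitude must be >= 0")
  structure(list(band_label = band_label, frequency = frequency,
                 amplitude = amplitude, phase = phase),
            class = "band_oscillator")
}

#' Phase trend specification
#'
#' A per-phase trend entry for [roi_signal_model()]: either a linear slope
#' (degC/s, integrated over the phase and carried forward, keeping the trend
#' continuous) or a plateau step (degC, applied at phase start).
#'
#' @param slope degC/s (default 0).
#' @param offset instantaneous step in degC at phase start (default 0).
#' @return list with `slope` and `offset`.
#' @export
phase_trend <- function(slope = 0, offset = 0) list(slope = slope, offset = offset)

#' Statistical signal model for one ROI
#'
#' Generates \eqn{T_{ROI}(t)} as baseline temperature + piecewise-linear
#' phase trends + band-limited oscillations (separately specifiable in the
#' baseline/pre and recovery/post epochs) + white Gaussian sensor noise at
#' the camera's NETD scale. The model is statistical, not biophysical: it
#' injects controllable ground truth, it does not model thermoregulation.
#'
#' @param baseline_temp starting skin temperature, degC.
#' @param phase_trends named list mapping a phase label (exact, e.g. `set2`,
#'   or generic `set`/`rest`) to a [phase_trend()] or a bare numeric slope
#'   in degC/s.
#' @param osc_pre,osc_post lists of [band_oscillator()] active during the
#'   baseline phase (pre) and the recovery phase (post) respectively.
#' @param noise_sd white-noise SD in degC; default 0.03 (bolometer NETD
#'   < 30 mK).
#' @param clamp physiological clamp applied to the final trace, degC.
#' @return a `roi_signal_model` object.
#' @export
roi_signal_model <- function(baseline_temp, phase_trends = list(),
                             osc_pre = list(), osc_post = list(),
                             noise_sd = 0.03, clamp = c(20, 45)) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  phase_trends <- lapply(phase_trends, function(x) {
    if (is.numeric(x) && length(x) == 1L) phase_trend(slope = x) else x
  })
  for (o in c(osc_pre, osc_post))
    if (!inherits(o, "band_oscillator")) stop("oscillators must be band_oscillator objects")
  structure(list(baseline_temp = baseline_temp, phase_trends = phase_trends,
                 osc_pre = osc_pre, osc_post = osc_post,
                 noise_sd = noise_sd, clamp = clamp),
            class = "roi_signal_model")
}

# Trend lookup: exact phase label first, then its generic stem ("set1"->"set").
trend_for_phase <- function(phase_trends, label) {
  if (!is.null(phase_trends[[label]])) return(phase_trends[[label]])
  stem <- sub("[0-9]+$", "", label)
  if (!is.null(phase_trends[[stem]])) return(phase_trends[[stem]])
  phase_trend()
}

# Piecewise-linear + step trend evaluated at times t (continuous across
# phase boundaries: slopes integrate, offsets step at phase start).
eval_trend <- function(model, timeline, t) {
  ph <- timeline$phases
  v <- rep(model$baseline_temp, length(t))
  level <- model$baseline_temp
  for (i in seq_len(nrow(ph))) {
    tr <- trend_for_phase(model$phase_trends, ph$label[i])
    level <- level + tr$offset
    in_ph <- t >= ph$start_s[i] & (t < ph$end_s[i] | i == nrow(ph))
    v[in_ph] <- level + tr$slope * (t[in_ph] - ph$start_s[i])
    level <- level + tr$slope * (ph$end_s[i] - ph$start_s[i])
  }
  v
}

#' Synthesize a single ROI temperature trace
#'
#' @param model a [roi_signal_model()].
#' @param timeline a [session_timeline()].
#' @param fs sampling rate (Hz), default 10. Must exceed twice the highest
#'   oscillator frequency (Nyquist).
#' @param seed integer; the trace is bit-reproducible for a fixed seed.
#' @param label ROI label carried on the trace.
#' @return a [roi_trace()] of length `round(end_s * fs)`.
#' @examples
#' tl <- make_default_timeline(c(60, 50, 40))
#' m  <- roi_signal_model(32, noise_sd = 0)
#' tr <- synthesize_trace(m, tl, seed = 1)
#' all(tr$values == 32)  # no trends, no oscillators, no noise
#' @export
synthesize_trace <- function(model, timeline, fs = 10, seed = 1, label = "ROI") {
  stopifnot(inherits(model, "roi_signal_model"),
            inherits(timeline, "session_timeline"))
  for (o in c(model$osc_pre, model$osc_post))
    if (fs <= 2 * o$frequency)
      stop(sprintf("Nyquist violation: %s oscillator at %g Hz needs fs > %g Hz (fs = %g)",
                   o$band_label, o$frequency, 2 * o$frequency, fs))
  n <- round(timeline$end_s * fs)
  t <- (seq_len(n) - 1L) / fs
  v <- eval_trend(model, timeline, t)
  ph <- timeline$phases
  base <- ph[ph$label == "baseline", ]
  rec  <- ph[ph$label == "recovery", ]
  add_osc <- function(v, oscs, win) {
    if (nrow(win) != 1L || length(oscs) == 0L) return(v)
    idx <- t >= win$start_s & t < win$end_s
    for (o in oscs)
      v[idx] <- v[idx] +
        o$amplitude * sin(2 * pi * o$frequency * t[idx] + o$phase)
    v
  }
  v <- add_osc(v, model$osc_pre, base)
  v <- add_osc(v, model$osc_post, rec)
  if (model$noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as_seed(seed))
    v <- v + stats::rnorm(n, 0, model$noise_sd)
  }
  v <- pmin(pmax(v, model$clamp[1]), model$clamp[2])
  roi_trace(v, fs, label = label, t0_s = 0)
}
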