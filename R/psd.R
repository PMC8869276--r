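#' PSD estimator settings
#'
#' Defaults: Welch's averaged periodogram with 150-s Hann-tapered segments
#' at 50% overlap and per-segment linear detrending, on an exactly 300-s
#' input window. 150-s segments give a frequency resolution of
#' 1/150 ~ 0.0067 Hz — fine enough to separate the neurogenic band from its
#' neighbours, though coarser than the 0.003 Hz lower edge of the metabolic
#' band, which is therefore integrated from the first available grid point
#' and flagged resolution-limited.
#'
#' @param segment_s Welch segment length, seconds (default 150).
#' @param overlap fractional segment overlap in \[0, 1) (default 0.5).
#' @param taper `"hann"` or `"none"` (boxcar).
#' @param detrend `"linear"` (per-segment least-squares line removal),
#'   `"mean"` or `"none"`.
#' @param window_s required input length in seconds (default 300, the 5-min
#'   analysis window); `NULL` accepts any input at least one segment long.
#' @return a `psd_settings` list.
#' @export
psd_settings <- function(segment_s = 150, overlap = 0.5, taper = "hann",
                         detrend = "linear", window_s = 300) {
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (!taper %in% c("hann", "none")) stop("taper must be 'hann' or 'none'")
  if (!detrend %in% c("linear", "mean", "none"))
    stop("detrend must be 'linear', 'mean' or 'none'")
  list(segment_s = segment_s, overlap = overlap, taper = taper,
       detrend = detrend, window_s = window_s)
}

detrend_segment <- function(x, how) {
  if (how == "none") return(x)
  if (how == "mean") return(x - mean(x))
  i <- seq_along(x)
  stats::lm.fit(cbind(1, i), x)$residuals
}

#' Welch power spectral density estimate
#'
#' One-sided PSD in degC^2/Hz. Density is normalised so that the sum of the
#' density over the frequency grid times the grid spacing equals the mean
#' tapered, detrended segment variance (Parseval within taper leakage): the
#' raw periodogram of each segment is `2 |FFT(w x)|^2 / (fs * sum(w^2))`
#' (no doubling at DC/Nyquist), averaged across segments.
#'
#' @param x numeric vector, the trace segment (or a [roi_trace()], whose
#'   values and rate are used).
#' @param fs sampling rate, Hz (ignored when `x` is a [roi_trace()]).
#' @param settings a [psd_settings()]. When `settings$window_s` is set, the
#'   input must be exactly `round(window_s * fs)` samples — no silent
#'   padding or truncation.
#' @return a `psd_estimate`: list with `frequencies` (Hz), `density`
#'   (degC^2/Hz), `df` (grid spacing), `n_segments`, and the `settings`
#'   used.
#' @export
estimate_psd <- function(x, fs = NULL, settings = psd_settings()) {
  if (inherits(x, "roi_trace")) { fs <- x$fs; x <- x$values }
  if (is.null(fs)) stop("fs required")
  n <- length(x)
  if (!is.null(settings$window_s)) {
    want <- round(settings$window_s * fs)
    if (n != want)
      stop(sprintf("segment has %d samples; settings require exactly %d (%g s at %g Hz); no silent padding",
                   n, want, settings$window_s, fs))
  }
  L <- round(settings$segment_s * fs)
  if (L > n) stop("segment_s longer than the input")
  step <- max(1L, round(L * (1 - settings$overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- if (settings$taper == "hann")
    0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))
  else rep(1, L)
  wss <- sum(w^2)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- detrend_segment(x[s0:(s0 + L - 1L)], settings$detrend)
    X <- stats::fft(seg * w)[seq_len(nf)]
    p <- 2 * (Mod(X)^2) / (fs * wss)
    p[1] <- p[1] / 2
    if (L %% 2 == 0) p[nf] <- p[nf] / 2
    acc <- acc + p
  }
  density <- acc / length(starts)
  structure(list(frequencies = (seq_len(nf) - 1) * fs / L,
                 density = density, df = fs / L,
                 n_segments = length(starts), fs = fs, settings = settings),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("psd_estimate: %d frequencies, df = %.4g Hz, %d Welch segment(s) (%s taper, %s detrend)\n",
              length(x$frequencies), x$df, x$n_segments,
              x$settings$taper, x$settings$detrend))
  invisible(x)
}

#' Band power: area under the PSD within a frequency band
#'
#' Trapezoidal integral of the density over \[f_lo, f_hi\], with linear
#' interpolation of the density at band edges that fall between grid
#' points. The DC bin is never integrated; a band whose lower edge falls
#' below the first positive grid frequency is integrated from that grid
#' point and the result carries attribute `resolution_limited = TRUE`.
#'
#' @param psd a `psd_estimate`.
#' @param band one-row data.frame with `f_lo`, `f_hi` (e.g. a row of
#'   [vasomotion_bands()]), or a band label string.
#' @return band power in degC^2 (>= 0), with attribute
#'   `resolution_limited`.
#' @export
band_power <- function(psd, band) {
  stopifnot(inherits(psd, "psd_estimate"))
  if (is.character(band)) band <- band_by_label(band)
  f_lo <- band$f_lo; f_hi <- band$f_hi
  nyq <- psd$fs / 2
  if (f_hi > nyq + 1e-12 || f_lo < 0)
    stop(sprintf("band [%g, %g] Hz outside the resolvable range [0, %g] Hz",
                 f_lo, f_hi, nyq))
  fr <- psd$frequencies; de <- psd$density
  f_min <- fr[2]  # first positive grid frequency
  limited <- f_lo < f_min - 1e-12
  lo <- max(f_lo, f_min)
  if (lo >= f_hi) {
    out <- 0
    attr(out, "resolution_limited") <- TRUE
    return(out)
  }
  interior <- fr[fr > lo & fr < f_hi]
  gx <- c(lo, interior, f_hi)
  gy <- stats::approx(fr, de, xout = gx, rule = 2)$y
  out <- sum(diff(gx) * (utils::head(gy, -1) + utils::tail(gy, -1)) / 2)
  attr(out, "resolution_limited") <- limited
  out
}

#' Total integrated PSD (degC^2)
#'
#' Trapezoid over the full positive-frequency grid, excluding the DC bin —
#' the reference total against which the five band powers are compared.
#'
#' @param psd a `psd_estimate`.
#' @return integrated power in degC^2.
#' @export
total_power <- function(psd) {
  fr <- psd$frequencies; de <- psd$density
  idx <- 2:length(fr)
  sum(diff(fr[idx]) * (utils::head(de[idx], -1) + utils::tail(de[idx], -1)) / 2)
}
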