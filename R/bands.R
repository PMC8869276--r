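#' The five vasomotion frequency bands
#'
#' Canonical spectral intervals attributed to skin blood-flow regulation:
#' metabolic (0.003–0.02 Hz, microvascular activity), neurogenic
#' (0.02–0.04 Hz, intrinsic neuronal activity), myogenic (0.04–0.15 Hz,
#' arteriolar smooth muscle), respiratory (0.15–0.5 Hz) and cardiac
#' (0.5–1 Hz). They are contiguous over \[0.003, 1\] Hz.
#'
#' @return data.frame with columns `label`, `f_lo`, `f_hi` (Hz).
#' @export
vasomotion_bands <- function() {
  data.frame(
    label = c("metabolic", "neurogenic", "myogenic", "respiratory", "cardiac"),
    f_lo  = c(0.003, 0.02, 0.04, 0.15, 0.5),
    f_hi  = c(0.02, 0.04, 0.15, 0.5, 1.0)
  )
}

#' A single frequency band
#'
#' @param label band name.
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi`.
#' @return one-row data.frame as in [vasomotion_bands()].
#' @export
frequency_band <- function(label, f_lo, f_hi) {
  if (!(is.finite(f_lo) && is.finite(f_hi) && f_lo > 0 && f_lo < f_hi))
    stop("need 0 < f_lo < f_hi")
  data.frame(label = as.character(label), f_lo = f_lo, f_hi = f_hi)
}

#' Geometric centre of a band (Hz)
#'
#' Default oscillator placement: the geometric mean of the band edges sits
#' away from both edges on a log-frequency axis, minimising leakage
#' ambiguity when band powers are checked against injected tones.
#'
#' @param band one-row data.frame with `f_lo`, `f_hi`.
#' @return frequency in Hz.
#' @export
band_centre <- function(band) sqrt(band$f_lo * band$f_hi)

band_by_label <- function(label, bands = vasomotion_bands()) {
  i <- match(label, bands$label)
  if (is.na(i)) stop("unknown band label: ", label)
  bands[i, , drop = FALSE]
}
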