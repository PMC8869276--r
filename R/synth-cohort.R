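#' Per-ROI effect distribution for a synthetic cohort
#'
#' Between-subject distributions of the injectable signal parameters for one
#' ROI: baseline temperature, the true pre-to-post temperature change
#' (realised as a linear ramp across the exercise sets, so the injected
#' \eqn{\Delta T_{ROI}} is exact), and per-band oscillator amplitudes in the
#' pre (baseline) and post (recovery) epochs. A sinusoid of amplitude A
#' carries A^2/2 degC^2 of band power, so the injected \eqn{\Delta PSD} of
#' band b is `(amp_post[b]^2 - amp_pre[b]^2) / 2`.
#'
#' @param baseline_temp_mean,baseline_temp_sd degC.
#' @param delta_t_mean,delta_t_sd true temperature change, degC.
#' @param osc_amp_pre,osc_amp_post named numeric vectors (band label ->
#'   mean amplitude in degC); bands omitted get amplitude 0.
#' @param osc_amp_rel_sd between-subject SD of amplitudes as a fraction of
#'   the mean (draws truncated at 0).
#' @param noise_sd sensor noise SD, degC.
#' @return a `roi_effect` list.
#' @export
roi_effect <- function(baseline_temp_mean = 32, baseline_temp_sd = 0.5,
                       delta_t_mean = 0, delta_t_sd = 0.3,
                       osc_amp_pre = c(), osc_amp_post = c(),
                       osc_amp_rel_sd = 0.3, noise_sd = 0.03) {
  structure(list(baseline_temp_mean = baseline_temp_mean,
                 baseline_temp_sd = baseline_temp_sd,
                 delta_t_mean = delta_t_mean, delta_t_sd = delta_t_sd,
                 osc_amp_pre = osc_amp_pre, osc_amp_post = osc_amp_post,
                 osc_amp_rel_sd = osc_amp_rel_sd, noise_sd = noise_sd),
            class = "roi_effect")
}

#' RPE coupling model
#'
#' The rating of perceived exertion is generated as a noisy linear readout
#' of chosen true features, then rounded and clamped to the 1-10 scale:
#' `RPE = round(intercept + sum(slope_f * feature_f) + N(0, residual_sd))`.
#'
#' @param intercept scale intercept.
#' @param slopes named numeric vector; names are `"<roi>:<feature>"` keys,
#'   e.g. `"Exercised Leg:delta_t"` or `"Nose Tip:dpsd_neurogenic"`.
#' @param residual_sd SD of the Gaussian residual.
#' @return an `rpe_coupling` list.
#' @export
rpe_coupling <- function(intercept = 7, slopes = c(), residual_sd = 0) {
  if (residual_sd < 0) stop("residual_sd must be >= 0")
  structure(list(intercept = intercept, slopes = slopes,
                 residual_sd = residual_sd), class = "rpe_coupling")
}

#' Slope/residual pair for a target feature-RPE correlation
#'
#' Standard construction: for a single coupled feature with between-subject
#' SD `feature_sd`, a slope `b = r * rpe_sd / feature_sd` and residual SD
#' `rpe_sd * sqrt(1 - r^2)` give a latent (pre-rounding) Pearson correlation
#' of exactly `r`; rounding to the integer scale attenuates it slightly.
#'
#' @param r_target desired correlation in (-1, 1).
#' @param feature_sd between-subject SD of the coupled feature.
#' @param rpe_sd latent RPE SD (default 1.2 scale points).
#' @return list with `slope` and `residual_sd`.
#' @export
coupling_for_target_r <- function(r_target, feature_sd, rpe_sd = 1.2) {
  if (abs(r_target) >= 1) stop("r_target must be in (-1, 1)")
  list(slope = r_target * rpe_sd / feature_sd,
       residual_sd = rpe_sd * sqrt(1 - r_target^2))
}

#' Cohort specification
#'
#' @param n_subjects number of subjects, >= 2 (the study design used 8).
#' @param roi_models named list of [roi_effect()] keyed by ROI label.
#' @param coupling an [rpe_coupling()].
#' @param rpe_per_set generate per-set RPE values (three per subject, rising
#'   towards exhaustion) instead of a single end-of-exercise value. Off by
#'   default; the correlation layer uses one value per subject.
#' @param seed integer.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 8, roi_models, coupling = rpe_coupling(),
                        rpe_per_set = FALSE, seed = 1) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (is.null(names(roi_models)) || any(names(roi_models) == ""))
    stop("roi_models must be a named list (ROI labels)")
  structure(list(n_subjects = as.integer(n_subjects), roi_models = roi_models,
                 coupling = coupling, rpe_per_set = rpe_per_set,
                 seed = as_seed(seed)),
            class = "cohort_spec")
}

feature_names <- function() {
  c("delta_t", paste0("dpsd_", vasomotion_bands()$label))
}

# Draw per-subject true parameters, features and RPE (no trace rendering).
# Returns list(params, truth, rpe).
#' Draw cohort ground truth (parameters, true features, RPE)
#'
#' Samples the per-subject, per-ROI signal parameters from a [cohort_spec()]
#' and the coupled RPE values, without rendering any traces. This is the
#' ground-truth layer of [synthesize_cohort()]; it is exposed so the RPE
#' coupling construction can be checked at large n cheaply.
#'
#' @param spec a [cohort_spec()].
#' @return list with `params` (per subject/ROI draw of baseline temperature,
#'   delta-T and band amplitudes), `truth` (tidy data.frame `subject_id`,
#'   `roi`, `feature`, `true_value`) and `rpe` (data.frame `subject_id`,
#'   `set`, `rpe` — one row per subject unless `rpe_per_set`).
#' @export
draw_cohort_truth <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  bands <- vasomotion_bands()$label
  rois <- names(spec$roi_models)
  params <- list(); truth <- list()
  for (s in seq_len(spec$n_subjects)) {
    sid <- sprintf("S%02d", s)
    for (r in rois) {
      m <- spec$roi_models[[r]]
      bt <- stats::rnorm(1, m$baseline_temp_mean, m$baseline_temp_sd)
      dt <- stats::rnorm(1, m$delta_t_mean, m$delta_t_sd)
      amp <- function(means) {
        a <- stats::setNames(numeric(length(bands)), bands)
        for (b in names(means))
          a[b] <- max(0, stats::rnorm(1, means[[b]], m$osc_amp_rel_sd * means[[b]]))
        a
      }
      a_pre <- amp(m$osc_amp_pre); a_post <- amp(m$osc_amp_post)
      ph_pre  <- stats::runif(length(bands), 0, 2 * pi)
      ph_post <- stats::runif(length(bands), 0, 2 * pi)
      params[[paste(sid, r, sep = "|")]] <- list(
        subject_id = sid, roi = r, baseline_temp = bt, delta_t = dt,
        amp_pre = a_pre, amp_post = a_post,
        phase_pre = ph_pre, phase_post = ph_post, noise_sd = m$noise_sd)
      truth[[paste(sid, r, sep = "|")]] <- data.frame(
        subject_id = sid, roi = r,
        feature = feature_names(),
        true_value = c(dt, (a_post^2 - a_pre^2) / 2))
    }
  }
  truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
  # RPE: linear readout of true features, one latent value per subject
  cp <- spec$coupling
  sids <- sprintf("S%02d", seq_len(spec$n_subjects))
  latent <- rep(cp$intercept, spec$n_subjects)
  for (key in names(cp$slopes)) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("coupling slope key must be '<roi>:<feature>': ", key)
    v <- truth$true_value[truth$roi == parts[1] & truth$feature == parts[2]]
    if (length(v) != spec$n_subjects) stop("coupling key matches no feature: ", key)
    latent <- latent + cp$slopes[[key]] * v
  }
  latent <- latent + stats::rnorm(spec$n_subjects, 0, cp$residual_sd)
  clamp_rpe <- function(x) pmin(10L, pmax(1L, as.integer(round(x))))
  if (spec$rpe_per_set) {
    rpe <- do.call(rbind, lapply(1:3, function(k)
      data.frame(subject_id = sids, set = k,
                 rpe = clamp_rpe(latent - (3 - k) * 1.5))))
    rpe <- rpe[order(rpe$subject_id, rpe$set), ]
    rownames(rpe) <- NULL
  } else {
    rpe <- data.frame(subject_id = sids, set = 3L, rpe = clamp_rpe(latent))
  }
  list(params = params, truth = truth, rpe = rpe)
}

#' Aggregate per-set RPE to one value per subject
#'
#' @param rpe data.frame `(subject_id, set, rpe)`.
#' @param method `"last"` (final set, the default), `"mean"` or `"max"`.
#' @return data.frame `(subject_id, rpe)`.
#' @export
rpe_aggregate <- function(rpe, method = c("last", "mean", "max")) {
  method <- match.arg(method)
  f <- switch(method,
              last = function(d) d$rpe[which.max(d$set)],
              mean = function(d) mean(d$rpe),
              max  = function(d) max(d$rpe))
  out <- do.call(rbind, lapply(split(rpe, rpe$subject_id), function(d)
    data.frame(subject_id = d$subject_id[1], rpe = f(d))))
  rownames(out) <- NULL
  out
}

#' Synthesize a full cohort of ROI traces with known ground truth
#'
#' Draws per-subject parameters via [draw_cohort_truth()], then renders one
#' trace per subject and ROI: the injected temperature change is realised as
#' a linear ramp spread across the three exercise sets (flat baseline,
#' rests and recovery), so the flat 10-s analysis windows recover it
#' exactly up to sensor noise; band oscillators at the band geometric
#' centres are active in the baseline and recovery epochs.
#'
#' @param spec a [cohort_spec()].
#' @param timeline a [session_timeline()].
#' @param fs sampling rate (Hz), default 10.
#' @return list with `traces` (list by subject of named lists of
#'   [roi_trace()]), `rpe` (per-set data.frame), `truth` (tidy ground-truth
#'   feature table), `timeline`, `spec`.
#' @export
synthesize_cohort <- function(spec, timeline, fs = 10) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(timeline, "session_timeline"))
  gt <- draw_cohort_truth(spec)
  ph <- timeline$phases
  set_dur <- sum(ph$end_s[grepl("^set", ph$label)] -
                 ph$start_s[grepl("^set", ph$label)])
  bands <- vasomotion_bands()
  traces <- list()
  for (s in seq_len(spec$n_subjects)) {
    sid <- sprintf("S%02d", s)
    traces[[sid]] <- list()
    for (j in seq_along(spec$roi_models)) {
      r <- names(spec$roi_models)[j]
      p <- gt$params[[paste(sid, r, sep = "|")]]
      mk_osc <- function(amps, phases) {
        keep <- which(amps > 0)
        lapply(keep, function(k) band_oscillator(
          bands$label[k], amplitude = amps[k],
          frequency = band_centre(bands[k, ]), phase = phases[k]))
      }
      model <- roi_signal_model(
        baseline_temp = p$baseline_temp,
        phase_trends = list(set = phase_trend(slope = p$delta_t / set_dur)),
        osc_pre = mk_osc(p$amp_pre, p$phase_pre),
        osc_post = mk_osc(p$amp_post, p$phase_post),
        noise_sd = p$noise_sd)
      traces[[sid]][[r]] <- synthesize_trace(
        model, timeline, fs = fs,
        seed = derive_seed(spec$seed, s * 101 + j), label = r)
    }
  }
  list(traces = traces, rpe = gt$rpe, truth = gt$truth,
       timeline = timeline, spec = spec)
}
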