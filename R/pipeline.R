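#' Built-in scenario configurations
#'
#' `"paper_like"` emulates the study design: 8 subjects, the three-set
#' knee-extension timeline (5-min baseline and recovery, 3-min rests), four
#' ROIs with an injected exercised-leg warming (+1.5 degC), mild nose-tip
#' warming, near-zero/negative changes elsewhere, raised post-exercise
#' neurogenic oscillations on the facial ROIs and raised myogenic power on
#' the exercised leg, and RPE coupled negatively to the exercised-leg
#' temperature change (latent r = -0.8). It runs at trace level
#' (`render_frames: false`): video rendering at full session length is out
#' of desk scale and adds nothing to the feature/statistics chain.
#'
#' `"tracking_demo"` is a short three-subject scenario with
#' `render_frames: true`: frames are rendered, each ROI is tracked under a
#' small drift, and traces are re-extracted from pixels, exercising the
#' full video path end to end (with proportionally shortened analysis
#' windows).
#'
#' @param name `"paper_like"` or `"tracking_demo"`.
#' @param seed integer seed stored in the config.
#' @return a config list, as [validate_config()] / [run_pipeline()] expect.
#' @export
scenario_config <- function(name = c("paper_like", "tracking_demo"), seed = 1) {
  name <- match.arg(name)
  common_bands <- vasomotion_bands()$label
  if (name == "paper_like") {
    cpl <- coupling_for_target_r(-0.8, feature_sd = 0.4)
    list(
      scenario = name, mode = "synthetic", seed = as_seed(seed),
      render_frames = FALSE,
      timeline = list(set_durations_s = c(60, 50, 40), baseline_s = 300,
                      rest_s = 180, recovery_s = 300),
      fs_hz = 10,
      cohort = list(
        n_subjects = 8,
        rois = list(
          "Exercised Leg" = list(baseline_temp_mean = 31.5, baseline_temp_sd = 0.5,
            delta_t_mean = 1.5, delta_t_sd = 0.4,
            osc_amp_pre = list(metabolic = 0.03, myogenic = 0.05, respiratory = 0.02, cardiac = 0.01),
            osc_amp_post = list(metabolic = 0.03, myogenic = 0.09, respiratory = 0.02, cardiac = 0.01),
            noise_sd = 0.03),
          "Nonexercised Leg" = list(baseline_temp_mean = 31.5, baseline_temp_sd = 0.5,
            delta_t_mean = -0.1, delta_t_sd = 0.25,
            osc_amp_pre = list(metabolic = 0.03, myogenic = 0.05, respiratory = 0.02, cardiac = 0.01),
            osc_amp_post = list(metabolic = 0.03, myogenic = 0.05, respiratory = 0.02, cardiac = 0.01),
            noise_sd = 0.03),
          "Nose Tip" = list(baseline_temp_mean = 34, baseline_temp_sd = 0.4,
            delta_t_mean = 0.3, delta_t_sd = 0.25,
            osc_amp_pre = list(metabolic = 0.03, neurogenic = 0.04, myogenic = 0.06, respiratory = 0.03, cardiac = 0.015),
            osc_amp_post = list(metabolic = 0.03, neurogenic = 0.08, myogenic = 0.04, respiratory = 0.03, cardiac = 0.015),
            noise_sd = 0.03),
          "Corrugator" = list(baseline_temp_mean = 34.2, baseline_temp_sd = 0.4,
            delta_t_mean = -0.1, delta_t_sd = 0.25,
            osc_amp_pre = list(metabolic = 0.03, neurogenic = 0.04, myogenic = 0.06, respiratory = 0.03, cardiac = 0.015),
            osc_amp_post = list(metabolic = 0.03, neurogenic = 0.08, myogenic = 0.04, respiratory = 0.03, cardiac = 0.015),
            noise_sd = 0.03)),
        coupling = list(intercept = 8 - cpl$slope * 1.5,
                        slopes = list("Exercised Leg:delta_t" = cpl$slope),
                        residual_sd = cpl$residual_sd),
        rpe_per_set = FALSE),
      psd = list(segment_s = 150, overlap = 0.5, taper = "hann",
                 detrend = "linear", window_s = 300),
      stats = list(epsilon = "gg", rpe_agg = "last", alpha = 0.05),
      bands = common_bands)
  } else {
    cfg <- scenario_config("paper_like", seed = seed)
    cfg$scenario <- name
    cfg$render_frames <- TRUE
    cfg$cohort$n_subjects <- 3
    cfg$timeline <- list(set_durations_s = c(5, 5, 5), baseline_s = 25,
                         rest_s = 3, recovery_s = 25)
    cfg$psd <- list(segment_s = 10, overlap = 0.5, taper = "hann",
                    detrend = "linear", window_s = 20)
    cfg$scene <- list(
      image_hw = c(90, 120), ambient_temp = 24, noise_sd = 0.03,
      rois = list(
        list(label = "Exercised Leg", x0 = 8, y0 = 8, width = 20, height = 16),
        list(label = "Nonexercised Leg", x0 = 50, y0 = 8, width = 20, height = 16),
        list(label = "Nose Tip", x0 = 88, y0 = 8, width = 20, height = 16),
        list(label = "Corrugator", x0 = 8, y0 = 50, width = 20, height = 16)),
      motions = list("Exercised Leg" = list(type = "drift", dx = 3, dy = 2)))
    cfg$track <- list(search_px = 5)
    cfg
  }
}

config_to_cohort_spec <- function(config) {
  rois <- lapply(config$cohort$rois, function(r)
    roi_effect(baseline_temp_mean = r$baseline_temp_mean %||% 32,
               baseline_temp_sd = r$baseline_temp_sd %||% 0.5,
               delta_t_mean = r$delta_t_mean %||% 0,
               delta_t_sd = r$delta_t_sd %||% 0.3,
               osc_amp_pre = unlist(r$osc_amp_pre),
               osc_amp_post = unlist(r$osc_amp_post),
               osc_amp_rel_sd = r$osc_amp_rel_sd %||% 0.3,
               noise_sd = r$noise_sd %||% 0.03))
  cp <- config$cohort$coupling %||% list()
  cohort_spec(n_subjects = config$cohort$n_subjects %||% 8,
              roi_models = rois,
              coupling = rpe_coupling(intercept = cp$intercept %||% 7,
                                      slopes = unlist(cp$slopes),
                                      residual_sd = cp$residual_sd %||% 0),
              rpe_per_set = isTRUE(config$cohort$rpe_per_set),
              seed = config$seed %||% 1)
}

config_psd_settings <- function(config) {
  p <- config$psd %||% list()
  psd_settings(segment_s = p$segment_s %||% 150, overlap = p$overlap %||% 0.5,
               taper = p$taper %||% "hann", detrend = p$detrend %||% "linear",
               window_s = p$window_s %||% 300)
}

#' Validate a run configuration
#'
#' Collects every violation (it does not stop at the first); a config is
#' runnable iff the returned list is empty. Each violation carries a
#' path-style locator into the config document.
#'
#' @param config a config list (e.g. from [scenario_config()] or
#'   [yaml::read_yaml()]).
#' @return data.frame `(path, problem)`; zero rows when valid.
#' @export
validate_config <- function(config) {
  v <- list()
  bad <- function(path, problem) v[[length(v) + 1L]] <<- data.frame(path = path, problem = problem)
  mode <- config$mode %||% "synthetic"
  if (!mode %in% c("synthetic", "real")) bad("$mode", "must be 'synthetic' or 'real'")
  if (mode == "synthetic" && is.null(config$seed))
    bad("$seed", "seed is mandatory in synthetic mode")
  if (!is.null(config$bands)) {
    want <- vasomotion_bands()$label
    if (!setequal(unlist(config$bands), want))
      bad("$bands", paste("band set must be exactly:", paste(want, collapse = ", ")))
  }
  tl <- tryCatch(timeline_from_config(config$timeline %||% list()),
                 error = function(e) e)
  if (inherits(tl, "error")) bad("$timeline", conditionMessage(tl))
  if (mode == "synthetic") {
    if (is.null(config$cohort)) bad("$cohort", "synthetic mode needs a cohort section")
    else {
      n <- config$cohort$n_subjects %||% 0
      if (n < 2) bad("$cohort.n_subjects", "must be >= 2")
      for (rn in names(config$cohort$rois %||% list())) {
        r <- config$cohort$rois[[rn]]
        if ((r$noise_sd %||% 0.03) < 0)
          bad(sprintf("$cohort.rois['%s'].noise_sd", rn), "must be >= 0")
        for (ep in c("osc_amp_pre", "osc_amp_post")) {
          a <- unlist(r[[ep]])
          if (any(a < 0)) bad(sprintf("$cohort.rois['%s'].%s", rn, ep), "amplitudes must be >= 0")
          unknown <- setdiff(names(a), vasomotion_bands()$label)
          if (length(unknown) > 0)
            bad(sprintf("$cohort.rois['%s'].%s", rn, ep),
                paste("unknown band(s):", paste(unknown, collapse = ", ")))
        }
      }
    }
  } else {
    for (k in c("stack_paths", "rois", "timeline", "rpe"))
      if (is.null(config$real[[k]]) && k != "timeline")
        bad(paste0("$real.", k), "required in real mode")
  }
  p <- config$psd %||% list()
  pchk <- tryCatch(config_psd_settings(config), error = function(e) e)
  if (inherits(pchk, "error")) bad("$psd", conditionMessage(pchk))
  eps <- config$stats$epsilon %||% "gg"
  if (!eps %in% c("gg", "hf", "none")) bad("$stats.epsilon", "must be gg, hf or none")
  agg <- config$stats$rpe_agg %||% "last"
  if (!agg %in% c("last", "mean", "max")) bad("$stats.rpe_agg", "must be last, mean or max")
  if (length(v) == 0) return(data.frame(path = character(), problem = character()))
  do.call(rbind, v)
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s stage] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline: simulate -> extract -> features -> stats
#'
#' Synthetic mode: generates the cohort from the config (optionally
#' rendering thermal frames, tracking the ROIs and re-extracting traces
#' from pixels), computes the feature table and writes the statistics
#' report. Real mode: reads frame stacks, ROI boxes, timeline and RPE from
#' the paths in `config$real`. All stage outputs land under `out_dir`
#' (`traces.csv`, `features.csv`, `truth.csv` and `rpe.csv` when synthetic,
#' `stacks/` when rendered, `report/`), plus `manifest.json` with the
#' config hash, per-file checksums and all collected warnings; a failing
#' stage aborts with a stage-named error, preserving earlier outputs.
#'
#' @param config config list (see [scenario_config()], [validate_config()]).
#' @param out_dir output directory.
#' @return the run manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  viol <- validate_config(config)
  if (nrow(viol) > 0)
    stop("invalid config:\n", paste(sprintf("  %s: %s", viol$path, viol$problem),
                                    collapse = "\n"), call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  warnings_log <- character()
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))
  mode <- config$mode %||% "synthetic"
  fs <- config$fs_hz %||% 10
  psd_set <- config_psd_settings(config)

  if (mode == "synthetic") {
    timeline <- stage_try("simulate", timeline_from_config(config$timeline))
    cohort <- stage_try("simulate", {
      spec <- config_to_cohort_spec(config)
      synthesize_cohort(spec, timeline, fs = fs)
    })
    traces <- cohort$traces
    if (isTRUE(config$render_frames)) {
      traces <- stage_try("extract", {
        sc <- config$scene
        boxes <- lapply(sc$rois, function(r)
          roi_box(r$label, r$x0, r$y0, r$width, r$height))
        layout <- scene_layout(unlist(sc$image_hw), boxes, motions = sc$motions)
        stacks_dir <- file.path(out_dir, "stacks")
        if (!dir.exists(stacks_dir)) dir.create(stacks_dir, recursive = TRUE)
        out <- list()
        for (sid in names(cohort$traces)) {
          fr <- synthesize_frames(cohort$traces[[sid]], layout,
                                  ambient_temp = sc$ambient_temp %||% 24,
                                  noise_sd = sc$noise_sd %||% 0.03,
                                  seed = derive_seed(config$seed, match(sid, names(cohort$traces))))
          write_frame_stack(fr$stack, file.path(stacks_dir, paste0(sid, ".tif")),
                            format = "tiff", truth = fr$truth)
          tset <- track_settings(
            search_px = config$track$search_px %||% 10,
            refresh_every = config$track$refresh_every %||% 50,
            min_score = config$track$min_score %||% 0.5)
          ext <- extract_traces(fr$stack, boxes, track = TRUE, settings = tset)
          for (l in names(ext)) {
            tk <- attr(ext[[l]], "track")
            if (any(tk$flagged))
              note("%s/%s: %d low-confidence tracking frame(s)", sid, l, sum(tk$flagged))
          }
          out[[sid]] <- ext
        }
        out
      })
    } else {
      note("trace-level run: frames not rendered, extraction bypassed (render_frames: false)")
    }
    write_traces(traces, file.path(out_dir, "traces.csv"))
    data.table::fwrite(cohort$rpe, file.path(out_dir, "rpe.csv"))
    data.table::fwrite(cohort$truth, file.path(out_dir, "truth.csv"))
    rpe <- cohort$rpe
  } else {
    traces <- stage_try("extract", {
      boxes <- read_roi_boxes(config$real$rois)
      out <- list()
      for (sid in names(config$real$stack_paths)) {
        stack <- read_frame_stack(config$real$stack_paths[[sid]],
                                  format = config$real$format %||% "tiff")
        out[[sid]] <- extract_traces(stack, boxes,
                                     track = !isTRUE(config$real$no_track))
      }
      out
    })
    timeline <- stage_try("extract", read_timeline(config$real$timeline))
    rpe <- stage_try("extract", read_rpe(config$real$rpe))
    write_traces(traces, file.path(out_dir, "traces.csv"))
  }

  ft <- stage_try("features", {
    out <- withCallingHandlers(
      compute_feature_table(traces, timeline, rpe,
                            rpe_agg = config$stats$rpe_agg %||% "last",
                            settings = psd_set),
      warning = function(w) {
        note("%s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (is.null(out) || nrow(out) == 0)
      stop("all subjects excluded: ",
           paste(attr(out, "excluded"), collapse = "; "))
    out
  })
  write_feature_table(ft, file.path(out_dir, "features.csv"))

  report <- stage_try("stats", build_report(
    ft, epsilon = config$stats$epsilon %||% "gg",
    alpha = config$stats$alpha %||% 0.05))
  write_report(report, file.path(out_dir, "report"))

  files <- c("traces.csv", "features.csv", file.path("report", "report.json"),
             file.path("report", "report.md"),
             if (mode == "synthetic") c("rpe.csv", "truth.csv"))
  files <- files[file.exists(file.path(out_dir, files))]
  manifest <- list(
    config_hash = digest_config(config),
    package_version = as.character(utils::packageVersion("thermofatigue")),
    seed = config$seed,
    checksums = as.list(tools::md5sum(file.path(out_dir, files))),
    warnings = c(warnings_log, report$warnings))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

digest_config <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}
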