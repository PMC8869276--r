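test_that("delta-T recovers constants, plateaus and the linear-ramp closed form", {
  tl <- default_tl()
  expect_equal(delta_t_roi(roi_trace(rep(30, 11100), 10), tl), 0)

  # linear ramp 0.001 degC/s: window means sit at t = 284.95 and 1104.95 s
  ramp <- roi_trace(30 + 0.001 * (0:11099) / 10, 10)
  expect_equal(delta_t_roi(ramp, tl), 0.820, tolerance = 1e-9)

  # each window holds exactly round(10 * fs) samples
  w <- analysis_windows(tl)
  expect_length(thermofatigue:::window_indices(ramp, w$dt_baseline), 100)
  expect_length(thermofatigue:::window_indices(ramp, w$dt_final), 100)
})

test_that("out-of-range windows raise errors naming the window", {
  tl <- default_tl()
  short <- roi_trace(rep(30, 4000), 10)  # 400 s: baseline windows fit, final ones do not
  expect_error(delta_t_roi(short, tl), "dt_final window")
  expect_error(delta_psd(short, tl), "psd_post window")
  tiny <- roi_trace(rep(30, 500), 10)
  expect_error(delta_t_roi(tiny, tl), "dt_baseline window")
})

test_that("delta-PSD is zero for literally equal epochs and flips under swap", {
  tl <- default_tl()
  set.seed(41)
  v <- rnorm(11100, 32, 0.05)
  pre_idx <- 1:3000            # [0, 300) s
  post_idx <- 8101:11100       # [810, 1110) s
  v[post_idx] <- v[pre_idx]
  dp0 <- delta_psd(roi_trace(v, 10), tl)
  expect_true(all(dp0$delta_psd == 0))

  # injected post-only myogenic tone
  t <- (0:11099) / 10
  v2 <- rep(32, 11100)
  v2[t >= 810] <- v2[t >= 810] + 0.1 * sin(2 * pi * 0.1 * t[t >= 810])
  dp <- delta_psd(roi_trace(v2, 10), tl)
  expect_equal(dp$delta_psd[dp$band == "myogenic"], 0.005, tolerance = 0.10)
  expect_lt(max(abs(dp$delta_psd[dp$band != "myogenic"])), 2e-4)

  # swapping the epochs flips every sign exactly
  v3 <- v2
  v3[pre_idx] <- v2[post_idx]
  v3[post_idx] <- v2[pre_idx]
  dp_swap <- delta_psd(roi_trace(v3, 10), tl)
  expect_equal(dp_swap$delta_psd, -dp$delta_psd, tolerance = 1e-12)
  expect_equal(dp_swap$power_pre, dp$power_post, tolerance = 1e-12)
})

test_that("feature tables have one row per subject x ROI with all features", {
  tl <- default_tl()
  spec <- cohort_spec(8, roi_models = list(
    "Exercised Leg" = roi_effect(delta_t_mean = 1.5, delta_t_sd = 0.2),
    "Nonexercised Leg" = roi_effect(),
    "Nose Tip" = roi_effect(baseline_temp_mean = 34),
    "Corrugator" = roi_effect(baseline_temp_mean = 34)),
    coupling = rpe_coupling(intercept = 8), seed = 5)
  co <- synthesize_cohort(spec, tl)
  ft <- compute_feature_table(co$traces, tl, co$rpe)
  expect_equal(nrow(ft), 32)
  expect_true(all(c("delta_t_C", paste0("dpsd_", vasomotion_bands()$label),
                    "rpe") %in% names(ft)))
  expect_length(attr(ft, "excluded"), 0)

  # injected exercised-leg warming is recovered within noise of the window means
  got <- ft$delta_t_C[ft$roi == "Exercised Leg"]
  want <- co$truth$true_value[co$truth$roi == "Exercised Leg" &
                              co$truth$feature == "delta_t"]
  expect_lt(max(abs(got - want)), 3 * 0.03 * sqrt(2 / 100))

  # duplicate subject x ROI is an error
  dup <- co$traces
  dup$S01 <- c(dup$S01, dup$S01[1])
  expect_error(compute_feature_table(dup, tl, co$rpe), "duplicate subject")
})

test_that("subjects with infeasible windows are excluded with a logged reason", {
  tl <- default_tl()
  tl_short <- make_default_timeline(c(60, 50, 40), recovery_s = 200)
  spec <- cohort_spec(3, roi_models = list(L = roi_effect()),
                      coupling = rpe_coupling(intercept = 7), seed = 6)
  co <- synthesize_cohort(spec, tl)
  co_short <- synthesize_cohort(spec, tl_short)
  traces <- co$traces
  traces$S02 <- co_short$traces$S02
  tls <- list(S01 = tl, S02 = tl_short, S03 = tl)
  expect_warning(
    ft <- compute_feature_table(traces, tls, co$rpe),
    "excluded subject")
  expect_equal(sort(unique(ft$subject_id)), c("S01", "S03"))
  expect_match(attr(ft, "excluded"), "S02.*recovery")
})
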