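test_that("noiseless trend-free model yields an exactly constant trace", {
  tr <- synthesize_trace(roi_signal_model(32, noise_sd = 0), default_tl(), seed = 1)
  expect_equal(length(tr$values), round(1110 * 10))
  expect_true(all(tr$values == 32))
})

test_that("piecewise trends integrate across phases and stay continuous", {
  tl <- default_tl()
  m <- roi_signal_model(30, phase_trends = list(set = 0.01), noise_sd = 0)
  tr <- synthesize_trace(m, tl, seed = 1)
  t <- trace_times(tr)
  # flat at 30 through the baseline, flat at 30 + 0.01*150 through recovery
  expect_true(all(tr$values[t < 300] == 30))
  expect_equal(unique(tr$values[t >= 810]), 30 + 0.01 * (60 + 50 + 40))
  # plateau construction: injected value recovered exactly by the dT windows
  expect_equal(delta_t_roi(tr, tl), 1.5)
})

test_that("single-oscillator recovery epoch carries variance A^2/2", {
  tl <- default_tl()  # recovery 300 s = 30 cycles of 0.1 Hz, integer count
  m <- roi_signal_model(32, osc_post = list(
    band_oscillator("myogenic", amplitude = 0.1, frequency = 0.1)),
    noise_sd = 0)
  tr <- synthesize_trace(m, tl, seed = 1)
  rec <- tr$values[trace_times(tr) >= 810]
  expect_equal(pvar(rec), 0.1^2 / 2, tolerance = 0.01)
})

test_that("Nyquist violations and out-of-band frequencies are rejected", {
  m <- roi_signal_model(32, osc_post = list(
    band_oscillator("cardiac", amplitude = 0.1, frequency = 0.9)))
  expect_error(synthesize_trace(m, default_tl(), fs = 1, seed = 1),
               "Nyquist.*cardiac")
  expect_error(band_oscillator("myogenic", 0.1, frequency = 0.3),
               "not strictly inside")
  expect_error(band_oscillator("myogenic", -0.1), "amplitude")
})

test_that("traces are bit-reproducible under a fixed seed and clamped", {
  m <- roi_signal_model(32, noise_sd = 0.03)
  tl <- default_tl()
  expect_identical(synthesize_trace(m, tl, seed = 7)$values,
                   synthesize_trace(m, tl, seed = 7)$values)
  expect_false(identical(synthesize_trace(m, tl, seed = 7)$values,
                         synthesize_trace(m, tl, seed = 8)$values))
  hot <- roi_signal_model(44, phase_trends = list(set = 0.5), noise_sd = 0)
  v <- synthesize_trace(hot, tl, seed = 1)$values
  expect_true(all(v <= 45) && all(v >= 20))
})

test_that("cohort RPE stays on the 1-10 scale and couples as constructed", {
  # slopes 0, intercept 7, residual 0 -> every RPE exactly 7
  spec <- cohort_spec(5, roi_models = list(L = roi_effect()),
                      coupling = rpe_coupling(intercept = 7), seed = 1)
  gt <- draw_cohort_truth(spec)
  expect_true(all(gt$rpe$rpe == 7L))
  # extreme intercepts clamp to the scale ends
  for (ic in c(-50, 50)) {
    g <- draw_cohort_truth(cohort_spec(
      4, roi_models = list(L = roi_effect()),
      coupling = rpe_coupling(intercept = ic, residual_sd = 2), seed = 2))
    expect_true(all(g$rpe$rpe %in% 1:10))
  }
})

test_that("cohort synthesis is deterministic and injects exact ground truth", {
  tl <- default_tl()
  spec <- cohort_spec(3, roi_models = list(
    "Exercised Leg" = roi_effect(delta_t_mean = 1.5, delta_t_sd = 0.3,
                                 noise_sd = 0)),
    seed = 42)
  a <- synthesize_cohort(spec, tl)
  b <- synthesize_cohort(spec, tl)
  expect_identical(a$traces, b$traces)
  expect_identical(a$rpe, b$rpe)
  expect_identical(a$truth, b$truth)
  # noiseless: the injected delta-T is recovered exactly from each trace
  for (s in names(a$traces)) {
    truth_dt <- a$truth$true_value[a$truth$subject_id == s &
                                   a$truth$feature == "delta_t"]
    expect_equal(delta_t_roi(a$traces[[s]][["Exercised Leg"]], tl), truth_dt)
  }
})

test_that("per-set RPE rises to the final set and aggregates as asked", {
  spec <- cohort_spec(4, roi_models = list(L = roi_effect()),
                      coupling = rpe_coupling(intercept = 8),
                      rpe_per_set = TRUE, seed = 3)
  gt <- draw_cohort_truth(spec)
  expect_equal(nrow(gt$rpe), 12)
  last <- rpe_aggregate(gt$rpe, "last")
  mx <- rpe_aggregate(gt$rpe, "max")
  expect_equal(nrow(last), 4)
  expect_true(all(mx$rpe >= last$rpe - 1e-9))
})
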