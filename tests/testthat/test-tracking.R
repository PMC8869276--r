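test_that("a static textured scene tracks to zero displacement", {
  fr <- synthesize_frames(list(A = flat_trace(33, 80)), one_roi_scene(),
                          noise_sd = 0.03, seed = 2)
  tk <- track_roi(fr$stack, roi_box("A", 10, 10, 20, 16))
  expect_true(all(tk$positions$x == 10))
  expect_true(all(tk$positions$y == 10))
  expect_false(any(tk$flagged))
})

test_that("featureless frames are flagged and the position held", {
  frames <- replicate(30, matrix(24, 60, 80), simplify = FALSE)
  stack <- thermal_frame_stack(frames, fs = 10)
  tk <- track_roi(stack, roi_box("A", 5, 5, 10, 8))
  expect_true(all(tk$flagged))
  expect_true(all(tk$positions$x == 5))
  expect_true(all(is.na(tk$score[-1])))
})

test_that("slow drift is recovered within a pixel of ground truth", {
  fr <- synthesize_frames(
    list(A = flat_trace(33, 300)),
    one_roi_scene(motion = list(type = "drift", dx = 5, dy = 3)),
    noise_sd = 0.03, seed = 6)
  tk <- track_roi(fr$stack, roi_box("A", 10, 10, 20, 16))
  p <- fr$truth$A
  rmse <- sqrt(mean((tk$positions$x - p$x)^2 + (tk$positions$y - p$y)^2))
  expect_lte(rmse, 1)
  expect_lte(abs(tk$positions$x[300] - p$x[300]), 1)
  expect_lte(abs(tk$positions$y[300] - p$y[300]), 1)
})

test_that("initial boxes must lie inside the image", {
  fr <- synthesize_frames(list(A = flat_trace(33, 3)), one_roi_scene(),
                          noise_sd = 0, seed = 1)
  expect_error(track_roi(fr$stack, roi_box("A", 110, 10, 20, 16)),
               "exceeds the .* image")
  # one position per frame is required
  short <- thermal_frame_stack(fr$stack$frames[1:2], fs = 10)
  tk3 <- static_track(fr$stack, roi_box("A", 10, 10, 20, 16))
  expect_error(extract_trace(short, tk3), "positions for")
})

test_that("extraction is the plain arithmetic box mean", {
  frames <- lapply(0:9, function(i) matrix(i * 0.1, 40, 50))
  stack <- thermal_frame_stack(frames, fs = 10)
  tk <- static_track(stack, roi_box("A", 5, 5, 10, 8))
  tr <- extract_trace(stack, tk)
  expect_equal(tr$values, (0:9) * 0.1)
  expect_equal(tr$fs, 10)

  all32 <- thermal_frame_stack(replicate(5, matrix(32, 40, 50),
                                         simplify = FALSE), fs = 10)
  expect_equal(extract_trace(all32, static_track(all32, roi_box("A", 0, 0, 50, 40)))$values,
               rep(32, 5))
})

test_that("extraction is translation-equivariant and offset-linear", {
  fr <- synthesize_frames(list(A = flat_trace(33, 20)), one_roi_scene(),
                          noise_sd = 0.03, seed = 8)
  box <- roi_box("A", 10, 10, 20, 16)
  tr1 <- extract_trace(fr$stack, static_track(fr$stack, box))
  # shift every frame and the box by the same (dx, dy)
  shifted <- lapply(fr$stack$frames, function(f) {
    g <- matrix(24, nrow(f), ncol(f))
    g[4:nrow(f), 7:ncol(f)] <- f[1:(nrow(f) - 3), 1:(ncol(f) - 6)]
    g
  })
  st2 <- thermal_frame_stack(shifted, fs = 10)
  tr2 <- extract_trace(st2, static_track(st2, roi_box("A", 16, 13, 20, 16)))
  expect_equal(tr2$values, tr1$values)
  # adding a constant c to every pixel adds exactly c to the trace
  st3 <- thermal_frame_stack(lapply(fr$stack$frames, function(f) f + 1.25),
                             fs = 10)
  tr3 <- extract_trace(st3, static_track(st3, box))
  expect_equal(tr3$values, tr1$values + 1.25)
})

test_that("tracked extraction reproduces the injected trace within noise", {
  tr_in <- flat_trace(33, 200)
  tr_in$values <- tr_in$values + 0.5 * sin(2 * pi * 0.05 * trace_times(tr_in))
  fr <- synthesize_frames(
    list(A = tr_in),
    one_roi_scene(motion = list(type = "drift", dx = 4, dy = 0)),
    noise_sd = 0.03, seed = 3)
  traces <- extract_traces(fr$stack, list(roi_box("A", 10, 10, 20, 16)))
  se <- 0.03 / sqrt(20 * 16)
  expect_lt(max(abs(traces$A$values - tr_in$values)), 6 * se)
  expect_false(any(attr(traces$A, "track")$flagged))
})
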