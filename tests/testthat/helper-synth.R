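# Shared fixture builders (generated in code; no stored data).

default_tl <- function() make_default_timeline(c(60, 50, 40))

# Null 8 x 4 feature table: exchangeable ROIs, iid normal cells.
null_table <- function(n = 8, k = 4) {
  wide_to_table(matrix(rnorm(n * k), n, k,
                       dimnames = list(NULL, paste0("R", 1:k))))
}

# A small static scene with one textured (Gaussian-edged) patch.
one_roi_scene <- function(hw = c(90, 120), box = roi_box("A", 10, 10, 20, 16),
                          motion = list(type = "none")) {
  scene_layout(hw, list(box), motions = stats::setNames(list(motion), box$label))
}

# Short flat trace for frame-rendering tests.
flat_trace <- function(temp = 33, n = 100, fs = 10, label = "A") {
  roi_trace(rep(temp, n), fs = fs, label = label)
}
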