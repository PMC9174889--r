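# Closed-form contrast of exposure-integrated speckle, x = T / tau_c
# (unit coherence factor): the module's independent oracle.
K2_integrated <- function(x) (exp(-2 * x) - 1 + 2 * x) / (2 * x^2)

# uniform parenchyma phantom with tau_c = a / speed
uniform_map <- function(n_px = 16, speed = 1, a = 1, pixel_size = 0.05) {
  make_flow_map(n_px, n_px, pixel_size,
                baseline_speed = c(parenchyma = speed), calibration_a = a)
}

quick_config <- function(seed, n_frames = 40, pixel_size = 0.05, ...) {
  acquisition_config(n_frames = n_frames, pixel_size_mm = pixel_size,
                     seed = seed, ...)
}

# ROI-mean flow-index ratio (mean-then-divide) over an arbitrary mask
mask_flow_ratio <- function(stack_t, stack_b, mask) {
  ft <- flow_index(temporal_contrast(stack_t))
  fb <- flow_index(temporal_contrast(stack_b))
  roi_mean(ft, mask) / roi_mean(fb, mask)
}

# a stack of explicitly supplied per-pixel frame values
stack_from_frames <- function(frames, seed = NULL) {
  speckle_stack(frames, acquisition_config(n_frames = dim(frames)[3],
                                           pixel_size_mm = 0.05, seed = seed))
}
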