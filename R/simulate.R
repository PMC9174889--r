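#' Simulate an exposure-integrated dynamic speckle stack
#'
#' Synthesizes raw speckle frames from a ground-truth flow map.  Each pixel
#' carries an independent complex circular-Gaussian field with single-
#' exponential field autocorrelation `|g1(tau)| = exp(-tau / tau_c)`,
#' realized as a first-order autoregressive process on a sub-step grid; a
#' frame's intensity is the mean of `|E|^2` over the sub-steps spanning the
#' exposure, and the field evolves continuously across the inter-frame gaps
#' (advanced by one exact autoregressive jump, so the gap costs nothing).
#'
#' The ensemble statistics of the simulated intensities follow the classical
#' integrated-speckle contrast
#' \deqn{K^2(x) = \frac{e^{-2x} - 1 + 2x}{2x^2}, \quad x = T/\tau_c,}
#' (unit coherence factor), which serves as the closed-form oracle for the
#' whole generator.
#'
#' The sub-step defaults to `min(min(tau_c)/8, exposure/16)` ms; supplying a
#' coarser step than `min(tau_c)/4` is refused (undersampled dynamics would
#' bias the frame statistics).  Detector noise, if any, is applied last.
#' With `config$seed` set, frames are reproducible bit-for-bit.
#'
#' @param flow_map A [make_flow_map()] ground truth.
#' @param config An [acquisition_config()].
#' @param substep_ms Optional explicit sub-step, ms.
#'
#' @return A [speckle_stack()] with `truth = flow_map`.  Mean intensity is 1
#'   per pixel (arbitrary units) before noise.
#' @export
#' @examples
#' fm <- make_flow_map(16, 16, 0.05)
#' st <- simulate_speckle_stack(fm, acquisition_config(pixel_size_mm = 0.05,
#'                                                     seed = 1))
#' dim(st$frames)
simulate_speckle_stack <- function(flow_map, config, substep_ms = NULL) {
  stopifnot(inherits(flow_map, "flow_map"), inherits(config, "acquisition_config"))
  tau <- flow_map$tau_c
  fin <- tau[is.finite(tau)]
  if (length(fin) == 0) stop("all pixels are frozen; nothing fluctuates")
  tau_min <- min(fin)
  if (is.null(substep_ms)) {
    substep_ms <- min(tau_min / 8, config$exposure_ms / 16)
  } else if (substep_ms > tau_min / 4) {
    stop("sub-step ", substep_ms, " ms is coarser than min(tau_c)/4 = ",
         tau_min / 4, " ms: dynamics would be undersampled")
  }
  substeps <- max(1L, as.integer(ceiling(config$exposure_ms / substep_ms)))
  if (!is.null(config$seed)) set.seed(config$seed)

  mat <- .speckle_frames_cpp(as.vector(tau), config$n_frames,
                             config$exposure_ms, config$frame_interval_ms,
                             substeps)
  frames <- array(mat, dim = c(nrow(tau), ncol(tau), config$n_frames))
  frames <- .apply_detector_noise(frames, config)
  speckle_stack(frames, config, truth = flow_map)
}

.apply_detector_noise <- function(frames, config) {
  switch(config$noise_model,
    none = frames,
    gaussian = pmax(frames + rnorm(length(frames), sd = config$noise_sd), 0),
    poisson = {
      arr <- rpois(length(frames), lambda = config$gain * frames) / config$gain
      array(arr, dim = dim(frames))
    })
}
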