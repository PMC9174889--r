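#' Acquisition settings for a speckle stack
#'
#' Bundles the camera/acquisition parameters used both by the phantom
#' generator and by the contrast analysis: number of frames, exposure time,
#' frame interval, pixel calibration, bit depth, detector noise model and the
#' random seed that makes a simulated acquisition reproducible.
#'
#' The defaults (40 frames at 20 ms exposure) are the standard temporal-
#' contrast acquisition for through-skull cerebral blood flow mapping; the
#' 25 ms frame interval leaves a 5 ms readout gap between exposures.
#'
#' @param n_frames Number of frames in the stack (>= 2).
#' @param exposure_ms Exposure time per frame, ms.
#' @param frame_interval_ms Start-to-start frame spacing, ms; must be >=
#'   `exposure_ms`.
#' @param pixel_size_mm Size of a pixel on the object, mm.
#' @param bit_depth Integer bit depth used when the stack is exported.
#' @param noise_model One of `"none"` (pure speckle), `"gaussian"`
#'   (additive Gaussian read noise of standard deviation `noise_sd`, in
#'   units of the mean speckle intensity), or `"poisson"` (shot noise:
#'   intensities are scaled by `gain` expected photons per unit intensity,
#'   Poisson-sampled, and rescaled).
#' @param noise_sd Additive noise standard deviation (used for `"gaussian"`).
#' @param gain Photon gain (used for `"poisson"`).
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#'
#' @return An object of class `acquisition_config`.
#' @export
#' @examples
#' acquisition_config(pixel_size_mm = 0.05, seed = 1)
acquisition_config <- function(n_frames = 40, exposure_ms = 20,
                               frame_interval_ms = 25, pixel_size_mm = 0.05,
                               bit_depth = 16L,
                               noise_model = c("none", "gaussian", "poisson"),
                               noise_sd = 0.05, gain = 500, seed = NULL) {
  noise_model <- match.arg(noise_model)
  if (n_frames < 2) stop("n_frames must be at least 2")
  if (exposure_ms <= 0) stop("exposure_ms must be positive")
  if (exposure_ms > frame_interval_ms)
    stop("exposure_ms must not exceed frame_interval_ms")
  if (pixel_size_mm <= 0) stop("pixel_size_mm must be positive")
  structure(
    list(n_frames = as.integer(n_frames), exposure_ms = exposure_ms,
         frame_interval_ms = frame_interval_ms,
         pixel_size_mm = pixel_size_mm, bit_depth = as.integer(bit_depth),
         noise_model = noise_model, noise_sd = noise_sd, gain = gain,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "acquisition_config")
}

#' Raw speckle frame stack
#'
#' Container for a sequence of raw speckle frames plus the acquisition
#' settings that produced them, and (for simulated stacks) the ground-truth
#' flow map.
#'
#' @param frames Numeric array `height x width x n_frames` of non-negative
#'   intensities.
#' @param config An [acquisition_config()].
#' @param truth Optional [make_flow_map()] ground truth.
#'
#' @return An object of class `speckle_stack`.
#' @export
speckle_stack <- function(frames, config, truth = NULL) {
  if (length(dim(frames)) != 3)
    stop("frames must be a height x width x n_frames array")
  if (dim(frames)[3] != config$n_frames)
    stop("frame count (", dim(frames)[3], ") does not match config$n_frames (",
         config$n_frames, ")")
  if (any(frames < 0)) stop("speckle intensities must be non-negative")
  structure(list(frames = frames, config = config, truth = truth),
            class = "speckle_stack")
}

#' @export
print.speckle_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<speckle_stack> %d x %d px, %d frames, %g ms exposure / %g ms interval\n",
              d[1], d[2], d[3], x$config$exposure_ms, x$config$frame_interval_ms))
  invisible(x)
}
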