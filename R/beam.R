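#' Radial intensity profile of a beam-spot image
#'
#' Mean intensity in concentric annular bins around the spot center.  If no
#' center is given it is located as the intensity-weighted centroid of the
#' top-decile pixels (robust against diffuse background).  Bins with no
#' pixels are omitted; radii are bin midpoints in mm.
#'
#' @param image Numeric matrix (single beam-spot image).
#' @param pixel_size_mm Pixel size, mm.
#' @param center Optional `c(row, col)` center in pixels.
#' @param bin_width_mm Annulus width, mm.
#' @return Data frame with columns `radius_mm` (strictly increasing) and
#'   `intensity`.
#' @export
radial_profile <- function(image, pixel_size_mm, center = NULL,
                           bin_width_mm = 0.02) {
  stopifnot(is.matrix(image))
  if (length(image) < 2) stop("degenerate 1-pixel image")
  if (bin_width_mm <= 0) stop("bin_width_mm must be positive")
  if (is.null(center)) center <- beam_center(image)
  if (center[1] < 1 || center[1] > nrow(image) ||
      center[2] < 1 || center[2] > ncol(image))
    stop("center lies outside the image")
  rows <- matrix(seq_len(nrow(image)), nrow(image), ncol(image))
  cols <- matrix(seq_len(ncol(image)), nrow(image), ncol(image), byrow = TRUE)
  r_mm <- sqrt((rows - center[1])^2 + (cols - center[2])^2) * pixel_size_mm
  bin <- floor(r_mm / bin_width_mm)
  means <- tapply(as.vector(image), as.vector(bin), mean)
  idx <- as.numeric(names(means))
  data.frame(radius_mm = (idx + 0.5) * bin_width_mm,
             intensity = as.vector(means))
}

#' Locate a beam-spot center
#'
#' Intensity-weighted centroid of the pixels at or above the 90th intensity
#' percentile.
#'
#' @param image Numeric matrix.
#' @return `c(row, col)` in pixels.
#' @export
beam_center <- function(image) {
  thr <- quantile(image, 0.9)
  top <- image >= thr
  w <- image * top
  rows <- matrix(seq_len(nrow(image)), nrow(image), ncol(image))
  cols <- matrix(seq_len(ncol(image)), nrow(image), ncol(image), byrow = TRUE)
  c(sum(rows * w) / sum(w), sum(cols * w) / sum(w))
}

#' Half-intensity distance of a radial profile
#'
#' The distance from the spot center to where the intensity first drops to
#' half the central (first-bin) value, linearly interpolated between the
#' adjacent bins.  Errors if the profile never falls below half (e.g. a
#' monotonically increasing profile).
#'
#' @param profile Data frame from [radial_profile()].
#' @return Half-intensity distance, mm.  Invariant under global intensity
#'   scaling.
#' @export
half_intensity_distance <- function(profile) {
  stopifnot(all(c("radius_mm", "intensity") %in% names(profile)))
  half <- profile$intensity[1] / 2
  below <- which(profile$intensity <= half)
  below <- below[below > 1]
  if (length(below) == 0)
    stop("profile never drops to half the central intensity; no crossing")
  k <- below[1]
  r0 <- profile$radius_mm[k - 1]; r1 <- profile$radius_mm[k]
  i0 <- profile$intensity[k - 1]; i1 <- profile$intensity[k]
  r0 + (i0 - half) / (i0 - i1) * (r1 - r0)
}

#' Transmitted power ratio of two beam-spot images
#'
#' Total (background-subtracted) intensity of `image_a` divided by that of
#' `image_b`.  The background of each image is estimated as the median of a
#' border region (`border_px` pixels wide) and subtracted before summation.
#' Both images must share exposure/gain semantics for the ratio to be
#' meaningful.
#'
#' @param image_a,image_b Non-negative numeric matrices.
#' @param border_px Border width for background estimation, pixels.
#' @return Dimensionless power ratio.
#' @export
power_ratio <- function(image_a, image_b, border_px = 10) {
  p <- vapply(list(image_a, image_b), function(img) {
    stopifnot(is.matrix(img))
    if (any(img < 0)) stop("beam images must be non-negative")
    b <- border_px
    border <- img
    keep <- matrix(FALSE, nrow(img), ncol(img))
    keep[c(seq_len(min(b, nrow(img))), seq.int(max(1, nrow(img) - b + 1), nrow(img))), ] <- TRUE
    keep[, c(seq_len(min(b, ncol(img))), seq.int(max(1, ncol(img) - b + 1), ncol(img)))] <- TRUE
    sum(img - median(img[keep]))
  }, numeric(1))
  if (p[2] <= 0)
    stop("denominator image has no power above background")
  p[1] / p[2]
}

#' All beam-spot metrics at once
#'
#' Convenience wrapper returning center, radial profile, half-intensity
#' distance and total background-subtracted power of a single spot image.
#'
#' @inheritParams radial_profile
#' @param border_px Border width for the background estimate.
#' @return An object of class `beam_metrics`.
#' @export
beam_metrics <- function(image, pixel_size_mm, center = NULL,
                         bin_width_mm = 0.02, border_px = 10) {
  if (is.null(center)) center <- beam_center(image)
  prof <- radial_profile(image, pixel_size_mm, center, bin_width_mm)
  b <- border_px
  keep <- matrix(FALSE, nrow(image), ncol(image))
  keep[c(seq_len(b), seq.int(nrow(image) - b + 1, nrow(image))), ] <- TRUE
  keep[, c(seq_len(b), seq.int(ncol(image) - b + 1, ncol(image)))] <- TRUE
  structure(
    list(center = center, radial_profile = prof,
         half_intensity_distance_mm = half_intensity_distance(prof),
         total_power = sum(image - median(image[keep]))),
    class = "beam_metrics")
}

#' @export
print.beam_metrics <- function(x, ...) {
  cat(sprintf("Beam spot: center (%.1f, %.1f) px, half-intensity distance %.4g mm, power %.4g a.u.\n",
              x$center[1], x$center[2], x$half_intensity_distance_mm,
              x$total_power))
  invisible(x)
}
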