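#' Binarize a vasculature image
#'
#' Turns a grayscale vessel image (e.g. a lectin-channel section or maximum
#' projection) into a binary vessel mask.  The default method is Otsu's
#' threshold computed on the image's own intensity range; a fixed threshold
#' is available for reproducibility tests.  Foreground (`TRUE`) is vessel.
#'
#' @param image Numeric matrix.
#' @param method `"otsu"` or `"fixed_threshold"`.
#' @param threshold Threshold intensity for `"fixed_threshold"` (foreground
#'   is `image > threshold`).
#' @return Logical matrix with attribute `method` recording the binarization
#'   (and the threshold actually used).
#' @export
binarize_vasculature <- function(image, method = c("otsu", "fixed_threshold"),
                                 threshold = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), is.numeric(image))
  if (method == "otsu") {
    rng <- range(image)
    if (rng[1] == rng[2])
      stop("constant image: Otsu threshold is undefined")
    thr <- EBImage::otsu(EBImage::Image(image), range = rng)
  } else {
    if (is.null(threshold)) stop("fixed_threshold needs a threshold")
    thr <- threshold
  }
  mask <- image > thr
  attr(mask, "method") <- sprintf("%s(threshold=%.6g)", method, thr)
  mask
}

#' Vascular density within an ROI
#'
#' The ratio of vessel-positive pixels to total pixels inside an evaluation
#' ROI (canonically a 1 mm x 1 mm square), computed exactly at pixel
#' resolution.
#'
#' @param mask Logical vessel mask (from [binarize_vasculature()] or a
#'   ground-truth channel).
#' @param roi_mask Logical ROI mask of the same shape; must be non-empty.
#' @return An object of class `density_result`: `density` in \[0, 1\],
#'   `vessel_area_px`, `roi_area_px`, and the binarization `method`.
#' @export
#' @examples
#' m <- matrix(FALSE, 10, 10); m[1:3, ] <- TRUE
#' vessel_density(m, matrix(TRUE, 10, 10))$density
vessel_density <- function(mask, roi_mask) {
  if (!identical(dim(mask), dim(roi_mask)))
    stop("mask and roi_mask have different shapes")
  roi_area <- sum(roi_mask)
  if (roi_area == 0) stop("empty ROI")
  vessel_area <- sum(mask & roi_mask)
  structure(
    list(density = vessel_area / roi_area,
         vessel_area_px = as.integer(vessel_area),
         roi_area_px = as.integer(roi_area),
         method = attr(mask, "method") %||% "supplied mask"),
    class = "density_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("Vascular density %.4f (%d / %d px; %s)\n",
              x$density, x$vessel_area_px, x$roi_area_px, x$method))
  invisible(x)
}
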