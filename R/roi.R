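#' Pixel calibration with a bregma reference
#'
#' Maps bregma-relative stereotaxic coordinates (AP, ML, in mm) to image
#' pixels.  By convention AP decreases downward in the image (negative AP is
#' caudal) and ML increases rightward:
#' `row = bregma_row - AP / mm_per_pixel`, `col = bregma_col + ML /
#' mm_per_pixel` (1-based pixel centers at integer indices).
#'
#' @param mm_per_pixel Pixel size, mm (> 0).
#' @param bregma_pixel Bregma position `c(row, col)` in pixels.
#' @param magnification Optional label, `"1x"` (9 x 6.7 mm field of view) or
#'   `"2.5x"` (3.6 x 2.7 mm).
#' @return An object of class `calibration`.
#' @export
calibration <- function(mm_per_pixel, bregma_pixel,
                        magnification = NULL) {
  if (mm_per_pixel <= 0) stop("mm_per_pixel must be positive")
  if (!is.null(magnification) &&
      !magnification %in% names(.lsci_fov))
    stop("magnification must be one of: ",
         paste(names(.lsci_fov), collapse = ", "))
  structure(list(mm_per_pixel = mm_per_pixel,
                 bregma_pixel = as.numeric(bregma_pixel),
                 magnification = magnification),
            class = "calibration")
}

# fields of view (width x height, mm) of the two imaging magnifications
.lsci_fov <- list(`1x` = c(width = 9, height = 6.7),
                  `2.5x` = c(width = 3.6, height = 2.7))

#' Check that a calibration reproduces the imaging field of view
#'
#' Verifies that `mm_per_pixel * image dimensions` matches the nominal field
#' of view of the calibration's magnification (9 x 6.7 mm at 1x,
#' 3.6 x 2.7 mm at 2.5x) within one pixel.
#'
#' @param cal A [calibration()] with a magnification label.
#' @param image_shape `c(rows, cols)`.
#' @return `TRUE` invisibly, or an error.
#' @export
check_calibration_fov <- function(cal, image_shape) {
  stopifnot(inherits(cal, "calibration"))
  if (is.null(cal$magnification))
    stop("calibration has no magnification label to check against")
  fov <- .lsci_fov[[cal$magnification]]
  got <- c(width = image_shape[2], height = image_shape[1]) * cal$mm_per_pixel
  if (any(abs(got - fov) > cal$mm_per_pixel))
    stop(sprintf(
      "image (%.3f x %.3f mm) does not reproduce the %s field of view (%g x %g mm) within one pixel",
      got["width"], got["height"], cal$magnification, fov["width"], fov["height"]))
  invisible(TRUE)
}

.ap_ml_to_pixel <- function(cal, ap, ml) {
  c(row = cal$bregma_pixel[1] - ap / cal$mm_per_pixel,
    col = cal$bregma_pixel[2] + ml / cal$mm_per_pixel)
}

#' Circular and vessel regions of interest
#'
#' ROIs are defined in bregma-relative mm and rasterized against a
#' [calibration()].  `circular_roi()` is a disk (e.g. the 1-mm light spot or
#' the 2-mm evaluation circle); `vessel_roi()` is a polyline of given width
#' tracing a vessel (the full vessel width is averaged, not just the
#' centerline).
#'
#' @param center_ap_ml Circle center `c(AP, ML)`, mm.
#' @param diameter_mm Circle diameter, mm (> 0).
#' @param label ROI label.
#' @return An object of class `circular_roi` or `vessel_roi`.
#' @export
circular_roi <- function(center_ap_ml, diameter_mm, label = "roi") {
  if (diameter_mm <= 0) stop("diameter_mm must be positive")
  structure(list(center_ap_ml = center_ap_ml, diameter_mm = diameter_mm,
                 label = label), class = "circular_roi")
}

#' @rdname circular_roi
#' @param polyline_ap_ml Matrix (n x 2) of `(AP, ML)` points, mm; n >= 2.
#' @param width_mm Vessel width, mm (> 0).
#' @export
vessel_roi <- function(polyline_ap_ml, width_mm, label = "vessel") {
  polyline_ap_ml <- as.matrix(polyline_ap_ml)
  if (nrow(polyline_ap_ml) < 2) stop("vessel polyline needs at least 2 points")
  if (width_mm <= 0) stop("width_mm must be positive")
  structure(list(polyline_ap_ml = polyline_ap_ml, width_mm = width_mm,
                 label = label), class = "vessel_roi")
}

#' Rasterize an ROI to a pixel mask
#'
#' A pixel belongs to the mask iff its center lies inside the shape
#' (circle: distance to center at most the radius; vessel: distance to the
#' polyline at most half the width).  No anti-aliasing or area weighting is
#' applied; rasterization is deterministic.
#'
#' @param roi A [circular_roi()] or [vessel_roi()].
#' @param calibration A [calibration()].
#' @param image_shape `c(rows, cols)`.
#' @return Logical matrix; an error if the ROI misses the image entirely.
#' @export
roi_mask <- function(roi, calibration, image_shape) {
  stopifnot(inherits(calibration, "calibration"))
  rows <- matrix(seq_len(image_shape[1]), image_shape[1], image_shape[2])
  cols <- matrix(seq_len(image_shape[2]), image_shape[1], image_shape[2],
                 byrow = TRUE)
  mpp <- calibration$mm_per_pixel
  if (inherits(roi, "circular_roi")) {
    ctr <- .ap_ml_to_pixel(calibration, roi$center_ap_ml[1], roi$center_ap_ml[2])
    r_px <- roi$diameter_mm / 2 / mpp
    mask <- (rows - ctr["row"])^2 + (cols - ctr["col"])^2 <= r_px^2
  } else if (inherits(roi, "vessel_roi")) {
    pts <- t(apply(roi$polyline_ap_ml, 1, function(p)
      .ap_ml_to_pixel(calibration, p[1], p[2])))
    dmin <- matrix(Inf, image_shape[1], image_shape[2])
    for (i in seq_len(nrow(pts) - 1)) {
      d <- .dist_to_segment(cols, rows,
                            c(pts[i, 2], pts[i, 1]),
                            c(pts[i + 1, 2], pts[i + 1, 1]))
      dmin <- pmin(dmin, d)
    }
    mask <- dmin * mpp <= roi$width_mm / 2
  } else stop("roi must be a circular_roi or vessel_roi")
  if (!any(mask))
    stop("ROI '", roi$label, "' does not intersect the image")
  mask
}

#' Mean of a map over an ROI mask
#'
#' Arithmetic mean over the masked pixels, excluding invalid pixels
#' (propagated from the contrast/flow/rcbf maps).  Accepts a plain matrix or
#' any of the package's map objects.
#'
#' @param map Matrix, `flow_index_map`, `relative_cbf_map` or `contrast_map`.
#' @param mask Logical matrix from [roi_mask()].
#' @return Scalar mean; an error if no valid masked pixels remain.
#' @export
roi_mean <- function(map, mask) {
  vals <- .map_values(map)
  if (!identical(dim(vals$x), dim(mask)))
    stop("map and mask have different shapes")
  keep <- mask & vals$valid
  if (!any(keep))
    stop("all masked pixels are invalid; ROI mean is undefined")
  mean(vals$x[keep])
}

.map_values <- function(map) {
  if (inherits(map, "flow_index_map"))
    list(x = map$flow, valid = !map$invalid_mask)
  else if (inherits(map, "relative_cbf_map"))
    list(x = map$rcbf, valid = map$valid)
  else if (inherits(map, "contrast_map"))
    list(x = map$kt, valid = map$valid)
  else if (is.matrix(map))
    list(x = map, valid = !is.na(map))
  else stop("unsupported map type: ", paste(class(map), collapse = "/"))
}

#' ROI time course of relative CBF from a stack series
#'
#' The ROI statistic used for time courses: for each acquisition the flow
#' index is averaged over the ROI's valid pixels and then normalized by the
#' ROI-mean flow index of the baseline acquisition (mean-then-divide).
#' Normalizing ROI means, rather than averaging per-pixel ratios, cancels
#' the small-sample inflation that per-pixel inversion of a noisy contrast
#' estimate produces, so recovered multipliers are unbiased to well below
#' the acquisition noise.
#'
#' @param stacks Ordered list of [speckle_stack()]s.
#' @param roi A [circular_roi()] or [vessel_roi()].
#' @param calibration A [calibration()].
#' @param baseline_index Which acquisition is the pre-stroke baseline.
#' @param times Optional numeric time stamps (same length as `stacks`).
#' @param epsilon Passed to [flow_index()].
#' @return Data frame with columns `time`, `roi`, `mean` (relative CBF).
#' @export
roi_flow_course <- function(stacks, roi, calibration, baseline_index = 1,
                            times = NULL, epsilon = 1e-3) {
  if (is.null(times)) times <- seq_along(stacks) - 1
  stopifnot(length(times) == length(stacks))
  mask <- roi_mask(roi, calibration, dim(stacks[[1]]$frames)[1:2])
  flows <- vapply(stacks, function(s)
    roi_mean(flow_index(temporal_contrast(s), epsilon = epsilon), mask),
    numeric(1))
  data.frame(time = times, roi = roi$label, mean = flows / flows[baseline_index])
}

#' ROI means of relative-CBF maps over time, with replicate spread
#'
#' Summarizes an ordered series of per-pixel relative-CBF maps (from
#' [flow_time_series()]) over one ROI.  `series` is either a list of
#' `relative_cbf_map`s (one per time point) or a list of lists (replicate
#' maps per time point, e.g. several seeds or animals), in which case the
#' across-replicate standard deviation is reported.
#'
#' @param series List of `relative_cbf_map`s, or list of lists of them.
#' @param roi,calibration As in [roi_flow_course()].
#' @param times Optional time stamps.
#' @return Data frame with columns `time`, `roi`, `mean`, `sd`, `n`.
#' @export
time_course <- function(series, roi, calibration, times = NULL) {
  if (is.null(times)) times <- seq_along(series) - 1
  stopifnot(length(times) == length(series))
  first <- if (inherits(series[[1]], "relative_cbf_map")) series[[1]]
           else series[[1]][[1]]
  mask <- roi_mask(roi, calibration, dim(first$rcbf))
  rows <- lapply(seq_along(series), function(i) {
    el <- series[[i]]
    reps <- if (inherits(el, "relative_cbf_map")) list(el) else el
    m <- vapply(reps, roi_mean, numeric(1), mask = mask)
    data.frame(time = times[i], roi = roi$label, mean = mean(m),
               sd = if (length(m) > 1) sd(m) else NA_real_, n = length(m))
  })
  do.call(rbind, rows)
}

#' One-way analysis of variance for group comparisons
#'
#' Classical one-way ANOVA (between/within mean squares, F-distribution
#' tail) across two or more labeled groups, with significance coded as
#' `ns` (p > 0.05), `*` (p < 0.05), `**` (p < 0.01) or `***` (p < 0.001).
#' The degenerate case of zero variance everywhere (identical groups with no
#' within-group spread) has an undefined F and is reported as `F = 0`,
#' `p = 1`, `ns`, with `degenerate = TRUE`.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @return An object of class `group_comparison`: `f_statistic`, `p_value`,
#'   `significance_code`, `degenerate`, and the input `group_values`.
#' @export
#' @examples
#' anova_oneway(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs at least 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  value <- unlist(groups, use.names = FALSE)
  group <- factor(rep(names(groups), vapply(groups, length, integer(1))))
  ss_within <- sum(unlist(lapply(groups, function(g) sum((g - mean(g))^2))))
  degenerate <- FALSE
  if (ss_within == 0 && sum((tapply(value, group, mean) - mean(value))^2) == 0) {
    f <- 0; p <- 1; degenerate <- TRUE
  } else {
    tab <- anova(lm(value ~ group))
    f <- tab[["F value"]][1]
    p <- tab[["Pr(>F)"]][1]
  }
  structure(list(group_values = groups, f_statistic = f, p_value = p,
                 significance_code = .signif_code(p), degenerate = degenerate),
            class = "group_comparison")
}

.signif_code <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.4g (%s)%s\n",
              x$f_statistic, x$p_value, x$significance_code,
              if (x$degenerate) " [degenerate: no variance]" else ""))
  invisible(x)
}
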