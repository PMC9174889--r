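#' Segment the unstained (infarct) region of a neuron-stained section
#'
#' Areas of brain tissue that remain unstained in the neuron channel are
#' considered infarct.  A pixel is called unstained when its intensity falls
#' below `threshold_fraction` times the median intensity of the stained
#' tissue (the tissue-wide median, robust as long as the infarct covers less
#' than half the tissue).  Small speckle-noise components below
#' `min_area_mm2` are suppressed and only the largest connected component is
#' retained.
#'
#' @param neuron_image Numeric matrix (neuron-stain channel).
#' @param tissue_mask Logical matrix marking brain tissue; must be non-empty.
#' @param threshold_fraction Fraction of the stained-tissue median below
#'   which a pixel is unstained; in (0, 1).
#' @param pixel_size_mm Pixel size, mm (needed for the area floor).
#' @param min_area_mm2 Minimum component area retained, mm^2.
#' @return Logical infarct mask (possibly empty).
#' @export
segment_infarct <- function(neuron_image, tissue_mask, threshold_fraction = 0.5,
                            pixel_size_mm, min_area_mm2 = 0.01) {
  stopifnot(is.matrix(neuron_image))
  if (!any(tissue_mask)) stop("empty tissue mask")
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  med <- median(neuron_image[tissue_mask])
  cand <- tissue_mask & (neuron_image < threshold_fraction * med)
  if (!any(cand)) return(cand)
  lab <- EBImage::bwlabel(EBImage::Image(cand * 1))
  sizes <- tabulate(as.integer(lab)[as.integer(lab) > 0])
  keep <- which.max(sizes)
  mask <- matrix(as.integer(lab) == keep, nrow(cand), ncol(cand))
  if (sum(mask) * pixel_size_mm^2 < min_area_mm2)
    mask[] <- FALSE
  mask
}

#' Infarct volume from serial coronal sections
#'
#' Computes the infarct volume as the sum over sections of infarct area
#' times slice thickness, `V = sum(S_i) * h`, with per-slice areas measured
#' in mm^2 (`pixel count * mm_per_pixel^2`) and `h` the slice spacing
#' (default 100 um) converted to mm.  Masks are either supplied (e.g. the
#' phantom's ground truth) or produced by [segment_infarct()] on the
#' neuron channel.
#'
#' @param sections A [make_section_stack()] object.
#' @param masks Optional list of logical infarct masks, one per slice.
#' @param threshold_fraction Passed to [segment_infarct()] when segmenting.
#' @return An object of class `infarct_measurement`: `per_slice_area_mm2`,
#'   `slice_spacing_um`, `volume_mm3`, and the masks used.
#' @export
infarct_volume <- function(sections, masks = NULL, threshold_fraction = 0.5) {
  stopifnot(inherits(sections, "section_stack"))
  if (is.null(sections$pixel_size_mm)) stop("sections are missing calibration")
  if (is.null(masks)) {
    masks <- lapply(seq_along(sections$neuron_channel), function(i)
      segment_infarct(sections$neuron_channel[[i]], sections$tissue_masks[[i]],
                      threshold_fraction = threshold_fraction,
                      pixel_size_mm = sections$pixel_size_mm))
  }
  stopifnot(length(masks) == length(sections$neuron_channel))
  areas <- vapply(masks, sum, numeric(1)) * sections$pixel_size_mm^2
  h_mm <- sections$slice_spacing_um / 1000
  structure(
    list(per_slice_area_mm2 = areas, slice_spacing_um = sections$slice_spacing_um,
         volume_mm3 = sum(areas) * h_mm, masks = masks),
    class = "infarct_measurement")
}

#' @export
print.infarct_measurement <- function(x, ...) {
  cat(sprintf("Infarct volume %.3f mm^3 over %d slices (h = %g um)\n",
              x$volume_mm3, length(x$per_slice_area_mm2), x$slice_spacing_um))
  invisible(x)
}
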