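#' Synthetic coronal section stack with known infarct volume and density
#'
#' Generates an ordered stack of coronal section images (neuron-stain channel
#' plus binary vessel channel) for testing infarct volumetry and vascular
#' density with exact ground truth.
#'
#' The neuron channel shows uniformly stained tissue (an ellipse emulating a
#' coronal brain outline) with an unstained low-intensity infarct region per
#' slice.  Per-slice infarct areas follow a smooth axial profile (ellipsoidal
#' cap by default, or uniform) and are scaled so that the analytic total
#' `sum(area_i) * h` equals `target_volume_mm3` to within half a voxel
#' (one pixel-area times `h`): the total pixel budget is rounded once and
#' apportioned across slices by largest remainder, and each slice's region
#' is drawn as the budgeted number of tissue pixels nearest the infarct
#' center.
#'
#' The vessel channel is a binary mask whose vascular-area fraction inside
#' the two 1 mm x 1 mm evaluation ROIs (one per hemisphere) equals the
#' requested densities exactly at pixel resolution (counts are rounded once;
#' the realized exact fractions are stored in `truth_densities`).
#'
#' @param target_volume_mm3 Ground-truth infarct volume (>= 0).
#' @param density_truths Named vascular-area fractions `c(ipsi = , contra = )`
#'   in \[0, 1\].
#' @param n_slices Number of coronal sections.
#' @param slice_spacing_um Slice thickness/spacing h, um.
#' @param pixel_size_mm Pixel size, mm.
#' @param width_px,height_px Section image size (default 8 x 6 mm at 0.02
#'   mm/px).
#' @param axial_profile `"ellipsoid"` (cap) or `"uniform"` per-slice areas.
#' @param stain_level,infarct_level Neuron-channel intensities of stained
#'   tissue and infarct.
#' @param noise_sd Additive Gaussian noise on the neuron channel (default
#'   noiseless).
#' @param seed Integer seed (vessel pixel placement, noise).
#'
#' @return An object of class `section_stack`: lists `neuron_channel`,
#'   `vessel_channel`, `tissue_masks`, `truth_infarct_masks`, the two
#'   `density_rois` masks, `truth_densities`, `truth_volume_mm3`,
#'   `slice_spacing_um`, `pixel_size_mm`.
#' @export
#' @examples
#' st <- make_section_stack(1.5, n_slices = 6, width_px = 120, height_px = 90,
#'                          pixel_size_mm = 0.05, seed = 1)
#' st$truth_volume_mm3
make_section_stack <- function(target_volume_mm3,
                               density_truths = c(ipsi = 0.12, contra = 0.10),
                               n_slices = 30, slice_spacing_um = 100,
                               pixel_size_mm = 0.02,
                               width_px = 400, height_px = 300,
                               axial_profile = c("ellipsoid", "uniform"),
                               stain_level = 1, infarct_level = 0.05,
                               noise_sd = 0, seed = 1) {
  axial_profile <- match.arg(axial_profile)
  if (target_volume_mm3 < 0) stop("target_volume_mm3 must be >= 0")
  if (slice_spacing_um <= 0) stop("slice_spacing_um must be positive")
  if (any(density_truths < 0 | density_truths > 1))
    stop("density_truths must lie in [0, 1]")
  set.seed(seed)

  h_mm <- slice_spacing_um / 1000
  q <- pixel_size_mm^2 * h_mm  # voxel quantum, mm^3

  # coronal tissue outline: centered ellipse
  rows <- matrix(seq_len(height_px), height_px, width_px)
  cols <- matrix(seq_len(width_px), height_px, width_px, byrow = TRUE)
  cy <- (height_px + 1) / 2; cx <- (width_px + 1) / 2
  tissue <- ((cols - cx) / (0.48 * width_px))^2 +
            ((rows - cy) / (0.47 * height_px))^2 <= 1

  # infarct centered in the ipsilateral (right) hemisphere
  icx <- cx + width_px / 4; icy <- cy
  d2 <- (rows - icy)^2 + (cols - icx)^2
  ord <- order(d2[tissue])          # tissue pixels by distance to the center
  tissue_idx <- which(tissue)[ord]

  total_px <- round(target_volume_mm3 / q)
  w <- if (axial_profile == "uniform") rep(1, n_slices) else {
    i <- seq_len(n_slices)
    pmax(0, 1 - ((i - (n_slices + 1) / 2) / ((n_slices + 1) / 2))^2)
  }
  counts <- .apportion(total_px, w)
  if (any(counts > length(tissue_idx)))
    stop("target volume unachievable: a slice would need ",
         max(counts), " pixels but the tissue has only ", length(tissue_idx))

  # density ROIs: 1 mm x 1 mm squares centered in each hemisphere
  roi_side <- round(1 / pixel_size_mm)
  mk_roi <- function(cxp) {
    r0 <- round(cy - roi_side / 2); c0 <- round(cxp - roi_side / 2)
    m <- matrix(FALSE, height_px, width_px)
    m[r0 + seq_len(roi_side) - 1, c0 + seq_len(roi_side) - 1] <- TRUE
    m
  }
  rois <- list(ipsi = mk_roi(cx + width_px / 4),
               contra = mk_roi(cx - width_px / 4))

  neuron <- vessel <- infarct <- vector("list", n_slices)
  for (s in seq_len(n_slices)) {
    im <- matrix(FALSE, height_px, width_px)
    if (counts[s] > 0) im[tissue_idx[seq_len(counts[s])]] <- TRUE
    infarct[[s]] <- im
    img <- matrix(0, height_px, width_px)
    img[tissue] <- stain_level
    img[im] <- infarct_level
    if (noise_sd > 0)
      img <- pmax(img + rnorm(length(img), sd = noise_sd), 0)
    neuron[[s]] <- img
    vm <- matrix(FALSE, height_px, width_px)
    for (side in names(rois)) {
      idx <- which(rois[[side]])
      k <- round(density_truths[[side]] * length(idx))
      if (k > 0) vm[sample(idx, k)] <- TRUE
    }
    vessel[[s]] <- vm
  }

  realized <- vapply(names(rois), function(side)
    round(density_truths[[side]] * sum(rois[[side]])) / sum(rois[[side]]),
    numeric(1))

  structure(
    list(neuron_channel = neuron, vessel_channel = vessel,
         tissue_masks = rep(list(tissue), n_slices),
         truth_infarct_masks = infarct, density_rois = rois,
         truth_densities = realized,
         truth_volume_mm3 = total_px * q,
         slice_spacing_um = slice_spacing_um, pixel_size_mm = pixel_size_mm),
    class = "section_stack")
}

# integer apportionment of `total` by weights `w` (largest remainder):
# sum of the result is exactly `total`.
.apportion <- function(total, w) {
  if (total == 0) return(rep(0L, length(w)))
  if (sum(w) == 0) stop("all axial-profile weights are zero")
  exact <- total * w / sum(w)
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    up <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[up] <- base[up] + 1
  }
  as.integer(base)
}

#' @export
print.section_stack <- function(x, ...) {
  cat(sprintf("<section_stack> %d slices %d x %d px @ %g mm/px, h = %g um, truth volume %.3f mm^3\n",
              length(x$neuron_channel), nrow(x$neuron_channel[[1]]),
              ncol(x$neuron_channel[[1]]), x$pixel_size_mm,
              x$slice_spacing_um, x$truth_volume_mm3))
  invisible(x)
}
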