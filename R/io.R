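#' Write / read a speckle stack as multi-page TIFF with a JSON sidecar
#'
#' `write_stack()` stores the frames as a 16-bit multi-page TIFF (one page
#' per frame; intensities divided by a single scale factor recorded in the
#' sidecar) and an accompanying `<path>.json` sidecar holding the
#' acquisition metadata, seed, intensity scale and a ground-truth summary.
#' `read_stack()` reverses this; writing a stack that was just read
#' reproduces the TIFF bit for bit (quantization to 16 bits happens only at
#' the first export).
#'
#' @param stack A [speckle_stack()].
#' @param path Output TIFF path.
#' @return `write_stack()` the path, invisibly; `read_stack()` a
#'   [speckle_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "speckle_stack"))
  scale <- max(stack$frames)
  if (scale <= 0) scale <- 1
  # quantize to the 16-bit grid ourselves (round to nearest): the values
  # handed to the TIFF writer are exact multiples of 1/65535, so a stack that
  # was read back re-exports bit-identically
  pages <- lapply(seq_len(dim(stack$frames)[3]), function(k)
    round(stack$frames[, , k] / scale * 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  cfg <- stack$config
  meta <- list(
    n_frames = cfg$n_frames, height = dim(stack$frames)[1],
    width = dim(stack$frames)[2], exposure_ms = cfg$exposure_ms,
    frame_interval_ms = cfg$frame_interval_ms,
    pixel_size_mm = cfg$pixel_size_mm, bit_depth = cfg$bit_depth,
    noise_model = cfg$noise_model, noise_sd = cfg$noise_sd, gain = cfg$gain,
    seed = cfg$seed, intensity_scale = scale,
    truth_summary = if (!is.null(stack$truth)) list(
      pixel_size_mm = stack$truth$pixel_size_mm,
      calibration_a = stack$truth$calibration_a,
      tau_c_range_ms = range(stack$truth$tau_c[is.finite(stack$truth$tau_c)]),
      labels = as.list(table(stack$truth$label))))
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

.sidecar_path <- function(path) paste0(path, ".json")

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such stack: ", path)
  side <- .sidecar_path(path)
  if (!file.exists(side))
    stop("missing sidecar ", side, "; stacks written by write_stack() carry ",
         "a JSON sidecar with acquisition metadata -- regenerate the stack ",
         "or restore the sidecar")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$n_frames)
    stop("page count (", length(pages), ") does not match sidecar n_frames (",
         meta$n_frames, ")")
  frames <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  frames <- frames * meta$intensity_scale
  cfg <- acquisition_config(
    n_frames = meta$n_frames, exposure_ms = meta$exposure_ms,
    frame_interval_ms = meta$frame_interval_ms,
    pixel_size_mm = meta$pixel_size_mm, bit_depth = meta$bit_depth,
    noise_model = meta$noise_model, noise_sd = meta$noise_sd,
    gain = meta$gain, seed = meta$seed)
  speckle_stack(frames, cfg)
}

#' Write / read a derived floating-point map (contrast, flow, rCBF)
#'
#' Derived maps are carried in floating point and quantized only at export:
#' a two-page 32-bit TIFF (scaled values, validity mask) plus a JSON sidecar
#' with the scale.  Invalid pixels round-trip as `NA`.
#'
#' @param map Numeric matrix, possibly with `NA` (invalid pixels).
#' @param path Output TIFF path.
#' @return `write_map()` the path, invisibly; `read_map()` a matrix.
#' @export
write_map <- function(map, path) {
  stopifnot(is.matrix(map))
  valid <- !is.na(map)
  offset <- min(map[valid])
  scale <- max(map[valid]) - offset
  if (scale <= 0) scale <- 1
  vals <- matrix(0, nrow(map), ncol(map))
  vals[valid] <- (map[valid] - offset) / scale
  tiff::writeTIFF(list(vals, valid * 1), path, bits.per.sample = 32L)
  jsonlite::write_json(list(intensity_scale = scale, intensity_offset = offset),
                       .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  out <- pages[[1]] * meta$intensity_scale + meta$intensity_offset
  out[pages[[2]] < 0.5] <- NA_real_
  out
}

#' Read an ROI/calibration configuration file
#'
#' Accepts YAML or JSON with a `calibration` block (`mm_per_pixel`,
#' `bregma_pixel`, optional `magnification`) and a `rois` list; each ROI has
#' `type` (`"circle"` or `"vessel"`), a `label`, and either `center_ap_ml` +
#' `diameter_mm` or `points_ap_ml` + `width_mm` (all mm, bregma-relative).
#'
#' @param path Config file path (`.yaml`/`.yml`/`.json`).
#' @return List with elements `calibration` ([calibration()]) and `rois`
#'   (list of ROI objects).
#' @export
read_roi_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path)
  else yaml::read_yaml(path)
  cal <- calibration(cfg$calibration$mm_per_pixel,
                     unlist(cfg$calibration$bregma_pixel),
                     cfg$calibration$magnification)
  rois <- lapply(cfg$rois, function(r) {
    switch(r$type,
      circle = circular_roi(unlist(r$center_ap_ml), r$diameter_mm,
                            r$label %||% "roi"),
      vessel = vessel_roi(do.call(rbind, lapply(r$points_ap_ml, unlist)),
                          r$width_mm, r$label %||% "vessel"),
      stop("unknown roi type: ", r$type))
  })
  list(calibration = cal, rois = rois)
}
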