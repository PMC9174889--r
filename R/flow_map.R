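#' Ground-truth flow map for the speckle phantom
#'
#' Rasterizes a simple cortical-vasculature phantom: straight vessel tubes of
#' given width and relative flow speed over a uniformly perfused parenchyma
#' background.  Each pixel carries a relative flow speed (arbitrary units), a
#' compartment label, and a speckle decorrelation time
#' `tau_c = calibration_a / speed`.
#'
#' Speeds are relative: only ratios of flow are meaningful downstream, so the
#' calibration constant `a` in `tau_c = a / v` is arbitrary and defaults to
#' 1 ms per speed unit.  Pixels with zero speed ("no-flow" tissue) are given
#' slow residual dynamics (`tau_noflow_ms`, default 200 ms) rather than a
#' frozen field, because a truly static field has zero temporal contrast and
#' a divergent flow index; a genuinely frozen field (`tau_c = Inf`) is
#' available through `static_mask` for artifact testing only.
#'
#' Geometry is in mm with the origin at the image top-left corner, x along
#' columns and y along rows; pixel (i, j) has its center at
#' `((j - 0.5) * pixel_size_mm, (i - 0.5) * pixel_size_mm)`.
#'
#' @param width_px,height_px Image size in pixels.
#' @param pixel_size_mm Pixel size, mm.
#' @param vessel_spec List of vessel segments; each element is a list with
#'   `from = c(x, y)` and `to = c(x, y)` endpoints in mm, `width_mm`,
#'   `speed` (> 0, relative units) and `label` (`"large_vessel"` or
#'   `"small_vessel"`).  Later entries overwrite earlier ones where they
#'   overlap.
#' @param baseline_speed Named numeric; must contain `parenchyma`, the
#'   background speed (> 0).
#' @param calibration_a Calibration constant in `tau_c = a / v`, ms times
#'   speed unit.
#' @param tau_noflow_ms Decorrelation time assigned to zero-speed tissue, ms.
#' @param static_mask Optional logical matrix marking frozen-field pixels.
#' @param seed Optional integer seed (the rasterizer itself is deterministic;
#'   the seed only matters for stochastic extensions and is recorded).
#'
#' @return An object of class `flow_map`: list with matrices `speed`,
#'   `tau_c` (ms), character matrix `label`, plus `pixel_size_mm`,
#'   `calibration_a` and `tau_noflow_ms`.
#' @export
#' @examples
#' fm <- make_flow_map(64, 64, 0.05,
#'   vessel_spec = list(list(from = c(0, 1.6), to = c(3.2, 1.6),
#'                           width_mm = 0.1, speed = 4, label = "large_vessel")))
#' table(fm$label)
make_flow_map <- function(width_px, height_px, pixel_size_mm,
                          vessel_spec = list(),
                          baseline_speed = c(parenchyma = 1),
                          calibration_a = 1, tau_noflow_ms = 200,
                          static_mask = NULL, seed = NULL) {
  if (pixel_size_mm <= 0) stop("pixel_size_mm must be positive")
  v_par <- unname(baseline_speed[["parenchyma"]])
  if (!is.finite(v_par) || v_par <= 0)
    stop("parenchyma baseline speed must be positive (perfused compartment)")
  if (!is.null(seed)) set.seed(seed)

  speed <- matrix(v_par, height_px, width_px)
  label <- matrix("parenchyma", height_px, width_px)

  # pixel-center coordinate grids in mm
  xc <- ((seq_len(width_px)) - 0.5) * pixel_size_mm
  yc <- ((seq_len(height_px)) - 0.5) * pixel_size_mm
  X <- matrix(xc, height_px, width_px, byrow = TRUE)
  Y <- matrix(yc, height_px, width_px)

  for (v in vessel_spec) {
    if (is.null(v$label)) v$label <- "large_vessel"
    if (!v$label %in% c("large_vessel", "small_vessel"))
      stop("vessel label must be 'large_vessel' or 'small_vessel', got '",
           v$label, "'")
    if (v$width_mm <= 0) stop("vessel width must be positive")
    if (v$width_mm > min(width_px, height_px) * pixel_size_mm)
      stop("vessel width ", v$width_mm, " mm exceeds the image extent")
    if (!is.finite(v$speed) || v$speed <= 0)
      stop("vessel '", v$label, "' has non-positive speed; perfused ",
           "compartments need speed > 0")
    d <- .dist_to_segment(X, Y, v$from, v$to)
    inside <- d <= v$width_mm / 2
    speed[inside] <- v$speed
    label[inside] <- v$label
  }

  if (!is.null(static_mask)) {
    stopifnot(identical(dim(static_mask), dim(speed)))
    speed[static_mask] <- 0
    label[static_mask] <- "static"
  }

  structure(
    list(speed = speed,
         tau_c = .tau_from_speed(speed, label, calibration_a, tau_noflow_ms),
         label = label, pixel_size_mm = pixel_size_mm,
         calibration_a = calibration_a, tau_noflow_ms = tau_noflow_ms),
    class = "flow_map")
}

# tau_c = a / v for perfused pixels; slow residual dynamics where v = 0;
# frozen field (Inf) only for the explicit "static" label.
.tau_from_speed <- function(speed, label, calibration_a, tau_noflow_ms) {
  tau <- matrix(tau_noflow_ms, nrow(speed), ncol(speed))
  perfused <- speed > 0
  tau[perfused] <- calibration_a / speed[perfused]
  tau[label == "static"] <- Inf
  tau
}

# Euclidean distance from points (X, Y) to the segment from -> to (all mm).
.dist_to_segment <- function(X, Y, from, to) {
  dx <- to[1] - from[1]; dy <- to[2] - from[2]
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((X - from[1])^2 + (Y - from[2])^2))
  t <- ((X - from[1]) * dx + (Y - from[2]) * dy) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((X - (from[1] + t * dx))^2 + (Y - (from[2] + t * dy))^2)
}

#' @export
print.flow_map <- function(x, ...) {
  cat(sprintf("<flow_map> %d x %d px @ %g mm/px; tau_c %s ms; labels: %s\n",
              nrow(x$speed), ncol(x$speed), x$pixel_size_mm,
              paste(signif(range(x$tau_c[is.finite(x$tau_c)]), 3),
                    collapse = "-"),
              paste(names(table(x$label)), collapse = ", ")))
  invisible(x)
}
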