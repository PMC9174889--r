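#' Photothrombotic stroke scenarios as compartment flow multipliers
#'
#' A stroke scenario represents the effect of photothrombosis purely as
#' time-dependent multipliers on baseline flow speed, per compartment
#' (irradiated core parenchyma, large and small vessels inside the irradiated
#' area, and everything outside it).  Multipliers are interpolated piecewise-
#' linearly between the stated time points and all equal 1 at time 0.
#'
#' `stroke_scenario()` builds the 14-day dose-response courses: the light
#' dose (irradiation time in minutes; 0, 1, 2 or 5) selects a built-in
#' timeline whose node values are the published group means of relative
#' cerebral blood flow in the 2-mm evaluation circle on days 1, 4, 7 and 14.
#' The dose-0 (light-only control) course stays within 10% of baseline at
#' all times.  For these day-scale courses the depression is applied
#' uniformly inside the 2-mm evaluation circle (`core_region =
#' "eval_circle"`).
#'
#' `stroke_scenario_6h()` builds the acute 6-hour course after a 2-min
#' exposure, with separate compartments: irradiated core falling to 50% at
#' 2 h and about 30% at 6 h; large vessels in the area to ~50% by 3 h;
#' small vessels to 50% at 1.5 h and ~20% at 6 h; and a slow, small decrease
#' (to ~0.9) outside.  The core multiplier is applied inside the 1-mm light
#' spot.
#'
#' @param dose_minutes Irradiation time: 0 (light-only control), 1, 2 or 5.
#' @param spot_center_ap_ml Spot center, bregma-relative `c(AP, ML)` mm
#'   (AP negative is caudal).
#' @param spot_diameter_mm Light spot diameter, mm.
#' @param eval_circle_diameter_mm Evaluation circle diameter, mm.
#'
#' @return An object of class `stroke_scenario`: timeline data frame
#'   (`time`, `core`, `large_vessel`, `small_vessel`, `outside`), time unit,
#'   spot geometry, and which region the core multiplier fills.
#' @export
#' @examples
#' sc <- stroke_scenario(5)
#' scenario_multipliers(sc, t = 14)
stroke_scenario <- function(dose_minutes,
                            spot_center_ap_ml = c(-2, 2),
                            spot_diameter_mm = 1,
                            eval_circle_diameter_mm = 2) {
  courses <- list(
    `0` = c(1, 1.03, 1.00, 0.97, 0.94),
    `1` = c(1, 0.39, 0.84, 1.07, 0.94),
    `2` = c(1, 0.27, 0.69, 0.84, 1.00),
    `5` = c(1, 0.00, 0.00, 0.38, 0.64))
  key <- as.character(dose_minutes)
  if (!key %in% names(courses))
    stop("dose_minutes must be one of 0, 1, 2, 5")
  core <- courses[[key]]
  timeline <- data.frame(time = c(0, 1, 4, 7, 14),
                         core = core, large_vessel = core,
                         small_vessel = core, outside = 1)
  .new_scenario(dose_minutes, timeline, "days", spot_center_ap_ml,
                spot_diameter_mm, eval_circle_diameter_mm,
                core_region = "eval_circle")
}

#' @rdname stroke_scenario
#' @export
stroke_scenario_6h <- function(spot_center_ap_ml = c(-2, 2),
                               spot_diameter_mm = 1,
                               eval_circle_diameter_mm = 2) {
  timeline <- data.frame(
    time         = c(0,    1.5,  2,    3,    6),
    core         = c(1,    0.62, 0.50, 0.42, 0.30),
    large_vessel = c(1,    0.75, 0.67, 0.50, 0.50),
    small_vessel = c(1,    0.50, 0.43, 0.33, 0.20),
    outside      = c(1,    0.97, 0.96, 0.95, 0.90))
  .new_scenario(2, timeline, "hours", spot_center_ap_ml,
                spot_diameter_mm, eval_circle_diameter_mm,
                core_region = "spot")
}

.new_scenario <- function(dose_minutes, timeline, time_unit, spot_center_ap_ml,
                          spot_diameter_mm, eval_circle_diameter_mm,
                          core_region) {
  comp <- setdiff(names(timeline), "time")
  at0 <- timeline[timeline$time == 0, comp, drop = FALSE]
  if (nrow(at0) != 1 || any(abs(unlist(at0) - 1) > 1e-12))
    stop("all compartment multipliers must equal 1 at time 0")
  if (any(unlist(timeline[comp]) < 0))
    stop("flow multipliers must be non-negative")
  if (dose_minutes == 0 &&
      any(unlist(timeline[comp]) < 0.9 | unlist(timeline[comp]) > 1.1))
    stop("dose-0 (light-only) multipliers must stay within [0.9, 1.1]")
  structure(
    list(dose_minutes = dose_minutes, timeline = timeline,
         time_unit = time_unit, spot_center_ap_ml = spot_center_ap_ml,
         spot_diameter_mm = spot_diameter_mm,
         eval_circle_diameter_mm = eval_circle_diameter_mm,
         core_region = core_region),
    class = "stroke_scenario")
}

#' Interpolated compartment multipliers at a time point
#'
#' @param scenario A [stroke_scenario()].
#' @param t Time, in the scenario's time unit; must lie inside the timeline.
#' @return Named numeric vector of multipliers.
#' @export
scenario_multipliers <- function(scenario, t) {
  tl <- scenario$timeline
  if (t < min(tl$time) || t > max(tl$time))
    stop("t = ", t, " ", scenario$time_unit, " is outside the scenario ",
         "timeline [", min(tl$time), ", ", max(tl$time), "]")
  comp <- setdiff(names(tl), "time")
  vapply(comp, function(k) approx(tl$time, tl[[k]], xout = t)$y, numeric(1))
}

#' Apply a stroke scenario to a flow map
#'
#' Multiplies per-compartment flow speeds by the scenario's interpolated
#' multipliers at time `t` and recomputes decorrelation times.  The core
#' multiplier applies to parenchyma inside the scenario's affected circle
#' (light spot or evaluation circle, per the scenario); vessel multipliers
#' apply to vessels inside that circle; everything outside it takes the
#' `outside` multiplier.  Frozen (`static`) pixels are untouched.
#'
#' @param flow_map A [make_flow_map()] baseline map.
#' @param scenario A [stroke_scenario()].
#' @param t Time in the scenario's time unit.
#' @param calibration A [calibration()] mapping bregma-relative mm to pixels;
#'   defaults to bregma at the image center with the flow map's pixel size.
#'
#' @return A new `flow_map`; at `t = 0` it equals the input.
#' @export
apply_scenario <- function(flow_map, scenario, t, calibration = NULL) {
  stopifnot(inherits(flow_map, "flow_map"), inherits(scenario, "stroke_scenario"))
  if (is.null(calibration))
    calibration <- calibration(flow_map$pixel_size_mm,
                               bregma_pixel = (dim(flow_map$speed) + 1) / 2)
  mult <- scenario_multipliers(scenario, t)

  known <- c("parenchyma", "large_vessel", "small_vessel", "static")
  bad <- setdiff(unique(as.vector(flow_map$label)), known)
  if (length(bad) > 0)
    stop("unknown compartment label(s): ", paste(bad, collapse = ", "))

  region_diam <- if (scenario$core_region == "spot")
    scenario$spot_diameter_mm else scenario$eval_circle_diameter_mm
  region <- roi_mask(circular_roi(scenario$spot_center_ap_ml, region_diam),
                     calibration, dim(flow_map$speed))

  m <- matrix(mult[["outside"]], nrow(flow_map$speed), ncol(flow_map$speed))
  lab <- flow_map$label
  m[region & lab == "parenchyma"]   <- mult[["core"]]
  m[region & lab == "large_vessel"] <- mult[["large_vessel"]]
  m[region & lab == "small_vessel"] <- mult[["small_vessel"]]
  m[lab == "static"] <- 1

  out <- flow_map
  out$speed <- flow_map$speed * m
  out$tau_c <- .tau_from_speed(out$speed, lab, flow_map$calibration_a,
                               flow_map$tau_noflow_ms)
  out
}
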