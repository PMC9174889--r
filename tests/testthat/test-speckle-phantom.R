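test_that("flow maps rasterize vessels with tau_c = a / v", {
  fm <- make_flow_map(32, 32, 0.05, baseline_speed = c(parenchyma = 1),
                      calibration_a = 1)
  expect_true(all(fm$tau_c == 1))
  expect_true(all(fm$label == "parenchyma"))

  fm2 <- make_flow_map(
    40, 40, 0.05,
    vessel_spec = list(list(from = c(0, 1), to = c(2, 1), width_mm = 0.1,
                            speed = 4, label = "large_vessel")),
    baseline_speed = c(parenchyma = 1), calibration_a = 2)
  vessel <- fm2$label == "large_vessel"
  expect_gt(sum(vessel), 0)
  expect_true(all(fm2$tau_c[vessel] == 0.5))
  expect_true(all(fm2$tau_c[!vessel] == 2))
  # labels partition the image
  expect_true(all(fm2$label %in% c("parenchyma", "large_vessel")))
})

test_that("flow map construction rejects impossible specs", {
  expect_error(make_flow_map(10, 10, 0.05, vessel_spec = list(
    list(from = c(0, 0.25), to = c(0.5, 0.25), width_mm = 5, speed = 1,
         label = "large_vessel"))), "exceeds")
  expect_error(make_flow_map(10, 10, 0.05, vessel_spec = list(
    list(from = c(0, 0.25), to = c(0.5, 0.25), width_mm = 0.1, speed = 0,
         label = "small_vessel"))), "non-positive")
  expect_error(make_flow_map(10, 10, 0.05,
                             baseline_speed = c(parenchyma = -1)), "positive")
})

test_that("zero-speed tissue gets slow residual dynamics, static gets Inf", {
  sm <- matrix(FALSE, 8, 8); sm[1:2, ] <- TRUE
  fm <- make_flow_map(8, 8, 0.05, static_mask = sm)
  expect_true(all(is.infinite(fm$tau_c[sm])))
  expect_true(all(fm$tau_c[!sm] == 1))
})

test_that("simulated ensembles reproduce the integrated-speckle closed form", {
  # mid-regime check at x = 10 on a small ensemble; the full x ladder is
  # exercised in the acceptance suite
  tau <- 2; T_ms <- 20
  fm <- uniform_map(4, speed = 1, a = tau)
  st <- simulate_speckle_stack(fm, quick_config(7, n_frames = 1500))
  kt <- temporal_contrast(st)$kt
  expect_lt(abs(mean(kt) / sqrt(K2_integrated(T_ms / tau)) - 1), 0.05)
})

test_that("quasi-static fields give near-zero temporal contrast", {
  fm <- uniform_map(6, speed = 1e-9)  # tau_c = 1e12 ms >> acquisition span
  st <- simulate_speckle_stack(fm, quick_config(3))
  expect_lt(max(temporal_contrast(st)$kt), 0.02)
})

test_that("single-sub-step frames follow the exponential intensity law", {
  # instantaneous sampling of a fully developed speckle field: negative
  # exponential intensity, so mean ~ sd and median ~ log(2) * mean
  fm <- uniform_map(4, speed = 0.2)  # tau_c = 5 ms
  cfg <- acquisition_config(n_frames = 2000, exposure_ms = 0.1,
                            frame_interval_ms = 25, pixel_size_mm = 0.05,
                            seed = 11)
  st <- simulate_speckle_stack(fm, cfg, substep_ms = 0.1)
  I <- as.vector(st$frames)
  expect_lt(abs(sd(I) / mean(I) - 1), 0.05)
  expect_lt(abs(median(I) / (log(2) * mean(I)) - 1), 0.05)
})

test_that("faster flow strictly lowers contrast and raises the flow index", {
  speeds <- c(0.5, 1, 2, 4, 8)
  kt <- vapply(seq_along(speeds), function(i) {
    st <- simulate_speckle_stack(uniform_map(12, speed = speeds[i]),
                                 quick_config(20 + i))
    mean(temporal_contrast(st)$kt)
  }, numeric(1))
  expect_true(all(diff(kt) < 0))
  expect_true(all(diff(1 / kt^2) > 0))
})

test_that("simulation is reproducible bit-for-bit under a seed", {
  fm <- uniform_map(8)
  a <- simulate_speckle_stack(fm, quick_config(99, n_frames = 10))
  b <- simulate_speckle_stack(fm, quick_config(99, n_frames = 10))
  expect_identical(a$frames, b$frames)
  c <- simulate_speckle_stack(fm, quick_config(100, n_frames = 10))
  expect_false(identical(a$frames, c$frames))
})

test_that("undersampled sub-steps are refused and noise keeps frames valid", {
  fm <- uniform_map(6, speed = 2)  # tau_c = 0.5 ms
  expect_error(simulate_speckle_stack(fm, quick_config(1), substep_ms = 1),
               "undersampled")
  for (nm in c("gaussian", "poisson")) {
    st <- simulate_speckle_stack(
      uniform_map(6), quick_config(5, n_frames = 8, noise_model = nm))
    expect_true(all(st$frames >= 0))
  }
})

test_that("scenario multipliers are 1 at t = 0 and interpolate linearly", {
  sc <- stroke_scenario(5)
  expect_equal(unname(scenario_multipliers(sc, 0)), rep(1, 4))
  # midway between day 7 (0.38) and day 14 (0.64)
  expect_equal(unname(scenario_multipliers(sc, 10.5)[["core"]]), 0.51)
  expect_error(scenario_multipliers(sc, 15), "outside")
  expect_error(scenario_multipliers(sc, -1), "outside")
})

test_that("applying a scenario at t = 0 is the identity", {
  fm <- uniform_map(32)
  cal <- calibration(0.05, c(16, 16))
  sc <- stroke_scenario_6h(spot_center_ap_ml = c(0, 0))
  fm0 <- apply_scenario(fm, sc, 0, cal)
  expect_equal(fm0$speed, fm$speed)
  expect_equal(fm0$tau_c, fm$tau_c)
})

test_that("scenarios scale speeds inside the affected circle only", {
  fm <- uniform_map(32)
  cal <- calibration(0.05, c(16, 16))
  sc <- stroke_scenario_6h(spot_center_ap_ml = c(0, 0))
  fm6 <- apply_scenario(fm, sc, 6, cal)
  spot <- roi_mask(circular_roi(c(0, 0), 1), cal, c(32, 32))
  expect_true(all(fm6$speed[spot] == 0.3))
  expect_true(all(fm6$speed[!spot] == 0.9))  # slow, small outside decrease
})

test_that("light-only control scenario stays within 10% of baseline", {
  sc <- stroke_scenario(0)
  for (t in seq(0, 14, by = 0.5)) {
    m <- scenario_multipliers(sc, t)
    expect_true(all(m >= 0.9 & m <= 1.1))
  }
})

test_that("section stacks hit the target volume to within one voxel", {
  # uniform axial profile: 30 slices x 5 mm^2 at h = 100 um -> 15 mm^3
  st <- make_section_stack(15, n_slices = 30, slice_spacing_um = 100,
                           pixel_size_mm = 0.02, axial_profile = "uniform",
                           seed = 2)
  areas <- vapply(st$truth_infarct_masks, sum, numeric(1)) * 0.02^2
  expect_equal(unique(areas), 5)
  expect_equal(st$truth_volume_mm3, 15)
  expect_equal(infarct_volume(st, masks = st$truth_infarct_masks)$volume_mm3, 15)

  st2 <- make_section_stack(7.06, n_slices = 25, seed = 3)
  areas2 <- vapply(st2$truth_infarct_masks, sum, numeric(1)) * st2$pixel_size_mm^2
  q <- st2$pixel_size_mm^2 * st2$slice_spacing_um / 1000
  expect_equal(st2$truth_volume_mm3, sum(areas2) * 0.1)
  expect_lte(abs(st2$truth_volume_mm3 - 7.06), q)
})

test_that("zero target volume gives unblemished sections", {
  st <- make_section_stack(0, n_slices = 4, width_px = 120, height_px = 90,
                           pixel_size_mm = 0.05, seed = 1)
  expect_true(all(vapply(st$truth_infarct_masks, sum, numeric(1)) == 0))
  vol <- infarct_volume(st)
  expect_equal(vol$volume_mm3, 0)
})

test_that("section stacks refuse impossible targets", {
  expect_error(make_section_stack(100, n_slices = 2, width_px = 60,
                                  height_px = 60, pixel_size_mm = 0.02),
               "unachievable")
  expect_error(make_section_stack(1, density_truths = c(ipsi = 1.2, contra = 0.1)),
               "\\[0, 1\\]")
})

test_that("beam scenes carry analytic half-radius and power truths", {
  th <- make_beam_scene("top_hat", list(radius_mm = 0.5))
  expect_equal(th$truth_half_radius_mm, 0.5)
  g <- make_beam_scene("gaussian", list(sigma_mm = 0.4926))
  expect_equal(g$truth_half_radius_mm, 0.4926 * sqrt(2 * log(2)))
  expect_equal(sum(g$image), 1)
  gh <- make_beam_scene("gaussian_halo",
                        list(sigma_mm = 0.2, halo_sigma_mm = 0.8,
                             halo_frac = 0.2), total_power = 5)
  expect_equal(sum(gh$image), 5)
  expect_gt(gh$truth_half_radius_mm, 0.2 * sqrt(2 * log(2)))
  expect_error(make_beam_scene("top_hat", list(radius_mm = 50)), "undefined")
})
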