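test_that("circle masks match analytic areas within rasterization error", {
  cal <- calibration(0.1, c(30, 30))
  m <- roi_mask(circular_roi(c(0, 0), 1), cal, c(60, 60))
  expect_lt(abs(sum(m) / (pi * 5^2) - 1), 0.04)
  # doubling the diameter quadruples the area within rasterization tolerance
  m2 <- roi_mask(circular_roi(c(0, 0), 2), cal, c(60, 60))
  expect_lt(abs(sum(m2) / (4 * sum(m)) - 1), 2 / 5)
  expect_error(roi_mask(circular_roi(c(50, 50), 1), cal, c(60, 60)),
               "does not intersect")
})

test_that("vessel masks cover the polyline at full width", {
  cal <- calibration(0.1, c(30, 30))
  v <- vessel_roi(rbind(c(0, -2), c(0, 2)), width_mm = 0.4, label = "vessel-1")
  m <- roi_mask(v, cal, c(60, 60))
  # ~ length x width = 4 mm x 0.4 mm = 160 px at 0.01 mm^2/px (+ round caps)
  expect_gt(sum(m), 140)
  expect_lt(sum(m), 230)
  expect_error(vessel_roi(rbind(c(0, 0)), 0.2), "at least 2")
})

test_that("bregma-relative coordinates map caudal-down, lateral-right", {
  cal <- calibration(0.1, c(50, 50))
  px <- speckleflow:::.ap_ml_to_pixel(cal, -2, 2)
  expect_equal(unname(px), c(70, 70))
  expect_equal(unname(speckleflow:::.ap_ml_to_pixel(cal, 1, -1)), c(40, 40))
})

test_that("field-of-view calibrations are validated within one pixel", {
  cal <- calibration(0.05, c(90, 67), magnification = "1x")
  expect_true(check_calibration_fov(cal, c(134, 180)))  # 9 x 6.7 mm
  expect_error(check_calibration_fov(cal, c(100, 100)), "field of view")
  cal25 <- calibration(0.015, c(90, 120), magnification = "2.5x")
  expect_true(check_calibration_fov(cal25, c(180, 240)))  # 3.6 x 2.7 mm
})

test_that("ROI means average valid pixels only and are linear", {
  mask <- matrix(FALSE, 10, 10); mask[3:8, 3:8] <- TRUE
  expect_equal(roi_mean(matrix(0.44, 10, 10), mask), 0.44)
  half <- matrix(0, 10, 10); half[, 6:10] <- 1
  expect_equal(roi_mean(half, matrix(TRUE, 10, 10)), 0.5)

  withna <- matrix(2, 10, 10); withna[3, 3] <- NA
  expect_equal(roi_mean(withna, mask), 2)
  expect_error(roi_mean(matrix(NA_real_, 10, 10), mask), "invalid")

  m <- matrix(runif(100), 10, 10)
  expect_equal(roi_mean(3 * m + 1, mask), 3 * roi_mean(m, mask) + 1)
})

test_that("time courses aggregate replicates with mean and SD", {
  cal <- calibration(0.05, c(8, 8))
  roi <- circular_roi(c(0, 0), 0.5)
  mk <- function(v) structure(list(rcbf = matrix(v, 16, 16),
                                   valid = matrix(TRUE, 16, 16)),
                              class = "relative_cbf_map")
  tc <- time_course(list(mk(1), mk(0.5), mk(0.3)), roi, cal,
                    times = c(0, 2, 6))
  expect_equal(tc$mean, c(1, 0.5, 0.3))
  expect_true(all(is.na(tc$sd)))

  reps <- list(list(mk(1), mk(1)), list(mk(0.4), mk(0.6)))
  tc2 <- time_course(reps, roi, cal, times = c(0, 1))
  expect_equal(tc2$mean, c(1, 0.5))
  expect_equal(tc2$sd[2], sd(c(0.4, 0.6)))
  expect_equal(tc2$n, c(2, 2))
  # replicate order is immaterial
  tc3 <- time_course(list(list(mk(1), mk(1)), list(mk(0.6), mk(0.4))),
                     roi, cal, times = c(0, 1))
  expect_equal(tc3$mean, tc2$mean)
})

test_that("one-way ANOVA matches the direct sum-of-squares oracle", {
  set.seed(8)
  for (rep in 1:5) {
    groups <- list(a = rnorm(3), b = rnorm(3, 1), c = rnorm(3, -0.5))
    res <- anova_oneway(groups)
    # textbook computation
    n <- vapply(groups, length, integer(1)); N <- sum(n); k <- length(groups)
    gm <- mean(unlist(groups))
    ssb <- sum(n * (vapply(groups, mean, numeric(1)) - gm)^2)
    ssw <- sum(unlist(lapply(groups, function(g) sum((g - mean(g))^2))))
    f <- (ssb / (k - 1)) / (ssw / (N - k))
    p <- pf(f, k - 1, N - k, lower.tail = FALSE)
    expect_lt(abs(res$f_statistic - f) / f, 1e-8)
    expect_lt(abs(res$p_value - p), 1e-8)
  }
})

test_that("two-group ANOVA equals the squared pooled t statistic", {
  set.seed(9)
  a <- rnorm(6); b <- rnorm(5, 0.8)
  res <- anova_oneway(list(a = a, b = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_lt(abs(res$f_statistic - tt$statistic^2) / res$f_statistic, 1e-8)
  expect_lt(abs(res$p_value - tt$p.value), 1e-8)
})

test_that("ANOVA significance codes and degenerate inputs behave", {
  same <- anova_oneway(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_equal(same$f_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$significance_code, "ns")

  sep <- anova_oneway(list(a = c(0, 0, 0) + c(0.01, -0.01, 0),
                           b = c(10, 10, 10) + c(0.01, -0.01, 0)))
  expect_lt(sep$p_value, 0.001)
  expect_equal(sep$significance_code, "***")

  flat <- anova_oneway(list(a = c(5, 5), b = c(5, 5)))
  expect_true(flat$degenerate)
  expect_equal(flat$p_value, 1)
  expect_equal(flat$significance_code, "ns")

  expect_error(anova_oneway(list(a = 1:3)), "2 groups")
  expect_error(anova_oneway(list(a = 1, b = 1:3)), "at least 2 values")
})
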