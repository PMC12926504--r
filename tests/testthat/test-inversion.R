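test_that("image calibration subtracts, floors, and divides by the reference median", {
  raw <- matrix(runif(100, 1, 5), 10, 10)
  zero <- calibrate_image(raw, raw, calibration_reference = matrix(2, 3, 3),
                          calibration_background = 0)
  expect_true(all(zero == 0))

  ref <- matrix(c(1, 1, 1, 100), 2, 2)
  cal <- calibrate_image(matrix(2, 3, 3), 0, calibration_reference = ref)
  expect_equal(unclass(cal)[1, 1], 2) # median divisor 1, not mean 25.75

  cal2 <- calibrate_image(matrix(6, 4, 4), 0,
                          calibration_reference = matrix(3, 4, 4))
  expect_true(all(cal2 == 2))
  expect_equal(attr(cal2, "norm_factor"), 3)

  expect_error(calibrate_image(matrix(1, 2, 2), 0,
                               calibration_reference = matrix(0, 2, 2)),
               class = "fluordepth_calibration_error")
})

test_that("log-ratio maps compute per-pixel ratios and mask degenerate pixels", {
  img <- matrix(runif(64, 1, 2), 8, 8)
  lrm <- log_ratio_map(img, img, intensity_floor = 0)
  expect_true(all(lrm$values[lrm$valid] == 0))

  lrm_e <- log_ratio_map(exp(1) * img, img, intensity_floor = 0)
  expect_equal(lrm_e$values[lrm_e$valid], rep(1, sum(lrm_e$valid)),
               tolerance = 1e-12)

  img2 <- img; img2[3, 4] <- 0
  lrm0 <- log_ratio_map(img, img2, intensity_floor = 0)
  expect_false(lrm0$valid[3, 4])
  expect_true(all(is.finite(lrm0$values[lrm0$valid])))

  expect_error(log_ratio_map(img, matrix(1, 4, 4)),
               class = "fluordepth_invalid_input")
})

test_that("linear inversion is the exact algebraic inverse with clamping", {
  ch <- example_channels()
  m <- linear_ratio_model(ch$target, ch$reference,
    ratio_model_spec("dual_excitation", "infinite", "point"))
  expect_equal(as.numeric(invert_linear(m$slope * 10 + m$intercept, m)), 10,
               tolerance = 1e-12)
  expect_equal(as.numeric(invert_linear(m$intercept, m)), 0, tolerance = 1e-12)
  # frozen worked example: lnGamma(10 mm) under the infinite point model
  expect_equal(as.numeric(invert_linear(1.091875, m)), 10, tolerance = 1e-3)

  neg <- invert_linear(m$intercept - m$slope, m)
  expect_equal(as.numeric(neg), 0)
  expect_true(attr(neg, "clamped"))

  same <- wavelength_channel(optical_properties(700, 0.02, 1.1), "target")
  same2 <- wavelength_channel(optical_properties(700, 0.02, 1.1), "reference")
  degen <- linear_ratio_model(same, same2,
    ratio_model_spec("dual_excitation", "infinite", "point"))
  expect_error(invert_linear(0.5, degen),
               class = "fluordepth_degenerate_model_error")
})

test_that("nonlinear dual-emission inversion round-trips through the forward model", {
  ch <- example_channels()
  for (d in c(1, 3, 7)) {
    r <- ratio_semi_infinite_emission(d, ch$target, ch$reference)
    expect_equal(invert_semi_infinite_emission(r, ch$target, ch$reference), d,
                 tolerance = 1e-3)
  }
  # the shallow limit of the boundary-corrected ratio maps back to zero depth
  r0 <- ratio_semi_infinite_emission(2e-3, ch$target, ch$reference)
  expect_lt(invert_semi_infinite_emission(r0, ch$target, ch$reference), 5e-3)
  expect_error(
    invert_semi_infinite_emission(1e6, ch$target, ch$reference),
    class = "fluordepth_no_solution_error")
})

test_that("depth maps propagate masks and recover model-generated scenes", {
  ch <- prostate_channels()
  m <- linear_ratio_model(ch$target, ch$reference, ratio_model_spec())

  const <- matrix(predict(m, 5), 6, 6)
  lrm <- structure(list(values = const, valid = matrix(TRUE, 6, 6),
                        pixel_mm = 1), class = "fd_log_ratio_map")
  dm <- depth_map(lrm, m)
  expect_true(all(abs(dm$depth - 5) < 1e-12))

  lrm$valid[2, 2] <- FALSE
  lrm$values[2, 2] <- NA
  dm2 <- depth_map(lrm, m)
  expect_identical(dm2$valid, lrm$valid)
  expect_true(is.na(dm2$depth[2, 2]))

  # synthetic image pair generated by the planar forward at 5 mm depth
  i2 <- matrix(runif(400, 0.5, 1.5), 20, 20)
  i1 <- i2 * exp(predict(m, 5))
  dm3 <- depth_map(log_ratio_map(i1, i2, intensity_floor = 0), m)
  expect_equal(mean(dm3$depth), 5, tolerance = 1e-10)
})

test_that("profile statistics follow the stated geometry and estimators", {
  mk_dm <- function(depth_mat, pixel_mm = 1) {
    structure(list(depth = depth_mat,
                   valid = !is.na(depth_mat), pixel_mm = pixel_mm,
                   n_clamped = 0, model = NULL), class = "fd_depth_map")
  }
  dm <- mk_dm(matrix(5, 30, 30))
  st <- profile_stats(dm, c(15, 15), c(0, 1), 10)
  expect_equal(st$mean_depth_mm, 5)
  expect_equal(st$sd_depth_mm, 0)
  expect_equal(st$n_pixels, 11) # 10 mm at 1 mm pixels, inclusive endpoints

  dm05 <- mk_dm(matrix(5, 60, 60), pixel_mm = 0.5)
  expect_equal(profile_stats(dm05, c(30, 30), c(1, 0), 10)$n_pixels, 21)

  vals <- matrix(NA_real_, 10, 10)
  vals[5, 4:6] <- c(4, 5, 6)
  st3 <- profile_stats(mk_dm(vals), c(5, 5), c(0, 1), 2)
  expect_equal(st3$mean_depth_mm, 5)
  expect_equal(st3$sd_depth_mm, sqrt(2 / 3), tolerance = 1e-6) # population sd

  empty <- mk_dm(matrix(NA_real_, 10, 10))
  expect_error(profile_stats(empty, c(5, 5), c(0, 1), 2),
               class = "fluordepth_empty_profile_error")
  expect_error(profile_stats(dm, c(1, 1), c(1, 0), 40),
               class = "fluordepth_invalid_input")
})

test_that("depth errors report signed and relative forms", {
  e <- depth_error(c(10, 13.33, 8), c(10, 10, 10))
  expect_equal(e$error_mm, c(0, 3.33, -2))
  expect_equal(e$error_pct, c(0, 33.3, -20), tolerance = 1e-6)
  expect_true(is.na(depth_error(1, 0)$error_pct))
})

test_that("pipeline invariances: calibration scale and excitation power cancel", {
  ch <- prostate_channels()
  m <- linear_ratio_model(ch$target, ch$reference, ratio_model_spec())
  set.seed(4)
  i2 <- matrix(runif(144, 0.5, 1.5), 12, 12)
  i1 <- i2 * exp(predict(m, 6.5))
  ref1 <- matrix(2, 4, 4); ref2 <- matrix(5, 4, 4)

  run <- function(s1) {
    c1 <- calibrate_image(s1 * i1, 0, calibration_reference = s1 * ref1)
    c2 <- calibrate_image(i2, 0, calibration_reference = ref2)
    calib <- median(ref2) / median(ref1) # residual reference ratio
    dm <- depth_map(log_ratio_map(unclass(c1), unclass(c2),
                                  calib = calib, intensity_floor = 0), m)
    dm$depth
  }
  expect_equal(run(1), run(37.5), tolerance = 1e-12)

  # dual-emission: a common excitation-power scale hits both images alike
  scale <- 3.7
  lr_a <- log_ratio_map(i1, i2, intensity_floor = 0)
  lr_b <- log_ratio_map(scale * i1, scale * i2, intensity_floor = 0)
  expect_equal(lr_a$values, lr_b$values, tolerance = 1e-12)

  # no unmasked negative depths anywhere
  noisy <- matrix(exp(rnorm(144, predict(m, 0.2), 0.3)), 12, 12)
  dmn <- depth_map(log_ratio_map(noisy, i2 * 0 + 1, intensity_floor = 0), m)
  expect_true(all(dmn$depth[dmn$valid] >= 0))
})
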