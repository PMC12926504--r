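test_that("infinite-medium Green's function matches its closed form and shape", {
  d1 <- derive_diffusion(optical_properties(640, 0.03, 1.0))
  expect_equal(green_infinite(5, d1), 1.073093e-2, tolerance = 1e-4)

  d <- seq(0.5, 30, 0.25)
  G <- green_infinite(d, d1)
  expect_true(all(diff(G) < 0))
  # asymptotic log-slope approaches -1/delta (the 1/d term dies off)
  slope_at <- function(dd) diff(log(green_infinite(c(dd - 1, dd + 1), d1))) / 2
  dev <- abs(vapply(c(10, 30, 100), slope_at, numeric(1)) + 1 / d1$delta)
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 0.011)

  expect_error(green_infinite(0, d1), class = "fluordepth_domain_error")
})

test_that("semi-infinite Green's function obeys the image construction", {
  d1 <- derive_diffusion(optical_properties(640, 0.03, 1.0, n = 1.3))
  expect_equal(green_semi_infinite(5, d1), 8.431751e-3, tolerance = 1e-3)
  # image term is strictly positive, and vanishes as zb -> infinity
  d <- c(1, 3, 5, 10)
  expect_true(all(green_semi_infinite(d, d1) < green_infinite(d, d1)))
  far <- d1; far$zb <- 1e6
  expect_equal(green_semi_infinite(d, far), green_infinite(d, d1),
               tolerance = 1e-10)
  expect_error(green_semi_infinite(-1, d1), class = "fluordepth_domain_error")
})

test_that("planar-source fluence has continuous branches and the deep log-slope", {
  d1 <- derive_diffusion(optical_properties(640, 0.03, 1.0, n = 1.3))
  expect_equal(fluence_planar_semi_infinite(5, d1), 1.208491, tolerance = 1e-3)
  z0 <- d1$z0
  expect_equal(fluence_planar_semi_infinite(z0 - 1e-9, d1),
               fluence_planar_semi_infinite(z0 + 1e-9, d1), tolerance = 1e-6)
  deep_slope <- diff(log(fluence_planar_semi_infinite(c(20, 21), d1)))
  expect_equal(deep_slope, -1 / d1$delta, tolerance = 1e-10)
  expect_error(fluence_planar_semi_infinite(-0.1, d1),
               class = "fluordepth_domain_error")
})

test_that("infinite-medium point-source Green's function satisfies the diffusion PDE", {
  d1 <- derive_diffusion(optical_properties(640, 0.03, 1.0))
  h <- 0.01
  for (d in c(3, 5, 8)) {
    # radial Laplacian via (1/r) d^2(r G)/dr^2, central differences
    rG <- function(r) r * green_infinite(r, d1)
    lap <- (rG(d + h) - 2 * rG(d) + rG(d - h)) / (h^2 * d)
    residual <- -d1$D * lap + d1$mua * green_infinite(d, d1)
    expect_lt(abs(residual) / (d1$mua * green_infinite(d, d1)), 1e-3)
  }
})

test_that("linear ratio model reproduces hand-evaluated slopes and intercepts", {
  ch <- example_channels()
  inf <- linear_ratio_model(ch$target, ch$reference,
    ratio_model_spec("dual_excitation", "infinite", "point"))
  expect_equal(inf$slope, 0.128546, tolerance = 1e-3)
  expect_equal(inf$intercept, -0.1935847, tolerance = 1e-3)

  printed <- linear_ratio_model(ch$target, ch$reference,
    ratio_model_spec(intercept_form = "as_printed"))
  rederived <- linear_ratio_model(ch$target, ch$reference, ratio_model_spec())
  expect_equal(printed$intercept, -0.04494729, tolerance = 1e-3)
  expect_equal(rederived$intercept, 0.04319569, tolerance = 1e-3)
  # the difference between the intercept forms is an algebraic identity
  t1 <- ch$target; t2 <- ch$reference
  expect_equal(rederived$intercept - printed$intercept,
               t2$zb / t2$delta - t1$zb / t1$delta, tolerance = 1e-12)
  expect_equal(rederived$intercept - printed$intercept, 0.08814298,
               tolerance = 1e-4)

  # identical channels: zero slope and intercept for every affine variant
  same <- wavelength_channel(optical_properties(700, 0.02, 1.1), "reference")
  same_t <- wavelength_channel(optical_properties(700, 0.02, 1.1), "target")
  for (spec in list(ratio_model_spec(),
                    ratio_model_spec("dual_emission", "infinite", "point"),
                    ratio_model_spec(intercept_form = "as_printed"))) {
    m <- linear_ratio_model(same_t, same, spec)
    expect_equal(m$slope, 0, tolerance = 1e-14)
    expect_equal(m$intercept, 0, tolerance = 1e-14)
  }

  expect_error(ratio_model_spec(geometry = "infinite", source = "planar"),
               class = "fluordepth_configuration_error")
  expect_error(linear_ratio_model(ch$target, ch$reference,
    ratio_model_spec("dual_emission", "semi_infinite", "point")),
    class = "fluordepth_configuration_error")
})

test_that("ln of the planar fluence ratio is affine with the rederived coefficients", {
  for (chs in list(example_channels(), prostate_channels())) {
    m <- linear_ratio_model(chs$target, chs$reference, ratio_model_spec())
    d <- seq(max(chs$target$z0, chs$reference$z0) + 0.01, 15, length.out = 40)
    lr <- log(fluence_planar_semi_infinite(d, chs$target) /
                fluence_planar_semi_infinite(d, chs$reference))
    expect_equal(lr, m$slope * d + m$intercept, tolerance = 1e-12)
  }
})

test_that("boundary-corrected dual-emission ratio reproduces both limiting regimes", {
  for (chs in list(example_channels(), prostate_channels(c(822, 889)))) {
    t1 <- chs$target; t2 <- chs$reference
    gamma_inf <- function(d) green_infinite(d, t1) / green_infinite(d, t2)
    # shallow limit: ratio -> infinite-medium ratio
    d0 <- 1e-4
    expect_lt(abs(ratio_semi_infinite_emission(d0, t1, t2) / gamma_inf(d0) - 1),
              1e-3)
    # deep limit: constant correction factor, approached as O(1/d)
    asym <- (1 - exp(-4 * t1$A * t1$D / t1$delta)) /
      (1 - exp(-4 * t2$A * t2$D / t2$delta))
    dev <- vapply(c(30, 100, 1200), function(dd) {
      abs(ratio_semi_infinite_emission(dd, t1, t2) / gamma_inf(dd) - asym)
    }, numeric(1))
    expect_true(all(diff(dev) < 0))
    expect_lt(dev[3], 1e-3)
  }
  ch <- example_channels()
  corr <- ratio_semi_infinite_emission(3, ch$target, ch$reference) /
    (green_infinite(3, ch$target) / green_infinite(3, ch$reference))
  expect_equal(corr, 0.9848725, tolerance = 1e-3)
  expect_error(ratio_semi_infinite_emission(0, ch$target, ch$reference),
               class = "fluordepth_domain_error")
})

test_that("uniform property scaling scales the slope and fixes the planar intercept", {
  ch <- example_channels()
  base_r <- linear_ratio_model(ch$target, ch$reference, ratio_model_spec())
  base_p <- linear_ratio_model(ch$target, ch$reference,
    ratio_model_spec(intercept_form = "as_printed"))
  for (s in c(0.5, 0.75, 1.25, 2)) {
    sc <- list(
      target = wavelength_channel(
        optical_properties(640, 0.03 * s, 1.0 * s), "target"),
      reference = wavelength_channel(
        optical_properties(760, 0.05 * s, 1.2 * s), "reference"))
    mr <- linear_ratio_model(sc$target, sc$reference, ratio_model_spec())
    mp <- linear_ratio_model(sc$target, sc$reference,
      ratio_model_spec(intercept_form = "as_printed"))
    expect_equal(mr$slope, base_r$slope * s, tolerance = 1e-12)
    expect_equal(mr$intercept, base_r$intercept, tolerance = 1e-10)
    expect_equal(mp$intercept, base_p$intercept, tolerance = 1e-10)
  }
})

test_that("calibration factors behave as pure normalization constants", {
  fl <- icg_like_fluorophore()
  em_spec <- ratio_model_spec("dual_emission", "infinite", "point")
  ex_spec <- ratio_model_spec()
  expect_equal(calibration_factor(fl, em_spec, 822, 822), 1)
  expect_equal(calibration_factor(fl, ex_spec, 640, 760,
                                  source_power = c(2, 2)), 1)
  # round trip: a raw ratio built as model * factor calibrates back exactly
  fac <- calibration_factor(fl, em_spec, 822, 889)
  model_gamma <- 1.37
  expect_equal((model_gamma * fac) / fac, model_gamma, tolerance = 1e-14)
  expect_error(calibration_factor(fl, ex_spec, 640, 760,
                                  source_power = c(1, 0)),
               class = "fluordepth_invalid_input")
  # dual-emission prediction is independent of any source description
  ch <- prostate_channels(c(822, 889))
  g <- ratio_semi_infinite_emission(4, ch$target, ch$reference)
  expect_true(is.finite(g)) # no source term enters the dual-emission ratio
})
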