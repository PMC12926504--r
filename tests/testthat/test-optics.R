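test_that("derived diffusion quantities match hand-evaluated closed forms", {
  d1 <- derive_diffusion(optical_properties(640, 0.03, 1.0, n = 1.3))
  expect_equal(d1$D, 0.3236246, tolerance = 1e-3)
  expect_equal(d1$delta, 3.284431, tolerance = 1e-3)
  expect_equal(d1$z0, 1.0, tolerance = 1e-12)
  expect_equal(d1$zb, 1.684184, tolerance = 1e-3)

  d2 <- derive_diffusion(optical_properties(640, 0.03, 1.0), "without_mua")
  expect_equal(d2$D, 1 / 3, tolerance = 1e-12)
  expect_equal(d2$delta, 3.333333, tolerance = 1e-4)

  # definition identity for arbitrary properties
  dd <- derive_diffusion(optical_properties(700, 0.017, 1.31, n = 1.4))
  expect_equal(dd$mueff * dd$delta, 1, tolerance = 1e-14)

  expect_error(derive_diffusion(optical_properties(640, -0.1, 1)),
               class = "fluordepth_invalid_input")
})

test_that("boundary mismatch factor follows the internal-reflection polynomial", {
  expect_equal(boundary_factor_A(1.3), 2.602064, tolerance = 1e-4)
  expect_equal(boundary_factor_A(1.4), 3.250697, tolerance = 1e-4)
  expect_lt(abs(boundary_factor_A(1.0) - 1), 0.01) # matched boundary limit
  expect_error(boundary_factor_A(0), class = "fluordepth_invalid_input")
})

test_that("penetration depth responds to absorption and uniform scaling as expected", {
  mua_grid <- c(0.005, 0.01, 0.02, 0.05, 0.1)
  for (conv in c("with_mua", "without_mua")) {
    deltas <- derive_diffusion(
      optical_properties(700, mua_grid, 1.2), conv)$delta
    expect_true(all(diff(deltas) < 0))
  }
  base <- derive_diffusion(optical_properties(700, 0.02, 1.1, n = 1.35))
  for (s in c(0.5, 0.75, 1.25, 2)) {
    sc <- derive_diffusion(optical_properties(700, 0.02 * s, 1.1 * s, n = 1.35))
    expect_equal(sc$D, base$D / s, tolerance = 1e-12)
    expect_equal(sc$delta, base$delta / s, tolerance = 1e-12)
    expect_equal(sc$z0, base$z0 / s, tolerance = 1e-12)
    expect_equal(sc$zb, base$zb / s, tolerance = 1e-12)
    expect_equal(sc$A, base$A, tolerance = 1e-12)
    expect_equal((sc$z0 + sc$zb) / sc$delta, (base$z0 + base$zb) / base$delta,
                 tolerance = 1e-12)
    expect_equal(sc$zb / sc$delta, base$zb / base$delta, tolerance = 1e-12)
  }
})

test_that("band averaging equals the exact mean of the interpolated curve", {
  flat <- spectrum(seq(600, 700, 5), rep(0.05, 21))
  expect_equal(band_average(flat, 650, 10), 0.05, tolerance = 1e-12)

  wl <- seq(600, 700, 2)
  lin <- spectrum(wl, 0.001 * (wl - 600) + 0.02)
  expect_equal(band_average(lin, 640, 10), 0.06, tolerance = 1e-12)
  # affine spectrum: band average equals point evaluation at the center
  for (ctr in c(612.3, 640, 688)) {
    expect_equal(band_average(lin, ctr, 7.7), eval_spectrum(lin, ctr),
                 tolerance = 1e-10)
  }

  ramp <- spectrum(635:645, 1:11)
  expect_equal(band_average(ramp, 640, 10), 6.0, tolerance = 1e-12)

  expect_error(band_average(ramp, 636, 10), class = "fluordepth_range_error")
})

test_that("spectrum construction and evaluation enforce the tabulation contract", {
  expect_error(spectrum(c(600, 600, 610), c(1, 2, 3)),
               class = "fluordepth_invalid_input")
  expect_error(spectrum(600:610, c(rep(1, 10), -1)),
               class = "fluordepth_invalid_input")
  sp <- spectrum(600:610, seq(1, 2, length.out = 11))
  expect_equal(eval_spectrum(sp, 605.5), 1.55, tolerance = 1e-12)
  expect_error(eval_spectrum(sp, 599.9), class = "fluordepth_range_error")
})

test_that("tissue spectra builder mixes chromophores and a scattering power law", {
  grid <- seq(600, 900, 10)
  empty <- build_tissue_spectra(wavelength_grid = grid)
  expect_true(all(empty$mua$value == 0))

  sc <- build_tissue_spectra(scatter_amplitude = 1.2, scatter_power = 1,
                             scatter_ref_nm = 640, wavelength_grid = grid)
  expect_equal(eval_spectrum(sc$musp, 640), 1.2, tolerance = 1e-12)
  expect_equal(eval_spectrum(sc$musp, 800), 0.96, tolerance = 1e-12)

  expect_error(build_tissue_spectra(wavelength_grid = seq(400, 900, 10)),
               class = "fluordepth_range_error")

  # diffusion-regime check for the default preset
  bg <- prostate_like_spectra()
  wl <- seq(620, 900, 2)
  ratio <- eval_spectrum(bg$musp, wl) / eval_spectrum(bg$mua, wl)
  expect_true(all(ratio > 10))
})

test_that("fluorophore fixture has the stated spectral peaks and absorption scale", {
  fl <- icg_like_fluorophore()
  expect_equal(fl$excitation$wavelength_nm[which.max(fl$excitation$value)], 779)
  expect_equal(fl$emission$wavelength_nm[which.max(fl$emission$value)], 820)
  expect_equal(max(fl$excitation$value), 1)
  expect_equal(max(fl$emission$value), 1)
  # peak absorption of 1 uM dye with peak extinction 2e5 1/M/cm
  expect_equal(fluorophore_mua(fl, 779), log(10) * 2e5 * 1e-6 / 10,
               tolerance = 1e-3)
  expect_error(fluorophore_spec(fl$excitation, fl$emission, quantum_yield = 1.2),
               class = "fluordepth_invalid_input")
})
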