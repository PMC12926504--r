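test_that("scattering-free beam deposits weight by the Beer-Lambert law", {
  med <- absorber_medium(mua = 0.1)
  cfg <- transport_config(n_photons = 1e5, seed = 42,
                          source = source_spec("pencil"))
  res <- run_excitation(med, cfg, 700)
  dep_first_mm <- sum(res$absorption[, , 1])
  p <- 1 - exp(-0.1)
  sigma <- sqrt(p * (1 - p) / cfg$n_photons)
  expect_lt(abs(dep_first_mm - p), 3 * sigma)
})

test_that("every pass conserves weight to the bookkeeping tolerance", {
  med <- small_cylinder_medium()
  cfg <- transport_config(n_photons = 2e4, seed = 9)
  exc <- run_excitation(med, cfg, 640)
  expect_lt(abs(weight_ledger(exc)$balance), 1e-6)
  em <- run_emission(med, exc, cfg, 820)
  expect_lt(abs(weight_ledger(em)$balance), 1e-6)
  expect_true(all(exc$absorption >= 0))
  expect_true(all(exc$surface >= 0))
  expect_lte(weight_ledger(exc)$deposited, 1)
})

test_that("transport is bit-reproducible for a fixed seed and stable across seeds", {
  med <- small_cylinder_medium()
  cfg <- transport_config(n_photons = 3e4, seed = 123)
  a <- run_excitation(med, cfg, 640)
  b <- run_excitation(med, cfg, 640)
  expect_identical(a$absorption, b$absorption)
  expect_identical(a$surface, b$surface)

  sums <- vapply(1:3, function(s) {
    sum(run_excitation(med, transport_config(n_photons = 3e4, seed = s),
                       640)$surface)
  }, numeric(1))
  # total diffuse reflectance fluctuates at the sub-percent level at 3e4 photons
  expect_lt(diff(range(sums)) / mean(sums), 0.02)
})

test_that("Henyey-Greenstein sampler has mean cosine g within 3 sigma", {
  for (g in c(0, 0.8)) {
    draws <- sample_hg(1e6, g, seed = 11)
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - g), 3 * se)
  }
})

test_that("point-source fluence matches the infinite-medium Green's function", {
  bg <- list(mua = 0.01, musp = 1.0)
  med <- build_medium(dims_mm = c(50, 50, 50), voxel_mm = 1, background = bg,
                      inclusion = inclusion_geometry("sphere", 0.4, 45),
                      fluorophore = icg_like_fluorophore(1e-12),
                      n = 1.0, g = 0.8)
  cfg <- transport_config(n_photons = 1e5, seed = 3,
                          source = source_spec("point", c(25, 25, 25)))
  res <- run_excitation(med, cfg, 700)
  der <- derive_diffusion(optical_properties(700, bg$mua, bg$musp, n = 1))
  xc <- (1:50) - 0.5
  r <- sqrt(outer(outer((xc - 25)^2, (xc - 25)^2, `+`), (xc - 25)^2, `+`))
  phi <- res$absorption / bg$mua
  for (rr in c(2, 3, 5, 8, 10)) {
    sel <- r >= rr - 0.5 & r < rr + 0.5
    expect_lt(abs(mean(phi[sel]) / green_infinite(rr, der) - 1), 0.10)
  }
})

test_that("planar-source excitation fluence tracks the diffusion profile at depth", {
  med <- build_medium(dims_mm = c(60, 60, 30), voxel_mm = 1,
                      inclusion = inclusion_geometry("sphere", 0.3, 28),
                      fluorophore = icg_like_fluorophore(1e-12))
  cfg <- transport_config(n_photons = 3e5, seed = 17)
  res <- run_excitation(med, cfg, 760)
  mua <- res$props$mua[1]
  phi <- apply(res$absorption[21:40, 21:40, ], 3, mean) / mua
  ch <- prostate_channels()$reference
  z <- (1:30) - 0.5
  model <- fluence_planar_semi_infinite(z, ch)
  # compare shapes normalized at 4.5 mm over d in [2, 10] mm
  idx <- which(z >= 2 & z <= 10)
  ratio <- (phi[idx] / phi[z == 4.5]) / (model[idx] / model[z == 4.5])
  expect_true(all(abs(ratio - 1) < 0.15))
})

test_that("emission pass weighting, bounds, and failure modes are correct", {
  med <- small_cylinder_medium(depth = 3)
  cfg <- transport_config(n_photons = 5e4, seed = 21)
  exc <- run_excitation(med, cfg, 640)
  em <- run_emission(med, exc, cfg, 820)
  inc_absorbed <- sum(exc$absorption[med$labels == 1L])
  expect_lte(em$source_weight,
             med$fluorophore$quantum_yield * inc_absorbed + 1e-12)
  expect_gt(sum(em$surface), 0)

  # absent fluorophore absorption -> empty emission source
  med0 <- build_medium(dims_mm = c(40, 40, 24), voxel_mm = 1,
                       inclusion = inclusion_geometry("cylinder", 1, 3),
                       fluorophore = icg_like_fluorophore(1e-30))
  exc0 <- run_excitation(med0, cfg, 640)
  expect_gt(em$source_weight / sum(exc0$absorption[med0$labels == 1L]) *
              1e30, 1) # concentration scales the source weight
  expect_error(run_emission(med, list(absorption = NULL), cfg, 820))
})

test_that("deeper inclusions yield monotonically weaker fluorescence images", {
  sums <- vapply(c(2, 5, 8), function(d) {
    med <- small_cylinder_medium(depth = d)
    cfg <- transport_config(n_photons = 1e5, seed = 77)
    sum(simulate_fluorescence(med, cfg, 640, 820)$surface)
  }, numeric(1))
  expect_true(all(diff(sums) < 0))
})
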