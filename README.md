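# fluordepth

Depth estimation of fluorescent inclusions buried in optically turbid
biological tissue, from ratiometric wide-field surface fluorescence images.

Surgeons (and phantom builders) often need to know *how deep* a dye-labelled
structure — a vessel, nerve, or tumor margin filled with an NIR fluorophore
such as indocyanine green — sits below the tissue surface. Because tissue
attenuation is wavelength dependent, the ratio of the fluorescence signal
measured at two wavelengths encodes that depth. Under the diffusion
approximation (`musp' >> mua`), for several source/geometry combinations the
calibrated log ratio is affine in depth `d`:

    ln Γ(d) = (1/δ₂ − 1/δ₁) · d + b,        δᵢ = sqrt(Dᵢ/μaᵢ)

where `D = 1/(3(μa + μs'))` is the diffusion coefficient and the intercept
`b` depends on the measurement strategy: `ln(D₂/D₁)` for a point source in
an infinite medium, or a sinh expression built from the source displacement
depth `z0 = 1/μs'` and the extrapolated boundary distance `zb = 2AD` for
planar epi-illumination of a semi-infinite medium. The package implements

* the full family of forward models — dual-emission (one excitation, two
  emission wavelengths) and dual-excitation (two excitations, one emission),
  infinite and semi-infinite media, point and planar sources, including the
  nonlinear boundary-corrected dual-emission ratio and its bisection
  inverse;
* the image pipeline: background subtraction, calibration-well
  normalization, per-pixel log-ratio maps, depth maps, and line-profile
  statistics;
* a voxelized two-pass fluorescence Monte Carlo simulator (weighted photon
  packets, Henyey–Greenstein scattering, Fresnel boundaries, Russian
  roulette; Rcpp kernel) used as an independent forward oracle and as the
  synthetic-data generator;
* scripted simulation studies: depth sweeps under different source models,
  inclusion size/geometry effects, and ±25% optical-property misestimation;
* synthetic prostate-like tissue spectra and an ICG-like fluorophore
  fixture (excitation peak 779 nm, emission peak 820 nm), so everything
  runs without external data.

## Worked example

Build the dual-excitation planar model at 640/760 nm from the packaged
prostate-like spectra (10-nm band-averaged), simulate a 1-mm-radius
dye-filled cylinder 5 mm deep, and invert the image pair:

```r
library(fluordepth)

bg <- prostate_like_spectra()
ch <- list(
  target = wavelength_channel(optical_properties(
    640, band_average(bg$mua, 640), band_average(bg$musp, 640)), "target"),
  reference = wavelength_channel(optical_properties(
    760, band_average(bg$mua, 760), band_average(bg$musp, 760)), "reference"))
model <- linear_ratio_model(ch$target, ch$reference, ratio_model_spec())
model
#> <linear ratio model: ln(ratio) = -0.129796 * d -0.0388469  [dual_excitation, semi_infinite, planar source]>

medium <- build_medium(inclusion = inclusion_geometry("cylinder", 1, 5))
i1 <- simulate_fluorescence(medium, transport_config(n_photons = 2e5, seed = 1), 640, 820)
i2 <- simulate_fluorescence(medium, transport_config(n_photons = 2e5, seed = 1), 760, 820)
calib <- fluorophore_mua(medium$fluorophore, 640) /
  fluorophore_mua(medium$fluorophore, 760)
dm <- depth_map(log_ratio_map(i1$surface, i2$surface, calib), model)
profile_stats(dm, c(30, 30), c(0, 1))
#>   mean_depth_mm sd_depth_mm n_pixels center_x center_y dir_x dir_y length_mm
#> 1      4.794695    2.470073       11       30       30     0     1        10
```

The slope −0.130 mm⁻¹ says the calibrated 640/760 log ratio drops by 0.13
per millimetre of depth (640 nm is the more strongly attenuated channel);
the 10-mm profile above the cylinder recovers 4.79 mm for a true boundary
depth of 5 mm at this modest photon count. `autoplot()` methods plot models,
depth maps, and study results; `tidy()`/`glance()` give broom-style
summaries.

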