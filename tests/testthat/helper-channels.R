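# Shared fixtures: the worked channel pair used across model tests, and the
# packaged prostate-like channels at the standard excitation pair.

example_channels <- function(convention = "with_mua") {
  list(
    target = wavelength_channel(optical_properties(640, 0.03, 1.0),
                                "target", convention),
    reference = wavelength_channel(optical_properties(760, 0.05, 1.2),
                                   "reference", convention)
  )
}

prostate_channels <- function(pair = c(640, 760), bandwidth_nm = 10,
                              convention = "with_mua") {
  bg <- prostate_like_spectra()
  mk <- function(wl, role) {
    wavelength_channel(optical_properties(
      wl, mua = band_average(bg$mua, wl, bandwidth_nm),
      musp = band_average(bg$musp, wl, bandwidth_nm)), role, convention)
  }
  list(target = mk(pair[1], "target"), reference = mk(pair[2], "reference"))
}

# non-scattering absorber for Beer-Lambert style oracles
absorber_medium <- function(mua = 0.1, dims = c(20, 20, 20)) {
  build_medium(dims_mm = dims, voxel_mm = 1,
               background = list(mua = mua, musp = 1e-9),
               inclusion = inclusion_geometry("sphere", 0.4, dims[3] - 5),
               fluorophore = icg_like_fluorophore(1e-12),
               n = 1.0, g = 0)
}

small_cylinder_medium <- function(depth = 5, radius = 1, n = 1.3, g = 0.8) {
  build_medium(dims_mm = c(40, 40, 24), voxel_mm = 1,
               inclusion = inclusion_geometry("cylinder", radius, depth),
               n = n, g = g)
}
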