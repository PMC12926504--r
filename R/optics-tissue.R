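# Synthetic tissue and fluorophore fixtures. The packaged chromophore curves
# (hemoglobin molar extinction, water absorption) are smooth approximations of
# the standard literature compilations, sampled at 10 nm over 550-920 nm, and
# are labelled "synthetic" in the file names: they reproduce the qualitative
# NIR shapes (steep hemoglobin fall-off 580-640 nm, deoxy-Hb bump near 760 nm,
# slowly rising water tail) rather than any one measured data set.

#' Packaged chromophore extinction tables
#'
#' @param which `"hemoglobin"` (columns `hbo2`, `hb`, molar extinction in
#'   M^-1 cm^-1) or `"water"` (column `value`, absorption in mm^-1 of pure
#'   water).
#' @return Tibble of the requested table.
#' @export
chromophore_table <- function(which = c("hemoglobin", "water")) {
  which <- match.arg(which)
  file <- switch(which,
    hemoglobin = "hemoglobin_extinction_synthetic.csv",
    water = "water_absorption_synthetic.csv")
  path <- system.file("extdata", "chromophores", file, package = "fluordepth",
                      mustWork = TRUE)
  as_tibble(read.csv(path))
}

#' Build background tissue spectra from a chromophore mixture
#'
#' Absorption is a linear mixture of packaged chromophore curves,
#' `mua(lambda) = sum_i c_i * extinction_i(lambda)`: oxy- and deoxyhemoglobin
#' concentrations in micromolar (converted via
#' `mua = ln(10) * eps * C / 10` mm^-1) plus a water volume fraction.
#' Reduced scattering follows the usual power law
#' `musp(lambda) = a * (lambda / lambda_ref)^(-b)`.
#'
#' @param hbo2_uM,hb_uM Oxy-/deoxyhemoglobin concentrations (micromolar, >= 0).
#' @param water_fraction Water volume fraction in `[0, 1]`.
#' @param scatter_amplitude `a`: musp at `scatter_ref_nm`, mm^-1 (> 0).
#' @param scatter_power `b`: scattering power (> 0).
#' @param scatter_ref_nm Reference wavelength for the power law (nm).
#' @param wavelength_grid Wavelengths (nm) on which to tabulate; must lie
#'   inside the packaged chromophore range.
#' @return List with elements `mua` and `musp`, each a [spectrum()].
#' @export
#' @examples
#' sp <- build_tissue_spectra(scatter_amplitude = 1.2, scatter_power = 1,
#'                            scatter_ref_nm = 640)
#' eval_spectrum(sp$musp, 800) # 0.96
build_tissue_spectra <- function(hbo2_uM = 0, hb_uM = 0, water_fraction = 0,
                                 scatter_amplitude = 1, scatter_power = 1,
                                 scatter_ref_nm = 640,
                                 wavelength_grid = seq(550, 920, by = 2)) {
  check_number(hbo2_uM, "hbo2_uM", nonnegative = TRUE)
  check_number(hb_uM, "hb_uM", nonnegative = TRUE)
  check_number(water_fraction, "water_fraction", nonnegative = TRUE)
  check_number(scatter_amplitude, "scatter_amplitude", positive = TRUE)
  check_number(scatter_power, "scatter_power", positive = TRUE)
  hb <- chromophore_table("hemoglobin")
  water <- chromophore_table("water")
  rng <- range(hb$wavelength_nm)
  if (min(wavelength_grid) < rng[1] || max(wavelength_grid) > rng[2]) {
    fd_stop(sprintf(
      "`wavelength_grid` exceeds the packaged chromophore range [%g, %g] nm.",
      rng[1], rng[2]), "fluordepth_range_error")
  }
  eps_hbo2 <- approx(hb$wavelength_nm, hb$hbo2, xout = wavelength_grid)$y
  eps_hb <- approx(hb$wavelength_nm, hb$hb, xout = wavelength_grid)$y
  mua_water <- approx(water$wavelength_nm, water$value,
                      xout = wavelength_grid)$y
  uM_to_mua <- log(10) * 1e-6 / 10 # eps [1/M/cm] * C [uM] -> mm^-1
  mua <- uM_to_mua * (hbo2_uM * eps_hbo2 + hb_uM * eps_hb) +
    water_fraction * mua_water
  musp <- scatter_amplitude * (wavelength_grid / scatter_ref_nm)^(-scatter_power)
  list(
    mua = spectrum(wavelength_grid, mua, kind = "absorption"),
    musp = spectrum(wavelength_grid, musp, kind = "reduced_scattering")
  )
}

#' Prostate-like background spectra preset
#'
#' Default background fixture: 125 micromolar total hemoglobin at 75% oxygen
#' saturation, 60% water, and a scattering power law with 1.45 mm^-1 at
#' 640 nm and power 1.2. Absorption then sits in the published in vivo
#' prostate range (~0.02-0.05 mm^-1 around 760-786 nm), `musp/mua > 10`
#' holds throughout 620-900 nm (the diffusive regime the forward models
#' assume), absorption varies strongly below 800 nm (driving dual-excitation
#' sensitivity) and is comparatively flat at 820-890 nm, and 600 nm is
#' strongly absorbing, at the edge of the diffusive regime.
#'
#' @inheritParams build_tissue_spectra
#' @return List with spectra `mua` and `musp`.
#' @export
prostate_like_spectra <- function(wavelength_grid = seq(550, 920, by = 2)) {
  build_tissue_spectra(
    hbo2_uM = 93.75, hb_uM = 31.25, water_fraction = 0.6,
    scatter_amplitude = 1.45, scatter_power = 1.2, scatter_ref_nm = 640,
    wavelength_grid = wavelength_grid
  )
}

#' Fluorophore specification
#'
#' Excitation and emission spectra (normalized to unit peak on construction),
#' quantum yield, concentration, and peak molar extinction. The fluorophore's
#' absorption coefficient at a wavelength is
#' `muaf(lambda) = excitation(lambda) * ln(10) * extinction_peak * C / 10`
#' (mm^-1), i.e. the normalized excitation spectrum scaled by the peak molar
#' absorption of the dissolved dye.
#'
#' @param excitation,emission [spectrum()] objects (kinds `"excitation"` /
#'   `"emission"`); values are renormalized to unit peak.
#' @param quantum_yield Emission quantum yield in (0, 1].
#' @param concentration_uM Concentration in micromolar (> 0).
#' @param extinction_peak Peak molar extinction, M^-1 cm^-1 (> 0).
#' @return Object of class `fd_fluorophore`.
#' @export
fluorophore_spec <- function(excitation, emission, quantum_yield = 0.13,
                             concentration_uM = 1,
                             extinction_peak = 2e5) {
  excitation <- as_fd_spectrum(excitation, "excitation")
  emission <- as_fd_spectrum(emission, "emission")
  check_number(quantum_yield, "quantum_yield", positive = TRUE)
  if (quantum_yield > 1) {
    fd_stop("`quantum_yield` must lie in (0, 1].", "fluordepth_invalid_input")
  }
  check_number(concentration_uM, "concentration_uM", positive = TRUE)
  check_number(extinction_peak, "extinction_peak", positive = TRUE)
  norm <- function(sp) {
    sp$value <- sp$value / max(sp$value)
    sp
  }
  structure(list(
    excitation = norm(excitation),
    emission = norm(emission),
    quantum_yield = quantum_yield,
    concentration_uM = concentration_uM,
    extinction_peak = extinction_peak
  ), class = "fd_fluorophore")
}

#' @export
print.fd_fluorophore <- function(x, ...) {
  cat(sprintf(
    "<fluorophore: %g uM, Qf %.3g, peak extinction %.3g 1/M/cm>\n",
    x$concentration_uM, x$quantum_yield, x$extinction_peak))
  invisible(x)
}

#' Fluorophore absorption coefficient at a wavelength
#'
#' @param fluor A [fluorophore_spec()].
#' @param wavelength_nm Wavelength(s), nm, inside the excitation spectrum range.
#' @return `muaf` in mm^-1.
#' @export
fluorophore_mua <- function(fluor, wavelength_nm) {
  stopifnot(inherits(fluor, "fd_fluorophore"))
  peak_mua <- log(10) * fluor$extinction_peak *
    fluor$concentration_uM * 1e-6 / 10
  eval_spectrum(fluor$excitation, wavelength_nm) * peak_mua
}

#' ICG-like fluorophore preset
#'
#' Synthetic indocyanine-green-like dye: excitation peaking at 779 nm with a
#' secondary shoulder near 708 nm and a short-wavelength tail reaching 550 nm,
#' emission peaking at 820 nm with a long red tail. Peak molar extinction
#' 2e5 M^-1 cm^-1, quantum yield 0.13, default concentration 1 micromolar.
#'
#' @param concentration_uM Dye concentration (micromolar).
#' @return An `fd_fluorophore`.
#' @export
icg_like_fluorophore <- function(concentration_uM = 1) {
  wl <- seq(550, 950, by = 1)
  # main-peak centers offset so the argmax of each composite curve lands on
  # the nominal 779 / 820 nm despite the shoulder terms
  exc <- exp(-0.5 * ((wl - 782.2) / 28)^2) +
    0.42 * exp(-0.5 * ((wl - 708) / 42)^2) +
    0.08 * exp(-0.5 * ((wl - 630) / 60)^2)
  emi <- exp(-0.5 * ((wl - 817.8) / 24)^2) +
    0.35 * exp(-0.5 * ((wl - 870) / 50)^2)
  fluorophore_spec(
    excitation = spectrum(wl, exc, kind = "excitation"),
    emission = spectrum(wl, emi, kind = "emission"),
    quantum_yield = 0.13,
    concentration_uM = concentration_uM,
    extinction_peak = 2e5
  )
}
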