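#' Tabulated optical spectrum
#'
#' A spectrum is a two-column tibble (`wavelength_nm`, `value`) carrying a
#' `kind` attribute. Evaluation between knots is defined as linear
#' interpolation; evaluation outside the tabulated range is an error (no
#' extrapolation), so callers must supply spectra that cover every band they
#' ask for.
#'
#' @param wavelength_nm Strictly increasing wavelengths in nm.
#' @param value Non-negative values; units depend on `kind` (mm^-1 for the
#'   coefficient kinds, arbitrary for fluorophore spectra).
#' @param kind One of `"absorption"`, `"reduced_scattering"`, `"excitation"`,
#'   `"emission"`.
#' @return A tibble of class `fd_spectrum`.
#' @export
#' @examples
#' sp <- spectrum(600:700, 0.02 + 0.0001 * (600:700 - 600), kind = "absorption")
#' eval_spectrum(sp, 650.5)
spectrum <- function(wavelength_nm, value,
                     kind = c("absorption", "reduced_scattering",
                              "excitation", "emission")) {
  kind <- match.arg(kind)
  check_number(wavelength_nm, "wavelength_nm")
  check_number(value, "value", nonnegative = TRUE)
  if (length(wavelength_nm) != length(value)) {
    fd_stop("`wavelength_nm` and `value` must have equal length.",
            "fluordepth_invalid_input")
  }
  if (length(wavelength_nm) < 2L || any(diff(wavelength_nm) <= 0)) {
    fd_stop("`wavelength_nm` must be strictly increasing with >= 2 knots.",
            "fluordepth_invalid_input")
  }
  out <- tibble(wavelength_nm = as.numeric(wavelength_nm),
                value = as.numeric(value))
  attr(out, "kind") <- kind
  class(out) <- c("fd_spectrum", class(out))
  out
}

#' @export
print.fd_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d knots, %g-%g nm>\n", spectrum_kind(x),
              nrow(x), min(x$wavelength_nm), max(x$wavelength_nm)))
  NextMethod()
}

#' @rdname spectrum
#' @param spec A spectrum.
#' @export
spectrum_kind <- function(spec) attr(spec, "kind") %||% "absorption"

as_fd_spectrum <- function(x, kind = "absorption") {
  if (inherits(x, "fd_spectrum")) return(x)
  if (is.data.frame(x) && all(c("wavelength_nm", "value") %in% names(x))) {
    return(spectrum(x$wavelength_nm, x$value, kind = kind))
  }
  fd_stop("Expected an `fd_spectrum` or a data frame with columns wavelength_nm, value.",
          "fluordepth_invalid_input")
}

#' Evaluate a spectrum by linear interpolation
#'
#' @param spec A [spectrum()].
#' @param wavelength_nm Wavelengths to evaluate (nm); all must lie within the
#'   tabulated range.
#' @return Numeric vector of interpolated values.
#' @export
eval_spectrum <- function(spec, wavelength_nm) {
  spec <- as_fd_spectrum(spec)
  check_number(wavelength_nm, "wavelength_nm")
  rng <- range(spec$wavelength_nm)
  if (any(wavelength_nm < rng[1] | wavelength_nm > rng[2])) {
    fd_stop(sprintf(
      "Requested wavelength outside the tabulated range [%g, %g] nm; no extrapolation.",
      rng[1], rng[2]), "fluordepth_range_error")
  }
  approx(spec$wavelength_nm, spec$value, xout = wavelength_nm,
         method = "linear", ties = "ordered")$y
}

#' Band-averaged spectrum value
#'
#' Mean of the linearly interpolated curve over
#' `[center - bandwidth/2, center + bandwidth/2]`, computed as the exact
#' integral of the piecewise-linear curve divided by the bandwidth. This is
#' how effective optical properties for a filtered illumination band are
#' derived from a full spectrum (default bandwidth 10 nm).
#'
#' @inheritParams eval_spectrum
#' @param center_nm Band center (nm).
#' @param bandwidth_nm Full bandwidth (nm); must be > 0.
#' @return Scalar band mean.
#' @export
band_average <- function(spec, center_nm, bandwidth_nm = 10) {
  spec <- as_fd_spectrum(spec)
  check_number(center_nm, "center_nm")
  check_number(bandwidth_nm, "bandwidth_nm", positive = TRUE)
  lo <- center_nm - bandwidth_nm / 2
  hi <- center_nm + bandwidth_nm / 2
  rng <- range(spec$wavelength_nm)
  if (lo < rng[1] || hi > rng[2]) {
    fd_stop(sprintf(
      "Band [%g, %g] nm exceeds the tabulated range [%g, %g] nm.",
      lo, hi, rng[1], rng[2]), "fluordepth_range_error")
  }
  # exact trapezoid on the union of band edges and interior knots
  inner <- spec$wavelength_nm[spec$wavelength_nm > lo & spec$wavelength_nm < hi]
  xs <- c(lo, inner, hi)
  ys <- eval_spectrum(spec, xs)
  integral <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  integral / bandwidth_nm
}

#' Read / write spectra as two-column CSV
#'
#' The on-disk dialect is comma-separated with a single header line
#' (`wavelength_nm,value`), wavelengths in nm.
#'
#' @param path File path.
#' @param kind Spectrum kind for the returned object.
#' @return `read_spectrum_csv()` returns a [spectrum()]; `write_spectrum_csv()`
#'   returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path, kind = "absorption") {
  df <- read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(df))) {
    fd_stop("Spectrum CSV must have columns `wavelength_nm` and `value`.",
            "fluordepth_io_error")
  }
  spectrum(df$wavelength_nm, df$value, kind = kind)
}

#' @rdname read_spectrum_csv
#' @param spec Spectrum to write.
#' @export
write_spectrum_csv <- function(spec, path) {
  spec <- as_fd_spectrum(spec)
  write.csv(as.data.frame(spec)[, c("wavelength_nm", "value")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
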