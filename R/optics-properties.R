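#' Per-wavelength tissue optical properties
#'
#' Bundles the background absorption coefficient `mua` and reduced scattering
#' coefficient `musp` (both mm^-1) with the refractive index `n` and scattering
#' anisotropy `g` at one or more wavelengths. Vectorized over all arguments;
#' returns one row per wavelength.
#'
#' @param wavelength_nm Wavelength(s) in nm.
#' @param mua Absorption coefficient(s), mm^-1, > 0.
#' @param musp Reduced scattering coefficient(s), mm^-1, > 0.
#' @param n Refractive index (>= 1). Default 1.3, a common soft-tissue value.
#' @param g Scattering anisotropy, 0 <= g < 1. Default 0.8. Only the Monte
#'   Carlo simulator uses `g`; the diffusion models depend on `musp` alone.
#' @return Tibble with columns `wavelength_nm`, `mua`, `musp`, `n`, `g`.
#' @export
#' @examples
#' optical_properties(640, mua = 0.02, musp = 1.45)
optical_properties <- function(wavelength_nm, mua, musp, n = 1.3, g = 0.8) {
  check_number(wavelength_nm, "wavelength_nm", positive = TRUE)
  check_number(mua, "mua", positive = TRUE)
  check_number(musp, "musp", positive = TRUE)
  check_number(n, "n")
  check_number(g, "g")
  if (any(n < 1)) fd_stop("`n` must be >= 1.", "fluordepth_invalid_input")
  if (any(g < 0 | g >= 1)) {
    fd_stop("`g` must satisfy 0 <= g < 1.", "fluordepth_invalid_input")
  }
  tibble(wavelength_nm = as.numeric(wavelength_nm), mua = as.numeric(mua),
         musp = as.numeric(musp), n = as.numeric(n), g = as.numeric(g))
}

#' Internal-reflection boundary mismatch factor A(n)
#'
#' Factor entering the extrapolated boundary condition, `zb = 2 A D`. Uses the
#' standard polynomial fit for the internal diffuse reflectance
#' `r_d = -1.440 n^-2 + 0.710 n^-1 + 0.668 + 0.0636 n` and returns
#' `A = (1 + r_d) / (1 - r_d)`. For a matched boundary (`n_relative = 1`) the
#' fit gives A within 0.01 of 1.
#'
#' @param n_relative Ratio of internal to external refractive index (> 0).
#' @return Dimensionless factor A (vectorized).
#' @export
#' @examples
#' boundary_factor_A(1.3) # ~2.602
boundary_factor_A <- function(n_relative) {
  check_number(n_relative, "n_relative", positive = TRUE)
  rd <- -1.440 * n_relative^-2 + 0.710 / n_relative + 0.668 +
    0.0636 * n_relative
  (1 + rd) / (1 - rd)
}

#' Derived diffusion-approximation quantities
#'
#' Adds to a table of optical properties the quantities the forward models are
#' built from: the diffusion coefficient `D` (mm), the effective penetration
#' depth `delta = sqrt(D / mua)` (mm), the effective attenuation coefficient
#' `mueff = 1/delta` (mm^-1), the source displacement depth `z0 = 1/musp`
#' (mm), the extrapolated boundary distance `zb = 2 A D` (mm), and the
#' boundary factor `A` from [boundary_factor_A()].
#'
#' Two conventions for `D` are supported: `"with_mua"` uses
#' `D = 1 / (3 (mua + musp))`; `"without_mua"` drops absorption,
#' `D = 1 / (3 musp)`, which is a common simplification in the diffusive
#' regime (`musp >> mua`) and changes both the slope and intercept of the
#' ratio models built downstream.
#'
#' @param props Data frame from [optical_properties()] (columns
#'   `wavelength_nm`, `mua`, `musp`, `n`; `g` optional).
#' @param convention `"with_mua"` (default) or `"without_mua"`.
#' @return `props` with columns `D`, `delta`, `mueff`, `z0`, `zb`, `A`,
#'   `convention` appended.
#' @export
#' @examples
#' derive_diffusion(optical_properties(640, 0.03, 1.0))
derive_diffusion <- function(props, convention = c("with_mua", "without_mua")) {
  convention <- match.arg(convention)
  if (!is.data.frame(props) ||
      !all(c("mua", "musp", "n") %in% names(props))) {
    fd_stop("`props` must be a data frame with columns mua, musp, n.",
            "fluordepth_invalid_input")
  }
  check_number(props$mua, "mua", positive = TRUE)
  check_number(props$musp, "musp", positive = TRUE)
  D <- if (convention == "with_mua") {
    1 / (3 * (props$mua + props$musp))
  } else {
    1 / (3 * props$musp)
  }
  A <- boundary_factor_A(props$n)
  out <- as_tibble(props)
  out$D <- D
  out$delta <- sqrt(D / props$mua)
  out$mueff <- 1 / out$delta
  out$z0 <- 1 / props$musp
  out$zb <- 2 * A * D
  out$A <- A
  out$convention <- convention
  out
}
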