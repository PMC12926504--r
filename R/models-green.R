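# Closed-form fluence building blocks. Each takes a one-row derived-property
# table (from derive_diffusion()) and is vectorized over depth. Wavelength-
# independent multiplicative constants that cancel in two-wavelength ratios
# are dropped (the 4*pi factors are kept; source strength is not).

as_derived_row <- function(derived, name = "derived") {
  need <- c("D", "delta", "z0", "zb", "A")
  if (!is.data.frame(derived) || !all(need %in% names(derived))) {
    fd_stop(sprintf(
      "`%s` must come from derive_diffusion() (columns %s).",
      name, paste(need, collapse = ", ")), "fluordepth_invalid_input")
  }
  if (nrow(derived) != 1L) {
    fd_stop(sprintf("`%s` must have exactly one row.", name),
            "fluordepth_invalid_input")
  }
  derived
}

#' Infinite-medium point-source Green's function
#'
#' Fluence response `exp(-d/delta) / (4 pi D d)` at distance `d` from a
#' point source in an unbounded diffusive medium.
#'
#' @param d Source-observer distance(s), mm, > 0.
#' @param derived One-row table from [derive_diffusion()].
#' @return Numeric vector (mm^-2, up to the dropped source constant).
#' @export
green_infinite <- function(d, derived) {
  derived <- as_derived_row(derived)
  check_number(d, "d")
  if (any(d <= 0)) {
    fd_stop("`d` must be > 0 (point-source singularity at d = 0).",
            "fluordepth_domain_error")
  }
  exp(-d / derived$delta) / (4 * pi * derived$D * d)
}

#' Semi-infinite-medium point-source Green's function
#'
#' Extrapolated-boundary image construction: real source at depth
#' `source_depth` plus a negative image at `-(source_depth + 2 zb)`, observed
#' at the surface point directly above the source, giving
#' `(1 / 4 pi D) * [exp(-r1/delta)/r1 - exp(-r2/delta)/r2]` with
#' `r1 = source_depth`, `r2 = source_depth + 2 zb`.
#'
#' @param source_depth Depth(s) of the point source below the surface, mm, > 0.
#' @inheritParams green_infinite
#' @return Numeric vector; always smaller than [green_infinite()] at the same
#'   depth because the image term is strictly positive.
#' @export
green_semi_infinite <- function(source_depth, derived) {
  derived <- as_derived_row(derived)
  check_number(source_depth, "source_depth")
  if (any(source_depth <= 0)) {
    fd_stop("`source_depth` must be > 0.", "fluordepth_domain_error")
  }
  r1 <- source_depth
  r2 <- source_depth + 2 * derived$zb
  (exp(-r1 / derived$delta) / r1 - exp(-r2 / derived$delta) / r2) /
    (4 * pi * derived$D)
}

#' Planar-source fluence in a semi-infinite medium
#'
#' Depth profile of the excitation fluence under wide-field epi-illumination,
#' modeled as a plane source displaced to `z0 = 1/musp` with a negative image
#' plane at `-(z0 + 2 zb)`. Two branches joined continuously at `d = z0`:
#' for `d > z0`, `(delta/D) exp(-(d+zb)/delta) sinh((z0+zb)/delta)`; for
#' `d <= z0`, `(delta/D) exp(-(z0+zb)/delta) sinh((d+zb)/delta)`. The shallow
#' branch is the one consistent with direct integration of the image-source
#' pair; the two expressions coincide at `d = z0`. Normalization is arbitrary
#' (a common factor cancels in ratios).
#'
#' @param d Depth(s) below the surface, mm, >= 0.
#' @inheritParams green_infinite
#' @return Numeric vector (arbitrary units).
#' @export
fluence_planar_semi_infinite <- function(d, derived) {
  derived <- as_derived_row(derived)
  check_number(d, "d")
  if (any(d < 0)) fd_stop("`d` must be >= 0.", "fluordepth_domain_error")
  delta <- derived$delta
  pref <- delta / derived$D
  deep <- pref * exp(-(d + derived$zb) / delta) *
    sinh((derived$z0 + derived$zb) / delta)
  shallow <- pref * exp(-(derived$z0 + derived$zb) / delta) *
    sinh((d + derived$zb) / delta)
  ifelse(d > derived$z0, deep, shallow)
}
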