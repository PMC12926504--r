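#' Ratio model specification
#'
#' Identifies one member of the family of ratiometric depth models:
#' the wavelength strategy (`approach`), the medium geometry, the excitation
#' source type, the diffusion-coefficient convention, and -- for the planar
#' semi-infinite variant -- which intercept form to use. `"as_printed"` is the
#' compact published intercept `ln[delta1 D2 sinh((z01+zb1)/delta1) /
#' (delta2 D1 sinh((z02+zb2)/delta2))]`; `"rederived"` (default) adds the
#' `zb2/delta2 - zb1/delta1` term required for exact consistency with the
#' planar fluence the model is derived from.
#'
#' @param approach `"dual_emission"` (one excitation, two emission
#'   wavelengths) or `"dual_excitation"` (two excitations, one emission).
#' @param geometry `"infinite"` or `"semi_infinite"`.
#' @param source `"point"` or `"planar"`. A planar source is only meaningful
#'   with a semi-infinite geometry.
#' @param convention Diffusion-coefficient convention, see
#'   [derive_diffusion()].
#' @param intercept_form `"rederived"` (default) or `"as_printed"`; only
#'   consulted for the planar semi-infinite variant.
#' @return A list of class `fd_ratio_model_spec`.
#' @export
ratio_model_spec <- function(approach = c("dual_excitation", "dual_emission"),
                             geometry = c("semi_infinite", "infinite"),
                             source = c("planar", "point"),
                             convention = c("with_mua", "without_mua"),
                             intercept_form = c("rederived", "as_printed")) {
  spec <- list(
    approach = match.arg(approach),
    geometry = match.arg(geometry),
    source = match.arg(source),
    convention = match.arg(convention),
    intercept_form = match.arg(intercept_form)
  )
  if (spec$source == "planar" && spec$geometry == "infinite") {
    fd_stop("A planar source is only supported with `geometry = \"semi_infinite\"`.",
            "fluordepth_configuration_error")
  }
  structure(spec, class = "fd_ratio_model_spec")
}

#' @export
print.fd_ratio_model_spec <- function(x, ...) {
  cat(sprintf("<ratio model spec: %s, %s medium, %s source, %s, intercept %s>\n",
              x$approach, x$geometry, x$source, x$convention, x$intercept_form))
  invisible(x)
}

#' Wavelength channel
#'
#' One measurement channel: a role (`"target"` = wavelength 1, the numerator
#' of the ratio; `"reference"` = wavelength 2, the denominator), its optical
#' properties, and the derived diffusion quantities under a convention.
#'
#' @param props One-row data frame from [optical_properties()].
#' @param role `"target"` or `"reference"`.
#' @param convention See [derive_diffusion()].
#' @return One-row tibble: properties, derived quantities, and `role`.
#' @export
wavelength_channel <- function(props, role = c("target", "reference"),
                               convention = c("with_mua", "without_mua")) {
  role <- match.arg(role)
  convention <- match.arg(convention)
  if (!is.data.frame(props) || nrow(props) != 1L) {
    fd_stop("`props` must be a one-row data frame of optical properties.",
            "fluordepth_invalid_input")
  }
  out <- derive_diffusion(props, convention)
  out$role <- role
  out
}

channel_derived <- function(channel) {
  as_derived_row(channel, "channel")
}

#' Linear log-ratio depth model
#'
#' Builds the affine model `ln Gamma(d) = slope * d + intercept` relating the
#' calibrated two-wavelength fluorescence ratio to inclusion depth. The slope
#' is always `1/delta2 - 1/delta1` (reference minus target effective
#' attenuation). The intercept depends on the variant:
#' * infinite medium, point source: `ln(D2 / D1)`;
#' * semi-infinite medium, planar source: the sinh intercept of the planar
#'   fluence ratio, in the `"as_printed"` or `"rederived"` form (see
#'   [ratio_model_spec()]).
#'
#' The semi-infinite point-source dual-emission ratio is not affine in depth;
#' use [ratio_semi_infinite_emission()] and
#' [invert_semi_infinite_emission()] for that variant.
#'
#' @param target,reference One-row channel tables from [wavelength_channel()]
#'   (or [derive_diffusion()]); target is wavelength 1, reference is
#'   wavelength 2.
#' @param spec A [ratio_model_spec()].
#' @return Object of class `fd_linear_ratio_model` with elements `slope`
#'   (mm^-1), `intercept` (dimensionless), `spec`, and `channels`.
#' @export
#' @examples
#' ch1 <- wavelength_channel(optical_properties(640, 0.03, 1.0), "target")
#' ch2 <- wavelength_channel(optical_properties(760, 0.05, 1.2), "reference")
#' m <- linear_ratio_model(ch1, ch2,
#'   ratio_model_spec("dual_excitation", "infinite", "point"))
#' tidy(m)
linear_ratio_model <- function(target, reference, spec = ratio_model_spec()) {
  if (!inherits(spec, "fd_ratio_model_spec")) {
    fd_stop("`spec` must come from ratio_model_spec().",
            "fluordepth_configuration_error")
  }
  t1 <- channel_derived(target)
  t2 <- channel_derived(reference)
  if (!identical(t1$convention %||% spec$convention, spec$convention) ||
      !identical(t2$convention %||% spec$convention, spec$convention)) {
    fd_stop("Channel diffusion convention disagrees with the model spec.",
            "fluordepth_configuration_error")
  }
  slope <- 1 / t2$delta - 1 / t1$delta
  intercept <- if (spec$geometry == "infinite" && spec$source == "point") {
    log(t2$D / t1$D)
  } else if (spec$geometry == "semi_infinite" && spec$source == "planar") {
    as_printed <- log(
      (t1$delta * t2$D * sinh((t1$z0 + t1$zb) / t1$delta)) /
        (t2$delta * t1$D * sinh((t2$z0 + t2$zb) / t2$delta)))
    if (spec$intercept_form == "rederived") {
      as_printed + (t2$zb / t2$delta - t1$zb / t1$delta)
    } else {
      as_printed
    }
  } else {
    fd_stop(paste0(
      "No affine log-ratio model for geometry = \"", spec$geometry,
      "\", source = \"", spec$source, "\"; the semi-infinite point-source ",
      "ratio is nonlinear (see ratio_semi_infinite_emission())."),
      "fluordepth_configuration_error")
  }
  channels <- dplyr::bind_rows(t1, t2)
  if (is.null(channels$role)) channels$role <- c("target", "reference")
  structure(list(slope = slope, intercept = intercept, spec = spec,
                 channels = channels),
            class = "fd_linear_ratio_model")
}

#' @export
print.fd_linear_ratio_model <- function(x, ...) {
  cat(sprintf(
    "<linear ratio model: ln(ratio) = %.6g * d %+.6g  [%s, %s, %s source]>\n",
    x$slope, x$intercept, x$spec$approach, x$spec$geometry, x$spec$source))
  invisible(x)
}

#' @export
predict.fd_linear_ratio_model <- function(object, d, ...) {
  check_number(d, "d", nonnegative = TRUE)
  object$slope * d + object$intercept
}

#' @exportS3Method generics::tidy
tidy.fd_linear_ratio_model <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope, x$intercept),
         unit = c("1/mm", ""))
}

#' @exportS3Method generics::glance
glance.fd_linear_ratio_model <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept,
    approach = x$spec$approach, geometry = x$spec$geometry,
    source = x$spec$source, convention = x$spec$convention,
    intercept_form = x$spec$intercept_form,
    wavelength_target = x$channels$wavelength_nm[1],
    wavelength_reference = x$channels$wavelength_nm[2]
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.fd_linear_ratio_model <- function(object, depths = seq(0, 10, 0.25),
                                           ...) {
  df <- tibble(depth_mm = depths,
               log_ratio = predict(object, depths))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth_mm, y = .data$log_ratio)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth (mm)", y = "ln ratio",
                  title = sprintf("%s / %s / %s source", object$spec$approach,
                                  object$spec$geometry, object$spec$source))
}

#' Semi-infinite dual-emission ratio (nonlinear in depth)
#'
#' The boundary-corrected dual-emission ratio for a point fluorophore under a
#' semi-infinite medium: `Gamma(d) = Gamma_inf(d) * f1(d) / f2(d)` with
#' `f_i(d) = 1 - exp(-4 A D_i / delta_i) / (1 + 4 A D_i / d)`. It approaches
#' the infinite-medium ratio as `d -> 0` and the constant-corrected ratio
#' `Gamma_inf * (1 - exp(-4AD1/delta1)) / (1 - exp(-4AD2/delta2))` for
#' `d >> 4 A max(D1, D2)`.
#'
#' @param d Depth(s), mm, > 0.
#' @inheritParams linear_ratio_model
#' @return The predicted calibrated ratio (not its logarithm).
#' @export
ratio_semi_infinite_emission <- function(d, target, reference) {
  t1 <- channel_derived(target)
  t2 <- channel_derived(reference)
  check_number(d, "d")
  if (any(d <= 0)) fd_stop("`d` must be > 0.", "fluordepth_domain_error")
  gamma_inf <- green_infinite(d, t1) / green_infinite(d, t2)
  f <- function(ch) 1 - exp(-4 * ch$A * ch$D / ch$delta) /
    (1 + 4 * ch$A * ch$D / d)
  gamma_inf * f(t1) / f(t2)
}

#' Calibration factor for a raw intensity ratio
#'
#' Dividing a raw two-channel intensity ratio by this factor yields the
#' calibrated ratio the forward models predict. Under the dual-emission
#' approach the factor is the ratio of the fluorophore's spectral weights at
#' the two emission wavelengths (which spectrum supplies the weight is a
#' configuration choice; the published derivation indexes the excitation
#' spectrum at the emission wavelengths, an emission-spectrum weighting is the
#' physically natural alternative). Under the dual-excitation approach the
#' factor is the source-power ratio `S0(lambda1) / S0(lambda2)`; any
#' wavelength dependence of the fluorophore's absorption is usually removed
#' upstream by normalizing against a calibration-well image at each
#' excitation wavelength (see [calibrate_image()]), or explicitly via
#' [fluorophore_mua()].
#'
#' @param fluor A [fluorophore_spec()].
#' @param spec A [ratio_model_spec()].
#' @param target_nm,reference_nm Channel wavelengths (nm).
#' @param source_power Length-2 numeric `c(target, reference)` output powers
#'   `S0` (dual-excitation only; arbitrary common units, > 0).
#' @param weighting For dual-emission: `"excitation"` (default, the printed
#'   form) or `"emission"` -- which fluorophore spectrum supplies the weights.
#' @return Scalar calibration factor.
#' @export
calibration_factor <- function(fluor, spec, target_nm, reference_nm,
                               source_power = c(1, 1),
                               weighting = c("excitation", "emission")) {
  stopifnot(inherits(fluor, "fd_fluorophore"))
  if (!inherits(spec, "fd_ratio_model_spec")) {
    fd_stop("`spec` must come from ratio_model_spec().",
            "fluordepth_configuration_error")
  }
  weighting <- match.arg(weighting)
  check_number(target_nm, "target_nm", positive = TRUE)
  check_number(reference_nm, "reference_nm", positive = TRUE)
  if (spec$approach == "dual_emission") {
    sp <- fluor[[weighting]]
    eval_spectrum(sp, target_nm) / eval_spectrum(sp, reference_nm)
  } else {
    check_number(source_power, "source_power")
    if (length(source_power) != 2L || any(source_power <= 0)) {
      fd_stop("`source_power` must be two positive values (target, reference).",
              "fluordepth_invalid_input")
    }
    source_power[1] / source_power[2]
  }
}
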