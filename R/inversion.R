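# Image calibration, log-ratio maps, per-pixel depth inversion, and profile
# statistics. Images are plain numeric matrices; depth/log-ratio maps are
# light list objects carrying a validity mask alongside the values.

#' Background-subtract and calibrate a fluorescence image
#'
#' `(raw - background)`, floored at zero, divided by the median of the
#' background-subtracted calibration-reference pixels (e.g. a well of exposed
#' fluorophore imaged at the same wavelength). The median makes the divisor
#' robust to hot pixels in the reference.
#'
#' @param raw Numeric matrix.
#' @param background Numeric matrix of the same shape, or a scalar (default 0).
#' @param calibration_reference Numeric matrix or vector of reference pixels
#'   at the same wavelength.
#' @param calibration_background Background for the reference region
#'   (defaults to `background` if shapes agree, else 0).
#' @return Calibrated matrix with attributes `norm_factor` (the divisor) and
#'   `pixel_mm` preserved from `raw` if present.
#' @export
calibrate_image <- function(raw, background = 0, calibration_reference,
                            calibration_background = NULL) {
  stopifnot(is.matrix(raw), is.numeric(raw))
  if (is.matrix(background) && !identical(dim(background), dim(raw))) {
    fd_stop("`background` shape does not match `raw`.", "fluordepth_invalid_input")
  }
  if (is.null(calibration_background)) {
    calibration_background <-
      if (is.matrix(background) &&
          identical(dim(background), dim(as.matrix(calibration_reference)))) {
        background
      } else if (!is.matrix(background)) background else 0
  }
  ref <- as.numeric(calibration_reference) - as.numeric(calibration_background)
  divisor <- median(pmax(ref, 0))
  if (!is.finite(divisor) || divisor <= 0) {
    fd_stop("Calibration reference median is not positive.",
            "fluordepth_calibration_error")
  }
  out <- pmax(raw - background, 0) / divisor
  attr(out, "norm_factor") <- divisor
  attr(out, "pixel_mm") <- attr(raw, "pixel_mm")
  out
}

#' Log-ratio map of two calibrated images
#'
#' Per-pixel `ln(img1 / img2) - ln(calib)`, where `calib` comes from
#' [calibration_factor()] (or is 1 for already fully calibrated images).
#' Pixels where either intensity is non-positive, non-finite, or below
#' `intensity_floor` times that image's maximum are masked rather than made
#' infinite. The default 1% floor suppresses pixels far off the inclusion
#' footprint, where the point-fluorophore models are meaningless anyway.
#'
#' @param img1,img2 Numeric matrices of equal shape (target = numerator,
#'   reference = denominator).
#' @param calib Scalar calibration factor.
#' @param intensity_floor Mask fraction relative to each image maximum
#'   (default 0.01; use 0 to disable).
#' @param pixel_mm Physical pixel size, mm.
#' @return Object of class `fd_log_ratio_map`: `values` (matrix, `NA` where
#'   masked), `valid` (logical matrix), `pixel_mm`.
#' @export
log_ratio_map <- function(img1, img2, calib = 1, intensity_floor = 0.01,
                          pixel_mm = NULL) {
  stopifnot(is.matrix(img1), is.matrix(img2))
  if (!identical(dim(img1), dim(img2))) {
    fd_stop("`img1` and `img2` must have the same shape.",
            "fluordepth_invalid_input")
  }
  check_number(calib, "calib", positive = TRUE)
  pixel_mm <- pixel_mm %||% attr(img1, "pixel_mm") %||% 1
  floor1 <- intensity_floor * max(img1, na.rm = TRUE)
  floor2 <- intensity_floor * max(img2, na.rm = TRUE)
  valid <- is.finite(img1) & is.finite(img2) & img1 > 0 & img2 > 0 &
    img1 >= floor1 & img2 >= floor2
  values <- matrix(NA_real_, nrow(img1), ncol(img1))
  values[valid] <- log(img1[valid] / img2[valid]) - log(calib)
  structure(list(values = values, valid = valid, pixel_mm = pixel_mm),
            class = "fd_log_ratio_map")
}

#' @export
print.fd_log_ratio_map <- function(x, ...) {
  cat(sprintf("<log-ratio map %dx%d, %d valid px, pixel %g mm>\n",
              nrow(x$values), ncol(x$values), sum(x$valid), x$pixel_mm))
  invisible(x)
}

#' Invert an affine log-ratio model for depth
#'
#' `d = (log_ratio - intercept) / slope`. Negative solutions (shallow noise)
#' are clamped to zero and flagged.
#'
#' @param log_ratio Numeric vector of calibrated log ratios.
#' @param model An [linear_ratio_model()].
#' @return Numeric vector of depths (mm) with attribute `clamped` (logical).
#' @export
invert_linear <- function(log_ratio, model) {
  stopifnot(inherits(model, "fd_linear_ratio_model"))
  if (!is.numeric(log_ratio)) {
    fd_stop("`log_ratio` must be numeric.", "fluordepth_invalid_input")
  }
  if (model$slope == 0) {
    fd_stop("Model slope is zero: the two channels are degenerate.",
            "fluordepth_degenerate_model_error")
  }
  d <- (log_ratio - model$intercept) / model$slope
  clamped <- !is.na(d) & d < 0
  d[clamped] <- 0
  attr(d, "clamped") <- clamped
  d
}

#' Invert the nonlinear semi-infinite dual-emission ratio
#'
#' Solves `ratio_semi_infinite_emission(d) = ratio` for `d` by bisection to
#' 1e-4 mm. The model's monotonicity over the bracket is verified first;
#' ratios outside the attainable range raise a no-solution error.
#'
#' @param ratio Calibrated ratio value(s) (not log).
#' @param target,reference Channel tables, see [linear_ratio_model()].
#' @param bracket Depth search interval, mm.
#' @return Depth(s), mm.
#' @export
invert_semi_infinite_emission <- function(ratio, target, reference,
                                          bracket = c(1e-3, 50)) {
  check_number(ratio, "ratio", positive = TRUE)
  check_number(bracket, "bracket", positive = TRUE)
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2])
  grid <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = 256))
  vals <- ratio_semi_infinite_emission(grid, target, reference)
  dv <- diff(vals)
  if (!(all(dv > 0) || all(dv < 0))) {
    fd_stop("Ratio model is not monotone on the bracket: ambiguous inversion.",
            "fluordepth_ambiguous_inversion_error")
  }
  lo_val <- vals[1]; hi_val <- vals[length(vals)]
  rng <- range(lo_val, hi_val)
  solve_one <- function(r) {
    if (r < rng[1] || r > rng[2]) {
      fd_stop(sprintf(
        "Ratio %.6g outside the attainable range [%.6g, %.6g] on the bracket.",
        r, rng[1], rng[2]), "fluordepth_no_solution_error")
    }
    lo <- bracket[1]; hi <- bracket[2]
    f_lo <- lo_val - r
    while (hi - lo > 1e-4) {
      mid <- (lo + hi) / 2
      f_mid <- ratio_semi_infinite_emission(mid, target, reference) - r
      if (sign(f_mid) == sign(f_lo)) {
        lo <- mid; f_lo <- f_mid
      } else {
        hi <- mid
      }
    }
    (lo + hi) / 2
  }
  vapply(ratio, solve_one, numeric(1))
}

#' Pixel-wise depth map from a log-ratio map
#'
#' Applies [invert_linear()] to every valid pixel; the mask propagates and
#' negative depths are clamped to zero (counted in `n_clamped`). Each pixel
#' is interpreted under the models' on-top assumption, so depths are
#' meaningful over the inclusion footprint only.
#'
#' @param lrm An [log_ratio_map()].
#' @param model An [linear_ratio_model()].
#' @return Object of class `fd_depth_map`: `depth` (matrix, mm, `NA` where
#'   masked), `valid`, `pixel_mm`, `n_clamped`, `model` (glance row).
#' @export
depth_map <- function(lrm, model) {
  stopifnot(inherits(lrm, "fd_log_ratio_map"))
  depth <- matrix(NA_real_, nrow(lrm$values), ncol(lrm$values))
  d <- invert_linear(lrm$values[lrm$valid], model)
  depth[lrm$valid] <- d
  structure(list(depth = depth, valid = lrm$valid, pixel_mm = lrm$pixel_mm,
                 n_clamped = sum(attr(d, "clamped")),
                 model = glance(model)),
            class = "fd_depth_map")
}

#' @export
print.fd_depth_map <- function(x, ...) {
  cat(sprintf("<depth map %dx%d, %d valid px, %d clamped, pixel %g mm>\n",
              nrow(x$depth), ncol(x$depth), sum(x$valid), x$n_clamped,
              x$pixel_mm))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.fd_depth_map <- function(object, ...) {
  df <- tidyr::expand_grid(
    x = seq_len(nrow(object$depth)), y = seq_len(ncol(object$depth)))
  df$depth_mm <- object$depth[cbind(df$x, df$y)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$depth_mm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "depth (mm)")
}

#' Line-profile statistics of a depth map
#'
#' Extracts the nearest-pixel samples of a line of physical length
#' `length_mm` centered at `center_px` along `direction`, and reports the
#' mean and population standard deviation of the unmasked depths -- the
#' summary used to reduce one scene to a single depth estimate.
#'
#' @param dm An [depth_map()].
#' @param center_px Integer `c(row, col)` of the profile center.
#' @param direction Direction vector `c(dx, dy)` in pixel axes (need not be
#'   normalized).
#' @param length_mm Profile length, mm (default 10).
#' @return One-row tibble: `mean_depth_mm`, `sd_depth_mm` (population),
#'   `n_pixels`, and the profile geometry.
#' @export
profile_stats <- function(dm, center_px, direction = c(1, 0),
                          length_mm = 10) {
  stopifnot(inherits(dm, "fd_depth_map"))
  check_number(center_px, "center_px")
  stopifnot(length(center_px) == 2L, length(direction) == 2L)
  u <- direction / sqrt(sum(direction^2))
  offsets <- seq(-length_mm / 2, length_mm / 2, by = dm$pixel_mm)
  px <- round(center_px[1] + offsets * u[1] / dm$pixel_mm)
  py <- round(center_px[2] + offsets * u[2] / dm$pixel_mm)
  inb <- px >= 1 & px <= nrow(dm$depth) & py >= 1 & py <= ncol(dm$depth)
  if (!all(inb)) {
    fd_stop("Profile extends outside the image bounds.",
            "fluordepth_invalid_input")
  }
  vals <- dm$depth[cbind(px, py)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) {
    fd_stop("All profile pixels are masked.", "fluordepth_empty_profile_error")
  }
  tibble(
    mean_depth_mm = mean(vals),
    sd_depth_mm = sqrt(mean((vals - mean(vals))^2)),
    n_pixels = length(vals),
    center_x = center_px[1], center_y = center_px[2],
    dir_x = u[1], dir_y = u[2], length_mm = length_mm
  )
}

#' Signed and relative depth-estimation error
#'
#' @param d_est,d_true Estimated and true depths, mm (vectorized).
#' @return Tibble with `d_est`, `d_true`, `error_mm = d_est - d_true`, and
#'   `error_pct = 100 * error_mm / d_true` (`NA` where `d_true <= 0`).
#' @export
depth_error <- function(d_est, d_true) {
  check_number(d_est, "d_est", finite = FALSE)
  check_number(d_true, "d_true", finite = FALSE)
  err <- d_est - d_true
  tibble(
    d_est = d_est, d_true = d_true, error_mm = err,
    error_pct = ifelse(d_true > 0, 100 * err / d_true, NA_real_)
  )
}
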