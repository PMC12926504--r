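# Seeded replications of the simulation experiments: depth sweeps under
# different source models, inclusion size/geometry effects, and the
# optical-property misestimation study.

#' Study configuration
#'
#' One declarative object drives all three study kinds. Scale defaults are
#' the reduced desk-scale preset (60 x 60 x 30 mm at 1 mm voxels, 1e6
#' excitation photons); `paper_scale = TRUE` switches to the full
#' 100 x 100 x 50 mm, 0.5 mm, 1e8-photon configuration.
#'
#' @param kind `"depth_sweep"`, `"geometry_size"`, or
#'   `"property_perturbation"`.
#' @param depths_mm True depth grid, mm.
#' @param radii_mm Inclusion radii, mm (geometry study).
#' @param shapes Subset of `c("cylinder", "sphere", "disk")`.
#' @param approach `"dual_excitation"` or `"dual_emission"`.
#' @param pairs List of `c(target, reference)` wavelengths, nm: excitation
#'   wavelengths for dual-excitation, emission wavelengths for dual-emission.
#' @param fixed_nm The shared wavelength, nm: the emission wavelength for
#'   dual-excitation, the excitation wavelength for dual-emission.
#' @param models Named list of [ratio_model_spec()]s used for inversion.
#' @param background Background spectra (list with `mua`, `musp`).
#' @param fluorophore A [fluorophore_spec()].
#' @param radius_mm Inclusion radius for non-geometry studies, mm.
#' @param shape Inclusion shape for non-geometry studies.
#' @param dims_mm,voxel_mm,n_photons,n_photons_emission MC scale.
#' @param perturbation_factors Multipliers applied to (mua, musp) during
#'   inversion, as a named list of length-2 vectors.
#' @param forward `"analytic"` (planar diffusion model, deterministic) or
#'   `"mc"` (two-pass Monte Carlo) for the perturbation study.
#' @param bandwidth_nm Band-averaging width for the inversion properties, nm.
#' @param n,g Medium refractive index and anisotropy.
#' @param summary How one simulated scene is reduced to a single depth:
#'   `"profile"` (default; 10-mm line profile over the centroid, along the
#'   cylinder axis) or `"footprint"` (mean over every valid pixel of the
#'   inclusion's surface footprint -- for a through-cylinder, the full-length
#'   strip).
#' @param seed Master seed; every per-condition seed derives from it.
#' @param paper_scale Use the full-scale MC preset.
#' @return List of class `fd_study_config`.
#' @export
study_config <- function(kind = c("depth_sweep", "geometry_size",
                                  "property_perturbation"),
                         depths_mm = 1:10,
                         radii_mm = c(0.5, 5),
                         shapes = c("cylinder", "sphere", "disk"),
                         approach = c("dual_excitation", "dual_emission"),
                         pairs = list(c(640, 760)),
                         fixed_nm = 820,
                         models = list(
                           planar = ratio_model_spec("dual_excitation",
                                                     "semi_infinite", "planar"),
                           point = ratio_model_spec("dual_excitation",
                                                    "infinite", "point")),
                         background = prostate_like_spectra(),
                         fluorophore = icg_like_fluorophore(),
                         radius_mm = 1, shape = "cylinder",
                         dims_mm = c(60, 60, 30), voxel_mm = 1,
                         n_photons = 1e6, n_photons_emission = NULL,
                         perturbation_factors = default_perturbations(),
                         forward = c("analytic", "mc"),
                         bandwidth_nm = 10, n = 1.3, g = 0.8,
                         summary = c("profile", "footprint"),
                         seed = 1, paper_scale = FALSE) {
  kind <- match.arg(kind)
  summary <- match.arg(summary)
  approach <- match.arg(approach)
  forward <- match.arg(forward)
  if (length(depths_mm) == 0L || length(radii_mm) == 0L) {
    fd_stop("Depth and radius grids must be nonempty.",
            "fluordepth_invalid_input")
  }
  if (paper_scale) {
    dims_mm <- c(100, 100, 50); voxel_mm <- 0.5; n_photons <- 1e8
  }
  cfg <- list(kind = kind, depths_mm = depths_mm, radii_mm = radii_mm,
              shapes = match.arg(shapes, several.ok = TRUE),
              approach = approach, pairs = pairs, fixed_nm = fixed_nm,
              models = models, background = background,
              fluorophore = fluorophore, radius_mm = radius_mm,
              shape = shape, dims_mm = dims_mm, voxel_mm = voxel_mm,
              n_photons = n_photons, n_photons_emission = n_photons_emission,
              perturbation_factors = perturbation_factors,
              forward = forward, bandwidth_nm = bandwidth_nm,
              n = n, g = g, summary = summary, seed = as.integer(seed))
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "hash")])
  structure(cfg, class = "fd_study_config")
}

#' @rdname study_config
#' @export
default_perturbations <- function() {
  list(
    control = c(1, 1),
    mua_under = c(0.75, 1), musp_under = c(1, 0.75), joint_under = c(0.75, 0.75),
    mua_over = c(1.25, 1), musp_over = c(1, 1.25), joint_over = c(1.25, 1.25),
    mua_under_musp_over = c(0.75, 1.25), mua_over_musp_under = c(1.25, 0.75)
  )
}

condition_seed <- function(cfg, index) {
  as.integer((cfg$seed + 7919 * index) %% 2147483629)
}

band_channels <- function(cfg, pair) {
  props <- function(wl, role) {
    wavelength_channel(optical_properties(
      wl,
      mua = band_average(cfg$background$mua, wl, cfg$bandwidth_nm),
      musp = band_average(cfg$background$musp, wl, cfg$bandwidth_nm),
      n = cfg$n, g = cfg$g), role = role,
      convention = cfg$models[[1]]$convention %||% "with_mua")
  }
  list(target = props(pair[1], "target"),
       reference = props(pair[2], "reference"))
}

build_scene <- function(cfg, shape, radius, depth) {
  build_medium(
    dims_mm = cfg$dims_mm, voxel_mm = cfg$voxel_mm,
    background = cfg$background,
    inclusion = inclusion_geometry(shape, radius, depth,
                                   thickness = 1, axis = "y"),
    fluorophore = cfg$fluorophore, n = cfg$n, g = cfg$g)
}

# Reduce a simulated scene's depth map to one estimate: a 10-mm profile along
# the cylinder axis above the centroid, or the lateral footprint mean for
# compact shapes.
scene_depth_estimate <- function(dm, medium, summary = "profile") {
  inc <- medium$inclusion
  center <- round(dim(dm$depth) / 2 + 0.5)
  if (inc$shape == "cylinder" && summary == "footprint") {
    half_w <- max(inc$radius / dm$pixel_mm, 0.51)
    cols_x <- which(abs(seq_len(nrow(dm$depth)) - center[1]) <= half_w)
    sel <- matrix(FALSE, nrow(dm$depth), ncol(dm$depth))
    if (inc$axis == "y") sel[cols_x, ] <- TRUE else sel[, cols_x] <- TRUE
    sel <- sel & dm$valid
    vals <- dm$depth[sel]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) {
      fd_stop("All footprint pixels are masked.",
              "fluordepth_empty_profile_error")
    }
    return(tibble(mean_depth_mm = mean(vals),
                  sd_depth_mm = sqrt(mean((vals - mean(vals))^2)),
                  n_pixels = length(vals), center_x = center[1],
                  center_y = center[2], dir_x = NA_real_, dir_y = NA_real_,
                  length_mm = NA_real_))
  }
  if (inc$shape == "cylinder") {
    dir <- if (inc$axis == "y") c(0, 1) else c(1, 0)
    profile_stats(dm, center, dir, length_mm = 10)
  } else {
    # the surface fluorescence spot is diffusion-blurred well beyond a
    # sub-voxel object, so the footprint never shrinks below one pixel ring
    r_px <- max(inc$radius / dm$pixel_mm, 1.01)
    nx <- nrow(dm$depth); ny <- ncol(dm$depth)
    dx <- (seq_len(nx) - center[1])
    dy <- (seq_len(ny) - center[2])
    sel <- outer(dx^2, dy^2, `+`) <= r_px^2 & dm$valid
    vals <- dm$depth[sel]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) {
      fd_stop("All footprint pixels are masked.",
              "fluordepth_empty_profile_error")
    }
    tibble(mean_depth_mm = mean(vals),
           sd_depth_mm = sqrt(mean((vals - mean(vals))^2)),
           n_pixels = length(vals), center_x = center[1],
           center_y = center[2], dir_x = NA_real_, dir_y = NA_real_,
           length_mm = NA_real_)
  }
}

# Simulate one scene and return its calibrated log-ratio map. For
# dual-excitation the calibration divides out the fluorophore absorption
# ratio muaf(l1)/muaf(l2) (source powers are equal per launched photon);
# for dual-emission the simulated images need no spectral calibration
# because the emission pass launches the same Qf-weighted total at either
# emission wavelength. Both channels of a pair run on the same seed
# (common random numbers): each channel stays unbiased while the shared
# geometric sampling noise largely cancels in the ratio.
simulate_log_ratio <- function(cfg, medium, pair, seed) {
  tcfg <- function(s) transport_config(
    n_photons = cfg$n_photons, seed = s,
    n_photons_emission = cfg$n_photons_emission,
    source = source_spec("planar"))
  if (cfg$approach == "dual_excitation") {
    em1 <- simulate_fluorescence(medium, tcfg(seed), pair[1], cfg$fixed_nm)
    em2 <- simulate_fluorescence(medium, tcfg(seed), pair[2],
                                 cfg$fixed_nm)
    calib <- fluorophore_mua(cfg$fluorophore, pair[1]) /
      fluorophore_mua(cfg$fluorophore, pair[2])
    log_ratio_map(em1$surface, em2$surface, calib = calib,
                  pixel_mm = medium$voxel_mm)
  } else {
    exc <- run_excitation(medium, tcfg(seed), cfg$fixed_nm)
    em1 <- run_emission(medium, exc, tcfg(seed + 104729), pair[1])
    em2 <- run_emission(medium, exc, tcfg(seed + 104729), pair[2])
    log_ratio_map(em1$surface, em2$surface, calib = 1,
                  pixel_mm = medium$voxel_mm)
  }
}

as_study_result <- function(records, cfg) {
  out <- dplyr::bind_rows(records)
  attr(out, "config") <- cfg
  attr(out, "hash") <- cfg$hash
  class(out) <- c("fd_study_result", class(out))
  out
}

#' Depth sweep study
#'
#' For each true depth and wavelength pair, simulates the two fluorescence
#' images with the Monte Carlo forward, reduces them to a calibrated
#' log-ratio, and inverts with every configured model. One record per
#' (pair, model, depth).
#'
#' @param cfg A [study_config()] with `kind = "depth_sweep"`.
#' @return An `fd_study_result` tibble with columns `pair`, `model`,
#'   `d_true`, `d_est`, `sd_est`, `error_mm`, `error_pct`, `seed`.
#' @export
depth_sweep <- function(cfg) {
  stopifnot(inherits(cfg, "fd_study_config"))
  idx <- 0
  records <- list()
  for (pair_i in seq_along(cfg$pairs)) {
    pair <- cfg$pairs[[pair_i]]
    ch <- band_channels(cfg, pair)
    models <- lapply(cfg$models, function(sp)
      linear_ratio_model(ch$target, ch$reference, sp))
    for (d in cfg$depths_mm) {
      idx <- idx + 1
      seed <- condition_seed(cfg, idx)
      medium <- build_scene(cfg, cfg$shape, cfg$radius_mm, d)
      lrm <- simulate_log_ratio(cfg, medium, pair, seed)
      for (m in names(models)) {
        dm <- depth_map(lrm, models[[m]])
        st <- scene_depth_estimate(dm, medium, cfg$summary %||% "profile")
        err <- depth_error(st$mean_depth_mm, d)
        records[[length(records) + 1]] <- tibble(
          pair = paste(pair, collapse = "/"), model = m,
          d_true = d, d_est = st$mean_depth_mm, sd_est = st$sd_depth_mm,
          error_mm = err$error_mm, error_pct = err$error_pct, seed = seed)
      }
    }
  }
  as_study_result(records, cfg)
}

#' Inclusion size and geometry study
#'
#' Error curves per (shape, radius) over the depth grid, using the first
#' configured model and wavelength pair.
#'
#' @param cfg A [study_config()] with `kind = "geometry_size"`.
#' @return An `fd_study_result` with columns `shape`, `radius_mm`, `d_true`,
#'   `d_est`, `error_mm`, `error_pct`, `seed`.
#' @export
geometry_size_study <- function(cfg) {
  stopifnot(inherits(cfg, "fd_study_config"))
  pair <- cfg$pairs[[1]]
  ch <- band_channels(cfg, pair)
  model <- linear_ratio_model(ch$target, ch$reference, cfg$models[[1]])
  idx <- 0
  records <- list()
  for (shape in cfg$shapes) {
    for (r in cfg$radii_mm) {
      for (d in cfg$depths_mm) {
        idx <- idx + 1
        seed <- condition_seed(cfg, idx)
        medium <- build_scene(cfg, shape, r, d)
        lrm <- simulate_log_ratio(cfg, medium, pair, seed)
        dm <- depth_map(lrm, model)
        st <- scene_depth_estimate(dm, medium, cfg$summary %||% "profile")
        err <- depth_error(st$mean_depth_mm, d)
        records[[length(records) + 1]] <- tibble(
          shape = shape, radius_mm = r, d_true = d,
          d_est = st$mean_depth_mm, sd_est = st$sd_depth_mm,
          error_mm = err$error_mm, error_pct = err$error_pct, seed = seed)
      }
    }
  }
  as_study_result(records, cfg)
}

#' Optical-property misestimation study
#'
#' Forward data are generated with the true properties; the inversion model
#' is rebuilt after multiplying `mua` and `musp` by the condition's factors
#' at both wavelengths. The default forward is the analytic planar model,
#' which isolates the property-mismatch effect from Monte Carlo noise; set
#' `forward = "mc"` in the config for the full simulated pipeline.
#'
#' @param cfg A [study_config()] with `kind = "property_perturbation"`.
#' @return An `fd_study_result` with columns `condition`, `factor_mua`,
#'   `factor_musp`, `d_true`, `d_est`, `error_mm`, `error_pct`.
#' @export
property_perturbation_study <- function(cfg) {
  stopifnot(inherits(cfg, "fd_study_config"))
  pair <- cfg$pairs[[1]]
  ch <- band_channels(cfg, pair)
  spec <- cfg$models[[1]]
  true_model <- linear_ratio_model(ch$target, ch$reference, spec)

  perturbed_model <- function(fa, fs) {
    mk <- function(row, role) {
      wavelength_channel(optical_properties(
        row$wavelength_nm, mua = row$mua * fa, musp = row$musp * fs,
        n = row$n, g = row$g), role = role, convention = spec$convention)
    }
    linear_ratio_model(mk(ch$target, "target"), mk(ch$reference, "reference"),
                       spec)
  }

  idx <- 0
  records <- list()
  for (cond in names(cfg$perturbation_factors)) {
    f <- cfg$perturbation_factors[[cond]]
    model_p <- perturbed_model(f[1], f[2])
    for (d in cfg$depths_mm) {
      idx <- idx + 1
      seed <- condition_seed(cfg, idx)
      if (cfg$forward == "analytic") {
        lr <- predict(true_model, d)
        d_est <- as.numeric(invert_linear(lr, model_p))
        sd_est <- 0
      } else {
        medium <- build_scene(cfg, cfg$shape, cfg$radius_mm, d)
        lrm <- simulate_log_ratio(cfg, medium, pair, seed)
        dm <- depth_map(lrm, model_p)
        st <- scene_depth_estimate(dm, medium, cfg$summary %||% "profile")
        d_est <- st$mean_depth_mm
        sd_est <- st$sd_depth_mm
      }
      err <- depth_error(d_est, d)
      records[[length(records) + 1]] <- tibble(
        condition = cond, factor_mua = f[1], factor_musp = f[2],
        d_true = d, d_est = d_est, sd_est = sd_est,
        error_mm = err$error_mm, error_pct = err$error_pct, seed = seed)
    }
  }
  as_study_result(records, cfg)
}

#' @exportS3Method ggplot2::autoplot
autoplot.fd_study_result <- function(object, metric = c("estimate", "error"),
                                     ...) {
  metric <- match.arg(metric)
  group_col <- intersect(c("model", "condition", "shape"), names(object))[1]
  df <- object
  df$group <- interaction(
    df[[group_col]],
    if ("radius_mm" %in% names(df)) df$radius_mm else "", drop = TRUE)
  if (metric == "estimate") {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$d_true, y = .data$d_est,
                                          colour = .data$group)) +
      ggplot2::geom_abline(linetype = "dashed") +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "true depth (mm)", y = "estimated depth (mm)")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$d_true,
                                          y = .data$error_mm,
                                          colour = .data$group)) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "true depth (mm)", y = "error (mm)")
  }
  p + ggplot2::labs(colour = group_col)
}

#' @exportS3Method generics::glance
glance.fd_study_result <- function(x, ...) {
  tibble(
    kind = attr(x, "config")$kind,
    n_records = nrow(x),
    max_abs_error_mm = max(abs(x$error_mm), na.rm = TRUE),
    mean_abs_error_mm = mean(abs(x$error_mm), na.rm = TRUE),
    seed = attr(x, "config")$seed,
    hash = attr(x, "hash")
  )
}
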