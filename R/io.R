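# File formats and configuration plumbing: float TIFF images with JSON
# sidecars, spectra CSVs, fixture generation, and a declarative run
# configuration dispatched from YAML.

#' Write / read a surface image as float TIFF with a JSON sidecar
#'
#' Images are stored as 32-bit float grayscale TIFF. TIFF float storage here
#' is normalized to `[0, 1]`, so the image maximum is divided out and
#' recorded (together with the pixel size and any metadata) in a
#' `<path>.json` sidecar; the reader restores the original scale.
#'
#' @param img Numeric matrix (rows = x, columns = y, origin at the medium's
#'   x = 0, y = 0 corner).
#' @param path Output TIFF path.
#' @param pixel_mm Physical pixel size, mm.
#' @param metadata Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_surface_tiff <- function(img, path, pixel_mm = 1, metadata = list()) {
  stopifnot(is.matrix(img), is.numeric(img))
  scale <- max(img, 0)
  norm <- if (scale > 0) img / scale else img
  tiff::writeTIFF(norm, path, bits.per.sample = 32L, compression = "none")
  sidecar <- c(list(scale = scale, pixel_mm = pixel_mm,
                    nrow = nrow(img), ncol = ncol(img)), metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_surface_tiff
#' @return `read_surface_tiff()` returns the matrix with attributes
#'   `pixel_mm` and `metadata`.
#' @export
read_surface_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    img <- img * (sc$scale %||% 1)
    attr(img, "pixel_mm") <- sc$pixel_mm %||% 1
    attr(img, "metadata") <- sc[setdiff(names(sc),
                                        c("scale", "pixel_mm", "nrow", "ncol"))]
  }
  img
}

#' Write / read a 3D absorption map as flat binary with a JSON sidecar
#'
#' Little-endian float64 in x-fastest order plus a sidecar recording the
#' grid dimensions and voxel size.
#'
#' @param arr 3D numeric array.
#' @param path Output path (`.bin`).
#' @param voxel_mm Voxel edge length, mm.
#' @return `path` invisibly; the reader returns the array with a `voxel_mm`
#'   attribute.
#' @export
write_volume_bin <- function(arr, path, voxel_mm = 1) {
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(arr), con, size = 8, endian = "little")
  jsonlite::write_json(list(dim = dim(arr), voxel_mm = voxel_mm),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume_bin
#' @export
read_volume_bin <- function(path) {
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = prod(sc$dim), size = 8,
                  endian = "little")
  arr <- array(vals, dim = sc$dim)
  attr(arr, "voxel_mm") <- sc$voxel_mm
  arr
}

#' Generate the packaged fixture set on disk
#'
#' Writes the prostate-like background spectra and the ICG-like fluorophore
#' spectra as two-column CSVs, plus ready-to-run scene configuration YAMLs
#' for the forward, simulate, and study tasks. Everything is deterministic;
#' `seed` is recorded in the scene configs so downstream runs are seeded.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Seed recorded into the run configurations.
#' @return Invisibly, a named list of the written file paths.
#' @export
generate_fixtures <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bg <- prostate_like_spectra()
  fl <- icg_like_fluorophore()
  paths <- list(
    mua = file.path(out_dir, "prostate_like_mua.csv"),
    musp = file.path(out_dir, "prostate_like_musp.csv"),
    excitation = file.path(out_dir, "icg_like_excitation.csv"),
    emission = file.path(out_dir, "icg_like_emission.csv"),
    scene = file.path(out_dir, "scene_default.yaml"),
    study = file.path(out_dir, "study_perturbation.yaml")
  )
  write_spectrum_csv(bg$mua, paths$mua)
  write_spectrum_csv(bg$musp, paths$musp)
  write_spectrum_csv(fl$excitation, paths$excitation)
  write_spectrum_csv(fl$emission, paths$emission)
  scene <- list(
    task = "simulate",
    seed = as.integer(seed),
    medium = list(dims_mm = c(60, 60, 30), voxel_mm = 1, n = 1.3, g = 0.8),
    inclusion = list(shape = "cylinder", radius_mm = 1, depth_mm = 5),
    fluorophore = list(concentration_uM = 1),
    wavelengths = list(excitation_nm = 640, emission_nm = 820),
    transport = list(n_photons = 1e6)
  )
  yaml::write_yaml(scene, paths$scene)
  study <- list(
    task = "study",
    kind = "property_perturbation",
    seed = as.integer(seed),
    depths_mm = 1:10,
    pair = c(640, 760),
    forward = "analytic"
  )
  yaml::write_yaml(study, paths$study)
  invisible(paths)
}

required_config_fields <- function(task) {
  switch(task,
    forward = c("channels", "model", "depths_mm"),
    simulate = c("medium", "inclusion", "wavelengths"),
    invert = c("images", "channels", "model"),
    study = c("kind", "depths_mm"),
    fixtures = character(0),
    fd_stop(sprintf("Unknown task `%s`.", task), "fluordepth_config_error"))
}

resolve_channels <- function(channels, convention = "with_mua") {
  mk <- function(x, role) {
    wavelength_channel(optical_properties(
      x$wavelength_nm, mua = x$mua, musp = x$musp,
      n = x$n %||% 1.3, g = x$g %||% 0.8), role, convention)
  }
  list(target = mk(channels$target, "target"),
       reference = mk(channels$reference, "reference"))
}

#' Execute a declarative run configuration
#'
#' Reads (or takes) a run description, validates it, and dispatches to the
#' forward-model, simulation, inversion, study, or fixture machinery. Every
#' run writes a resolved copy of its configuration next to its outputs.
#'
#' @param config A named list, or a path to a YAML file.
#' @param out_dir Output directory (default `"."`).
#' @param dry_run Validate and return the resolved plan without computing.
#' @return Invisibly, a list with the resolved config and output paths.
#' @export
run_config <- function(config, out_dir = ".", dry_run = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$task)) {
    fd_stop("Config is missing required field `task`.",
            "fluordepth_config_error")
  }
  task <- config$task
  required <- required_config_fields(task)
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    fd_stop(sprintf("Config is missing required field `%s`.", missing[1]),
            "fluordepth_config_error")
  }
  known <- c("task", "seed", "channels", "model", "depths_mm", "medium",
             "inclusion", "wavelengths", "transport", "fluorophore",
             "images", "kind", "pair", "pairs", "forward", "radii_mm",
             "shapes", "out_prefix", "bandwidth_nm", "calib")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    fd_stop(sprintf("Unknown config field `%s`.", unknown[1]),
            "fluordepth_config_error")
  }
  config$seed <- as.integer(config$seed %||% 1)

  if (dry_run) {
    return(invisible(list(config = config, outputs = character(0),
                          plan = sprintf("task %s (dry run)", task))))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- config$out_prefix %||% task
  outputs <- character(0)

  if (task == "fixtures") {
    outputs <- unlist(generate_fixtures(out_dir, seed = config$seed))
  } else if (task == "forward") {
    spec <- do.call(ratio_model_spec, config$model %||% list())
    ch <- resolve_channels(config$channels, spec$convention)
    model <- linear_ratio_model(ch$target, ch$reference, spec)
    df <- tibble(d_mm = as.numeric(config$depths_mm),
                 log_ratio = predict(model, as.numeric(config$depths_mm)))
    out <- file.path(out_dir, paste0(prefix, "_log_ratio.csv"))
    write.csv(df, out, row.names = FALSE, quote = FALSE)
    outputs <- out
  } else if (task == "simulate") {
    med <- config$medium
    inc <- config$inclusion
    wl <- config$wavelengths
    medium <- build_medium(
      dims_mm = as.numeric(med$dims_mm %||% c(60, 60, 30)),
      voxel_mm = med$voxel_mm %||% 1,
      background = prostate_like_spectra(),
      inclusion = inclusion_geometry(inc$shape %||% "cylinder",
                                     inc$radius_mm %||% 1,
                                     inc$depth_mm %||% 5),
      fluorophore = icg_like_fluorophore(
        config$fluorophore$concentration_uM %||% 1),
      n = med$n %||% 1.3, g = med$g %||% 0.8)
    cfg <- transport_config(
      n_photons = config$transport$n_photons %||% 1e5,
      seed = config$seed)
    res <- simulate_fluorescence(medium, cfg, wl$excitation_nm,
                                 wl$emission_nm)
    out <- file.path(out_dir, paste0(prefix, "_fluorescence.tif"))
    write_surface_tiff(res$surface, out, pixel_mm = medium$voxel_mm,
                       metadata = list(excitation_nm = wl$excitation_nm,
                                       emission_nm = wl$emission_nm,
                                       seed = config$seed,
                                       n_photons = cfg$n_photons))
    outputs <- out
  } else if (task == "invert") {
    spec <- do.call(ratio_model_spec, config$model %||% list())
    ch <- resolve_channels(config$channels, spec$convention)
    model <- linear_ratio_model(ch$target, ch$reference, spec)
    img1 <- read_surface_tiff(config$images$target)
    img2 <- read_surface_tiff(config$images$reference)
    lrm <- log_ratio_map(img1, img2, calib = config$calib %||% 1)
    dm <- depth_map(lrm, model)
    out <- file.path(out_dir, paste0(prefix, "_depth.tif"))
    write_surface_tiff(dm$depth * ifelse(dm$valid, 1, NA), out,
                       pixel_mm = dm$pixel_mm)
    stats <- profile_stats(dm, round(dim(dm$depth) / 2 + 0.5), c(0, 1))
    stats_out <- file.path(out_dir, paste0(prefix, "_stats.csv"))
    write.csv(stats, stats_out, row.names = FALSE, quote = FALSE)
    outputs <- c(out, stats_out)
  } else if (task == "study") {
    pairs <- if (!is.null(config$pairs)) {
      lapply(config$pairs, as.numeric)
    } else {
      list(as.numeric(config$pair %||% c(640, 760)))
    }
    cfg <- study_config(
      kind = config$kind, depths_mm = as.numeric(config$depths_mm),
      pairs = pairs, seed = config$seed,
      forward = config$forward %||% "analytic",
      radii_mm = as.numeric(config$radii_mm %||% c(0.5, 5)),
      shapes = config$shapes %||% c("cylinder", "sphere", "disk"))
    res <- switch(config$kind,
      depth_sweep = depth_sweep(cfg),
      geometry_size = geometry_size_study(cfg),
      property_perturbation = property_perturbation_study(cfg))
    out <- file.path(out_dir, paste0(prefix, "_results.csv"))
    write.csv(as.data.frame(res), out, row.names = FALSE, quote = FALSE)
    outputs <- out
  }

  resolved <- file.path(out_dir, paste0(prefix, "_config_resolved.yaml"))
  yaml::write_yaml(config, resolved)
  invisible(list(config = config, outputs = c(outputs, resolved)))
}
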