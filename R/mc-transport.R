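#' Excitation source specification
#'
#' @param type `"planar"` (uniform normal-incidence illumination over the full
#'   top surface, emulating wide-field epi-illumination), `"pencil"` (normal
#'   beam at the top center), or `"point"` (isotropic interior point source at
#'   `position`).
#' @param position For `"point"`: `c(x, y, z)` in mm.
#' @param power Source output power `S0` (arbitrary units, > 0); a pure scale
#'   factor that cancels in calibrated ratios.
#' @return List of class `fd_source`.
#' @export
source_spec <- function(type = c("planar", "pencil", "point"),
                        position = NULL, power = 1) {
  type <- match.arg(type)
  check_number(power, "power", positive = TRUE)
  if (type == "point") {
    check_number(position, "position")
    stopifnot(length(position) == 3L)
  }
  structure(list(type = type, position = position, power = power),
            class = "fd_source")
}

#' Photon transport configuration
#'
#' @param n_photons Photons launched per excitation pass (>= 1).
#' @param seed Integer seed; the same seed and configuration reproduce every
#'   tally bit-for-bit.
#' @param n_photons_emission Photons per emission pass (default
#'   `n_photons / 5`: emission photons all start inside the inclusion, so far
#'   fewer are needed for comparable image noise).
#' @param roulette_threshold Weight below which Russian roulette is played
#'   (in (0, 1)).
#' @param roulette_survival Survival probability of the roulette.
#' @param source A [source_spec()].
#' @return List of class `fd_transport_config`.
#' @export
transport_config <- function(n_photons = 1e6, seed = 1,
                             n_photons_emission = NULL,
                             roulette_threshold = 1e-4,
                             roulette_survival = 0.1,
                             source = source_spec("planar")) {
  check_number(n_photons, "n_photons", positive = TRUE)
  if (n_photons < 1) fd_stop("`n_photons` must be >= 1.", "fluordepth_invalid_input")
  check_number(seed, "seed")
  check_number(roulette_threshold, "roulette_threshold", positive = TRUE)
  check_number(roulette_survival, "roulette_survival", positive = TRUE)
  if (roulette_threshold >= 1 || roulette_survival > 1) {
    fd_stop("Roulette threshold must be < 1 and survival <= 1.",
            "fluordepth_invalid_input")
  }
  stopifnot(inherits(source, "fd_source"))
  structure(list(
    n_photons = as.numeric(n_photons), seed = as.integer(seed),
    n_photons_emission = as.numeric(n_photons_emission %||% max(1, n_photons / 5)),
    roulette_threshold = roulette_threshold,
    roulette_survival = roulette_survival,
    source = source
  ), class = "fd_transport_config")
}

mc_call <- function(medium, props, source_type, source_params, source_voxels,
                    source_cumw, n_photons, seed, cfg, record_absorption) {
  dims <- dim(medium$labels)
  .fd_mc_transport(
    labels = as.integer(medium$labels), dims = as.integer(dims),
    voxel_mm = medium$voxel_mm,
    mua_by_label = props$mua, mus_by_label = props$mus, g_by_label = props$g,
    n_rel = medium$n,
    source_type = source_type, source_params = source_params,
    source_voxels = source_voxels, source_cumw = source_cumw,
    n_photons = n_photons, seed = seed,
    roulette_threshold = cfg$roulette_threshold,
    roulette_survival = cfg$roulette_survival,
    record_absorption = record_absorption)
}

finish_mc_result <- function(raw, medium, props, wavelength_nm, pass, cfg,
                             seed, scale = 1) {
  dims <- dim(medium$labels)
  absorption <- NULL
  if (length(raw$absorption)) {
    absorption <- array(raw$absorption * scale, dim = dims)
  }
  ledger <- tibble(
    launched = 1 * scale,
    deposited = raw$deposited * scale,
    escaped_top = raw$escaped_top * scale,
    escaped_side = raw$escaped_side * scale,
    specular = raw$specular * scale,
    roulette_killed = raw$roulette_killed * scale,
    roulette_gained = raw$roulette_gained * scale,
    guard_killed = raw$guard_killed * scale
  )
  structure(list(
    surface = raw$surface * scale,
    absorption = absorption,
    ledger = ledger,
    wavelength_nm = wavelength_nm,
    pass = pass,
    props = props,
    pixel_mm = medium$voxel_mm,
    n_photons = raw$n_photons,
    seed = seed,
    scale = scale
  ), class = "fd_mc_result")
}

#' @export
print.fd_mc_result <- function(x, ...) {
  cat(sprintf(
    "<MC %s pass @ %g nm: %g photons, seed %d, image sum %.4g>\n",
    x$pass, x$wavelength_nm, x$n_photons, x$seed, sum(x$surface)))
  invisible(x)
}

#' Weight conservation ledger of a transport pass
#'
#' @param result An `fd_mc_result`.
#' @return One-row tibble of tallies plus `balance`, the relative deviation
#'   of (deposited + escaped + specular + roulette-terminated - roulette-gained)
#'   from the launched weight. Should be ~1e-12 for every run.
#' @export
weight_ledger <- function(result) {
  stopifnot(inherits(result, "fd_mc_result"))
  l <- result$ledger
  l$balance <- (l$deposited + l$escaped_top + l$escaped_side + l$specular +
                  l$roulette_killed + l$guard_killed - l$roulette_gained -
                  l$launched) / l$launched
  l
}

#' Run the excitation transport pass
#'
#' Launches `cfg$n_photons` photons from the configured source, transporting
#' them at the excitation wavelength's optical properties. Every interaction
#' deposits the fraction `mua/mut` of the photon weight into the absorption
#' map; weight leaving the top face is binned into a surface image (pixel =
#' voxel face). All tallies are normalized per unit launched weight.
#'
#' @param medium A [build_medium()] object.
#' @param cfg A [transport_config()].
#' @param wavelength_nm Excitation wavelength, nm.
#' @param bandwidth_nm Optional band-averaging bandwidth for resolving the
#'   background spectra (default: point evaluation).
#' @return An `fd_mc_result` with elements `absorption` (3D array),
#'   `surface` (matrix), and the conservation `ledger`.
#' @export
run_excitation <- function(medium, cfg = transport_config(), wavelength_nm,
                           bandwidth_nm = NULL) {
  stopifnot(inherits(medium, "fd_voxel_medium"),
            inherits(cfg, "fd_transport_config"))
  props <- medium_properties(medium, wavelength_nm, bandwidth_nm)
  src <- cfg$source
  source_type <- match(src$type, c("planar", "pencil", "point")) - 1L
  source_params <- if (src$type == "point") as.numeric(src$position) else numeric(3)
  raw <- mc_call(medium, props, source_type, source_params,
                 integer(0), numeric(0),
                 cfg$n_photons, cfg$seed, cfg, record_absorption = TRUE)
  finish_mc_result(raw, medium, props, wavelength_nm, "excitation", cfg,
                   cfg$seed)
}

#' Run the emission transport pass
#'
#' Uses the excitation pass's absorption map as the fluorescence source:
#' each inclusion voxel launches isotropic emission photons with probability
#' proportional to `absorbed_weight * muaf(lambda_x) / mua_voxel(lambda_x) *
#' Qf` (the fraction of locally absorbed excitation light taken up by the
#' fluorophore times the quantum yield). Transport runs at the emission
#' wavelength's properties; the returned surface image is normalized per
#' launched excitation photon.
#'
#' @param medium A [build_medium()] object.
#' @param excitation An `fd_mc_result` from [run_excitation()] on the same
#'   medium.
#' @param cfg A [transport_config()]; `n_photons_emission` photons are
#'   launched with seed `cfg$seed`.
#' @param wavelength_nm Emission wavelength, nm.
#' @param bandwidth_nm Optional band-averaging bandwidth.
#' @return An `fd_mc_result` (no absorption map recorded).
#' @export
run_emission <- function(medium, excitation, cfg = transport_config(),
                         wavelength_nm, bandwidth_nm = NULL) {
  stopifnot(inherits(medium, "fd_voxel_medium"),
            inherits(excitation, "fd_mc_result"),
            inherits(cfg, "fd_transport_config"))
  if (is.null(excitation$absorption) ||
      !identical(dim(excitation$absorption), dim(medium$labels))) {
    fd_stop("`excitation` must carry an absorption map on the medium's grid.",
            "fluordepth_configuration_error")
  }
  exc_props <- excitation$props
  inc <- medium$labels == 1L
  frac <- exc_props$muaf[2] / exc_props$mua[2] * medium$fluorophore$quantum_yield
  weights <- excitation$absorption[inc] * frac
  total <- sum(weights)
  if (total <= 0) {
    fd_stop("No absorbed excitation weight in the inclusion: empty emission source.",
            "fluordepth_empty_source_error")
  }
  vox_idx <- which(inc) - 1L # 0-based flat indices
  keep <- weights > 0
  vox_idx <- vox_idx[keep]
  cumw <- cumsum(weights[keep]) / total

  props <- medium_properties(medium, wavelength_nm, bandwidth_nm)
  raw <- mc_call(medium, props, 3L, numeric(3), vox_idx, cumw,
                 cfg$n_photons_emission, cfg$seed, cfg,
                 record_absorption = FALSE)
  res <- finish_mc_result(raw, medium, props, wavelength_nm, "emission", cfg,
                          cfg$seed, scale = total)
  res$source_weight <- total
  res$excitation_nm <- excitation$wavelength_nm
  res
}

#' Two-pass fluorescence simulation
#'
#' Composition of [run_excitation()] and [run_emission()]: the excitation
#' pass records where excitation light is absorbed, the emission pass
#' launches fluorescence from the fluorophore-weighted absorption map. The
#' emission pass uses seed `seed + 500009` so the two passes draw
#' independent streams.
#'
#' @inheritParams run_excitation
#' @param excitation_nm,emission_nm Wavelengths, nm.
#' @return The emission-pass `fd_mc_result`, with the excitation result
#'   attached as `$excitation_pass`.
#' @export
simulate_fluorescence <- function(medium, cfg = transport_config(),
                                  excitation_nm, emission_nm,
                                  bandwidth_nm = NULL) {
  exc <- run_excitation(medium, cfg, excitation_nm, bandwidth_nm)
  em_cfg <- cfg
  em_cfg$seed <- as.integer((cfg$seed + 500009) %% .Machine$integer.max)
  em <- run_emission(medium, exc, em_cfg, emission_nm, bandwidth_nm)
  em$excitation_pass <- exc
  em
}

#' Draw Henyey-Greenstein scattering cosines
#'
#' Diagnostic access to the transport kernel's phase-function sampler; the
#' sample mean of `cos(theta)` estimates the anisotropy `g`.
#'
#' @param n Number of draws.
#' @param g Anisotropy, -1 < g < 1.
#' @param seed Integer seed.
#' @return Numeric vector of sampled scattering cosines.
#' @export
sample_hg <- function(n, g, seed = 1) {
  check_number(n, "n", positive = TRUE)
  check_number(g, "g")
  if (abs(g) >= 1) fd_stop("`g` must satisfy -1 < g < 1.", "fluordepth_invalid_input")
  .fd_sample_hg(as.integer(n), g, as.integer(seed))
}
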