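#' Fluorescent inclusion geometry
#'
#' Depth `d` follows the shortest-distance convention: it is the distance
#' from the top surface (`z = 0`) to the nearest point of the inclusion
#' boundary, not to its center.
#'
#' @param shape `"cylinder"` (horizontal axis parallel to the surface,
#'   spanning the full lateral extent), `"sphere"`, or `"disk"` (flat
#'   vertical-axis cylinder of constant `thickness`).
#' @param radius Radius, mm (> 0).
#' @param depth Depth of the top boundary, mm (>= 0).
#' @param thickness Disk thickness, mm (default 1; ignored otherwise).
#' @param axis Cylinder axis direction, `"y"` or `"x"`.
#' @return List of class `fd_inclusion`.
#' @export
inclusion_geometry <- function(shape = c("cylinder", "sphere", "disk"),
                               radius, depth, thickness = 1,
                               axis = c("y", "x")) {
  shape <- match.arg(shape)
  axis <- match.arg(axis)
  check_number(radius, "radius", positive = TRUE)
  check_number(depth, "depth", nonnegative = TRUE)
  check_number(thickness, "thickness", positive = TRUE)
  structure(list(shape = shape, radius = radius, depth = depth,
                 thickness = thickness, axis = axis),
            class = "fd_inclusion")
}

resolve_background_spectrum <- function(x, wavelength_nm, bandwidth_nm) {
  if (is.numeric(x) && length(x) == 1L) return(x)
  sp <- as_fd_spectrum(x)
  if (is.null(bandwidth_nm)) {
    eval_spectrum(sp, wavelength_nm)
  } else {
    band_average(sp, wavelength_nm, bandwidth_nm)
  }
}

#' Build a labeled voxel medium
#'
#' Voxelizes a homogeneous background slab with one embedded fluorescent
#' inclusion. A voxel is labeled as inclusion iff its center lies inside the
#' analytic shape; the inclusion top boundary sits at `z = depth` and the
#' shape is laterally centered. If the radius is smaller than half a voxel the
#' voxel containing the shape center is labeled (point-like limit). Inside
#' the inclusion the absorption is background plus fluorophore
#' (`mua_inc = mua_bg + muaf`); scattering is that of the background.
#'
#' @param dims_mm Medium extents `c(x, y, z)`, mm.
#' @param voxel_mm Voxel edge length, mm.
#' @param background List with elements `mua` and `musp`, each either a
#'   [spectrum()] or a single number (mm^-1), e.g. [prostate_like_spectra()].
#' @param inclusion An [inclusion_geometry()].
#' @param fluorophore A [fluorophore_spec()] confined to the inclusion.
#' @param n,g Refractive index (relative to the outside) and anisotropy of
#'   the whole medium.
#' @return Object of class `fd_voxel_medium`; element `labels` is an
#'   integer array (0 background, 1 inclusion).
#' @export
build_medium <- function(dims_mm = c(60, 60, 30), voxel_mm = 1,
                         background = prostate_like_spectra(),
                         inclusion = inclusion_geometry("cylinder", 1, 5),
                         fluorophore = icg_like_fluorophore(),
                         n = 1.3, g = 0.8) {
  check_number(dims_mm, "dims_mm", positive = TRUE)
  check_number(voxel_mm, "voxel_mm", positive = TRUE)
  stopifnot(length(dims_mm) == 3L, inherits(inclusion, "fd_inclusion"),
            inherits(fluorophore, "fd_fluorophore"))
  nvox <- round(dims_mm / voxel_mm)
  if (any(abs(nvox * voxel_mm - dims_mm) > 1e-9)) {
    fd_stop("`dims_mm` must be integer multiples of `voxel_mm`.",
            "fluordepth_geometry_error")
  }
  nx <- nvox[1]; ny <- nvox[2]; nz <- nvox[3]

  vertical_extent <- switch(inclusion$shape,
    cylinder = 2 * inclusion$radius,
    sphere = 2 * inclusion$radius,
    disk = inclusion$thickness)
  lateral_need <- switch(inclusion$shape,
    cylinder = if (inclusion$axis == "y") inclusion$radius * 2 else 0,
    sphere = 2 * inclusion$radius,
    disk = 2 * inclusion$radius)
  if (inclusion$depth + vertical_extent > dims_mm[3] ||
      lateral_need > min(dims_mm[1:2])) {
    fd_stop("Inclusion does not fit inside the medium at the requested depth.",
            "fluordepth_geometry_error")
  }

  cx <- dims_mm[1] / 2; cy <- dims_mm[2] / 2
  xc <- (seq_len(nx) - 0.5) * voxel_mm
  yc <- (seq_len(ny) - 0.5) * voxel_mm
  zc <- (seq_len(nz) - 0.5) * voxel_mm
  r <- inclusion$radius
  d <- inclusion$depth
  labels <- array(0L, dim = c(nx, ny, nz))
  if (inclusion$shape == "cylinder") {
    zcen <- d + r
    if (inclusion$axis == "y") {
      disc <- outer((xc - cx)^2, (zc - zcen)^2, `+`) <= r^2 # nx x nz
      for (iy in seq_len(ny)) labels[, iy, ] <- labels[, iy, ] | disc
    } else {
      disc <- outer((yc - cy)^2, (zc - zcen)^2, `+`) <= r^2 # ny x nz
      for (ix in seq_len(nx)) labels[ix, , ] <- labels[ix, , ] | disc
    }
    center <- c(cx, cy, zcen)
  } else if (inclusion$shape == "sphere") {
    zcen <- d + r
    dist2 <- outer(outer((xc - cx)^2, (yc - cy)^2, `+`), (zc - zcen)^2, `+`)
    labels[] <- as.integer(dist2 <= r^2)
    center <- c(cx, cy, zcen)
  } else {
    inz <- zc >= d & zc <= d + inclusion$thickness
    disc <- outer((xc - cx)^2, (yc - cy)^2, `+`) <= r^2
    for (iz in which(inz)) labels[, , iz] <- labels[, , iz] | disc
    center <- c(cx, cy, d + inclusion$thickness / 2)
  }
  mode(labels) <- "integer"
  if (sum(labels) == 0L) {
    ci <- pmin(pmax(ceiling(center / voxel_mm), 1L), c(nx, ny, nz))
    labels[ci[1], ci[2], ci[3]] <- 1L
  }

  structure(list(
    labels = labels, dims_mm = dims_mm, voxel_mm = voxel_mm,
    background = background, fluorophore = fluorophore,
    inclusion = inclusion, n = n, g = g
  ), class = "fd_voxel_medium")
}

#' @export
print.fd_voxel_medium <- function(x, ...) {
  cat(sprintf(
    "<voxel medium %gx%gx%g mm @ %g mm, %s r=%g mm at depth %g mm (%d voxels)>\n",
    x$dims_mm[1], x$dims_mm[2], x$dims_mm[3], x$voxel_mm,
    x$inclusion$shape, x$inclusion$radius, x$inclusion$depth, sum(x$labels)))
  invisible(x)
}

#' Resolve per-label optical properties of a medium at a wavelength
#'
#' @param medium An [build_medium()] object.
#' @param wavelength_nm Wavelength, nm.
#' @param bandwidth_nm If non-`NULL`, band-average the background spectra over
#'   this bandwidth instead of point evaluation.
#' @return Tibble with one row per label (0 background, 1 inclusion) and
#'   columns `label`, `mua`, `musp`, `mus`, `g`, `muaf`.
#' @export
medium_properties <- function(medium, wavelength_nm, bandwidth_nm = NULL) {
  stopifnot(inherits(medium, "fd_voxel_medium"))
  mua_bg <- resolve_background_spectrum(medium$background$mua,
                                        wavelength_nm, bandwidth_nm)
  musp_bg <- resolve_background_spectrum(medium$background$musp,
                                         wavelength_nm, bandwidth_nm)
  muaf <- fluorophore_mua(medium$fluorophore, wavelength_nm)
  mus <- musp_bg / (1 - medium$g)
  tibble(
    label = c(0L, 1L),
    mua = c(mua_bg, mua_bg + muaf),
    musp = musp_bg,
    mus = mus,
    g = medium$g,
    muaf = c(0, muaf),
    wavelength_nm = wavelength_nm
  )
}
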