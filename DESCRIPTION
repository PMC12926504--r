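Package: fluordepth
Title: Ratiometric Fluorescence Depth Estimation in Turbid Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the depth of fluorescent inclusions embedded
    in optically turbid biological media from ratiometric surface fluorescence
    measurements. Implements diffusion-approximation forward models for
    dual-emission and dual-excitation wavelength strategies (infinite and
    semi-infinite geometries, point-like and planar epi-illumination sources),
    the image calibration and log-ratio inversion pipeline that turns paired
    fluorescence images into per-pixel depth maps, and a voxelized two-pass
    fluorescence Monte Carlo photon-transport simulator used as an independent
    forward oracle and synthetic-data generator. Ships synthetic prostate-like
    tissue spectra and an indocyanine-green-like fluorophore fixture so that
    depth-sweep, inclusion-geometry, and optical-property misestimation studies
    run without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
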