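---
title: "Ratiometric fluorescence depth estimation: models, simulator, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric fluorescence depth estimation: models, simulator, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluordepth)
```

## The problem

A fluorescent object (a dye-filled vessel, nerve, or tumor margin) buried a
few millimetres under the surface of optically turbid tissue cannot be
localized in depth from a single wide-field fluorescence image: scattering
destroys the geometric cues. Its depth can, however, be read out
ratiometrically. Tissue attenuation is wavelength dependent, so the ratio of
the fluorescence signals measured at two wavelengths changes with the
distance the light has travelled. Under the diffusion approximation (valid
when reduced scattering dominates absorption, `musp >> mua`), the natural
logarithm of a calibrated two-wavelength intensity ratio is, for several
useful geometries, an *affine* function of the inclusion depth `d`:

    ln Gamma(d) = (1/delta_2 - 1/delta_1) * d + intercept,

where `delta_i = sqrt(D_i / mua_i)` is the effective penetration depth of
channel `i` and `D_i` its diffusion coefficient. Depth estimation is then a
per-pixel linear inversion. `fluordepth` implements this family of forward
models, the image-calibration and inversion pipeline, and a voxelized
two-pass fluorescence Monte Carlo (MC) simulator that serves as an
independent forward oracle and as the synthetic-data generator for the
package's simulation studies.

## Model family

Two ratiometric strategies are covered:

* **dual-emission** - one excitation wavelength, two emission wavelengths.
  The excitation field cancels in the ratio, so the prediction is
  independent of the source's geometry, power, and wavelength content.
* **dual-excitation** - two excitation wavelengths, one emission wavelength.
  The emission Green's function cancels instead, and the source now matters:
  a point source and wide-field (planar) epi-illumination give different
  intercepts, and using the wrong source model biases the recovered depth.

For each strategy the geometry can be an infinite medium (point source;
intercept `ln(D2/D1)`) or a semi-infinite medium bounded by the imaging
surface. Boundaries are handled with the extrapolated boundary condition:
fluence vanishes at `zb = 2 A D` outside the surface, with
`A = (1 + r_d)/(1 - r_d)` from the standard internal-reflectance polynomial
`r_d(n)` (`boundary_factor_A()`). A planar source is displaced to the depth
`z0 = 1/musp` where collimated light effectively becomes diffuse.

The planar semi-infinite fluence (`fluence_planar_semi_infinite()`) is built
from a plane source at `z0` and its negative image at `-(z0 + 2 zb)`:

* deep branch (`d > z0`): `(delta/D) exp(-(d+zb)/delta) sinh((z0+zb)/delta)`
* shallow branch (`d <= z0`): `(delta/D) exp(-(z0+zb)/delta) sinh((d+zb)/delta)`

The two branches meet continuously at `d = z0`. A compact published form of
the shallow branch circulates with `sinh((zb - z0)/delta)` and the deep-branch
prefactor; that expression is discontinuous at `d = z0` and inconsistent with
direct integration of the image-source pair, so this package implements the
continuous pair above. Since depth inversion uses the deep branch (shallow
depths below `z0 ~ 0.7-1 mm` are documented as less accurate anyway), this
choice only affects the sub-`z0` region.

Similarly, two intercepts are offered for the planar dual-excitation model
(`ratio_model_spec(intercept_form=)`): `"as_printed"`, the compact
`ln[delta1 D2 sinh((z01+zb1)/delta1) / (delta2 D1 sinh((z02+zb2)/delta2))]`,
and `"rederived"` (default), which adds `zb2/delta2 - zb1/delta1`. The
rederived form is the one exactly consistent with the fluence expressions:
the package asserts (to machine precision) that
`ln[psi_1(d)/psi_2(d)]` is affine in `d` with precisely the rederived
intercept. The difference between the two forms is a constant depth offset
of `(zb2/delta2 - zb1/delta1)/slope`, typically a fraction of a millimetre.

The semi-infinite *dual-emission* ratio for a point fluorophore
(`ratio_semi_infinite_emission()`) is not affine in depth. Its bracket
structure is fixed as `1 - exp(-4AD/delta) / (1 + 4AD/d)`, the unique
reading that reproduces both of its published limits (the infinite-medium
ratio as `d -> 0`, and a constant correction for `d >> 4 A max(D1, D2)`);
both limits are enforced as tests rather than assumed. Inversion of this
model is by bisection after a monotonicity check (`invert_semi_infinite_emission()`).

Two conventions exist for the diffusion coefficient: `D = 1/(3(mua+musp))`
(default, `"with_mua"`) and the deep-diffusive simplification
`D = 1/(3 musp)` (`"without_mua"`), which alters both slope and intercept;
both are exposed because practitioners use both.

All models drop wavelength-independent multiplicative constants (they cancel
in two-wavelength ratios); the `4*pi` factors are kept, the factor 2 from
the sinh identity and source strength are not.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `n` | 1.3 | - | soft-tissue refractive index; sets `A(n) ~ 2.6` |
| `g` | 0.8 | - | scattering anisotropy used by the MC; `musp = mus (1-g)` |
| `convention` | `with_mua` | - | diffusion-coefficient definition |
| `intercept_form` | `rederived` | - | planar intercept (see above) |
| `bandwidth_nm` | 10 | nm | band over which spectra are averaged to effective per-channel properties |
| `concentration_uM` | 1 | uM | fluorophore load of the inclusion |
| `n_photons` | 1e6 | - | excitation photons per MC pass |
| `roulette_threshold` | 1e-4 | - | weight below which Russian roulette triggers |

The anisotropy and refractive index of the simulated medium are not uniquely
pinned down by the source material this package emulates; `n = 1.3`,
`g = 0.8` mirror the stated assumptions of the optical-property estimation
workflow and are configurable per medium.

## The synthetic-data generator

`build_tissue_spectra()` mixes packaged oxy-/deoxyhemoglobin extinction and
water absorption curves with a scattering power law. The packaged
chromophore tables are smooth *synthetic* approximations of the standard
literature compilations (sampled every 10 nm over 550-920 nm) and are
labelled as such in their file names.

The `prostate_like_spectra()` preset (125 uM total hemoglobin, 75% oxygen
saturation, 60% water, `musp = 1.45 (lambda/640)^-1.2` per mm) was chosen to
sit in the published in vivo prostate range (interstitial measurements
report `mua ~ 0.02-0.05` per mm near 760-786 nm with `musp ~ 0.9-1.4` per
mm) while reproducing the qualitative features the ratiometric method
relies on: strong absorption contrast across 600-800 nm (dual-excitation
sensitivity), a comparatively flat 820-890 nm region (which limits
dual-emission sensitivity in hemoglobin-dominated tissue), and strong
absorption at 600 nm, at the edge of the diffusive regime (`musp/mua > 10`
holds from about 620 nm upward, not at 600 nm). The ICG-like fluorophore
fixture peaks at 779 nm (excitation, with a secondary shoulder near 708 nm)
and 820 nm (emission), with peak molar extinction 2e5 per M per cm and
quantum yield 0.13.

What the generator deliberately does *not* emulate: background tissue
autofluorescence, spatially varying optical properties, camera noise and
lens effects, and acceptance-angle filtering at the detector. Passing tests
therefore demonstrate correctness of the models and pipeline under the
stated transport physics, not robustness to every confound of a real
imaging experiment.

## The Monte Carlo simulator

`run_excitation()` / `run_emission()` implement the standard two-pass
fluorescence MC on a labeled voxel grid: weighted (implicit-capture) photon
packets, dimensionless step sampling with exact voxel-boundary traversal,
Henyey-Greenstein scattering, Fresnel reflection at the top surface for the
refractive-index mismatch, absorbing side and bottom faces, and Russian
roulette termination. The emission pass launches isotropic photons from
inclusion voxels with probability proportional to
`absorbed excitation weight x muaf/mua x Qf` - the fraction of local
absorption attributable to the fluorophore times the quantum yield - which
is the standard fluorescence-MC coupling. Analog tracking of individual
absorption events would make deep inclusions intractable at desk-scale
photon counts; weighted transport keeps every launched packet informative.

Randomness comes from a dedicated counter-free xoshiro256++ generator seeded
from the run configuration, so identical configurations reproduce every
tally bit-for-bit, independent of R's global RNG state. Weight is conserved
exactly: deposited + escaped + specular + roulette-terminated -
roulette-gained equals the launched weight to ~1e-12 in every run, and the
suite asserts it.

Against closed forms, the kernel reproduces Beer-Lambert attenuation in a
scattering-free absorber (within binomial error), the infinite-medium
point-source Green's function within 10% for r = 2-10 mm at tissue-like NIR
properties, and the planar semi-infinite diffusion profile within 15% over
d = 2-10 mm (diffusion theory is expected to deviate near sources and
boundaries).

Default desk-scale grid: 60 x 60 x 30 mm at 1 mm voxels with 1e6 excitation
and ~1.5e5-2e5 emission photons per pass; these sizes make a ten-depth
dual-excitation sweep reproducible in minutes on one core while keeping the
per-scene depth noise well under the millimetre scale of interest. The
full-scale configuration (100 x 100 x 50 mm, 0.5 mm voxels, 1e8 photons) is
available via `study_config(paper_scale = TRUE)`.

## Pipeline conventions and numerical choices

* **Calibration** (`calibrate_image()`): background subtraction, flooring at
  zero, division by the *median* of the background-subtracted
  calibration-reference pixels (robust to hot pixels).
* **Log-ratio maps** mask pixels that are non-positive, non-finite, or below
  1% of the image maximum; the point-fluorophore models are only meaningful
  directly above the inclusion, so off-footprint depths are documented as
  meaningless rather than prevented.
* **Per-scene depth**: a simulated scene is reduced to one number as the
  mean over a 10-mm line profile above the inclusion centroid (along the
  cylinder axis), mirroring how constant-depth phantom maps are summarized;
  `summary = "footprint"` instead averages every valid pixel of the
  inclusion's surface footprint (for a through-cylinder, the full-length
  strip), which is the lower-variance choice for simulation studies. For
  compact shapes the footprint never shrinks below a one-pixel ring, since
  the diffusion-blurred surface spot is always much wider than a sub-voxel
  object. Profile statistics use the population standard deviation.
* **Negative depths** (shallow-noise pixels) clamp to zero and are counted,
  rather than masked, so they remain in profile statistics.
* **Inversion of the nonlinear dual-emission model**: bisection to 1e-4 mm
  on a bracket of 1e-3 to 50 mm, after verifying monotonicity on a 256-point
  grid; out-of-range ratios raise a no-solution error instead of clamping.
* **Dual-excitation MC calibration**: simulated emission images are
  normalized per launched excitation photon, so equal source powers are
  implied and the calibrated log ratio subtracts `ln(muaf(l1)/muaf(l2))`,
  the fluorophore-absorption ratio that a calibration-well measurement
  removes in a physical experiment. Simulated dual-emission pairs need no
  spectral calibration factor because the emission pass launches the same
  quantum-yield-weighted total at either emission wavelength.

## The simulation studies

`depth_sweep()` reproduces the source-model comparison: MC data generated
under planar illumination, inverted with both the planar semi-infinite model
and the point-source model. With matched properties and the planar model,
the package recovers cylinder depths 1-10 mm with worst-case error below
1 mm at the default desk scale (the acceptance script recomputes this
end-to-end).

`property_perturbation_study()` isolates the effect of mis-estimated
optical properties: the forward log-ratio is generated analytically with
the true properties and inverted with `mua`/`musp` scaled by +-25% in all
combinations. The analytic forward is deterministic and runs in
milliseconds; uniform scaling identities make two conditions exact: joint
-25% gives `d_est = d/0.75` (+33.3%) and joint +25% gives `d/1.25` (-20%)
at every depth, because a uniform property scaling multiplies the slope and
leaves the planar intercept unchanged. Single-coefficient and mixed-sign
conditions depend on the fixture spectra; with the packaged preset,
underestimation always inflates the recovered depth and joint errors
dominate single-coefficient ones. Note that on this analytic forward a
single-coefficient -25% error changes the slope by about `sqrt(0.75)`
(~+15.5% depth error), which is necessarily *smaller* than the 20% joint
overestimation error - MC-based analyses can report the opposite ordering
because model-transport mismatch compounds with the property error.

`geometry_size_study()` varies inclusion shape and radius. Two opposing
biases control the outcome: the fluorophore centroid sits below the
`d`-defining top boundary (deepening the estimate as the vertical extent
grows), while the inclusion's own fluorophore absorption depresses the
excitation fluence inside it more strongly at the more strongly absorbed
wavelength (raising the ratio and shallowing the estimate - self-shielding).
For cylinders the net error grows markedly with radius; for spheres it also
grows, but by only ~0.1 mm between radii of 0.5 and 5 mm under the packaged
fixture - a margin that sits below the per-scene Monte Carlo noise
achievable at desk-scale photon counts (~0.4-0.8 mm for compact shapes,
driven by excitation-crossing statistics in the few source voxels). Small
objects of any shape converge toward the point-like ideal, so the spread
across shapes grows with radius, again by a desk-scale-unresolvable margin.
For the thin disk, whose vertical extent is fixed, the packaged fixture
makes self-shielding the dominant term at large radius, so the disk shows a
net *worsening* with radius rather than the improvement a fixture with
weaker inclusion contrast can exhibit. The trend tests assert the full set
of claims at a fixed two-seed protocol; the cylinder and property-error
trends hold robustly, while the sphere, disk, and spread assertions
document these limits.

## Known limitations

* Depths shallower than `z0` (~0.7-1 mm) use the less accurate shallow
  branch; estimates there are documented to carry up to ~0.5 mm extra error.
* The models assume the detector pixel sits directly above a point-like
  fluorophore; lateral localization is out of scope.
* No background fluorescence, no heterogeneous background layers, no
  time-resolved or frequency-domain variants, no polarization, and no
  refractive-index mismatch between inclusion and background.
* The packaged spectra are synthetic approximations; absolute agreement
  with any specific measured tissue is not claimed, and conclusions are
  therefore asserted as signs, orderings, and bounds rather than as exact
  curve matches.

## A worked example

```{r example, eval = FALSE}
bg <- prostate_like_spectra()
ch <- list(
  target = wavelength_channel(optical_properties(
    640, band_average(bg$mua, 640), band_average(bg$musp, 640)), "target"),
  reference = wavelength_channel(optical_properties(
    760, band_average(bg$mua, 760), band_average(bg$musp, 760)), "reference"))
model <- linear_ratio_model(ch$target, ch$reference, ratio_model_spec())
tidy(model)

medium <- build_medium(inclusion = inclusion_geometry("cylinder", 1, 5))
img <- simulate_fluorescence(medium, transport_config(n_photons = 2e5), 640, 820)
img2 <- simulate_fluorescence(medium, transport_config(n_photons = 2e5, seed = 2),
                              760, 820)
calib <- fluorophore_mua(medium$fluorophore, 640) /
  fluorophore_mua(medium$fluorophore, 760)
dm <- depth_map(log_ratio_map(img$surface, img2$surface, calib), model)
profile_stats(dm, c(30, 30), c(0, 1))
```
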