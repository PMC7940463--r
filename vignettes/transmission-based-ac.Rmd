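---
title: "Transmission-based hardware attenuation correction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmission-based hardware attenuation correction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txac)
```

## The problem

Quantitative PET requires correcting emission data for photon attenuation.
On hybrid PET/MRI systems the patient tissue can be mapped with MR-based
segmentation, but hardware in the field of view — the patient table, the
posterior half of an RF array, phantoms holders — is invisible to MRI and
still removes up to ~9% of true counts along posterior lines of response.
The common workaround converts a CT scan of the hardware to 511 keV linear
attenuation coefficients (LAC, `mu`, cm^-1) with a bilinear Hounsfield-unit
model, but that model was calibrated for the air–water–bone range and a
polychromatic beam; for dense or high-Z hardware it systematically
mis-corrects.

`txac` implements the alternative this package is built around: measure the
hardware attenuation *with the PET system itself*, using a static Ge-68
line source fixed at the bore centre. Two acquisitions are taken — a
*blank* scan (source only, counts `I0`) and a *transmission* scan (source
plus hardware, counts `I`) — and the hardware LAC follows from the
Beer–Lambert law along every line of response (LOR):

    I(p) / I0(p) = exp( -sum_j mu_j(p) * l_j(p) )

where `j` indexes voxels and `l_j` is the partial path length of the LOR
through voxel `j`. With a registered binary hardware profile `b_j` on a
known voxel grid, the path lengths are computable geometry, and for
hardware that is homogeneous in density there is a single unknown `mu`:

    mu_hat = -ln(I / I0) / l,       l = sum_j b_j * l_j

estimated per LOR and aggregated. The estimate is then broadcast over the
profile to form the hardware mu-map used in reconstruction.

## Scanner model and LOR enumeration

The scanner is modelled as a cylinder of detector blocks: by default 8
rings of 56 blocks (block pitch 360/56 = 6.43 degrees, displayed as 6.4),
8 x 8 crystals per block, ring radius 328 mm, axial block pitch 32.25 mm —
the layout of a whole-body PET/MRI system. Parameters that scanner
descriptions often leave unstated (ring radius, crystal pitches) are
configurable and recorded in output provenance. Detectors can be modelled at crystal granularity or, for fast
simulation, at block granularity.

`enumerate_source_lors()` samples annihilation events uniformly along the
rod axis (the source is uniform and static) and pair directions on
stratified azimuth/inclination grids with a seeded random phase, then
snaps the two cylinder crossings to the nearest detector elements. Two
properties follow by construction and are enforced in tests:

* every returned LOR line passes within the source radius of the rod axis
  (at crystal granularity);
* for a centred source, choosing the azimuth count as a multiple of the
  block count makes the LOR multiset exactly invariant under rotation by
  one block pitch.

**Geometric weights.** Because the two annihilation photons travel along
one line, the acceptance of a detector *pair* is governed by the solid
angle of line directions subtending it, not by an inverse-square factor
per detector (that applies to single-photon transmission sources). The
blank forward model therefore weights each LOR by the fraction of sampled
emission lines that map to it (`weight_mode = "pair"`). A uniform weight
mode exists for controlled unit tests where exact per-LOR expectations are
wanted. Detector efficiency is a single scalar `sensitivity`; scatter,
randoms, dead time and attenuation inside the rod are intentionally out of
the forward model (scatter is assumed non-dominant for hardware and is
handled downstream in reconstruction, which is out of scope here).

Decay between the blank and transmission scans is available as
`decay_fraction()` (closed form `1 - 2^(-t/T_half)`; for Ge-68 and 7
minutes this is ~1.2e-5) but is not applied by default — at that magnitude
decay correction between the paired scans is justifiably ignored.

## Ray tracing

`trace_ray()` implements exact Siddon-style parametric traversal: all
voxel-face crossing parameters inside the grid box are merged and sorted,
interval midpoints identify voxels, interval lengths are the partial path
lengths. Conventions: 0-based voxel indexing; a voxel owns the half-open
interval `[edge, next edge)`; rays through an exact edge are resolved by
the interval midpoint, and slivers below 1e-9 mm are dropped. Total traced
length equals the ray–box chord to 1e-9 relative; rays missing the grid
return empty segments rather than an error; rays are terminated at the
detector cylinder face (no depth-of-interaction).

A `planar` fast mode flattens each LOR to its mean axial plane before
tracing, reflecting the near-central-source simplification that partial
path lengths change little across planes; the default is full 3-D tracing.

## The estimator

Per-LOR estimates `-ln(I/I0)/l` (lengths converted mm → cm exactly once)
are filtered and aggregated by `estimate_lac()`:

* `min_length` (default 5 mm): short chords amplify count noise into `mu`;
* `min_counts` (default 10 on both scans): starved LORs are unstable;
  zero-count transmission LORs are excluded and counted rather than
  clamped;
* aggregation: weighted mean with weights `l^2 * I`, the delta-method
  inverse variance of the per-LOR estimator; an unweighted mean is
  available for comparison;
* negative per-LOR estimates (noise pushing `I > I0`) are retained in the
  aggregate and flagged, so the estimator stays unbiased near `mu = 0`; a
  negative *aggregate* is refused at map assembly with advice to review
  the filters.

The reported uncertainty is the weighted SD of the retained per-LOR
estimates and is labelled as per-LOR spread (an aggregation convention
this package fixes explicitly, since mean ± SD shapes in the field do not
always state their population).

Sensitivity cancels in `I/I0`, so the estimate is invariant to any common
rescaling of both scans — tested as a property.

In a noiseless closed loop (simulate blank → attenuate → re-estimate) the
estimator is exact to machine precision for any profile, because forward
model and inversion share the same line integrals; this is the fixed-point
sanity check. With Poisson noise at ~1e3 expected counts per LOR over
~1e3 LORs, recovery is within 2% — the scale of the theory-vs-measured
gaps reported for this class of technique.

## Theoretical LAC from elemental tables

For validation against a material of known composition (the acrylic
cylinder, C5O2H8), `compound_mu()` evaluates the mixture rule
`LAC(E) = rho * sum_i w_i (mu/rho)_i(E)` from embedded elemental mass
attenuation tables for H, C and O (photoelectric, incoherent and coherent
components on a 9-point grid over 0.1–1.0 MeV, transcribed from the
standard published compilations; log-log interpolation within each
component). `lac_at_511()` then samples the compound LAC on 19 energies
uniformly spanning 0.1–1.0 MeV, least-squares fits a fourth-order
polynomial in energy and evaluates it at 0.511 MeV, reporting the fit R^2
over the sampled points:

```{r physics}
acrylic <- material("C5O2H8", density = 1.19)
lac_at_511(acrylic, include_coherent = FALSE)
lac_at_511(acrylic, include_coherent = TRUE)
compound_mu(material("H2O", 1.0), 0.511)
```

Choices made here, once: 19 uniform energies (the sampled range is fixed
by the method; the grid density is not critical — R^2 stays above 0.9995);
PMMA density 1.19 g/cm^3 (the standard handbook value for acrylic); the
polynomial is a smoother, not different physics, so the fitted value is
also required (in tests) to agree with direct log-log interpolation at
0.511 MeV within 1%. The quoted uncertainty of a fit is its residual SD
and is labelled as such. Note that the physical coherent-scattering
contribution at 511 keV is small (~0.0003 cm^-1 for acrylic); the
with/without-coherent difference is dominated by low energies, where
coherent scattering reaches ~3% of the total.

## The CT comparator

`hu_to_lac()` implements the bilinear model the technique is compared
against: linear from air (-1000 HU, 0 cm^-1) to water (0 HU, 0.096 cm^-1),
then a shallower kVp-dependent bone slope above 0 HU (default 140 kVp,
5.64e-5 cm^-1/HU), continuous at the breakpoint, clamped at the air floor.
Beam hardening and high-Z materials are deliberately not modelled: the
comparator is shipped faithfully limited, because those limitations are
exactly why a transmission-based method is preferable for dense hardware.

## Comparison metrics

* `rpd()`: voxel-wise relative percentage difference
  `(reference - test)/reference * 100` (positive = test under-corrects),
  with global mean ± SD, a per-plane profile, and exclusion (with counts)
  of voxels whose reference value is below 1e-6 of the reference maximum.
* `count_histogram()`: fixed-edge histograms with explicit out-of-range
  accounting (`sum(counts) + out_of_range = total`).
* `aha17()`: the standard AHA 17-segment reduction of a short-axis volume.
  The long axis between the caller's apex and base planes is split into
  basal/mid/apical thirds by plane count (remainder assigned base-first);
  basal and mid rings get six 60-degree sectors, the apical ring four
  90-degree sectors, all anchored at the caller-supplied anterior
  RV-insertion angle (the AHA standard requires this anchor; there is no
  sensible default orientation, so it is an explicit argument). Segment 17
  is the apical cap below the apex plane. Segment values are sector means
  over the masked voxels (not maximum-intensity radial samples — a
  documented convention); empty segments are `NA` and flagged, never zero.
* `regional_rpd()`: per-segment RPD averaged into apex/apical/mid/basal
  regions, the shape in which regional cardiac differences are reported.

## Synthetic data: what it does and does not emulate

The generator covers the geometry and counting statistics of the
technique: exact chord geometry through voxelized phantoms (cylinder
shells, slabs, or any supplied binary volume), Beer–Lambert attenuation,
Poisson counting noise, scalar sensitivity, decay. It does not emulate
scatter, randoms, detector energy response, block effects, positron range,
or reconstruction — so passing closed-loop tests demonstrates that the
geometry, forward model and inversion are self-consistent and
noise-robust, not that scanner data would be free of the corresponding
systematic effects. The scanner-measured quantities in this problem space
(count-loss fractions, in vivo RPDs) depend on physical acquisitions and
are therefore covered by property-based surrogates, not numeric
reproduction.

Problem sizes used in the shipped tests (chosen to exercise every code
path at desk scale): a 96 x 96 x 32 grid at 4 x 4 x 8 mm for closed loops
(the full 310 mm phantom still fits), block-granularity LOR enumeration
with ~1500–2500 unique LORs, and the native 344 x 344 x 127 grid at
2.09 x 2.09 x 2.02 mm where single-ray accuracy against the 9 mm wall is
asserted.

## Numerical and degenerate-input conventions

* Lengths are mm everywhere; conversion to cm happens exactly once, inside
  `estimate_lac()`; LAC is always cm^-1.
* Ties at voxel faces: resolved by interval midpoints; 1e-9 mm slivers
  dropped; duplicate voxels from tangent corner crossings aggregated.
* `I = I0` on every LOR gives estimate 0 exactly; "no LOR passes the
  filters" is an error, not a silent NaN.
* Phantom builders use voxel-centre membership with half-open intervals,
  so abutting phantoms never double-count a voxel; degenerate dimensions
  (zero wall, zero thickness) give empty profiles, not errors.
* Noiseless pipelines are bit-reproducible; Poisson pipelines are
  reproducible given the seed, and seeded helpers save and restore the
  caller's RNG state.

## Known limitations

Single-unknown homogeneity: one LAC per profile; hardware with regions of
very different density needs per-region profiles and separate runs.
Mobile or flexible hardware is out of scope (the method requires a
registered static profile). No TOF, no depth-of-interaction, no
normalization beyond a scalar, no scatter model. The AHA tooling assumes
the volume is already reoriented to short axis.
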