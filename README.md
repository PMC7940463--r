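# txac — transmission-based hardware attenuation correction for PET/MRI

Hardware in a PET/MRI field of view (the patient table, the posterior part
of an RF array) attenuates annihilation photons but is invisible to MRI, so
its 511 keV attenuation map cannot come from the MR-based tissue
segmentation. `txac` implements a transmission-based alternative to the
usual CT-derived maps: estimate the hardware linear attenuation coefficient
(LAC, μ, cm⁻¹) directly on the PET system from two scans of a static Ge-68
line source fixed at the bore centre — a *blank* scan without the hardware
(counts `I₀`) and a *transmission* scan with it (counts `I`).

For every line of response (LOR) the discrete Beer–Lambert law reads

    I(p) / I₀(p) = exp( − Σ_j μ_j(p) · l_j(p) )

with voxel index `j` and partial path lengths `l_j` obtained by exact
Siddon ray tracing through a binary hardware profile registered to the PET
voxel grid. For density-homogeneous hardware there is one unknown, so each
LOR gives `μ̂ = −ln(I/I₀)/l` with `l` the LOR's chord through the profile;
filtered, inverse-variance-weighted aggregation yields the hardware LAC,
which is broadcast over the profile into the μ-map used in reconstruction.

The package is the whole desk-scale workflow:

* **geometry** — cylindrical scanner model (8 rings × 56 blocks × 8×8
  crystals by default, block pitch 360/56 ≈ 6.4°) and enumeration of the
  LORs subtended by a static line source;
* **raytrace** — exact per-voxel path lengths (Siddon) and masked chord
  lengths through binary hardware profiles;
* **simulate** — blank/transmission forward model with optional Poisson
  noise, Ge-68 decay bookkeeping, and cylinder-shell / slab phantom
  builders (default shell: 310 mm outer diameter, 9 mm wall, 210 mm long);
* **mumap** — the Beer–Lambert inversion, filters, diagnostics and μ-map
  assembly;
* **physics** — theoretical compound LAC at 511 keV from embedded H/C/O
  mass-attenuation tables via a fourth-order polynomial fit over
  0.1–1.0 MeV (the validation route for materials of known composition,
  e.g. acrylic C₅O₂H₈);
* **ctac** — the bilinear HU→LAC comparator (continuous at 0 HU,
  kVp-dependent bone slope);
* **analysis** — voxel-wise relative percentage difference (RPD), count
  histograms, AHA 17-segment polar maps and regional RPDs;
* **io** — NIfTI-1 volumes, columnar CSV sinograms, YAML run configs, a
  provenance-stamped `run_pipeline()`, and a thin CLI
  (`inst/cli/txac.R`) with `pipeline`, `theory`, `ctac`, `compare` and
  `polar` subcommands.

## Worked example

Closed-loop validation on the acrylic-cylinder phantom: simulate a blank
and a transmission scan of the 310 mm shell with true μ = 0.10698 cm⁻¹,
Poisson noise, then re-estimate the LAC and assemble the μ-map.

```r
library(txac)
cfg <- list(
  seed = 42,
  grid = list(dims = c(96L, 96L, 32L), voxel_size = c(4, 4, 8)),
  phantom = list(type = "cylinder_shell", mu = 0.10698),
  acquisition = list(duration = 300, sensitivity = 2.5e-4, noise = "poisson"),
  lor_sampling = list(sampling = 0.08, n_polar = 8L, detail = "block"),
  output_dir = "demo_out")
res <- run_pipeline(cfg)
print(res$estimate)
print(res$mumap)
```

```
LAC estimate: 0.10544 +/- 0.02479 cm^-1 (1288 of 1344 LORs used, invvar weighting)
  filters: min length 5 mm, min counts 10; 56 short-chord, 0 zero-TX, 9 negative per-LOR estimates
mu-map on 96 x 96 x 32 grid; 14664 non-zero voxels, mean LAC 0.10544 cm^-1
  method: tx-based
```

The point estimate recovers the true 0.10698 cm⁻¹ within 1.5% at these
count levels (noiselessly the loop closes to machine precision); the
± value is the spread of the per-LOR estimates, and the filter line
reports how many LORs were dropped for short chords or low counts. The
theoretical reference for acrylic comes from the physics module:

```r
lac_at_511(material("C5O2H8", density = 1.19), include_coherent = FALSE)
```

```
LAC at 0.511 MeV (excluding coherent): 0.11062 cm^-1
  degree-4 fit over 19 energies in [0.1, 1] MeV: R^2 = 0.999777, residual SD = 0.00053 cm^-1
```

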