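# opticart

Inverse Monte Carlo estimation of articular cartilage optical properties
from integrating-sphere spectra.

## What it does

Diffuse optical spectroscopy of cartilage measures, per wavelength, a
diffuse reflectance R and a total transmittance T. The tissue properties
of interest — the absorption coefficient μa (mm⁻¹) and the reduced
scattering coefficient μs′ = μs(1 − g) (mm⁻¹) — have to be inferred by
inverting a forward model of the whole measurement construct: a
cartilage cylinder (≈14 mm diameter, 0.5–3 mm thick) between glass
windows, with air or water filling the lateral gap to the holder wall.

`opticart` provides:

* a 3D weighted-photon **Monte Carlo forward model** (C++) of that
  construct — Henyey–Greenstein scattering, unpolarized Fresnel
  boundaries, absorbing holder wall, optional oblique-cut and
  Lambertian-rough bottom face — with exact energy bookkeeping and
  per-photon seeded streams (common random numbers across experiments);
* **lookup-table inversion**: R/T surfaces over a (μa, μs′) grid,
  bicubic interpolation on log axes, standard-error-weighted
  least-squares inversion with boundary flagging;
* a **theoretical absorption reference** (volume-fraction mixture of
  water/collagen/elastin/lipid at 68/30/1/1%) and the observation-removal
  **QC filter** for distorted spectra (absorption floor 1e-5 mm⁻¹,
  flatness, missing water features);
* **sensitivity analyses**: surrounding medium (air vs water),
  anisotropy factor g ∈ {0.8, 0.9, 0.99}, refractive index 1.3–1.5,
  bottom-surface roughness, and volume-irregularity correlation
  (Pearson/Spearman gated on a Shapiro–Wilk normality check);
* a **synthetic cohort generator** (per-site cylinders, jittered mixture
  fractions, power-law μs′, volume irregularity up to 18%, multiplicative
  measurement noise) so the whole pipeline runs end to end without
  instrument data.

## Worked example

Forward-simulate a 2 mm cartilage-like sample, build a small lookup
table, and invert the measurement back to optical properties:

```r
library(opticart)

con <- sample_construct(sample_thickness = 2)     # 14 mm plug, air gap
props <- optical_properties(mu_a = 0.05, mu_s = 15, g = 0.9, n = 1.358)
rt <- simulate_rt(props, con, n_photons = 1e5, seed = 1)
rt
#> <RTResult> R=0.3672 (se 1.3e-03)  T=0.2477 (se 1.1e-03)  A=0.2627  side=0.0769  [N=100000, seed=1]

grids <- default_grids(12, 12, mu_a_range = c(1e-3, 1), mu_s_range = c(0.3, 5))
lut <- build_lut(grids$mu_a, grids$mu_s_prime, con,
                 g = 0.9, n_sample = 1.358, n_photons = 2e4, seed = 1)
invert_rt(rt$R_diffuse, rt$T_total, lut)
#> <InversionResult> mu_a=0.05005 mu_s'=1.505 mm^-1 (residual 2.95e-11)
```

About 37% of the light returns diffusely, 25% is transmitted, 26% is
absorbed in the sample and 8% is lost to the holder wall. The inversion
recovers the truth (μa = 0.05 mm⁻¹, μs′ = 1.5 mm⁻¹) to 0.09% and 0.31%
here; `residual` is the standard-error-weighted
squared misfit and an `on_boundary` flag would mark estimates pinned to
the grid edge. `invert_spectrum()` applies this per wavelength,
`mixture_absorption()` / `qc_filter()` give the theoretical reference
and the keep/remove decision, and `g_sensitivity()`,
`medium_sensitivity()`, `n_sensitivity()`, `roughness_experiment()` and
`volume_correlation()` run the sensitivity analyses.

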