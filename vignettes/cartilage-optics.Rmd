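---
title: "Estimating cartilage optical properties by inverse Monte Carlo"
author: "opticart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cartilage optical properties by inverse Monte Carlo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Integrating-sphere spectroscopy measures two numbers per wavelength for a
tissue sample: the diffuse reflectance $R(\lambda)$ and the total
transmittance $T(\lambda)$. Neither is an intrinsic tissue property. The
quantities of interest — the absorption coefficient $\mu_a$ (mm$^{-1}$)
and the reduced scattering coefficient
$\mu_s' = \mu_s (1 - g)$ (mm$^{-1}$) — must be *inferred* by inverting a
forward model of light transport through the whole measurement construct:
the cartilage cylinder, the glass windows that hold it, and the air or
water filling the lateral gap between sample and holder wall.

`opticart` implements that pipeline for articular cartilage plugs
(cylinders of roughly 14 mm diameter and 0.5–3 mm thickness, drilled from
the joint surface) over the 400–1400 nm band, together with the
sensitivity analyses that ask how strongly the recovered properties
depend on choices the experimenter cannot fully control: the surrounding
gap medium, the assumed scattering anisotropy factor $g$, the assumed
refractive index $n$, the roughness of the detached bottom face, and the
deviation of the sample's true volume from a perfect cylinder.

## Forward model

Photon transport is a weighted Monte Carlo in full 3D cylinder geometry
(`simulate_rt()`, implemented in C++):

* A collimated top-hat beam (default radius 1 mm) enters at normal
  incidence through the top window.
* Free paths are exponential in $\mu_t = \mu_a + \mu_s$; at each
  interaction a fraction $\mu_a/\mu_t$ of the packet weight is deposited
  and the direction is deflected by the Henyey–Greenstein phase function
  $$p(\theta, g) = \frac{1}{4\pi}\,
    \frac{1-g^2}{\left(1+g^2-2g\cos\theta\right)^{3/2}},$$
  sampled by its closed-form inverse CDF; the azimuth is uniform (the
  phase function is azimuthally symmetric).
* Every index step (ambient/glass, glass/sample, sample/gap at the
  lateral cylinder wall, glass/ambient) applies unpolarized Fresnel
  reflection or Snell refraction, including total internal reflection.
* The holder wall is treated as perfectly absorbing; weight reaching it
  is tallied as `side_loss`.
* Packets below weight $10^{-4}$ play Russian roulette (survival 0.1).
  The net roulette adjustment is kept in its own tally, so the seven
  tallies of an `RTResult` sum to 1 exactly — energy bookkeeping is a
  hard invariant, tested to $10^{-9}$.
* `R_diffuse` excludes the specular return of the never-scattered beam;
  `T_total` includes the ballistic component. Collection is ideal: all
  escaping diffuse weight counts, with no port geometry. The instrument's
  sphere-throughput and detector model is deliberately out of scope; for
  raw-count workflows a substitution calibration against a reference
  standard (`calibrate_substitution()`) is provided instead.

Randomness comes from a xoshiro256++ generator seeded per photon from
(run seed, photon index). Photon $i$ therefore sees the same stream in
every simulation sharing a seed, which gives *common random numbers*
across lookup-table nodes and across sensitivity arms: differences
between arms are systematic, not Monte Carlo noise. The same property
makes every result bit-reproducible from its recorded seed.

## Lookup-table inversion

`build_lut()` simulates $R$ and $T$ on a $(\mu_a, \mu_s')$ grid
(default: 20 log-spaced nodes over $[10^{-4}, 5]$ and $[0.05, 10]$
mm$^{-1}$, spanning the literature range for cartilage) for one geometry,
$g$ and $n$, converting $\mu_s = \mu_s'/(1-g)$. The table does not
depend on wavelength, so one table serves a whole spectrum at fixed
geometry.

`invert_rt()` minimizes
$$\left(\frac{R(\mu_a,\mu_s') - R_\mathrm{meas}}{\sigma_R}\right)^2 +
  \left(\frac{T(\mu_a,\mu_s') - T_\mathrm{meas}}{\sigma_T}\right)^2$$
over surfaces interpolated by separable cubic splines ("bicubic") on
log$_{10}$-parameter axes, with Nelder–Mead started at the best grid
node. The weights $\sigma_R, \sigma_T$ are the Monte Carlo standard
errors at that node, floored at $10^{-4}$ to avoid division blow-up.
Estimates that end on the grid hull are flagged `on_boundary` rather
than trusted. Interpolation on the log axes keeps the surfaces gentle;
on a smooth closed-form surface the interpolation error is below
$10^{-4}$ absolute and node-exact pairs invert to machine tolerance
(both tested).

Numerical edge cases: $(R, T) = (0, 0)$ has no interior optimum and is
flagged on the boundary; $R + T > 1$ is unphysical and produces a
warning before an attempted fit; ties in the residual resolve toward
the starting node, which for flat low-absorption basins is the smaller
$\mu_a$ node.

## Theoretical absorption reference and quality filter

Cartilage absorption is modeled as a volume-fraction-weighted mixture of
its constituents,
$$\mu_{a,\mathrm{theoretical}} =
  \mu_{a,\mathrm{water}} V_\mathrm{water} +
  \mu_{a,\mathrm{collagen}} V_\mathrm{collagen} +
  \mu_{a,\mathrm{elastin}} V_\mathrm{elastin} +
  \mu_{a,\mathrm{lipid}} V_\mathrm{lipid},$$
with default fractions 0.68 / 0.30 / 0.01 / 0.01. The bundled component
spectra are *synthetic stand-ins* generated in code
(`synthetic_component_library()`): a water-like curve with bands near
970 and 1200 nm rising steeply toward 1400 nm, and smooth monotone
collagen/elastin/lipid curves of realistic magnitude. Digitized
literature spectra can be substituted through
`read_component_library()` without touching the rest of the pipeline.

`qc_filter()` operationalizes the observation-removal rule for distorted
signals with three declared, configurable criteria: any value at or
below $10^{-5}$ mm$^{-1}$ (`below_floor`); coefficient of variation of
the spectrum below 0.05 (`flat_signal`, the flattening criterion); and
Pearson correlation with the mixture reference over 900–1400 nm below
0.5 (`missing_features` — the water bands dominate that window, so a
spectrum lacking them decorrelates). The flatness and feature thresholds
are surrogates chosen here; they are parameters, not constants.

## Sensitivity analyses

All sensitivity results are *relative differences in percent*,
$100\,(x - x_\mathrm{ref})/x_\mathrm{ref}$, with the reference always
the second argument (the theoretical mixture, or the $g = 0.9$ /
smooth-surface / $n = 1.358$ arm), summarized per wavelength as median
with first/third quartile bands across samples.

* `g_sensitivity()` inverts one record with tables built at
  $g \in \{0.8, 0.9, 0.99\}$ (the physiologically plausible
  forward-scattering range; $g$ is treated as wavelength-independent
  within a run because its dispersion is unknown for cartilage).
* `medium_sensitivity()` compares inversions assuming an air gap
  ($n = 1$, transparent) versus a water gap ($n = 1.33$, absorbing with
  the water spectrum).
* `n_sensitivity()` sweeps the assumed sample index over 1.3–1.5 around
  the 1.358 baseline.
* `roughness_experiment()` contrasts a smooth bottom face with a
  maximally rough one. Maximal roughness is modeled microfacet-style:
  the surface decorrelates the photon direction, the Fresnel split is
  decided at a cosine-weighted local incidence angle, and both branches
  leave with a Lambertian direction. Among the candidate
  idealizations this is the one that behaves correctly in the bare-slab
  limit, where roughness defeats total internal reflection instead of
  leaving the light untouched or trapping it perfectly.
* `volume_correlation()` tests the per-sample association between
  volume deficit and absorption deviation, using Pearson's correlation
  when both variables pass a Shapiro–Wilk normality gate at
  $\alpha = 0.05$ and Spearman's rank correlation otherwise. A
  location test cannot assess normality, so a dedicated normality test
  is used for the gate by design.

A structural caveat the package makes visible rather than hiding:
at wavelengths where $\mu_a d \ll 1$ (for the mixture reference,
$\mu_a \approx 3\times10^{-3}$ mm$^{-1}$ near 850 nm and $d = 2$ mm),
$T$ is almost insensitive to $\mu_a$, so *any* systematic forward-model
mismatch — a wrong $n$, an unmodeled rough interface — is amplified into
large relative excursions of the recovered $\mu_a$. The quartile bands
and the `on_boundary` flags are the instruments for judging those
regions. The reduced scattering coefficient, by contrast, is well
constrained everywhere, which is exactly the robustness ordering the
sensitivity suite checks.

## Synthetic cohorts

`generate_cohort()` emulates the study conditions end to end so the
pipeline is testable without instrument data: per-site groups (FL, FM,
PL, PM, TL, TM) of cylinders with thickness uniform in 0.5–3 mm and
14 mm diameter; mixture absorption with volume fractions jittered
(SD 0.02, renormalized); power-law reduced scattering
$a(\lambda/500)^{-b}$ with $a \in [1.0, 2.5]$ mm$^{-1}$ and
$b \in [0.5, 1.5]$; $g = 0.9$, $n = 1.358$; and a relative volume
deficit drawn uniformly from $[-0.18, 0]$ — the bound adopted from the
volume-segmentation error of the imaging protocol — realized
geometrically as an oblique planar cut of the bottom face, so transport,
not just bookkeeping, feels the irregularity. Measurement noise is
multiplicative log-normal with CV 0.02 on $R$ and $T$ independently
(the instrument noise model is not documented; a multiplicative model
is the standard choice for ratio-calibrated spectra).

What the generator does *not* emulate: real chromophore spectra (the
component library is synthetic), depth-varying collagen orientation and
anisotropic scattering, instrument stray light and sphere-throughput
errors, and freeze–thaw structural changes. Passing round-trip tests on
these cohorts therefore demonstrates the *estimator's* correctness and
conditioning, not the accuracy of any particular published tissue value.

## Problem sizes and budgets

The package's own experiments use desk-scale sizes, chosen once: a
50 nm default wavelength grid (21 points over 400–1400 nm; the
instrument's 3–7 nm resolution is a config option, not a default),
lookup tables of 10–15 nodes per axis on a locally refined grid
covering the truth with margin, $2\text{–}4\times10^4$ photons per node
($2\times10^4$ at $g = 0.99$, where $\mu_s = 100\,\mu_s'$ makes nodes
costly), and $10^5$ photons per forward spectrum point. At these sizes
the anisotropy-swap experiment resolves sub-percent systematic
differences because of the common-random-number design.

## Known limitations

* Ideal sphere collection; no port losses or throughput model.
* $g$ and $n$ are wavelength-independent within a run.
* The holder wall is perfectly absorbing — a conservative bound on
  lateral losses.
* Inversion is per-wavelength; no spectral smoothness constraint ties
  neighboring wavelengths together.
* The recovered $\mu_a$ is structurally ill-conditioned where
  $\mu_a d \ll 1$, as discussed above; bounds quoted for sensitivity
  experiments depend strongly on how much of that region the evaluation
  band includes.
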