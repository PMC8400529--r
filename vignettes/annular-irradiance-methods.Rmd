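---
title: "Annular irradiance as a proxy for the diffuse attenuation coefficient: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annular irradiance methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the radiometric
quantities it computes, the synthetic radiance model behind its
simulation grid, the numerical conventions, and the design choices that
were genuinely open — together with what the passing test suite does and
does not establish about real-world data.

## 1. Radiometric model

### Quad geometry

All integrations run on a fixed discretization of the downward
hemisphere, with the polar angle θ measured from the downward vertical:
a polar cap (0–5°, a single quad spanning all azimuths), eight 10°
measurement bands (5–15° … 75–85°, labelled by their centres 10°…80°),
an equator band (85–90°), and 24 azimuth bins of 15°. Per band the grid
stores the polar thickness `dθᵢ = cos θ_lower − cos θ_upper`, so a quad's
solid angle is `dθᵢ·dφ` with `dφ = 2π/24 ≈ 0.2618 rad`, and the polar
cap's is `2π(1 − cos 5°)`. The quads close the hemisphere to 2π within
10⁻¹² by construction.

### Planar and annular irradiance

Planar downwelling irradiance weights each quad by the **exact band mean
cosine** `μ̄ᵢ = (cos²θ_lower − cos²θ_upper)/(2 dθᵢ)` rather than
`cos(θ_center)`. This is the standard quad-averaging convention and it
makes two closed forms exact, which the tests exploit: an isotropic
radiance L integrates to exactly πL, and the cosine-weighted solid angle
of the hemisphere is exactly π. Annular irradiance `Ea(θᵢ)` is the band's
radiance summed over its 24 azimuth quads times the quad solid angles,
with **no cosine factor**: the sensor ring is normal to the θ direction,
so every photon in the band hits it head-on. The alternative,
cosine-weighted reading of "irradiance" was rejected on that geometric
ground. Ea is defined only for the eight 10°–80° bands; the cap and the
equator band exist in the grid (and participate in planar integration)
but are not measurement rings. Ea's units follow the defining sum —
radiance × solid angle, W m⁻² nm⁻¹ per band.

A useful exact identity links the two: summing `μ̄ᵢ ×` (band integral)
over all ten bands reproduces planar Ed to machine precision — planar
irradiance is a fixed cosine-weighted combination of annular integrals.

### PAR

Spectral irradiance reduces to PAR quantum flux (mol quanta s⁻¹ m⁻²) by a
rectangle band sum of `E(λ)·Δλ·λ/(hc·N_A)` over 400–700 nm. Band widths
are taken from the wavelength grid, so the two end points carry half
bands (2.5 nm on the default 5 nm grid); with that convention a flat
1 W m⁻² nm⁻¹ spectrum integrates to 1.3793 × 10⁻³ mol quanta s⁻¹ m⁻²,
identical to the closed-form integral. The source quantities are band
averages, which is why a rectangle sum (not a trapezoid) is the right
quadrature.

### Attenuation estimators

Two estimators of the diffuse attenuation coefficient are provided: the
two-depth formula `K̄ = ln(E₁/E₂)/(z₂−z₁)` and minus the slope of the
ordinary least-squares regression of ln E on z (unweighted, as is
standard for profile data). They coincide exactly on pure exponentials;
all profile analyses use the regression form. A depth range "0–x m" means
every grid depth ≤ x: the depth grid starts at 0.02 m, so depth 0 never
enters a fit. Broadband (PAR) K is computed from PAR-integrated
irradiances, not by averaging spectral K — the broadband decay rate is a
property of the integrated profile and is dominated, at depth, by the
most penetrating wavelengths. For exactly that reason broadband K in
absorbing waters sits well below the surface-PAR-weighted mean of the
spectral coefficients; the tests assert the bracketing property (broadband
K lies inside the spectral range) rather than a naive weighted-mean
identity, and use spectrally narrow fields when exact recovery is the
point.

## 2. The synthetic radiance generator

The simulation grid that drives all assessments needs radiance fields
with the structure that radiative-transfer output has in infinitely deep,
homogeneous water under a flat surface. The generator is parametric and
deterministic; it is **not** a transfer solver, and its role is to be a
controlled, internally consistent stand-in.

### Bio-optics

Seven reference water classes (ultra clear, very clear, clear, moderate,
turbid, very turbid, brown) are defined by low/high concentrations of
chlorophyll (mg m⁻³), CDOM absorption at 380 nm (m⁻¹) and suspended
minerals (g m⁻³). One class row in the source table lists its pair in
reversed order (a "max" smaller than its "min"); the pairs are therefore
treated as unordered {low, high} sets. Constituents map to inherent
optical properties through a standard-magnitude case-2 parameterization:
pure-water absorption from a built-in 10 nm table of published values
(interpolated to the working grid) and molecular scattering with the
λ⁻⁴·³² law; a two-Gaussian chlorophyll-specific absorption spectrum
(0.05 m² mg⁻¹ at 440 nm, secondary peak at 675 nm); CDOM slope
0.014 nm⁻¹; mineral absorption 0.03 m² g⁻¹ at 443 nm with slope
0.011 nm⁻¹; particulate scattering 0.30 m² mg⁻¹ (phytoplankton) and
0.50 m² g⁻¹ (mineral) at 550 nm with 1/λ shape; particulate backscatter
ratio 0.018. The exact values matter for realism, not for any headline
statistic: every attenuation and ratio quantity is scale-free or
normalised.

### Lighting

The above-surface solar zenith angle refracts through a flat interface
(n = 1.34), so the whole sky folds into Snell's window, a cone of
half-angle ≈ 48.27°. Cloud cover c maps to a diffuse fraction
`f_dif = min(1, c + 0.15(1 − c))` — monotone, with 15% clear-sky
skylight — and the diffuse stream carries a mean cosine μ_dif = 0.83.
The effective mean cosine `μ_eff = (1−f_dif)·cos θ_sw + f_dif·μ_dif`
yields the generator's ground-truth attenuation
`Kd = (a + b_b)/μ_eff`, non-decreasing in zenith angle, cloud cover and
every constituent.

### The field

Radiance on the quad grid is the sum of two components:

- a **direct lobe**: a Gaussian in the great-circle angle ψ from the
  refracted sun direction (sun azimuth fixed at φ = 0 — legitimate
  because every downstream quantity integrates over all azimuths), with
  width σ(z,λ) = 5° + 3°·b(λ)·z capped at 40°, mimicking
  multiple-scattering broadening toward the asymptotic distribution. The
  lobe rides on a window-filling pedestal (30% relative weight, same
  shape as the diffuse background): physically, a collimated beam in
  water is always accompanied by a broad forward-scattered aureole, and
  without the pedestal the radiance in bands on the lobe's shoulder
  would start from near zero and produce log-slope transients of several
  m⁻¹ as σ grows — an artifact of a Gaussian's quadratic log-tail, not a
  feature of transfer solutions;
- a **diffuse background**: the cardioid 1 + 2cos θ multiplied by a
  smooth Snell-window transmission factor, a logistic edge at 48.27°
  whose softness grows as 3° + 1.5°·b(λ)·z (capped at 20°) — skylight is
  refraction-compressed into the window, and in-water scattering
  gradually fills the outside angles with depth.

Both components are renormalised at every depth so that their planar
irradiance decays **exactly** as `exp(−Kd·z)` with the two-stream rate
above, and the surface planar irradiance partitions as
(1−f_dif) : f_dif of a 5800 K blackbody reference spectrum (1 W m⁻² nm⁻¹
at 550 nm; the absolute scale cancels everywhere). Making the nominal
attenuation the actual decay is a deliberate property of a validation
fixture: log-linear regression recovers `kd_true` exactly at every
wavelength, so any disagreement between Ka and Kd downstream is
attributable to the one thing that differs between bands — the angular
redistribution of radiance with depth. An earlier design with separate
direct/diffuse decay rates was rejected because the regression estimate
of such a two-exponential mixture drifts with the fitting range and
misses its own nominal truth by up to ~9% in turbid water.

Optional multiplicative log-normal noise (mean 1, relative sd
`noise_sd`) is applied per quad under a per-scenario seed derived from a
base seed by a running counter; the default pipelines are noise-free and
fully deterministic, and the RNG state is isolated and restored.

### What the generator does and does not emulate

It reproduces: near-exponential decay, the sun-peaked lobe inside
Snell's window, azimuthal uniformity under overcast sky, the collapse of
Ea beyond ~60°, lobe broadening and window softening with scattering
optical depth, and exact ground-truth recoverability. It omits: rigorous
multiple scattering, Raman scattering and chlorophyll/CDOM fluorescence
(which brighten red wavelengths at depth in real water), wave focusing,
bottom reflection, and stratification. Consequently, passing tests
demonstrate that the *method* — quadrature, attenuation fitting,
slope-based reconstruction, error mapping — behaves correctly on fields
with the assumed structure; they do not certify error magnitudes for
field data. One known location difference: with this generator the
strongest Ka40 degradation in turbid water occurs where the *refracted*
solar angle (≈40°) falls inside the 35–45° ring, i.e. at an
above-surface zenith near 60°, whereas transfer-model studies report it
near an above-surface 40°; the mechanism (sun aligned with the ring) is
the same, the location differs by the refraction mapping.

## 3. The simulation grid and analyses

The full grid crosses 7 water classes × 8 concentration corners (the
low/high corner of each of the three constituents — corners rather than
interior samples keep the design at 56 water points) × 9 solar zenith
angles (0–80° by 10°) × 6 cloud covers (0–100% by 20%) = 3024 scenarios;
the optimal-angle and scatter analyses restrict to zenith ≤ 60°
(2352 scenarios), since near-horizon sun angles are both optically
extreme and rare in field practice. Wavelengths run 400–700 nm at 5 nm
(a 10 nm coarse mode exists for fast runs and is what the acceptance
script uses); depths follow a surface-refined grid from 0.02 m to 20 m
(2 cm steps to 0.5 m, coarsening to 5 m steps at the bottom), truncated
to the largest analysis depth in use.

Per scenario and band (planar Ed plus Ea10…Ea80, as PAR), regression K
is fitted over the standard ranges 0–0.2, 0–0.5, 0–1, 0–1.5, 0–5 and
0–10 m. The analyses then compute:

- **ratio statistics**: mean and sd of log₁₀(Ea(θᵢ)/Ed) per band at the
  analysis depths (0.2–10 m), the basis for choosing the optimal ring
  angle;
- **scatter statistics**: Pearson r and the least-squares slope m of Ka
  on Kd. The orientation is deliberate: with m defined this way, the
  reconstruction `K̂d = Ka/m̄` returns Kd exactly when the relation is
  exact. m̄ is the mean of the per-lighting-cell slopes at a fixed depth
  range. Correlation significance (two-sided, 0.05 level) is computed
  and reported per cell but never used to filter;
- **lighting heat-maps**: r and m per (zenith × cloud) cell, each cell
  pooling all 56 water points — pooling both concentration corners and
  all classes per cell keeps every cell's regression well conditioned;
- **error tables and maps**: per band and depth range, the mean of
  |ε| = |K̂d − Kd|/Kd·100 — absolute values, since signed cell means can
  cancel opposite biases across water types — reported overall (as a
  fraction), per lighting cell and per water type (percent).

## 4. Numerical conventions and edge cases

- Angles are degrees at every interface, radians internally; solid
  angles in steradians.
- The polar cap is a single quad; in the field array its value is
  replicated across the 24 azimuth slots and its weight split evenly, so
  integrals count it exactly once. `quad_solid_angle()` reports the full
  cap solid angle and accepts only `phi_index = 1` for it.
- Regression requires ≥ 3 depths and positive irradiance; a constant
  profile returns K = 0 with `r_squared = NA` (flagged degenerate rather
  than an error). `scatter_stats()` errors on zero predictor variance
  and flags (r = NA, m = 0) a constant response.
- Ratios are undefined where Ed = 0 and raise an error rather than
  returning −Inf.
- Heat-maps demand a complete (zenith × cloud) lattice; a missing cell
  is an explicit error, not a silent NA.
- Stage failures inside the scenario loop abort with the stage name and
  scenario id.
- Radiance fields persist in a validated serialized container
  (dimensions, coordinates, scenario metadata, ground truth); reading
  verifies every dimension and names the offending one on mismatch. A
  tidy CSV export of per-depth band sums serves spot checks.

## 5. Problem sizes used by the tests

The test suite and the acceptance script run the full 3024-scenario grid
in the 10 nm coarse mode with depths to 1.5 m — the scale at which all
headline statistics stabilise (the pooled correlations and worst-cell
errors change in the third decimal between 10 nm and 5 nm) — plus the
2352-scenario ratio analysis at 1.5 m and a 56-corner exact-recovery
check over 0–10 m. The 5 nm mode and the full 20 m depth grid are the
defaults for interactive use.

## 6. Limitations

Beyond the generator's physical simplifications (§2), the assessment
inherits two structural caveats. First, pooled correlations across water
classes are dominated by the enormous between-class spread of Kd
(roughly 0.05–8 m⁻¹); per-cell slopes and error maps are the sharper
diagnostics, and both are reported. Second, all conclusions are for
homogeneous water — the instrument concept targets stratified waters,
but a depth-resolved Ka(z) in stratified columns is out of scope here.
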