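---
title: "Methods: glass transition, transport and elasticity of moist amorphous lignin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glass transition, transport and elasticity of moist amorphous lignin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligninpress)
```

## Scope

`ligninpress` is a desk-scale analysis toolkit for the observables that
molecular-dynamics studies of moist amorphous softwood lignin produce —
density-versus-temperature (dilatometry) curves from stepwise cooling,
unwrapped molecular position time series from isothermal runs, and
strain/stress/box-dimension series from uniaxial deformation runs — together
with the laboratory-side computations for hot-pressed paper sheets (tensile
index and its apparent activation energy). It does **not** run molecular
dynamics: every analysis stage is driven either by user-supplied tables or
by the package's synthetic generators, which emulate the statistical
structure of those MD outputs with known ground truth.

## The lignin chain model

Softwood (spruce) milled-wood lignin is represented as a single uniform
26-repeat-unit guaiacyl chain, the number-average degree of polymerization.
`build_reference_chain()` returns that chain as an annotated undirected
graph: a beta-O-4 backbone plus two aliphatic alpha-O-gamma ether linkages at
the annotated branch positions, and terminal-group modifications
(gamma-carboxyl on unit 1, gamma-aldehyde on unit 7, a truncated
alpha-aldehyde on unit 11, alpha-ketones on units 21 and 26, a beta-ketone
on unit 22). The structural model's range annotation for the second ether
linkage is ambiguous ("12–3"); the package reads it as the contiguous pair
12–13 and exposes the reading as an argument, without asserting intent.

Atom-level geometry is deliberately out of scope — 3-D structure generation
belongs to dedicated builder tools. Masses are therefore bookkeeping
quantities: each residue carries a nominal elemental formula (base guaiacyl
C10H12O3 with documented deltas per modification, see `?monomer_formula`),
the per-linkage condensation loss defaults to zero (residue masses are
treated as in-chain masses), and both choices are configurable.
`assemble_system_spec()` converts a target moisture content `mc` (wt %) into
a water count by the closed form
`n_water = round(mc/(100 - mc) * n_chains * M / 18.015)`;
for the reference 128-chain systems the achieved content is within a small
fraction of a percentage point of the request.

## Synthetic data: the study conditions

The generators define the conditions under which the estimators are
validated; their defaults are fixed once and are not tuned per test.

* **Dilatometry** (`gen_dilatometry()`): temperature grid 150–550 K in 25 K
  steps (the stepwise-cooling protocol: 25 K per 10 ns, i.e. an effective
  rate of 2.5 K/ns), five replicas averaged, per-replica Gaussian density
  noise 0.002 g/cm^3, true transition at 420 K with half-width 40 K, glassy
  slope −2×10⁻⁴ and melt slope −6×10⁻⁴ g/cm^3/K. The default blend is the
  same hyperbolic family the estimator fits (so that estimator is exactly
  well-specified), with the mapping `a = −slope_melt`,
  `b = slope_melt − slope_glass`, `T0 = Tg_true`, `c = 2 ln(breadth)`; these
  follow from matching the model's asymptote slopes (low-T slope is
  `−(a+b)`, high-T slope `−a`), and make `b` negative whenever expansivity
  increases through the transition, as it physically must. A tanh blend of
  the two asymptote lines is provided to probe mis-specification.
* **Brownian walkers** (`gen_random_walks()`): per-axis Gaussian increments
  of variance `2 D dt` (1 m²/s = 10⁹ nm²/ns), unwrapped coordinates,
  optional mixtures with per-walker component labels in the ground truth.
* **Deformation** (`gen_deformation()`): engineering strain 0–25 % sampled
  at 10⁻⁴, stress `E ε` plus Gaussian noise of 0.05 GPa (emulating
  pressure-tensor fluctuation), transverse edges `L0 (1 − ν ε)` plus 0.02 nm
  length noise, 21 nm box, rate metadata 0.1/1/10 m/s.
* **Arrhenius series** (`gen_arrhenius_series()`):
  `D(T) = D0 exp(−Ed/(R T))` on the isothermal production temperatures
  (300–550 K) with multiplicative log-normal noise.

Every generator consumes one named integer seed (replicas use fixed seed
offsets) and restores the caller's RNG state, so identical seeds give
byte-identical output regardless of surrounding code.

What the generators do **not** emulate: correlated (AR-type) noise along a
cooling ramp, sub-diffusive caging at short lags, strain-rate-dependent
stiffening, void nucleation, or any chemistry. Passing recovery tests
therefore demonstrate estimator correctness under idealized noise, not
robustness to every artefact of real trajectories.

## Glass-transition estimation

Three estimators operate on a replica-averaged curve:

1. **Bilinear** (`bilinear_tg()`): least-squares lines on the 150–225 K and
   500–550 K windows (the standard defaults; configurable), transition at
   their crossover. Uncertainty is first-order error propagation through the
   intersection formula from the two lines' coefficient covariances; a
   200-resample bootstrap is available. A warning fires when the estimate
   falls within 100 K of an inner window edge.
2. **Hyperbolic** (`fit_hyperbolic()` + `hyperbolic_tg()`): nonlinear least
   squares of `ρ(T) = ρ0 − a(T−T0) − b H0(T,T0,c)`,
   `H0 = (T−T0)/2 − sqrt((T−T0)²/4 + e^c)`, multi-start over a 5-point `T0`
   grid × 3 `c` values with Levenberg–Marquardt refinement; the transition
   is the extremum of the model's second derivative, scanned numerically at
   0.01 K (for this family the extremum equals `T0` analytically, which the
   tests enforce to 0.1 K). `b` is signed and unconstrained; `|b|` below
   10⁻⁷ flags the fit degenerate, and pure-line data fall back to an
   explicit straight-line fit with the degenerate flag set. The optional
   `lowT_taper` weighting multiplies inverse-variance weights by a linear
   taper from 2 (coldest point) to 1 (hottest), giving the glassy end more
   statistical weight; it is off by default so oracle tests see the plain
   estimator.
3. **Onset** (`onset_tg()`): the first temperature, scanning upward at
   0.1 K on the interpolated model curve, where the relative deviation
   between the hyperbolic model and the glassy line exceeds a threshold
   (default 2 %). Onset marks where the expansivity change is initiated
   rather than completed: on narrow transitions it sits above the bilinear
   estimate and on broad ones below it, and it is monotone non-decreasing
   in the threshold.

Temperatures are kelvin throughout. The Williams–Landel–Ferry relation
`log10 a_T = C1 (T − Tg)/(C2 + (T − Tg))` is provided with its closed-form
inverse `ΔT = C2 L/(C1 − L)`; the constants `C1`, `C2` are system-specific
calibrations and must be supplied by the user, so only the sign behaviour
(shifting to a slower rate lowers the apparent transition) is asserted.

## Transport

`compute_msd()` averages squared displacements over molecules and sliding
origins (default every 10th frame — a balance between correlation and cost,
declared rather than inferred) and refuses wrapped coordinates (any
single-step jump over half the box). `einstein_diffusivity()` takes the
least-squares slope over a fit window of 10–50 % of the lag span — short
lags excluded as ballistic/caging-contaminated, long lags as
noise-dominated — and divides by 6, converting nm²/ns to m²/s (factor
10⁻⁹); a slope more than two standard errors below zero is clamped to zero
with a flag. `arrhenius_fit()` regresses `ln D` on `1/T`
(`Ed = −R·slope`, kJ/mol) with optional independent branches below/above a
split temperature (typically a Tg estimate) for strongly curved plots.
`per_molecule_diffusivity()` computes `|Δr(τ)|²/(6τ)` per molecule and
sampling time; because no dip-test implementation is available to the
package, multimodality is summarized by Sarle's bimodality coefficient
(`(skew²+1)/kurtosis`, uniform benchmark 5/9) — a descriptive indicator,
never a hard assertion, since mobility-class exchange blurs the modes at
long τ. `water_density_map()` wraps positions into the box, bins the two
in-plane axes, mass-weights and frame-averages; total mass is conserved to
machine precision by construction, tested at 10⁻⁶ relative.

## Elastic constants

Stress is smoothed by a centered moving average over a 1 % strain width
(shrinking windows at the ends, so constants are fixed points); Young's
modulus is the regression slope of stress on strain over 0.3–9.9 % strain —
regression rather than an endpoint secant because it is far less sensitive
to pressure-tensor fluctuation, though the secant mode is available.
Poisson's ratio averages the pointwise transverse-contraction/axial-strain
ratio over 2–10 % strain (the sub-2 % region is excluded because the ratio
fluctuates strongly there) and over both transverse axes. The bulk modulus
uses the Lamé relation `K = −E/(6(ν − ½)) = E/(3(1−2ν))` with an
incompressibility guard at ν ≥ 0.5 − 10⁻⁶. `aggregate_triplicate()` averages
the three orthogonal pulling directions; the reported `K` is recomputed from
the aggregated `E` and `ν` so the Lamé identity holds exactly for every
reported triple, while its spread comes from the per-axis values.

## Sheet experiments

Tensile index is strength over grammage (N·m/g). Percentage gains are
relative to a positive reference (an unmeasurable zero wet reference admits
none). The apparent activation energy of wet tensile index versus pressing
temperature is the slope of `ln(index)` against `1/T_K`
(`T_K = T_C + 273.15`) times `−R`; zero-index records are excluded as
below-threshold rather than censored. The bundled
`inst/extdata/sheet_tensile_reference.csv` carries the published reference
indices (27.7, 49.7, 62.9, 21.2, 25.7 N·m/g at their conditions) for
regression tests; the corresponding published activation energies
(55 and 42 kJ/mol for dry- and moist-pressed sheets) are used only as the
scales of exact-recovery tests on closed-form synthetic records, because
the underlying per-temperature data exist only in graphical form.

## Validation studies and problem sizes

The recovery studies behind `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` use sizes chosen by the estimators' sampling
variance: 100 seeded dilatometry curves (median absolute Tg error must stay
within half the transition breadth for the bilinear and hyperbolic methods;
in practice the bilinear median is ~13–16 K and the hyperbolic ~5–7 K at
breadth 40 K), 50 Brownian sets of 800 walkers × 3 000 steps spanning
D = 10⁻¹⁵–10⁻¹⁰ m²/s (mean relative Einstein error ≈ 1.2–1.6 %, against a
2 % requirement; the walker count follows from the ~0.8 %·√(8×10⁵/N·n) error
scaling observed in pilot runs), 500 Arrhenius draws for 95 % CI coverage,
and 10 deformation records per (E, ν) grid point. The acceptance script
reuses the same machinery at reduced replication (20 Brownian sets of
600 × 2 500; 200 coverage draws) and finishes in well under a minute.

## Known limitations

* The hyperbolic density family approaches its asymptotes slowly (the tail
  of `H0` decays like `e^c/|T−T0|`), so for very broad transitions the
  150–225 K window is contaminated and the bilinear glassy line is biased;
  this is a property of the model family, visible in the recovery studies
  as a low-biased bilinear estimate, and mirrors the known sensitivity of
  bilinear fitting to curvature.
* WLF constants are taken as user input; no cooling-rate calibration is
  performed in-package.
* Wrapped trajectories are rejected, not unwrapped; unwrapping is the job
  of the trajectory converter that produced the input.
* The linkage census validates only the annotated modifications strictly;
  the full native linkage inventory of the reference structure is not
  enumerable from the source text and the backbone is represented uniformly
  as beta-O-4.
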