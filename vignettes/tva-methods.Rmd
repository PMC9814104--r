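---
title: "Models and methods behind tvakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tvakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvakit)
```

## The experiment being modelled

A UV pump pulse excites one geometric isomer of a photoswitch (the packaged
fixtures mimic ethyl sinapate in acetonitrile); a mid-IR probe then measures
the difference absorbance ΔA(ν, Δt) across the carbonyl-stretch region as a
function of pump–probe delay. Three features carry the photochemistry:

* a negative **ground-state bleach (GSB)** at the starting isomer's C=O
  stretch (1707 cm⁻¹ for E, 1713 cm⁻¹ for Z), whose recovery tracks
  repopulation of the initial ground state;
* a broad positive band red-shifted from the bleach (~1680 / ~1690 cm⁻¹)
  from **vibrationally hot** molecules relaxing after internal conversion;
* a sharper positive band (1718 / 1708 cm⁻¹) from the **photoisomer**
  growing in.

Because the bleach only recovers partially, its residual amplitude measures
how much of the excited population isomerized rather than returned.

## Spectral decomposition

`decompose()` fits every delay independently as ΔA(·, t) ≈ Σₖ cₖ(t) Sₖ(·)
with *fixed* band shapes Sₖ (unit-peak Gaussians by default; the broad hot
band can be made Lorentzian via `build_basis()` overrides). Signs are
physical constraints, not initial guesses: the GSB coefficient is
constrained ≤ 0 and the two ESA coefficients ≥ 0. With only three
components the constrained problem is solved exactly by enumerating active
sets, so no iterative NNLS tolerance enters. Standard errors use the
unconstrained normal-equation covariance σ²(SᵀS)⁻¹ with σ² the per-delay
residual variance — a deliberate simplification that is exact whenever no
constraint binds, which on the fixtures is every delay after time zero.

Fixing band shapes per delay (rather than a global variable-projection fit)
mirrors common practice in transient-IR decomposition software; it keeps
each delay's fit linear, exact and diagnosable. The cost is that real
band-shape evolution (anharmonic shifting of the hot band as it cools) is
absorbed into the coefficients; the synthetic generator deliberately omits
such shifting, so tests exercise the solver, not that approximation.

Pre-time-zero delays are fit like all others and flagged; their
coefficients should scatter around zero, making them a free baseline check.

## Kinetic models

All component kinetics are mono-exponential by design (`fit_monoexp()`):

* hot-band decay: A e^(−t/τ) + C,
* photoisomer rise: A (1 − e^(−t/τ)),
* bleach recovery: −|A₀| [1 − R (1 − e^(−t/τ))], R ∈ [0, 1] the recovered
  fraction.

Fits start at t ≥ 0.3 ps to stay clear of the time-zero region (the
generator's instrument-response convolution is off by default, but real
data need the guard). Initialisation is deterministic — τ₀ from the 1/e
crossing of the trace's range, amplitudes from endpoints — so repeated fits
are bit-identical; a deterministic ladder of τ₀ rescalings handles the rare
non-convergence. Uncertainties come from the Levenberg–Marquardt covariance
σ²(JᵀJ)⁻¹; `bootstrap_tau()` offers a residual-resampling alternative, and
on the fixtures the two agree within a factor of two, which is the
consistency the test suite enforces.

The percentage recovery statistic uses window means rather than fit
parameters: 100 (|c̄_early| − |c̄_late|)/|c̄_early| with defaults
early = [0.2, 1] ps and late = [300, 600] ps. The early window sits after
pulse overlap but well before the ~7–9 ps recovery; the late window sits
after all fitted time constants (> 15 τ). Both are configurable because
published work rarely states its endpoints. With a ~9 ps recovery the early
window already contains a few percent of decay, so the statistic reads
~47–48% on a fixture whose true recovered fraction is 49% — an inherent,
documented property of windowed estimates, not corrected for.

## Photokinetics and quantum yields

Under monochromatic irradiation with total absorbance A_tot, the absorbed
photon flux is I = F (1 − 10^(−A_tot)) and each isomer absorbs its share
εX [X] l / A_tot (competitive inner filter). The two-state rate equations

d[E]/dt = −φ_EZ I_E + φ_ZE I_Z = −d[Z]/dt

conserve mass exactly and approach the photostationary state; the closed
form x_Z = φ_EZ ε_E / (φ_EZ ε_E + φ_ZE ε_Z) (absorptivities at the
irradiation wavelength) is independent of flux and starting composition,
and the integrator is tested against it to 10⁻⁶.

`estimate_pqy()` inverts an irradiation series in two steps. Step 1 unmixes
each spectrum onto the pure-component absorptivities by linear least
squares; because both concentration estimates at one time point share the
same spectral noise, their errors are strongly correlated. Step 2 therefore
fits (φ_EZ, φ_ZE) by *generalized* least squares, whitening each time
point's (E, Z) residual with the unmixing covariance s_t²(XᵀX)⁻¹ estimated
from that spectrum's own residuals. Ignoring that correlation makes the
nominal standard errors optimistic; with whitening the packaged series
recover 0.57/0.23 with honest uncertainties (two-standard-error coverage
≥ 80% over repeated seeds, enforced by a test).

The polychromatic solar-simulator exposure of the real experiment is
emulated as a single effective wavelength at the starting isomer's
absorption maximum (321 nm E / 318 nm Z); the fixture ε spectra are
synthetic Gaussians (peaks 2.0×10⁴ and 1.4×10⁴ M⁻¹cm⁻¹, FWHM 50 nm) chosen
for testability, not literature shapes. Thermal Z→E reversion is neglected,
matching its absence on the experimental timescale.

## The branching tree

The measured yields are explained by a small probability tree over the
ground-state exit channels of the conical intersections. From Z, the CI
exit is symmetric along the isomerization coordinate: half the population
returns directly to Z, half lands hot on the E side and splits again
~50:50 over the E–Z ground-state barrier — predicting 75% Z recovery and
25% E formation. From E, the hydrogen out-of-plane motion blocks the
E-side exit, so everything passes the barrier node and splits 50:50.
`evaluate_tree()` performs the exact arithmetic (½ splits are exact in
binary floating point, so 0.75/0.25 and 0.5/0.5 are identities, not
approximations), and `fit_splits()` inverts the linear yield relation in
closed form — the observed 77% Z recovery corresponds to a barrier split of
0.54, usefully close to the statistical assumption. Trees of arbitrary
depth can be built from `branch_node()`/`branch_leaf()` to express
alternative mechanisms.

## CI topography classification

Near a conical intersection the two sheets are E±(r) = s·r ±
√((g̃r₁)² + (h̃r₂)²) in the branching plane spanned by the
gradient-difference and coupling vectors. `branching_plane()`
orthogonalises (g, h) by the standard mixing-angle rotation
tan 2β = 2 g·h / (|g|² − |h|²); `classify_ci()` samples both sheets on a
circle and labels the intersection *sloped* if the upper sheet dips below
the intersection energy anywhere (else *peaked*) and *single-path* or
*bifurcating* by counting strict local minima of the lower sheet, merging
minima degenerate to 10⁻⁹ eV at adjacent angles. Direct sampling was chosen
over closed-form topography parameters to keep the classifier
self-contained; the labels agree with a 10⁶-point sampling oracle, and they
are scale- and rotation-invariant by construction (both properties are
property-tested). The actual molecular g/h/s vectors are not packaged, so
the shipped examples are synthetic models spanning the qualitative classes.

## Band assignment

Computed harmonic frequencies are scaled by a single factor (fixtures use
0.9879/0.9908), broadened as unit-area Lorentzians, and matched to observed
peaks by greedy nearest-neighbour assignment within 15 cm⁻¹ (a typical
scaled-harmonic residual; configurable). Peak positions are refined by a
three-point parabola, giving sub-grid accuracy on isolated bands; two
equal-width equal-weight Gaussians 6 cm⁻¹ apart merge into a single peak at
their midpoint, which is exactly the behaviour that makes the
post-irradiation C=O band of a PSS mixture appear *between* the pure-isomer
positions (1710 cm⁻¹ between 1707 and 1713). Ties in matching resolve
toward the lower-wavenumber peak — an arbitrary but documented rule.

## Synthetic data: what it does and does not emulate

`generate_tva_map()` builds rank-3 maps: three fixed bands, mono-exponential
coefficients (bleach −[1 − R(1 − e^(−t/τ))], instantaneous hot-band onset,
pure-exponential photoisomer rise from t = 0), iid Gaussian pixel noise of
0.01 mOD against a 1 mOD bleach, a 1620–1780 cm⁻¹ step-1 grid and delays
{−0.5 ps, 60 log-spaced points 0.2–600 ps}. Fixture kinetic values are the
published acetonitrile time constants (9.05/16.42/18.90 ps E;
7.33/13.30/18.72 ps Z) and recovery fractions (0.49/0.94); ESA amplitudes
(0.5 hot, 0.45/0.10 photoisomer) keep band overlap mild, because strongly
overlapped photoisomer and bleach bands are known to bias apparent recovery
upward and the fixtures are meant to have clean ground truth. Not emulated:
coherent artifacts near t = 0, band-shape evolution during cooling, solvent
heating, a photoisomer onset lag (the visible ~10 ps onset of the real rise
is treated as the natural shape of an 18.9 ps exponential, not an induction
period), and any instrument response by default (a Gaussian IRF of
configurable FWHM can be convolved in analytically). Passing tests
therefore demonstrate correctness of the estimators under the stated noise
model — not robustness to every artifact of real data.

Seeding: every stochastic generator takes an explicit seed, restores the
caller's RNG state, and errors if noise is requested without a seed.
Identical seeds give bit-identical data; different seeds share the
identical noiseless part.

## Problem sizes and numerical choices

The test suite and acceptance script run the full pipeline on 61×161 maps,
50 seeds per fixture for ensemble summaries, 20-spectrum irradiation
series, 25-seed coverage checks and 200-replicate bootstraps — sizes chosen
so the whole suite completes in well under a minute while leaving Monte
Carlo error comfortably inside the tested tolerances. Degenerate inputs
fail loudly rather than silently: constant traces, collinear bases or pure
spectra, zero photochemical rates, flat classification circles and
non-monotone axes all raise descriptive errors.
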