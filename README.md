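# tvakit

Analysis toolkit for ultrafast UV-pump / mid-IR-probe studies of E/Z
photoswitches — molecules such as sinapate esters whose photoprotective
function rests on fast excited-state decay and partial photoisomerization.
It is written for spectroscopists who have a transient vibrational
absorption (TVA) dataset ΔA(ν, Δt), steady-state irradiation series, and
computed harmonic frequencies, and who want the standard analysis chain as
scriptable, tested functions rather than point-and-click tools.

## What it computes

* **Spectral decomposition.** Each transient spectrum is modelled as a
  fixed-shape linear combination ΔA(ν, t) ≈ Σₖ cₖ(t) Sₖ(ν) of three bands —
  ground-state bleach (GSB, c ≤ 0), a broad vibrationally hot ESA, and the
  growing photoisomer ESA (c ≥ 0) — solved per delay by sign-constrained
  least squares with normal-equation standard errors.
* **Kinetics.** Component traces are fit with mono-exponential models:
  decay A e^(−t/τ) + C, rise A (1 − e^(−t/τ)), and bleach recovery
  −|A₀| [1 − R (1 − e^(−t/τ))], with covariance and residual-bootstrap
  uncertainties on τ, plus the percentage bleach recovery
  100 (|c̄_early| − |c̄_late|)/|c̄_early|.
* **Photokinetics.** The two-state system E ⇌ Z under monochromatic
  irradiation: d[E]/dt = −φ_EZ I_E + φ_ZE I_Z with competitive inner-filter
  absorption, the closed-form photostationary state (PSS)
  x_Z = φ_EZ ε_E / (φ_EZ ε_E + φ_ZE ε_Z), and a generalized-least-squares
  estimator of (φ_EZ, φ_ZE) from an irradiation series of UV-Vis spectra.
* **Branching model.** A probability tree over the ground-state exit paths
  from the conical intersections (CIs): with statistical 50:50 splits it
  predicts ~75% recovery / ~25% photoisomer starting from Z and a 50:50
  split starting from E, and it can be inverted against measured yields.
* **CI topography.** First-order double-cone model from g/h/s vectors with
  peaked/sloped and single-path/bifurcating classification by sampling the
  cone on a circle.
* **Band assignment.** Harmonic line-list scaling, peak finding with
  parabolic refinement, greedy band matching, difference spectra and
  two-component isomer unmixing of FTIR spectra.
* **Synthetic data.** Seeded generators for all of the above, with packaged
  fixtures whose band positions, time constants, recovery fractions and
  quantum yields follow the published acetonitrile measurements of ethyl
  sinapate.

## Worked example

```r
library(tvakit)
report <- run_pipeline("E", seed = 1)   # simulate -> decompose -> fit
report
#> <pipeline_report> E isomer, seed 1
#>   gsb          tau =   9.09 +/- 0.09 ps
#>   vib_relax    tau =  16.36 +/- 0.06 ps
#>   photoisomer  tau =  18.78 +/- 0.11 ps
#>   GSB recovery = 47.9%
```

The fixture's generating values are τ = 9.05 / 16.42 / 18.90 ps and 49%
recovery: with 0.01 mOD pixel noise the full pipeline returns each time
constant within its quoted uncertainty, and the bleach only recovers
halfway because ~half of the excited E isomer ends up as Z. The branching
model explains those numbers mechanistically:

```r
evaluate_tree(build_exit_tree("Z"))
#> $y_E
#> [1] 0.25
#> $y_Z
#> [1] 0.75
```

The numbered scripts under `analysis/` run the whole study: `01` simulates
the datasets (into `scratch/data/`), `02`–`06` decompose, fit kinetics,
estimate quantum yields, evaluate/invert the branching trees, classify CI
models and assign vibrational bands, writing tables under `results/`.

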