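# ssnadyn

Conformational ensembles and nanosecond chain dynamics of short
single-stranded nucleic acids (ssNAs) from single-molecule FRET and
nanosecond fluorescence correlation spectroscopy (nsFCS).

Short ssDNA and ssRNA oligonucleotides sample broad conformational
ensembles and reconfigure on the ~10 ns scale — fast enough that
resolving their dynamics requires combining photon-level FRET burst
analysis, correlation spectroscopy down to nanosecond lags, polymer
theory, and ensemble refinement. This package implements that analysis
chain for terminally dye-labeled chains (Alexa 488/594, Förster radius
R₀ = 5.4 nm), together with seed-deterministic simulators that generate
photon streams and distance trajectories with exactly the statistical
structure the analysis assumes, so every estimator can be validated
against a known ground truth.

## What it computes

* **Distance distributions** P(r): Gaussian chain, worm-like chain,
  SAW-ν, and empirical densities; calibration of any family to a
  measured mean transfer efficiency via
  ⟨ε⟩ = ∫ ε(r) P(r) dr with ε(r) = R₀⁶/(R₀⁶ + r⁶); Boltzmann
  inversion to potentials of mean force F(r) = −k_BT ln P(r).
* **FRET observables**: efficiency moments, dynamic FRET lines
  τ_D/τ_D0 = 1 − ⟨ε⟩ + σ²_ε/(1 − ⟨ε⟩) (and the acceptor analogue),
  and the glycerol conformational free-energy estimate
  ΔF/k_BT = ln √(⟨r²⟩_b/⟨r²⟩_a).
* **Chain dynamics**: correlation times for diffusion in a potential
  of mean force,
  τ_f = ∫P⁻¹[∫δf P]² dr / (D ∫δf² P dr), the D-independent conversion
  ratio θ = τ_cd/τ_r, internal friction as the zero-viscosity
  intercept of τ_r ≈ τ_i + (η/η₀) τ_s, and end-to-end contact rates
  1/k_ee = 1/(qP(a)) + D⁻¹∫_a P⁻¹[∫_r P]² dr.
* **Photon pipeline**: fixed-bin burst search (>50 photons), count
  corrections (background, crosstalk, direct excitation, γ),
  E = n_A/(n_A+n_D), stoichiometry filtering (0.2 < S < 0.8),
  burst-mean lifetimes with background/IRF correction, Gaussian and
  binomial shot-noise histogram analysis.
* **FCS**: cross-detector photon-pair correlators (Eq.-10-style
  normalized correlations), global full-FCS fits (antibunching ×
  chain dynamics × triplet over a diffusion denominator) and nsFCS
  fits with a shared chain-dynamics time; FCS-based viscosity
  calibration.
* **Anisotropy**: global IRF-reconvolution fits of polarized decays
  with fast dye rotation and slower molecular tumbling (r₀ = 0.38).
* **BioEn reweighting**: maximum-entropy refinement of conformer (or
  discretized polymer) ensembles against the measured efficiency mean
  and variance, with a θ schedule and φ_eff = e^{ΔS}.
* **Hierarchical chain growth**: Kabsch superposition gated at
  RMSD < 0.8 Å, 2.0 Å clash filtering, hierarchical doubling, dye
  attachment.

## Worked example

Calibrate the three polymer models of a 19-mer to a measured transfer
efficiency of 0.5 and convert a measured nsFCS correlation time of
10 ns into reconfiguration times and contact rates:

```r
library(ssnadyn)
R0 <- 5.4; lc <- 19 * 0.63
models <- list(
  GC    = calibrate_to_efficiency("GC", 0.5, R0),
  WLC   = calibrate_to_efficiency("WLC", 0.5, R0, lc = lc),
  SAWNU = calibrate_to_efficiency("SAWNU", 0.5, R0, b = 0.63, n = 19))
for (nm in names(models)) {
  res <- reconfiguration_time(models[[nm]], R0, tau_cd = 10)
  k <- contact_rate(models[[nm]], res$D)
  cat(sprintf("%-6s R = %.2f nm  theta = %.3f  tau_r = %.1f ns  k_ee = %.2g /s\n",
              nm, ddist_moments(models[[nm]])$R, res$theta_conv,
              res$tau_r, k$k_ee))
}
```

```
GC     R = 6.19 nm  theta = 0.884  tau_r = 11.3 ns  k_ee = 3.9e+06 /s
WLC    R = 5.74 nm  theta = 0.984  tau_r = 10.2 ns  k_ee = 1.5e+06 /s
SAWNU  R = 5.78 nm  theta = 0.975  tau_r = 10.3 ns  k_ee = 1e+06 /s
```

All three models place the root-mean-square dye-to-dye distance near
6 nm, the fluorescence and reconfiguration correlation times within
~10% of each other (θ ≈ 1 near R ≈ R₀), and end-to-end contact rates
around 10⁶ s⁻¹ — rapid, flexible chains whose dynamics are dominated
by solvent friction.

The numbered scripts under `analysis/` run the full workflow —
polymer models and FRET lines, the glycerol free-energy estimate,
dynamics and contact rates, an end-to-end synthetic single-molecule
recovery, BioEn reweighting, and chain growth — writing tables under
`results/`. `vignettes/ssnadyn-methods.Rmd` documents the models,
assumptions and numerical choices.

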