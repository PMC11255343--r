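---
title: "Models and methods behind ssnadyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ssnadyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ssnadyn analyzes the conformational ensembles and nanosecond chain
dynamics of short single-stranded nucleic acids (ssNAs) measured by
single-molecule FRET and nanosecond fluorescence correlation
spectroscopy (nsFCS). This vignette explains the models the package
implements, the assumptions they rest on, the numerical choices made
where the mathematics leaves freedom, and what the synthetic-data
generators do and do not emulate.

## The distance-distribution picture

A terminally labeled ssNA is described by the radial probability
density $P(r)$ of its dye-to-dye distance. Three analytical families
are provided:

* **Gaussian chain (GC)** — $P(r) \propto r^2
  \exp[-3r^2/(2\langle r^2\rangle)]$, one parameter, the mean-square
  end-to-end distance $\langle r^2\rangle$ (nm²).
* **Worm-like chain (WLC)** — the standard interpolation density with
  contour length $l_c$ and persistence length $l_p$ (nm), exactly zero
  beyond $l_c$; its normalization constant has no closed form and is
  computed once per parameter set by adaptive quadrature.
* **SAW-$\nu$** — a self-avoiding-walk shape with scaling exponent
  $\nu$, using $g = (\gamma-1)/\nu$, $\delta = 1/(1-\nu)$ and
  $\gamma \approx 1.1615$. Its two constants (the normalization $A$ and
  the exponential coefficient $\alpha$) are fixed jointly by requiring
  unit integral and $\int r^2 P\,dr = R^2$; both conditions reduce to
  Gamma-function ratios, so the package evaluates them in closed form.
  The literature leaves the value of $\alpha$ unstated; tying it to the
  normalization and second-moment conditions is our choice and is the
  unique one consistent with $R$ being the root-mean-square distance.

Empirical (gridded) densities — e.g. from chain-growth ensembles — are
first-class members of the same interface.

All lengths are in nm because the Förster radius of the Alexa 488/594
pair, $R_0 = 5.4$ nm, is the natural scale of the experiment.
Quadrature uses adaptive Gauss–Kronrod (`stats::integrate`) on
$[0, r_{cap}]$ with $r_{cap} = \max(6R, l_c)$; every supported density
decays at least Gaussian-fast, so the cap loses less than $10^{-8}$ of
the mass.

### FRET observables and calibration

Transfer efficiency at fixed distance is
$\varepsilon(r) = R_0^6/(R_0^6 + r^6)$ (orientation factor
$\kappa^2 = 2/3$ assumed throughout, justified by the fast dye rotation
the anisotropy module measures). A chain sampling $P(r)$ slowly
compared with the donor lifetime but quickly compared with the
interphoton time shows the burst-averaged moments
$\langle\varepsilon\rangle$ and $\sigma_\varepsilon^2$, which also set
the dynamic FRET lines

$$\tau_D/\tau_{D0} = 1 - \langle\varepsilon\rangle +
  \frac{\sigma_\varepsilon^2}{1-\langle\varepsilon\rangle},
  \qquad
  (\tau_A-\tau_{A0})/\tau_{D0} = 1 - \langle\varepsilon\rangle -
  \frac{\sigma_\varepsilon^2}{\langle\varepsilon\rangle}.$$

`calibrate_to_efficiency()` inverts
$\langle\varepsilon\rangle(P) = E$ for the family's free parameter
($\langle r^2\rangle$ for GC, $l_p$ at fixed $l_c$ for WLC, $\nu$ at
fixed $(b, n)$ for SAW-$\nu$) by bracketing plus Brent root finding on
a log/logit transform of the parameter, which makes the objective
monotone and the bracket expansion safe.

For the 19-nucleotide constructs the package defaults to
$l_c = 19 \times 0.63$ nm and SAW-$\nu$ segments $b = 0.63$ nm,
$n = 19$ — the standard ssDNA backbone contour per nucleotide. These
are package choices; dye linkers would add a few Å that we neglect.

### The glycerol free-energy estimate

For two Gaussian-chain states the entropy difference collapses to
$\Delta F/k_BT = \ln\sqrt{\langle r^2\rangle_b/\langle r^2\rangle_a}$.
`glycerol_workup()` calibrates the 0% state at $R_0 = 5.4$ nm and the
35% (w/w) glycerol state at $R_0$ scaled by $(n_{mix}/n_{water})^{-2/3}$
using tabulated refractive indices of glycerol–water mixtures
(interpolated; $n_{35\%} = 1.3772$). Only the magnitude of the
efficiency shift ($|\Delta E| = 0.07$ for dT$_{19}$) is known; with a
base efficiency of 0.5 the *compaction* direction (efficiency rising
with glycerol) reproduces the reported magnitudes
($|\Delta F| \approx 0.1\,k_BT$, $|\Delta R| \approx 0.7$ nm), so it
is the default; the expansion direction is available and yields
$\approx 0.074\,k_BT$ / $0.48$ nm. `analysis/02` tabulates the
sensitivity to the assumed base efficiency: over base $E$ in
$[0.40, 0.60]$ the magnitude moves by less than $0.01\,k_BT$, so the
headline conclusion (glycerol barely perturbs the chain) is robust.

## Chain dynamics in a potential of mean force

The end-to-end distance is modeled as overdamped diffusion with a
single, distance-independent coefficient $D$ in the potential of mean
force $F(r) = -k_BT \ln P(r)$. For any observable $f(r)$ the
correlation time is

$$\tau_f = \frac{\int_0^\infty P^{-1}(r)
  \left[\int_0^r \delta f\, P\, d\rho\right]^2 dr}
  {D \int_0^\infty \delta f^2 P\, dr},$$

evaluated by nested trapezoidal quadrature on a shared grid (default
6001 points; the headline checks verify a 10× finer grid moves the
conversion ratio by under 0.1%). The integrable $1/P$ singularity at
the support edges is regularized by flooring $P$ at $10^{-12}$ of its
maximum and truncating where it falls below that floor.

nsFCS measures the efficiency correlation time
$\tau_{cd} = \tau_\varepsilon$; the reconfiguration time follows as
$\tau_r = \tau_{cd}/\theta$ with $\theta = \tau_\varepsilon/\tau_r$,
which is independent of $D$ (both times scale as $1/D$). $D$ itself is
recovered from the same scaling. Contact rates use

$$1/k_{ee} = 1/(qP(a)) + D^{-1}\int_a^\infty P^{-1}(r)
  \left[\int_r^\infty P\,d\rho\right]^2 dr$$

with defaults $q = 10^{12}\,s^{-1}$ and $a = 0.4$ nm; internal
arithmetic runs in ns and converts to s$^{-1}$ at the interface.
Internal friction is the zero-viscosity intercept of a weighted linear
fit $\tau_r \approx \tau_i + (\eta/\eta_0)\tau_s$, with 95% confidence
intervals from the t distribution on the weighted-least-squares
covariance (the estimator behind such published confidence bands is
rarely stated; this is the conventional choice).

## Photon pipeline

Bursts are fixed-bin threshold events: bins (1 ms without, 0.2 ms with
zero-mode waveguides) holding strictly more than 50 photons, merged
when consecutive with no gap tolerance. Count corrections apply in a
fixed order — background ($rate \times \Delta$), donor leakage
(crosstalk $\times$ corrected donor counts), direct acceptor
excitation (fraction of acceptor-excitation counts), then the
detection-efficiency factor $\gamma$ on the donor — because the
literature lists the corrections without an order; the chosen order
subtracts signal-independent terms first and scales last. Corrections
can overshoot on small bursts; counts clamp at zero with a flag and
efficiencies are stored unclipped.

Stoichiometry uses the pulsed-interleaved-excitation convention
$S = (n_D + n_A)/(n_D + n_A + n_{Aex})$ with the strict window
$0.2 < S < 0.8$, and the FRET subpopulation keeps bursts within
$\pm 0.2$ of the active peak (estimated as the density mode of $E$
above 0.25 to exclude the donor-only cluster). Burst-mean lifetimes
correct the mean microtime for background and the IRF shift, with
perpendicular photons weighted $2G$.

The shot-noise reference for efficiency histograms is the binomial
mixture over the observed burst-size distribution — deliberately the
shot-noise *limit* only; full photon-distribution analysis with
explicit background statistics is out of scope.

## Correlators and FCS fits

The correlator is a photon-pair histogram: ordered pair lags binned on
a linear (nsFCS) or logarithmic (full FCS) grid, normalized by the
expectation for independent stationary streams, with inverse-variance
weights from Poisson counting. Correlation is always computed between
*distinct* detectors; `split_detectors()` emulates the 50/50 beam
splitter so that zero-lag self-pairs, deadtime and afterpulsing cannot
contaminate the curves even in simulation.

The full-FCS model multiplies antibunching, chain-dynamics and triplet
factors over a 3D-Gaussian diffusion denominator with fixed aspect
ratio ($s = 5.3$ confocal, $1.0$ in zero-mode waveguides); global fits
share the chain-dynamics time $\tau_{cd}$ across detector pairs and
keep everything else per pair. The nsFCS model is its short-lag limit.
Two estimator-level choices deserve note:

* **Normalization.** Curves are normalized to unity at $\tau_{max}$ on
  the $1+G$ (coincidence-rate) scale rather than on $G$. For
  subpopulation data with an elevated diffusion plateau the two differ
  by an affine constant absorbed in the per-curve amplitude $b$; for
  fully stationary streams ($G(\tau_{max}) \to 0$) the $1+G$ scale
  remains finite where $1/G(\tau_{max})$ would diverge.
* **Multi-start.** The antibunching and chain-dynamics components can
  trade against each other in noisy curves; the global fit is run from
  a small grid of starting timescales and the lowest-residual solution
  is kept. The antibunching contrast is constrained to $(0,1)$ (a
  single emitter cannot be more than fully antibunched).

Viscosity calibration fits raw diffusion times against known relative
viscosities and inverse-predicts with a delta-method standard error;
normalizing by the *fitted* buffer time rather than the measured
buffer point keeps that point's noise from correlating the whole
curve.

## Anisotropy

Polarized decays $I_{VV}, I_{VH}$ are fit globally with two rotational
components (fast dye rotation $\tau_{rot}$, slower tumbling $\tau_M$),
shared amplitude and fluorescence lifetime, discrete IRF reconvolution
on the measurement grid (no color-shift parameter), Poisson weights,
and the limiting anisotropy fixed at $r_0 = 0.38$. The $G$ factor
comes from horizontal-excitation decays when available, otherwise it
is fitted; offsets are fitted (whether the original analysis fixed
them from pre-pulse baselines is unstated). If the fitted $\tau_{rot}$
exceeds $\tau_M$ the labels are swapped and flagged.

## Hierarchical chain growth

Chains are assembled from fragment libraries by rigid-body (Kabsch)
superposition of tail-onto-head overlap atom sets — proper rotations
only, so chirality is never mirrored — gated at RMSD $< 0.8$ Å, then
clash-filtered at 2.0 Å using a cell-list neighbor search (with a
vectorized all-pairs fast path for small assemblies). Hierarchical
doubling builds fragments → 2-mers → half-chains → chains; each
conformer is grown from an independent recursion tree so ensemble
members are independent draws (a per-level pool would be cheaper but
correlates conformers through shared sub-assemblies, which distorts
ensemble statistics). A sequential one-fragment-at-a-time mode covers
non-power-of-two lengths. The retry cap is $10^4$ per junction. Dye
fragments attach at either end under the same gates and carry a
reference atom defining the dye-to-dye distance.

## Synthetic data: what it does and does not emulate

The generators provide data with exactly the statistical structure the
analysis assumes:

* **Brownian trajectories** integrate the overdamped Langevin equation
  with drift $D\,d\ln P/dr$ (tabulated and linearly interpolated),
  noise $\sqrt{2D\,dt}$, reflecting boundaries at the $10^{-10}$
  density edges, and deep-tail drift clamped to three noise standard
  deviations (those excursions carry negligible probability but would
  otherwise force a much smaller step). A stability check rejects
  steps that exceed a fifth of the well width over the probable
  region. Time steps of $\tau_r/500$ or smaller keep discretization
  bias below the 5% oracle tolerances; first-passage simulations need
  smaller steps still ($5\times10^{-4}$ ns in the headline check)
  because discrete crossing detection biases passage times upward by
  $O(\sqrt{dt})$.
* **Photon streams** excite the molecule as a Poisson process (CW) or
  alternating pulse train (PIE at 20 MHz per color), transfer with
  probability $\varepsilon(r(t))$, and draw exponential emission
  delays. Antibunching arises by forbidding re-excitation during an
  excited-state dwell; triplet blinking and translational diffusion
  are two-state telegraph gates sharing one realization across
  excitation slots; crosstalk, direct excitation, background,
  detection-efficiency imbalance and Gaussian IRF jitter are each
  independently switchable for ablation tests.
* **Ensembles and viscosity series** are direct draws from a target
  distribution and the additive friction law.

What passing tests on these data show is that the *analysis chain is
self-consistent*: it recovers the parameters of the process it
assumes. They do not show that real ssNA photon streams satisfy those
assumptions — a single effective $D$ independent of $r$, exponential
dwell photophysics, a telegraph-like focal volume — and distance
distributions inferred from real data inherit whatever bias those
idealizations carry. The paper-facing quantities that survive this
caveat are the deterministic desk calculations (model calibration,
free-energy estimate, conversion ratios, contact-rate integrals),
which depend only on the model definitions.

Problem sizes in the shipped tests and analysis scripts (e.g. $2\times
10^4\,\tau_r$ of trajectory for decorrelation checks, ~2 ms of photon
stream for nsFCS recovery, 400 grown chains) were chosen so that each
stochastic check has a sampling error comfortably below its assertion
tolerance.

## Reweighting (BioEn)

Ensemble weights follow the exponential family
$w_\alpha \propto w^0_\alpha\exp(f\varepsilon_\alpha +
g\varepsilon_\alpha^2)$; the generalized forces $(f,g)$ minimize
$\Delta G = \chi^2/2 - \theta\Delta S$ with the measured mean and
variance of the transfer efficiency as observables (default
uncertainties 0.03 and 0.003). The solver is a damped 2D
Newton–Raphson on $(f,g)$: analytic gradient (covariances of
$\varepsilon, \varepsilon^2$ under the current weights),
finite-difference Hessian of that gradient, step halving whenever
$\Delta G$ increases, a trust-region cap on the force step, and a
scaled gradient fallback when the Hessian is unusable. Because the
entropy term scales the gradient by $\theta$, convergence is declared
at gradient norm $10^{-10}\max(1,\theta)$. The $\theta$ schedule walks
a geometric ladder ($10^4 \to 10^{-2}$, factor 2) downward with warm
starts, returning the largest $\theta$ whose reweighted moments agree
with the targets within tolerance; the acceptance tolerance can be
varied independently of the $\chi^2$ weights, which keeps the
"smaller tolerance, smaller $\theta^*$" monotonicity clean.

Discretized polymer priors place mass on the uniform efficiency grid
$\varepsilon_\alpha = (\alpha-1)\times 0.03$, $\alpha = 1..33$, with
weights $\propto P(r(\varepsilon))\left|dr/d\varepsilon\right|$; the
singular $\varepsilon = 0$ bin takes its analytic limit, zero, because
every supported density vanishes faster than the Jacobian diverges.
The retained fraction of the prior is $\phi_{eff} = e^{\Delta S}$.

## Known limitations

* The effective diffusion coefficient is a single number; $r$-dependent
  friction is out of scope.
* Photon-distribution analysis is binomial shot-noise only.
* The 3D-Gaussian diffusion factor is kept for zero-mode waveguides
  (with $s = 1$) although the true aperture optics differ, matching
  common practice.
* Photon streams travel as CSV tables; the Photon-HDF5 container is
  not read or written.
* Chain growth here demonstrates the assembly operators on synthetic
  or user-supplied libraries; generating molecular-dynamics fragment
  libraries is explicitly not part of the package.
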