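---
title: "Free-energy surfaces and Marcus rates for chlorophyll concentration quenching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy surfaces and Marcus rates for chlorophyll concentration quenching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchsep)
```

## The scientific problem

Concentrated solutions of chlorophyll lose fluorescence ("concentration
quenching") even though the same pigments, packed just as tightly inside
photosynthetic antenna proteins, fluoresce normally.  The leading hypothesis
is that when two chlorophylls happen to sit within roughly 10 Å of each other
(a *statistical pair*), the photoexcited pair `(Chl–Chl)*` can undergo
symmetric charge separation to an ion-pair state `Chl⁺–Chl⁻` that then
recombines nonradiatively.  Whether this mechanism is feasible is a
kinetics question: does the charge-separation rate constant $k_{CS}$ compete
with the fluorescence rate constant $k_f \approx 1/5.1\,\mathrm{ns} \approx
0.2\,\mathrm{ns^{-1}}$ at the separations and concentrations where quenching
is observed?

This package implements the analysis layer of that question.  It takes
per-frame electronic-state energies (ground GS, charge-separated CS, and
photoexcited ES) sampled along equilibrated molecular-dynamics trajectories —
or synthetic tables with the same statistical structure — and turns them into
free-energy surfaces, Marcus parameters, rate constants with uncertainty
envelopes, exciton-state classifications and statistical-pair concentrations.

## The model

### Free-energy surfaces from energy-gap statistics

Within linear response, the Boltzmann distribution of a vertical energy gap
$\Delta E$ sampled along a trajectory is Gaussian with mean $\mu$ and
standard deviation $\sigma$, and the free-energy surface along the gap
coordinate is the parabola

$$V(\Delta E) = \frac{k_B T}{2}\left(\frac{\Delta E - \mu}{\sigma}\right)^2,$$

with minimum $V(\mu) = 0$.  `fit_gap_distribution()` performs the
maximum-likelihood normal fit (sample mean; sample SD with denominator
$n-1$) and attaches exact small-sample confidence intervals — Student-$t$
for $\mu$, chi-square for $\sigma$.  `build_sampled_fes()` converts a fit
into the parabola.

Two constructions locate the ES surface, which cannot be sampled directly:

* **Companion** (`companion_surface()`): on the $\Delta E = E_{ES}-E_{CS}$
  axis, $V_{ES}(\Delta E) = V_{CS}(\Delta E) + \Delta E$.  Closed forms
  follow: $\lambda = \sigma^2/(2 k_B T)$ and
  $\Delta A = \sigma^2/(2 k_B T) - \mu$.
* **Cross-fit** (`crossfit_es_surface()`): on the $x = E_{CS}-E_{GS}$ axis,
  the linear relation $y = a x + b$ between $y = E_{ES}-E_{CS}$ and $x$
  (fitted by ordinary least squares over the ground-state trajectory, where
  configurations near the ES minimum are actually visited) gives
  $V_{ES}(x) = V_{CS}(x) + a x + b$, with
  $\lambda = a^2\sigma_x^2/(2 k_B T)$ and
  $\Delta A = a^2\sigma_x^2/(2k_BT) - a\mu_x - b$.  Because the
  ground-state thermal ensemble is the geometry distribution immediately
  after photoexcitation, this parameter set doubles as the "initial-rate"
  set.

`summarize_surface_pair()` extracts $\Delta A$ (positive = the CS minimum
lies above the ES minimum, i.e. charge separation is uphill), $\lambda$
(the energy to rearrange nuclei from the ES-optimal to the CS-optimal
geometry without transferring the electron), the surface crossing (the root
of $V_{ES}-V_{CS}$ between the two minima when one exists, else the
lower-energy root) as a height above the ES minimum, and the Marcus region
(inverted iff $-\Delta A > \lambda$).  For equal-curvature surfaces the
crossing height reduces to the Marcus activation energy
$(\lambda+\Delta A)^2/(4\lambda)$, which the tests assert to $10^{-10}$ eV
against golden-section minimization and root bracketing.

### Marcus kinetics

`marcus_rate()` evaluates

$$k_{et} = \frac{2\pi}{\hbar}\,|H_{AB}|^2\,
\frac{1}{\sqrt{4\pi\lambda k_B T}}\,
\exp\!\left(-\frac{(\lambda+\Delta A)^2}{4\lambda k_B T}\right)$$

entirely in eV-based units ($k_B = 8.617333\times10^{-5}$ eV/K,
$\hbar = 6.582120\times10^{-16}$ eV·s, see `physical_constants()`), reported
in ns⁻¹.  The coupling decays with Mg–Mg distance as $\exp(-nR)$ with
$n = \sqrt{-2\epsilon}$ in atomic units (`coupling_decay_constant()`); a
6.5 eV ionization energy gives $n = 1.3$ Å⁻¹, i.e. a factor of ~13 in
$H_{AB}$ — two orders of magnitude in $k$ — per additional 2 Å.

With the literature inputs $H_{ll} = 0.115$ eV, $\lambda = 0.66$ eV,
$\Delta A = 0.39$ eV at 300 K:

```{r rate}
r <- marcus_rate(0.115, 0.66, 0.39,
                 bounds = list(lambda_reorg = c(0.63, 0.71),
                               delta_A = c(0.38, 0.39)))
r
branching_fraction(r$k, 1 / 5.1)
```

### Uncertainty propagation

`propagate_uncertainty()` evaluates a derived quantity over the Cartesian
product of each input parameter's lower bound, point estimate and upper
bound and returns the min/max envelope — the "full range over the
confidence intervals" convention.  Analytic $t$/chi-square/OLS intervals are
the default; the corner scan is conservative (the envelope covers at least
the nominal rate).  A corner at which the evaluator fails is recorded, never
silently dropped.  `marcus_rate_envelope()` propagates the *statistical*
parameters ($\mu$, $\sigma$, and for the cross-fit $a$, $b$) through the
whole surface construction into the rate, which respects the fact that
$\lambda$ and $\Delta A$ are correlated (both are functions of $\sigma$);
combining their individual envelopes as if independent would be wider.
Note that the companion construction carries a substantially larger
$\Delta A$ uncertainty than the cross-fit one, because its ES minimum is an
extrapolation rather than a sampled feature — this is visible in the width
of the pipeline's rate envelopes.

### Exciton model

For the pair excited state, `exciton_system()` builds the Frenkel
Hamiltonian $\hat H = \sum_i E_i |i\rangle\langle i| + \sum_{i\neq j} V_{ij}
|i\rangle\langle j|$ with Coulomb couplings between atomic transition
charges (`transition_charge_coupling()`, vacuum Coulomb with an optional
scalar screening multiplier; the environment's effect is assumed to be
encoded in the transition charges themselves).  `build_and_diagonalize()`
returns eigenstates with a dimensionless oscillator-strength proxy
$|\sum_i c_i \vec\mu_i|^2 / \langle|\vec\mu|^2\rangle$ and a dominance
measure $\max_i c_i^2$; `classify_states()` labels states dark
(proxy < 0.05) or bright and localized (dominance > 0.8) or delocalized.
The thresholds are configurable; the defaults are round numbers chosen once
for a qualitative classification.  An ideal cofacial H-dimer produces a
dark lowest state at $E - V$; site-energy disorder much larger than $|V|$
localizes the lowest state, which is why fluctuating solvent environments
disfavour dark H-aggregate traps.

### Charge embedding

`correct_ion_charges()` implements the per-atom ion correction
$q_i' = q_i + (q_i^{ion} - q_i^{neutral})$, which conserves the moved charge
exactly.  `point_charge_energy()` and `assemble_total_energy()` perform the
direct-sum (non-periodic) electrostatic assembly of the monomer-based QM/MM
decomposition $E = \sum_A E_A^{qm,pol} + \sum_{A<B} E_{AB}^{elec}$; the
direct sum is appropriate for the desk-scale, non-periodic fixtures this
package operates on (periodic Ewald electrostatics belong to the external
simulation engine that produces the energy tables).

### Statistical pairs

`paired_fraction()` estimates the fraction of molecules with a neighbor
within a cutoff $r$ at concentration $c$: with number density
$\rho = c N_A$, the expected neighbor count is $m = \rho\,\tfrac43\pi r^3$.
Three conventions are exposed: `expected_count` ($m$, clamped to [0,1]; the
default, which reproduces the classic 25% at 0.1 mol dm⁻³ and ~4% at
0.014 mol dm⁻³ with $r = 1$ nm), `poisson` ($1-e^{-m}$), and
`expected_count_free_volume` ($\rho$ rescaled by the chlorophyll excluded
volume $\tfrac43\pi r_g^3$, $r_g = 0.96$ nm).  How exactly the excluded
volume enters the literature's printed percentages is not derivable from
the text, so the convention is a method switch rather than hard-coded;
`expected_count` is the default because it is the only variant that
reproduces both printed values.  `paired_fraction_mc()` verifies any of
them by seeded Monte-Carlo placement with periodic minimum-image neighbor
counting (`generate_random_placement()` supplies uniform hard-sphere
configurations).

```{r pairs}
c(at_0.1 = paired_fraction(0.1), at_0.014 = paired_fraction(0.014))
```

## The synthetic-trajectory generator

Real inputs are 500-frame MD trajectories (1 ps spacing) post-processed by
semiempirical electronic-structure calculations.  The generator
(`gap_model_spec()`, `generate_cs_trajectory()`, `generate_gs_trajectory()`,
`generate_couplings()`) emulates exactly the statistical structure the
analysis relies on:

* Gaussian vertical gaps per trajectory (`n_frames = 500` by default,
  matching the study scale);
* an approximately linear ES−CS vs CS−GS gap relation with homoscedastic
  Gaussian residuals (`resid_sd = 0.02` eV);
* log-normally distributed coupling magnitudes (log₁₀ centre −2.8, spread
  0.65 dex), giving the orders-of-magnitude, positively skewed spread seen
  in orientation-resolved coupling distributions with a 500-sample maximum
  near 0.1 eV.

The gap-distribution defaults are *back-derived* from the published Marcus
parameters via the companion closed forms, because the underlying empirical
$\mu,\sigma$ are not reported: $\sigma = \sqrt{2 k_B T \lambda} = 0.1847$ eV
and $\mu = \lambda - \Delta A = 0.27$ eV for the relaxed (CS-trajectory)
set, and $\mu_x = 3.32$ eV, $\sigma_x = 0.3609$ eV, $a = -0.5$, $b = 1.9$ eV
for the ground-state axis so that the cross-fit reproduces the
post-photoexcitation set ($\lambda = 0.63$, $\Delta A = 0.39$ eV).

What the generator deliberately does **not** emulate: temporal
autocorrelation between frames (1 ps spacing justifies treating frames as
independent), anharmonicity of the true surfaces away from their minima,
correlation between coupling magnitude and energy gap, and any
orientation-resolved structure.  Passing tests on synthetic data therefore
demonstrate that the estimators recover parameters of data satisfying the
linear-response assumptions — not that real chlorophyll trajectories
satisfy them.

Every generated artifact takes a single named seed, uses a private RNG
stream (the caller's `.Random.seed` is untouched), and is byte-identical
under a fixed seed.

## Numerical choices

* Physical constants are pinned in one table (`physical_constants()`);
  reproducing the rate constant to its printed precision depends on this.
* Surfaces are stored in the canonical form
  $V(x) = c_2(x-x_0)^2 + c_1(x-x_0) + c_0$; minima and crossings are closed
  form, with golden-section minimization and `uniroot` used only as test
  oracles.
* Crossing-root selection: the root between the two minima (the thermally
  relevant crossing) is preferred; with two such roots, the one with lower
  ES energy wins; identical surfaces report a crossing height of 0.
* Degenerate inputs error early and by name: zero-variance gap samples,
  fewer than 3 frames, constant $x$ in the relation fit, $\lambda \le 0$,
  non-symmetric coupling matrices, coincident charges, over-packed
  hard-sphere boxes.
* A zero slope in the cross-fit makes re-expression onto the gap axis
  impossible; the surface is returned on the original axis with
  `reexpress_failed = TRUE`.
* The "sampled region" of a surface is the 2.5–97.5% sample quantile range;
  a surface minimum outside it sets the `extrapolated` flag on the fit (a
  warning flag, not a correction).
* Whole-percent rounding of pair fractions (half-up) happens only at report
  time.
* Helmholtz free energies are used directly in place of Gibbs; for these
  low-compressibility condensed systems the difference is negligible.

## Design decisions

* The package is organised around one fitting function, `fes_fit()`,
  returning a classed object with `print`/`summary`/`coef`/`predict`/
  `plot`/`simulate`/`residuals` methods, in the style of classic R
  modelling packages; kinetics, exciton, embedding and pair-statistics
  calculators are plain functions.
* Confidence intervals are analytic by default (exact $t$ and chi-square,
  OLS intervals from `stats::confint`); `simulate()` on a fitted model
  provides the building block for bootstrap cross-checks.
* The coupling selection policy from a sampled distribution defaults to the
  maximum (the most optimistic value, appropriate for a feasibility
  argument); mean and median are available.
* The initial-rate estimate (`initial_rate()`) is the same Marcus formula
  with the ground-state-ensemble parameters substituted.  With the rounded
  published inputs ($\lambda = 0.63$, $\Delta A = 0.39$ eV) direct
  evaluation gives ≈0.03 ns⁻¹, whereas the literature quotes 0.04 ns⁻¹ —
  the unrounded inputs behind that figure are unavailable, so the package
  does not force agreement; the two estimates agree to well within a factor
  of 2, which is the level at which the pre-relaxation correction matters.
* Pipeline problem sizes (500 frames, 100-replicate recovery checks, 2,000
  molecules × 20 replicates for the Monte-Carlo pair verifier) mirror the
  study scale while keeping a full run in seconds.

## Known limitations

* Quadratic surfaces are extrapolations beyond the sampled window; the
  `extrapolated` flag is the only diagnostic, mirroring the caution that
  applies to any linear-response reconstruction.
* Marcus theory assumes a thermalized donor ensemble; it is not a model of
  the fast recombination step that follows charge separation, and no
  nonequilibrium dynamics are attempted here.
* Couplings are inputs (or synthetic); no electronic-structure calculation
  of couplings or transition charges is performed.
* The Monte-Carlo pair verifier treats molecules as points/hard spheres;
  orientation-resolved pair statistics are out of scope.

## End-to-end pipeline

```{r pipeline}
report <- run_pipeline(default_config(n_frames = 500, seed = 1))
report
```

The report is deterministic given the config (seed included), serializes to
JSON with `report_as_list()`, and records provenance (seed, confidence,
temperature, config hash, package version).
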