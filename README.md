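# quenchsep

Marcus-theory analysis of chlorophyll fluorescence **concentration
quenching** via photoinduced charge separation.

Concentrated chlorophyll solutions lose their fluorescence because pairs of
molecules that randomly end up within ~10 Å of each other ("statistical
pairs") open a nonradiative decay channel: the photoexcited pair
`(Chl–Chl)*` separates charge to an ion pair `Chl⁺–Chl⁻`, which recombines
to the ground state.  Deciding whether that mechanism is kinetically
feasible requires reconstructing free-energy surfaces for the excited (ES)
and charge-separated (CS) states from molecular-dynamics energy-gap samples
and evaluating electron-transfer rates.  This package is that analysis
layer, for computational (bio)physical chemists working with energy-gap
trajectories from any MD + excited-state engine.

## What it computes

Within linear response, a Gaussian vertical-gap distribution (mean μ, SD σ)
sampled along a trajectory implies the quadratic free-energy surface

    V(ΔE) = (k_B T / 2) · ((ΔE − μ) / σ)²

and the companion/cross-fit constructions locate the ES surface, giving the
reorganization energy λ and driving force ΔA in closed form
(λ = σ²/2k_BT, ΔA = λ − μ for the companion route).  The charge-separation
rate follows from Marcus theory,

    k_et = (2π/ħ) |H_AB|² (4πλk_BT)^(−1/2) exp(−(λ+ΔA)²/(4λk_BT)),

with confidence intervals on the fitted statistical parameters propagated
into envelopes on λ, ΔA and k by a full corner scan.  Around that core the
package provides: an exponential coupling-distance-decay model
(n = √(−2ε) in atomic units), a Frenkel exciton Hamiltonian with
transition-charge Coulomb couplings and dark/localized state
classification, the per-atom ion charge correction and direct-sum QM/MM
electrostatic assembly, statistical-pair concentration estimators with a
Monte-Carlo verifier, and a seeded synthetic-trajectory generator so the
whole pipeline is testable without raw MD data.

## Worked example

The 10 Å ether-solvated chlorophyll pair, using the published Marcus
parameters and the most optimistic LUMO–LUMO coupling:

```r
library(quenchsep)

r <- marcus_rate(0.115, 0.66, 0.39,
                 bounds = list(lambda_reorg = c(0.63, 0.71),
                               delta_A = c(0.38, 0.39)))
r
#> Marcus rate: k = 0.03 ns^-1 (0.0263018 ns^-1), normal region
#>   envelope: [0.02, 0.04] ns^-1
#>   H = 0.115 eV, lambda = 0.66 eV, Delta A = 0.39 eV, T = 300 K

branching_fraction(r$k, 1 / 5.1)
#> [1] 0.118274
```

Charge separation at 0.03 ns⁻¹ is noticeable against fluorescence
(k_f = 1/5.1 ns ≈ 0.2 ns⁻¹) but does not dominate at 10 Å — about 12% of
excitations branch into the charge-transfer channel.  Because the coupling
decays as exp(−nR) with n ≈ 1.3 Å⁻¹ (`coupling_decay_constant(-6.5)`), the
rate collapses by ~two orders of magnitude per additional 2 Å, so the race
flips over just a few ångströms.

Fitting surfaces to a (here synthetic, seeded) 500-frame trajectory of the
ion pair:

```r
tab <- generate_cs_trajectory(gap_model_spec(seed = 1))
fit <- fes_fit(tab, trajectory = "cs")
fit
#> Free-energy surface fit (CS trajectory, 500 frames, 300 K)
#>   gap mu = 0.2742 eV, sigma = 0.1869 eV
#>   lambda  = 0.6758 eV  [0.5992, 0.7682]
#>   Delta A = 0.4017 eV  [0.3086, 0.5105]
#>   Marcus region: normal  (minimum outside sampled region)
```

`mu` and `sigma` describe the fitted gap distribution; `lambda` and
`Delta A` are the derived Marcus parameters with their propagated 95%
envelopes; the flag notes that the companion ES minimum lies outside the
directly sampled gap window (an extrapolation, as expected for this
construction).  `plot(fit)` draws both parabolas with the sampled region
thickened; `run_pipeline(default_config())` chains generator → surfaces →
rates → pair statistics into a JSON-serializable report.

Statistical-pair fractions at the benchmark concentrations:

```r
round(100 * c(paired_fraction(0.1), paired_fraction(0.014)))
#> [1] 25  4
```

## Documentation

The methods vignette (`vignettes/charge-separation-quenching.Rmd`) explains
the model, the uncertainty propagation, what the synthetic generator does
and does not emulate, and the package's numerical and design choices.
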