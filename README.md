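# riboballistic

Ballistic modeling of ribosome density profiles with mRNA degradation, and
the inverse problem of recovering translation kinetic rates from
ribosome-profiling (Ribo-seq) data split by ribosome number.

## The problem

Ribo-seq measures per-codon ribosome coverage, but turning a coverage
profile into absolute kinetic rates — the initiation rate α (1/s) and the
per-codon elongation rates p₁…p_L (codons/s) — is an under-determined
inverse problem: a polysome profile supplies L numbers for L + 1 unknowns,
and its normalization depends on an unknown sequencing depth. This package
implements a modeling framework that resolves the degeneracy by (i)
accounting for finite mRNA lifetime (degradation rate ω, measurable
independently from half-lives, ω = ln 2 / t½) and (ii) splitting the mRNA
population into *k-somes* — mRNAs carrying exactly k ribosomes (monosomes,
disomes, …) — whose density profiles are far more sensitive to degradation
than the bulk polysome signal.

It is aimed at quantitative biologists and modelers who work with
fractionated polysome/Ribo-seq experiments or who need a tractable,
fully-solvable null model of translation.

## The model

Ribosomes are point particles loading at the start codon as a Poisson
process of rate α and moving deterministically with local velocity p(x),
so the crossing time is T(x) = ∫₀ˣ dy/p(y); the transcript is degraded at
rate ω (exponential lifetimes, hence exponential ages
φ_a(a) = ω e^(−ωa)). With dimensionless rates α̃ = αT(L), ω̃ = ωT(L) and
z = α̃ + ω̃, everything is closed-form:

- k-some probabilities
  P_k = (ω̃/z)(α̃/z)^k γ(k+1, z)/k! + α̃^k e^(−z)/k!,
  with Poisson limit P_k^∞ = α̃^k e^(−α̃)/k! at ω̃ = 0;
- k-some densities ρ_k(x) = S_k(x) + F_k(x) (stationary + transient
  contributions), whose entry-codon ratio R_k(0) = F_k(0)/S_k(0)
  quantifies the degradation signal — R₁(0) = ω̃(e^z − 1)/z for
  monosomes;
- polysome density ρ(x) = α e^(−ωT(x))/p(x), mean load
  ⟨k⟩ = α̃ (1 − e^(−ω̃))/ω̃.

The inverse procedure minimizes the summed squared relative residuals
X² = χ²_polysome + χ²_monosome of the unit-normalized polysome and
monosome profiles over (log α, log pᵢ) by L-BFGS-B, at known ω. An exact
stochastic sampler, a TASEP-style exclusion comparator, multinomial
read-noise emulation, a recovery benchmark, and an (α̃, ω̃) phase-diagram
classifier (LD/ID/HD degradation regimes) round out the toolkit. See the
vignette `vignettes/ballistic-model.Rmd` for derivations and design
decisions.

## Worked example

A histone-like gene: α = 0.06 /s, half-life 40 min, homogeneous elongation
with T(L) = 178 s (so p = 0.56 codons/s, L = 100):

```r
library(riboballistic)

prof  <- elongation_profile(rep(100 / 178, 100))
truth <- kinetic_params(alpha = 0.06, omega = log(2) / (40 * 60), prof)
truth
#> <kinetic_params> alpha = 0.06 /s, omega = 0.0002888 /s, L = 100, T(L) = 178 s
#>   dimensionless: alpha_t = 10.68, omega_t = 0.05141

dp <- nondimensionalize(truth)
classify_phase(dp$alpha_t, dp$omega_t)
#> # A tibble: 1 × 5
#>   alpha_t omega_t r1_entry mean_k regime
#> 1    10.7  0.0514     219.   10.4 ID
```

The gene sits in the intermediate-degradation (ID) regime — R₁(0) ≈ 219
means its monosome profile carries a strong degradation signature while
⟨k⟩ ≈ 10.4 is barely below the infinite-lifetime value α̃ ≈ 10.7 — so the
inverse fit is well posed. Recover the rates from the model's own
monosome + normalized polysome profiles:

```r
fit <- fit_rates(forward_profiles(truth), omega = truth$omega)
fit
#> <ballistic_fit> L = 100 codons, alpha* = 0.0616 /s, X^2 = 0.0003024
#>   (polysome 0.000233 + monosome 6.95e-05)
#>   converged: TRUE after 221 objective evaluations; 0 codon(s) masked

score_fit(fit, truth)
#> # A tibble: 1 × 3
#>   err_alpha err_mean err_max
#> 1    0.0267   0.0240  0.0257
```

All 101 rates come back within ~3% (this homogeneous working point is
deliberately modest; random inhomogeneous profiles at higher R₁(0) recover
to ~1%, see `run_benchmark()`). `tidy(fit)` returns the per-codon rates,
`autoplot()` methods plot distributions, profiles and benchmark curves.

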