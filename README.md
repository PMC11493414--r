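# gutmacro

Macroecological models and emergent patterns of gut microbiome count
tables.

Shotgun-metagenomic species profiles of the human gut display a set of
reproducible macroecological patterns — a heavy-tailed mean abundance
distribution (MAD), Taylor's law between a species' across-sample mean
and variance, species abundance distributions, abundance–occupancy
curves, and characteristic α/γ diversity — and those patterns carry an
ecological signal: in dysbiotic (unhealthy) guts the width of
environmental growth-rate fluctuations is larger than in healthy ones.
`gutmacro` is for microbiome researchers and theoretical ecologists who
want to compute these patterns from species × sample count tables, fit
interpretable generative models with at most three free parameters, and
ask which patterns actually discriminate between models and between
community states.

## The models

The starting point is the stochastic logistic model (SLM) for the
abundance `x_i` of species `i`,

    dx_i/dt = (x_i/τ_i)(1 − x_i/K_i) + sqrt(σ_i/τ_i) x_i ξ_i(t),

with carrying capacity `K_i`, environmental noise width `σ_i` and white
Gaussian noise `ξ_i`. Its stationary abundance-fluctuation distribution
is a Gamma with shape `α_i = (2 − σ_i)/σ_i` and rate
`β_i = 2/(σ_i K_i)`: modal away from zero when `σ < 1`, diverging at
zero (rarity- and extinction-prone) when `σ > 1`.

Under compositionality the relative abundances of independent Gamma
species follow the Scaled Dirichlet distribution (2S parameters). Two
macroecological laws reduce it to a fittable family: Taylor's law
`σ²_i = A x̄_i^ζ` collapses the Gamma parameters to
`α_i = x̄_i^{2−ζ}/A`, `β_i = x̄_i^{1−ζ}/A`, and the MAD
(log-Laplace or log-Normal with location μ and scale λ) generates the
mean abundances themselves. Convolving with the read-sampling process
yields three generative models for count tables:

| model | composition | sampling | ζ | free parameters |
|-------|-------------|----------|---|-----------------|
| MD    | Dirichlet | multinomial | 1 | μ, λ, A |
| MSSD  | Symmetric Scaled Dirichlet | multinomial | 2 | λ, A |
| PSLG  | independent Gammas (means sum to 1) | Poisson | 2 | μ, λ, A |

For the ζ = 2 models the Taylor amplitude maps onto the noise width via
`σ = 2A/(1 + A)`, so `A = 1` is exactly the `σ = 1` healthy/dysbiotic
boundary. Models are scored against data with an R²-like statistic per
pattern, per detection cutoff κ ∈ {4.5×10⁻⁷, 9×10⁻⁶, 1.8×10⁻⁴}, averaged
over many seeded model realizations matched to the data's species pool,
sample count and read depths.

## Worked example

Two synthetic cohorts sharing species pool, MAD and read depths,
differing only in noise width (σ = 0.8 vs 1.2):

```r
library(gutmacro)
pc <- paired_cohorts(seed = 42)
pc$healthy
#> abundance_table: 500 species x 100 samples
#>   depths: 102,160 .. 989,331 reads/sample
#>   cohorts: H=100

fit_h <- fit_model(pc$healthy, "mssd")
summary(fit_h)
#> model_spec: Multinomial Symmetric Scaled Dirichlet (zeta = 2)
#>   free parameters: lam = 1.448, A = 0.9446
#>   implied noise width sigma = 0.9715
#>   ...
#> MAD fit: log_laplace, mu = -9.198, lam = 1.448
#>   BIC ratio (LN/LL) = 1.038 (>1 favors Log-Laplace), dBIC = -78.97
#> Taylor's law fit on 476 species
#>   free:  zeta = 1.914, A = 0.4348  (R2 = 0.9949)
#>   fixed: zeta = 2,  A = 0.9446  (R2 = 0.9929, ratio = 0.9980)
```

The fitted MAD scale (λ ≈ 1.45) recovers the generating λ = 1.41, the
Taylor exponent is ≈ 2 (the fixed-exponent fit loses almost nothing:
ratio 0.998), and the implied noise width 0.97 vs 1.34 for the paired
dysbiotic cohort reproduces the σ ordering. The dysbiotic cohort also
loses local diversity after the medium cutoff (mean α 361 vs 410 here).
Model comparison on the healthy table:

```r
compare_models(pc$healthy, models = c("mssd", "md"),
               cutoffs = c(mid = 9e-6), n_realizations = 20, seed = 1,
               patterns = c("AO", "OCCUPANCY"))
#>  cohort model AO.k9e-06 OCCUPANCY.k9e-06
#>       H    md     0.897           -0.560
#>       H  mssd     0.984            0.408
```

The abundance–occupancy curve is reproduced by both models (sampling +
heterogeneous means suffice), while species occupancy separates them:
the MSSD, which carries the Taylor ζ = 2 constraint, clearly beats the
Dirichlet-multinomial. `plot(fit_h)` draws the Taylor scatter with both
fits and the MAD histogram; `simulate(fit_h, nsim = 5, seed = 1)`
returns matched synthetic tables.

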