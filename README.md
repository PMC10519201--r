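# isopart

Quantifying **trophic resource partitioning** among sympatric predators
from two complementary data sources: bulk stable isotope ratios (δ¹³C,
δ¹⁵N — the long-term assimilated diet) and stomach-content prey weights
(the recently ingested diet). The package grew around a three-species
coastal batoid assemblage (*Hypanus dipterurus*, *Narcine entemedor*,
*Rhinoptera steindachneri*) and ships synthetic-data generators
calibrated to that system, but every model works on any data with the
same shape.

## What it computes

**Hierarchical bivariate robust isotope model** (`fit_isotope_hier`):
for individual *i* of species *s*,

    (δ13C_i, δ15N_i) ~ St2(ν, μ_{s,i}, Σ_s),   μ_{s,i} = α_s + Σ_f β_{s,f} x_{f,i}

with season/sex/maturity-stage effects nested within species
(cold = 1, male = 1, juvenile = 1), partial pooling of the intercepts
across species, a Laplace ("Bayesian lasso") shrinkage prior on every
slope, per-species scale matrices via a separation strategy, and a
shared heavy-tail parameter ν. MCMC runs through JAGS; convergence
requires rank-normalized split R-hat < 1.01 and bulk ESS > 2000 on
every parameter (`hier_config`), with automatic retries. Posterior
summaries: species means (`species_means`), pairwise contrasts with
directional probabilities (`species_contrasts`), factor slopes
(`factor_effects`).

**Isotopic niches** (`fit_niche`, `sea_b`): standard ellipse area
SEA = π·√det(Σ), small-sample corrected SEA_c = SEA·(n−1)/(n−2), and the
Bayesian posterior area SEA_B under a vague conjugate
normal–inverse-Wishart prior, with posterior area comparisons
(`compare_areas`).

**Directional niche overlap** (`directional_overlap`,
`overlap_matrix`): the probability that a random individual of species A
falls inside the 95% probability region of species B's bivariate niche,
propagated over posterior uncertainty in both niches — asymmetric by
construction.

**Diet classification** (`rf_classify`): tuned random forests on raw
prey-gram profiles (grid search over trees/depth/features with
stratified 5-fold CV, stratified 75–25 train-test split, ROC AUC),
with undersampling + SMOTE rebalancing of unbalanced training classes
(`balance_classes`) and Shapley prey attributions
(`shapley_importance`, validated against the exhaustive `exact_shapley`
oracle).

**Synthetic data** (`simulate_isotopes`, `simulate_diet`): generators
whose defaults encode the published study conditions (sample sizes and
group compositions, species means, ellipse areas, effect magnitudes,
prey-importance structure), so the entire workflow is testable without
any data download. `run_full_analysis` orchestrates every stage from a
single config and root seed.

## Worked example

```r
library(isopart)

iso <- simulate_isotopes(default_isotope_spec(), seed = 1)
fit <- fit_isotope_hier(iso,
  hier_config(chains = 2, adapt = 250, warmup = 100, draws = 500,
              target_ess = 50, rhat_max = 1.2, max_retries = 0),
  seed = 1)   # lean demo budget; use hier_config() defaults for inference
species_means(fit, force = TRUE)
#>           species isotope      mean hdi_lower hdi_upper
#> 1     N_entemedor    d13C -12.79126 -13.00242 -12.57021
#> 2 R_steindachneri    d13C -14.06883 -14.26518 -13.92169
#> 3    H_dipterurus    d13C -15.90294 -16.30378 -15.48707
#> 4     N_entemedor    d15N  17.94545  17.72497  18.14937
#> 5    H_dipterurus    d15N  16.23972  15.92170  16.53518
#> 6 R_steindachneri    d15N  16.06613  15.91471  16.22690
```

The recovered species means sit where the generator placed them
(*N. entemedor* most ¹³C-enriched — the most benthic/infaunal feeder —
and highest in δ¹⁵N; the other two species similar in δ¹⁵N), with 95%
HDIs of a few tenths of a per-mil at the study's sample sizes.

```r
ellipses <- fit_niche_by_group(iso, ndraw = 2000, seed = 2)
sea_b(ellipses$H_dipterurus)
#> SEA_B [H_dipterurus]: mean 8.66, interval (6.92, 10.60) [2000 draws]
round(unclass(overlap_matrix(ellipses, conf = 0.95, nmc = 5000,
                             seed = 3))[1:3, 1:3], 1)
#>                 H_dipterurus N_entemedor R_steindachneri
#> H_dipterurus              NA        15.4            33.8
#> N_entemedor             68.0          NA            26.2
#> R_steindachneri         99.6        40.0              NA
```

*H. dipterurus* has by far the broadest isotopic niche (SEA_B ≈ 8.7 ‰²
vs ≈ 2 ‰² for the others), so the narrow niches sit largely inside it
(row N_entemedor: 68% of its individuals fall in *H. dipterurus*'s 95%
region; row R_steindachneri: ~100%) while the reverse overlaps are small
— the directional asymmetry that signals one generalist coexisting with
two specialists.

```r
diet <- simulate_diet(default_diet_spec(), seed = 4)
rf <- rf_classify(diet, "species",
                  grid = default_rf_grid()[seq(1, 210, 7), ], seed = 5)
rf
#> Random-forest diet classifier [species]: H_dipterurus vs N_entemedor
#>   tuned: 100 trees, max depth 4, max features 1
#>   CV AUC 1.000 | held-out test AUC 1.000
#>   classes H_dipterurus=205, N_entemedor=187
head(shapley_importance(rf, d = rf$test_data, n_samples = 50,
                        seed = 6)$ranking, 3)
#> [1] "sipunculids" "polychaetes" "stomatopods"
```

The two species' stomach contents are near-perfectly separable, and the
Shapley ranking identifies the infaunal prey (sipunculids, polychaetes)
as the discriminating categories — the prey-level mechanism behind the
isotopic gradient above.

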