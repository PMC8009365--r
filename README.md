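# biomeshift

Biome shift estimation and biome conservatism testing on dated phylogenies,
under both **single-biome** (modal) and **multiple-biome** tip coding.

Many clades contain species that occupy more than one biome, yet analyses of
biome conservatism — the tendency of diversifying lineages to remain in their
ancestral biome — often force each species into a single "modal" biome.
That coding decision changes what counts as a biome shift: switches and
modal-changing expansions survive the collapse, but expansions into a minor
biome and reductions that leave the modal biome unchanged become invisible,
while a change of modal biome within an unchanged occupancy set creates a
spurious shift. `biomeshift` implements the full comparison pipeline for the
two coding approaches, built around New Zealand's three-biome system (Forest
always present, Open since 4 Ma, Alpine since 1.9 Ma) but configurable for
any small biome set.

## What is implemented

* **Time-stratified range-evolution models.** A continuous-time Markov chain
  over biome-occupancy sets *R ⊆ {1..B}*: anagenetic gains at rate
  *d·|R|* into each available unoccupied biome, losses at rate *e* per
  occupied biome (the empty range is absorbing), and cladogenetic event
  tables for the DEC, DIVALIKE and BAYAREALIKE families, each with an
  optional founder-event (+J) component of weight *j* competing with unit
  base weights. Biome availability windows stratify the tree: a state is
  allowed in a stratum only if all its biomes exist there, and the pruning
  likelihood re-masks conditional likelihoods at each stratum boundary.
* **Model selection.** `fit_range_model()` maximises the likelihood with
  bounded quasi-Newton multi-start; `fit_biogeo_models()` fits all six
  models, compares each family against its +J counterpart with a one-tailed
  chi-squared LRT (df = 1), and selects by AIC among the survivors.
* **Biogeographic stochastic mapping.** `sample_history()` /
  `bsm_rates()` draw complete anagenetic + cladogenetic shift histories
  conditional on the tips (endpoint-conditioned uniformization within each
  stratum segment), and count shifts per branch; *simplified* counting
  collapses multiple shifts on a branch to one, and the shift rate is
  shifts / clade size.
* **Conservatism tests.** `conservatism_test()` compares the observed mean
  shift rate (100 stochastic maps) against shift rates from tip-randomised
  occupancy (1000 nulls in a full analysis); conservatism is flagged when
  ≥ 0.95 of null rates exceed the observed rate. `d_statistic()` measures
  phylogenetic signal in each biome's binary occupancy:
  *D = (d_obs − d̄_Brownian) / (d̄_random − d̄_Brownian)*, 1 under random tip
  arrangement, 0 under a Brownian threshold model, NA for invariant traits.
* **Meta-analysis statistics.** Shift rates, specialist percentages, type-7
  group quartiles, one-tailed Welch and paired t tests, OLS regressions with
  residual diagnostics, the proportional decline
  *B_decline = (B_multiple − B_single) / B_multiple*, and stem/crown
  diversification rates (log(n)/t and (log(n) − log 2)/t at ε = 0). The
  compiled table of 25 published lineages and the New Zealand clade tables
  ship as plain TSV (`biome_shift_studies()`, `nz_clade_ages()`,
  `nz_conservatism()`).
* **Synthetic data with known truth.** Birth–death trees
  (`simulate_tree()`), forward Gillespie occupancy histories under the same
  stratified process (`simulate_history()`), Dirichlet modal-biome weights,
  the shift-detection typology classifier (`classify_transitions()`), and
  synthetic meta-analysis tables (`make_meta_table()`).

## Worked example

A 20-tip clade simulated under DEC (d = 0.2, e = 0.05) in the three-biome
system, analysed under both codings:

```r
library(biomeshift)

sim <- simulate_biome_clade(n_tips = 20, d = 0.2, e = 0.05, seed = 7)
fit <- fit_range_model(sim$tree, sim$occ, nz_availability(), "DEC")
fit
#> Range-evolution model fit: DEC
#>   tips: 20, biomes: Forest/Open/Alpine
#>   d = 0.169, e = 0.01242
#>   lnL = -31.73971, k = 2, AIC = 67.47942

bsm_rates(fit, n_runs = 100, seed = 2)
#> Biogeographic stochastic mapping: 100 runs (simplified counting)
#>   mean shift rate 0.678 (± 0.095)

conservatism_test(fit, n_null = 199, n_bsm_obs = 100, seed = 3)
#> Biome conservatism test (199 tip-randomised nulls, simplified counting)
#>   observed shift rate: 0.662 (± 0.084)
#>   proportion of nulls greater: 0.774

# the same clade under single-biome (modal) coding
fit_s <- fit_range_model(sim$tree, sim$occ_single, nz_availability(), "DEC")
bsm_rates(fit_s, n_runs = 100, seed = 2)
#> Biogeographic stochastic mapping: 100 runs (simplified counting)
#>   mean shift rate 0.539 (± 0.08)

b_decline(0.678, 0.539)$percent
#> [1] 21
```

The fitted dispersal rate recovers the generating value, and collapsing the
nine multi-biome species to their modal biome lowers the estimated shift
rate by about a fifth — the single-coding bias the package quantifies.

The packaged meta-analysis reproduces the published comparison of coding
approaches:

```r
meta_report()
#> Biome shift rate meta-analysis
#>   single-coding rates  (n=9): median 0.04 (Q1 0.04, Q3 0.08)
#>   multiple-coding rates (n=16): median 0.55 (Q1 0.41, Q3 0.75)
#>   Welch one-tailed (non-NZ multiple vs single): t(7) = 3.20, p = 0.007791
#>   paired one-tailed (NZ clades): t(8) = 8.449, p = 1.47e-05
#>   proportional decline in shift rate: 14% - 67%
#>   ...
```

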