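# girkrates

Estimation of agonist association (k_on) and dissociation (k_off) rate
constants at G-protein-coupled receptors from the kinetics of GIRK channel
currents — the functional readout used in two-electrode voltage-clamp
recordings from *Xenopus* oocytes — together with a seeded ODE simulator of
the receptor → G protein → GIRK cascade that makes the whole estimation
chain verifiable by parameter recovery.

The package is aimed at pharmacologists analysing (or planning) kinetic
GIRK-readout experiments at the dopamine D2 receptor and similar
Gi/o-coupled receptors: it implements the estimators, the synthetic-data
generator used to validate them, and the downstream statistics.

## The method

The GIRK current tracks receptor occupancy when RGS-accelerated G-protein
turnover is fast, so three protocol shapes yield the kinetics:

* washout of a brief (13 s) application → monoexponential decay, with
  **k_off = 1/τ_deact**;
* sustained applications at several concentrations → monoexponential rise
  with observed rate **k_obs = 1/τ_act**, and
  **k_obs = k_on·[A] + k_off**, so k_on is the slope of k_obs vs [A] over
  the linear (low-concentration) range;
* concentration staircases → **Y = Top/(1 + 10^(LogEC50 − X))** (Bottom 0,
  Hill slope 1), giving pEC50 and the dopamine-normalized efficacy Top.

The kinetic dissociation constant **K_d = k_off/k_on** (pK_d = −log10 K_d)
is validated against the fitted pEC50s across ligands by Spearman rank
correlation with an exact permutation p-value (all n! permutations at
n ≤ 9). A summary-statistics two-way ANOVA (unweighted means) with Sidak
comparisons and an ordinal "arrow" classification of mutant-vs-wild-type
shifts complete the reporting.

The simulator integrates bath exchange (first-order, τ = 0.45 s),
occupancy (with optional competitive antagonist), a single active-G pool
and an instantaneous Hill gate, at 156 Hz with seeded recording noise, in a
deliberately near-linear reporter regime (see the methods vignette in
`vignettes/estimating-binding-kinetics.Rmd`).

## Worked example

```r
library(girkrates)

# ground truth: dopamine at the wild-type D2 receptor
lig <- ligand_kinetics("dopamine", k_on = 9.7e7, k_off = 0.197)
params <- cascade_params()

# washout experiment -> k_off
prot <- make_protocol("washout", "dopamine", 1e-8, tail_s = 52)
trace <- simulate_trace(lig, params, prot, seed = 4)
fit <- fit_deactivation(trace, washout_start = prot$t_end[1], window_s = 42)
koff_from_tau(fit$tau)
#> [1] 0.1897003

# activation series -> k_on from the linear range of k_obs
pts <- purrr::map_dfr(
  activation_concentrations(9.7e7, 0.197),
  ~ run_activation_experiment(lig, params, .x, seed = 4)
)
glance(estimate_kon(pts))
#> # A tibble: 1 × 7
#>        k_on  k_on_sem intercept intercept_sem r_squared n_included n_excluded
#>       <dbl>     <dbl>     <dbl>         <dbl>     <dbl>      <int>      <int>
#> 1 83176356. 2317635.      0.201       0.00369     0.998          4          0

kinetic_kd(koff_from_tau(fit$tau), estimate_kon(pts)$slope)
#> # A tibble: 1 × 2
#>              kd   pkd
#>           <dbl> <dbl>
#> 1 0.00000000228  8.64
```

The recovered k_off (0.190 s⁻¹), k_on (8.3 × 10⁷ M⁻¹s⁻¹) and pK_d (8.64)
sit within a few percent of the generating truths (0.197, 9.7 × 10⁷, 8.69);
the small k_off deficit is the expected solution-exchange bias, which the
property tests assert is always toward slower apparent dissociation.

Reference-dataset arithmetic (kinetic pK_ds, the exact-permutation Spearman
correlation ρ = 0.9048 / p = 0.0046, EC50 transforms, fold changes and the
16-symbol shift-arrow grid) is recomputed by:

```r
reference_checks()
```

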