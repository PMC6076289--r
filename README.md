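# mrafit

Fit ODE models of signalling networks to steady-state perturbation response
data **without simulating the perturbation experiments**.

## The problem

Perturbation screens — siRNA knockdowns of each pathway component, read out
at steady state with amplifying reporters — are a standard way to probe
signal transduction networks such as the RAF → MEK → ERK (MAPK) cascade.
Fitting an ODE model to such data the direct way is expensive: every
candidate parameter vector must be simulated once per perturbation, and the
"direct" target of many perturbing reagents is not even known.

`mrafit` implements the alternative of fitting in the space of **local
response coefficients** (LRCs), the network's scaled Jacobian:

- from **data**, modular response analysis (MRA) turns the measured global
  responses `R_ij = 2 (x_i^j − x_i) / (x_i + x_i^j)` into local ones by
  matrix inversion, `r = −dg(R⁻¹)⁻¹ R⁻¹` (diagonal −1 by definition);
- from a **model**, the same quantity is
  `r_ij = −J_ij x_j / (J_ii x_i)` at the unperturbed steady state — one
  steady state and one Jacobian per stimulation condition, no perturbation
  simulations at all.

An adaptive-weight ABC-SMC sampler then matches the two, using a distance
that combines per-condition LRC matrices with ligand response ratios
(between-condition fold changes), optionally augmented with time courses
and pseudo-steady-state rate constraints. The package ships the two MAPK
cascade models this method was developed around (an EGF-driven cascade with
two ERK-mediated negative feedbacks, and an EGF/NGF cascade with transient
RAS input and ligand-dependent wiring), a full in-silico perturbation
experiment generator, and posterior-predictive tools (dose–response curves,
ligand wash-out time courses, cell-population modality analysis).

## Worked example

```r
library(mrafit)

# 1. simulate the in-silico perturbation experiment: starved cells, EGF at
#    4 doses, siRNA knockdowns of RAF/MEK/ERK totals, amplification x100,
#    Gaussian noise sd 2, six replicates
data <- simulate_experiment(
  function(dose) build_mapk_egf_model(egf = dose),
  doses = c(0.1, 1, 2, 5), sigma = 2, seed = 1
)
nrow(data)
#> [1] 288

# 2. data route: replicate means -> global response matrix -> LRCs
rs <- estimate_response_set(data)
round(unclass(rs$conditions[["EGF_0.1"]]$r), 3)
#>        aRAF   aMEK   aERK
#> aRAF -1.000  0.322 -0.619
#> aMEK  1.138 -1.000  0.093
#> aERK -0.030  0.935 -1.000
round(unclass(rs$conditions[["EGF_5"]]$rho), 2)
#>  aRAF  aMEK  aERK
#> 21.45 13.00 22.32

# 3. model route: one steady state + one Jacobian, no perturbations
round(unclass(model_lrc(build_mapk_egf_model(egf = 0.1))), 3)
#>        aRAF   aMEK   aERK
#> aRAF -1.000  0.000 -0.154
#> aMEK  1.364 -1.000 -0.353
#> aERK  0.000  1.035 -1.000

# 4. the ABC-SMC objective: normalised distance between the two routes
ev <- mapk_egf_evaluator(rs)
ev(mapk_egf_parameters())$distance
#> [1] 0.8789375
```

The data-route matrix recovers the cascade's structure even at this noise
level: the two causal links (RAF→MEK 1.14, MEK→ERK 0.94) and the ERK→RAF
feedback are clearly non-zero, while the absent MEK→RAF and RAF→ERK
interactions stay small; the noise-free model-route matrix shows the exact
pattern. `rho` gives the fold change of each kinase between EGF 5 and
0.1 ng/ml. Fitting then minimises the distance in step 4 over parameters:

```r
res <- run_abc_smc(ev, mapk_egf_prior(), n_abc = 200, n_batch = 200,
                   max_stages = 10, seed = 1)
ensemble_summary(res$final)        # weighted posterior per parameter
pred <- predict_features(res$final) # ensemble-mean LRCs and ratios
ssq_fit_error(rs, pred)            # sum-of-squares fit error
```

A configuration-driven command line (`inst/cli/mrafit.R`) wraps the same
pipeline as `simulate | estimate-lrc | fit | predict` subcommands with YAML
configs, JSON run manifests and resumable, seed-exact fits.

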