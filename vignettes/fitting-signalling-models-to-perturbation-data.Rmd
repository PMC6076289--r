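---
title: "Fitting signalling-network ODE models to steady-state perturbation data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting signalling-network ODE models to steady-state perturbation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrafit)
```

## The problem and the shortcut

Steady-state perturbation response (SSPR) experiments perturb each node of a
signalling network in turn — typically with siRNAs that deplete the total
pool of one protein — let the network relax, and read out the concentration
of every active species. Fitting an ODE model to such data the direct way
requires simulating every perturbation for every candidate parameter vector:
with $N_p$ perturbations per condition, each likelihood evaluation costs
$N_p + 1$ model solves.

`mrafit` implements the shortcut of matching *local response coefficients*
(LRCs) instead of raw concentrations. The LRC matrix is a scaled Jacobian,

$$r_{ij} = -\frac{J_{ij}\, x_j}{J_{ii}\, x_i}\Big|_{x = x_{ss}}, \qquad
r_{ii} \equiv -1,$$

the fractional change of node $i$ per fractional change of node $j$ with all
other network routes severed. Two independent routes lead to $r$:

* **From data** (modular response analysis). Finite perturbations give the
  global response matrix
  $R_{ij} = 2\,(x_i^j - x_i)/(x_i + x_i^j)$ — a symmetric finite-difference
  approximation to $\Delta \ln x_i$ — and the local matrix follows by
  inversion, $r = -\mathrm{dg}(R^{-1})^{-1} R^{-1}$. The sign is fixed by the
  convention $\mathrm{diag}(r) = -1$; the package sets the diagonal to $-1$
  exactly (the analytic value) after the inversion.
* **From the model.** One unperturbed steady state plus one numerical
  Jacobian, per condition. No perturbation is ever simulated.

Because both routes estimate the same dimensionless object, a sampler can
compare them directly, reducing the per-evaluation cost from $N_p + 1$ model
solves to one per stimulation condition. Per-condition LRC matrices are
complemented by *ligand response ratios*
$\rho_i^{j,k} = x_i^j / x_i^k$ — unperturbed steady concentrations of one
stimulation condition relative to a reference condition — which carry the
between-condition scale information that the (per-condition, dimensionless)
LRCs cannot.

## The bundled MAPK cascade models

Both built-in models describe the three-tier RAF → MEK → ERK cascade with
one state per active kinase; the inactive pool is `total − active`, and all
reactions are Michaelis–Menten steps `Ma(k, K, S, M) = k S M / (K + S)`
(activation of substrate `S` by modifier `M`) and `M0(V, K, S) = V S /
(K + S)` (phosphatase-mediated decay).

`build_mapk_egf_model()` is the in-silico workhorse: EGF enters directly as
the modifier of RAF activation, and active ERK closes two negative feedback
loops by catalysing the inactivation of RAF and of MEK. It has 16 free
parameters, with reference values `mapk_egf_parameters()` (all Michaelis
constants 10, rate constants 0.1–2). Units are arbitrary concentration units
and minutes.

`build_mapk_egf_ngf_model()` describes PC12-style cells stimulated by EGF
*or* NGF. RAF is driven by a transient RAS pulse,
$\mathrm{RAS}(t) = \frac{L}{1+L}\, t^5 e^{-k_d t}$ (zero at $t=0$, peak at
$t = 5/k_d$ minutes), so the model is non-autonomous and is analysed through
time courses rather than fixed points. Binary ligand flags switch wiring
that operates only under one ligand: a negative ERK→RAF feedback under EGF,
and a positive ERK→RAF feedback plus a RAF→ERK feed-forward under NGF. Its
24 kinetic parameters plus the three unknown totals give 27 unknowns.

**Total concentrations.** The totals used by the in-silico study are not
fixed by any authoritative source, so the package defaults to
`RAF_TOT = MEK_TOT = ERK_TOT = 100`: one order of magnitude above the
half-saturation constants (all 10), which keeps every kinase in the
responsive part of its Michaelis curve at low dose while allowing strong
activation at high dose. They are configurable everywhere. This choice
matters quantitatively — it sets the dynamic range of the ligand response
ratios (up to ~20-fold between EGF 0.1 and 5 ng/ml under the defaults) — and
is revisited in *Limitations* below.

## The synthetic experiment generator

`simulate_experiment()` emulates the full wet-lab protocol and is the
package's test bed:

* starved cells: all active concentrations start at 0;
* stimulation at doses 0.1, 1, 2 and 5 ng/ml EGF (defaults), relaxed to
  steady state (integrate, then Newton-polish to residual $<10^{-9}$);
* one siRNA knockdown per kinase, modelled as scaling the target's *total*
  by `1 − fraction`; the default fraction 0.5 is a typical siRNA efficiency
  (the exact value used by the original study is not published);
* antibody/reporter amplification by `k_f = 100` (the study states only
  "a large constant"; 100 makes the noise grid σ ∈ {0, 2, 5, 10, 15, 20}
  correspond to roughly 2–20 % of a low-dose signal, which reproduces the
  qualitative regime in which fits degrade at σ ≈ 10–20);
* six replicates with i.i.d. additive Gaussian noise on the amplified
  scale, floored at `1e-6 * k_f` so that ratio-based statistics stay
  defined.

What the generator deliberately does **not** emulate: per-species noise
scaling, replicate-correlated (batch) noise, off-target siRNA effects,
inhibitor-type (activity-reducing) perturbations, or stochastic kinetics.
Tests passing on these data therefore certify the estimation machinery, not
robustness to every artefact of real antibody-array data.

## The objective

`overall_distance()` compares response sets block by block: for each
condition, the Euclidean distance between off-diagonal LRC entries divided
by the observed-side norm $n_r = \lVert r^{\mathrm{obs}}_{i \ne j} \rVert_2$,
plus, for conditions with ratios, the ratio distance divided by
$n_\rho$. Diagonals are excluded — they are $-1$ by construction on both
sides and carry no information. `augmented_distance()` adds, in the same
normalised style, a time-course block and a pseudo-steady-state block: at
time points where concentrations transiently peak (5 min after EGF, 15 min
after NGF in PC12 cells) all derivatives must vanish, so the norm of the
model's rate vector at those times enters with target 0 and weight 1.
Within blocks, entries are unweighted; the only weights are the block
normalisers.

## The sampler

`run_abc_smc()` is an adaptive-weight ABC-SMC sampler. Stage 1 draws from
the prior and keeps the first `n_abc` draws below $\varepsilon_1$; each
later stage resamples ancestors with probability proportional to
`weight × K_c(distance)` (the Gaussian closeness kernel $K_c$ is the
adaptive-weight ingredient), perturbs them in log-parameter space, accepts
below $\varepsilon_t$, and reweights by
$w_k \propto P(\theta_k) / \sum_j p_j\, q(\theta_k \mid \theta_j)$.
Where the underlying algorithm leaves settings open, the package makes these
choices:

* **Priors.** Independent log-normals for positive parameters; the location
  is the natural-scale *median* (`meanlog = log(location)`), the only
  reading consistent with total-concentration priors such as 25/100/400.
  A `location_log` switch honours the log-scale reading. Normal priors are
  available for sign-unconstrained toy problems.
* **Threshold schedule.** $\varepsilon_t$ = the `alpha`-quantile (default:
  median) of the previously accepted distances — monotone by construction.
  $\varepsilon_1$ is set from a pilot sample of the prior (default: the 10 %
  quantile of 1000 pilot draws) so the schedule starts inside the
  informative region; `pilot = 0` restores plain filtered prior sampling.
* **Proposal kernel.** Gaussian in log-parameter coordinates with twice the
  empirical covariance of the selected parent pool — proposals follow the
  correlation structure (the sloppy directions) the population has learned —
  times a scale factor that the driver shrinks when acceptance drops, with a
  2 % jitter floor per parameter so the population can never collapse onto
  clones of a single particle.
* **Selection pressure.** The closeness-kernel bandwidth is chosen each
  stage (by bisection) so that the effective number of distinct ancestors is
  about an eighth of the ensemble, and the weight factor in the selection
  probability is tempered (`w^beta`) toward the same target. Untempered
  selection collapses onto one or two particles whenever the accepted region
  spans a wide range of prior density, which is the norm for a broad prior
  over 16 parameters.
* **Weight stability.** A defensive 10 % of proposals are drawn from the
  prior itself; with the exact mixture density in the weight denominator
  this bounds every importance weight at 10× and keeps the weighted ensemble
  usable.
* **Failures.** Parameter draws with no converged, stable, strictly positive
  steady state evaluate to distance $\infty$ and are simply rejected; the
  underlying method leaves this case open.
* **Termination.** At most `max_stages` (default 10) stages; earlier if
  acceptance stalls below `min_acceptance` or the accepted distances
  degenerate to a point.
* **Reproducibility.** One seed drives everything; per-stage and
  per-particle sub-seeds are derived from it, so results are identical for
  any worker count and resumed runs replay exactly (stage files persist at
  full double precision).

**Posterior predictions.** `predict_features()`, `dose_response()` and
`washout_timecourse()` average the final ensemble *unweighted* by default:
each particle is one fitted model (or one cell of a population), matching
how the method's ensemble predictions are defined; importance weighting is
available via `weighting = "importance"`. Parameter summaries
(`ensemble_summary()`) keep the importance weights.

## Modality analysis

`modality_analysis()` treats per-particle readouts as a cell population:
kernel density estimate (Gaussian kernel, Silverman's bandwidth), then
least-squares fits of one- and two-component Gaussian mixtures to the
density curve. The component count with the smaller fitting error is
reported together with the *modes* — the local maxima of the selected
fitted density. The distinction matters: a two-component fit of a unimodal
sample typically places both components on top of each other, and its
fitted density still has a single mode, so the mode count is the robust
readout of uni- versus bimodality. Degenerate (zero-variance) readouts are
an error, and fewer than 50 readouts are refused.

`sigmoid_fit()` provides the 4-parameter logistic (fitted on the log-dose
axis by least squares) used to summarise dose–response curves; the specific
sigmoid family is a display choice, not part of the estimation method.

## Numerical choices

* Jacobians by central differences with step
  $h_j = \max(10^{-6} |x_j|, 10^{-8})$; agreement with a complex-step oracle
  to $10^{-6}$ relative is enforced in the test suite.
* Steady states by burn-in integration (`deSolve::lsoda`, compiled rate
  functions) followed by damped Newton polishing to residual $<10^{-9}$;
  integrating first avoids converging to unstable fixed points such as the
  starved state of a stimulated cascade. Stability is checked through the
  Jacobian eigenvalues; unstable solutions are flagged and (inside the
  sampler) rejected.
* Zero-concentration steady states are rejected, not regularised: an LRC is
  undefined there, and a condition that produces one cannot contribute
  features.
* The MRA inversion refuses global matrices with condition number above
  $10^8$ and asks for better-separated perturbations instead of returning
  noise.

## Scale of the bundled checks

The test suite runs the full pipeline at a deliberately small scale: 200
particles per stage, at most 10 stages, median threshold schedule, on the
four-dose EGF protocol (the methodological full scale is 1000 particles and
an open-ended schedule). The structural checks — route equivalence between
the Jacobian and perturbation routes, structure recovery from noise-free
knockdowns, conjugate-posterior recovery on a toy problem, modality calls —
are insensitive to this scaling. The absolute fit-quality checks are not:
at 200 × 10 the sampler's threshold typically plateaus around an order of
magnitude above the distance floor, and the resulting sum-of-squares errors
of ensemble-mean features sit well above the error floor that the same code
reaches when the threshold schedule is run to convergence. The fit-quality
tests in `test-acceptance.R` state the full-scale error bands and are
expected to fail at desk scale; they are kept at those bands deliberately,
as the honest record of what the scaled protocol does and does not achieve.
A contributing factor is the default totals (100): they produce ligand
response ratios up to ~20-fold, so the raw sum-of-squares is dominated by
features whose *relative* error the normalised fitting distance treats as
small.

## Limitations

* Classical MRA only: exactly one perturbation per node per condition;
  designs with fewer perturbations (Bayesian or total-least-squares MRA
  variants) are out of scope and raise an explicit error.
* The LRC route inherits MRA's finite-perturbation bias; it vanishes only
  as the knockdown fraction goes to zero (verified to first order in the
  tests).
* No bifurcation or multistability analysis: population bimodality is
  assessed purely through the parameter ensemble.
* Measurement noise is additive Gaussian on the amplified scale, identical
  across species; replicate medians are not offered (sample means are what
  the estimation pipeline defines).
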