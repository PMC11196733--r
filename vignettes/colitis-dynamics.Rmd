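---
title: "Modelling colonic cell-population dynamics in IBD: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling colonic cell-population dynamics in IBD: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`colitisdyn` models the abundance dynamics of colonic cell populations
during experimental colitis and human IBD remission with small systems of
ordinary differential equations, estimates their rate constants from
longitudinal replicate data by penalized maximum likelihood, quantifies
identifiability with profile likelihoods, selects among alternative
stimulus wirings with the corrected Akaike criterion, and connects the
models to transcriptomic data through signature-based deconvolution and
gene-module scoring. This vignette explains the models, the estimation
machinery, the numerical choices, and what the bundled synthetic data
generators do and do not emulate.

## The models

All three variants share one mechanistic idiom: each cell population `X`
follows first-order mass-action kinetics

    dX/dt = (k_turnX * driver - 1 / k_turnX) * X,

where `k_turnX` is the population's *turnover rate*, interpreted as the
ratio of a proliferation to a death rate. The two factors never appear
separately anywhere in the equations, so only their ratio is a model
parameter; `colitisdyn` exposes exactly that ratio. A large turnover makes
the population respond strongly to its stimulus and decay slowly; a small
turnover makes it inert to stimulation and short-lived. Because every cell
equation is multiplicative in `X`, non-negative states can never cross
zero — a structural guarantee the integrator tests assert numerically.

**Core murine model** (6 states, 5 rate constants). DSS in the drinking
water is a known, piecewise-constant input (2.5% for seven days in the
flow-cytometry design). It feeds a tissue `Damage` compartment that decays
into `healedMucosa` at the mucosal healing rate `k_heal`. B cells are
driven by healed mucosa; macrophages, neutrophils and T cells are each
driven by either DSS itself or by accumulated damage — which of the two is
a biological hypothesis, not an assumption, and is resolved by model
selection (below). The default wiring is the selected best model:
neutrophils stimulated directly by DSS, macrophages and T cells by tissue
damage. The free parameters are the five rate constants plus the four
initial cell abundances; `Damage(0)` and `healedMucosa(0)` are fixed at 0
because the experiment starts in healthy animals.

**Extended murine model** (7 states, 6 rate constants) adds an epithelial
population whose turnover is *suppressed* by DSS
(`dEpi/dt = (k_turnE - DSS / k_turnE) * Epi`), matching the epithelial
collapse and recovery seen in the single-cell time course (1.5% DSS for
six days).

**Human remission model** (8 states, 8 rate constants). Clinical sampling
starts in patients with active disease, not at disease onset, so the
external DSS input is replaced by an internal decaying `Cue`
(`Cue(0) = 1` fixed; its scale is absorbed by `k_cue` and `k_turnN`),
active disease and resolution become first-order relaxation variables with
closed-form equilibria `ActiveIBD -> k_act^2` and `Resolution -> k_res^2`,
and the five cell populations keep the murine wiring pattern with
`Cue`/`ActiveIBD`/`Resolution` as drivers. `ActiveIBD(0)`,
`Resolution(0)` and the five cell fractions are estimated. Observables are
relative abundances from deconvolution rather than counts; the state
equations are identical in form, so no transform is applied.

Time is measured in days throughout; the human sampling times 0 h, 4 h,
24 h, 2 weeks, 6 weeks and 14 weeks map to days 0, 1/6, 1, 14, 42 and 98.
DSS concentrations enter the equations as their numeric percentage values
(2.5, 1.5, 1.8) without rescaling. Input segments use the half-open
convention `[start, end)`, which makes a treatment switch on day 7
unambiguous: day 7 itself is off-treatment.

## Numerical integration

The right-hand sides are compiled C code driven by `deSolve::lsoda`
(relative tolerance `1e-8`, absolute `1e-10`). The integration is
restarted at every protocol switch time, so the discontinuous input is
represented exactly instead of being smoothed through a step function —
within each segment the system is autonomous and smooth. Far outside the
data scale (above 1e6 abundance units) the derivatives are smoothly damped
so that the hopeless parameter draws visited during global search return
huge but finite predictions with usable gradients instead of overflowing
the solver; the guard is inactive in any region a converged fit occupies.

## Estimation

The objective is the weighted sum of squared residuals over all records
(replicate mean vs. model prediction, weighted by the replicate SD), which
equals `-2 log L` up to a constant under Gaussian measurement error,
optionally plus a parameter prior. Measurement SDs are taken from the
data, never estimated; because 3-animal SDs can degenerate, every record's
SD is floored at 5% of its observable's mean absolute level.

Parameters are estimated in log10 space, which enforces positivity by
construction and makes the prior natural to state: the default prior
(`mean = 1e0`, `sigma = 1e1`) is implemented as a Gaussian on the log10
parameter centred at 0 with a standard deviation of one decade. Whether
such a prior should act on the natural or the log scale is genuinely open;
the log-scale reading is the default here because a natural-scale Gaussian
with that width would put substantial mass on negative rates, and the
alternative is available by configuring `ibd_prior()` on transformed
values.

**Multi-start search.** Each fit runs `n_starts` Levenberg–Marquardt
trust-region least-squares optimizations (`minpack.lm::nls.lm`) on the
stacked residual vector (data residuals, then prior residuals), started
from points drawn uniformly from the log10 box `[-2, 2]` with a seeded
generator — the box spans the prior's ±2 SD range. The reference analyses
used 100 starts; that remains the default. The optimizer is kept inside
`[-4, 4]` not by hard bounds (hard bounds pin parameters at the box edge
and stall the trust region) but by steeply weighted penalty residuals that
are exactly zero inside the box.

**Structure-aware start points.** The murine landscape on the linear
observation scale is badly multimodal: a population that explodes under a
bad parameter draw produces saturated residual plateaus with almost no
gradient. The package therefore exploits an exact property of the model
class: given `k_heal`, the damage/healing subsystem has a closed form, and
every cell population is exactly `X0 * exp(k * I(t) - t / k)` with `I`
the cumulative integral of its driver. A coarse deterministic grid over
`(k_heal, k)` with `log X0` profiled out in closed form locates the
neighbourhood of the global optimum in milliseconds; the best grid points
are prepended to the random start set (`auto_init = TRUE`, the default).
With them, a handful of starts reliably reach the global optimum that
100 purely random starts frequently miss.

**Two-stage workflow.** The prior regularizes the search but biases the
optimum by more than the width of the (very tight) confidence intervals
this data yields. Point estimation and interval calibration therefore use
two stages: a prior-regularized multi-start search, then a pure-ML polish
started from its optimum (`fit_ibd(..., prior = NULL, init = ...)`).
Profiles of the polished fit give correctly calibrated frequentist
intervals; on noise-free data the polish recovers the generating
parameters to better than `1e-3` in log10.

## Profile likelihood and identifiability

`profile()` steps each parameter away from its optimum in log10 space,
re-optimizing all others at every step (warm-started from the
neighbouring solution), until the objective exceeds the confidence
threshold or a ±3 decade bound. The 95% threshold is the 1-dof
chi-squared quantile 3.84 above the optimum — the pointwise convention;
a simultaneous threshold can be requested through `level`. Stepping is
adaptive with a target objective increment of about 0.25 per step, an
overshoot-shrink retry loop so the crossing is resolved rather than leapt
over, and interpolation of the crossing on the `sqrt(delta chi2)` scale,
which is exact for quadratic profiles. A fixed large minimum number of
points per side would add cost without accuracy here, because the
interpolated crossing is insensitive to step placement; the adaptive
scheme typically spends 10–25 re-optimizations per side. Parameters are
classified `identifiable` (threshold crossed on both sides),
`practically_nonidentifiable` (one side) or
`structurally_nonidentifiable` (flat profile across the bounds).

## Model selection over stimulus wirings

Whether each of macrophages, neutrophils and T cells responds to DSS
itself or to accumulated damage gives 2^3 = 8 candidate wirings,
enumerated in a fixed binary order (Mac as the most significant toggle,
DSS = 0, Damage = 1, ids 1–8); the winning wiring — neutrophils on DSS,
macrophages and T cells on damage — is candidate 6 in this ordering. The
published ordering of its candidate table is not recoverable from the
text, so only the winning wiring itself, not the label, is treated as
ground truth. Each candidate is fitted by the full multi-start machinery
and scored by `AICc = chi2 + 2k + 2k(k+1)/(n-k-1)` computed from the
*data* chi-squared with the prior penalty excluded — the criterion is
defined on the likelihood, and including the prior would penalize
complexity twice. All eight candidates share one parameter count, so the
ranking reduces to the chi-squared ordering; ties break by fewer
parameters, then lower candidate id.

## Deconvolution and module scoring

The reference signature is built by summing single-cell counts per cell
type (pseudo-bulk), dropping all-zero genes and normalizing each column
to counts-per-10k. `deconvolve()` estimates, per bulk sample, the convex
combination of signature columns closest to the sample in least squares,
with non-negativity and an exact sum-to-one equality solved as a quadratic
programme (`quadprog`). Before solving, both matrices are restricted to
shared genes and standardized per gene with the signature's row mean and
SD so that highly expressed genes do not dominate; because that map is
affine per gene and fractions sum to one, noise-free mixtures are still
recovered exactly. "Other" cells are an explicit signature column, not a
residual slack, since real bulk samples contain types absent from any
curated reference. All shared genes enter by default; restricting to
marker genes is available by subsetting the signature. Sum-to-one is a
hard constraint because the outputs are interpreted as relative
abundances.

Gene-module scores are plain means over the module genes of per-gene
z-scored expression, summarized per cell type; genes missing from the
matrix are ignored and constant genes contribute zero. Fancier
binned-control scoring exists in the single-cell literature, but the
published analysis does not specify its scoring function, so the
transparent z-score mean is the default. `correlate()` wraps the Pearson
test used to relate type-level module scores to fitted turnover rates.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the *statistical shape* of each real input so
the whole pipeline is testable offline:

* `synth_counts_dataset()` — replicate cell abundances on the study
  designs: 2.5% DSS days 0–7 sampled on days 0/3/7/10/14 with 3
  replicates (core), 1.5% DSS days 0–6 sampled on days 0/3/6/9/12/15 with
  10 replicates (extended), and the human remission grid with 3 subjects.
  Noise is truncated-at-zero Gaussian with SD proportional to the true
  value, which keeps the replicate SD interpretable as the chi-squared
  weight while respecting non-negativity.
* `synth_reference_scrnaseq()` — negative-binomial counts with disjoint
  up-regulated marker blocks per type, guaranteeing distinguishable
  signatures.
* `synth_bulk_mixtures()` — known convex combinations of signature
  columns under mean-one lognormal noise.
* `synth_module_turnover()` — expression in which module-gene levels rise
  linearly with each type's assigned turnover, so the score–turnover
  correlation is positive by construction.

The generating parameter values (`true_params_core()` and relatives) were
chosen once to give bounded, qualitatively realistic dynamics under the
fixed protocols — neutrophils peaking at the end of DSS exposure, B cells
dipping and then expanding with healing, epithelium collapsing and
recovering, human neutrophil depletion during remission — with the
near-balance between stimulation and decay that any bounded 14-day
trajectory of this model class requires. Every generator is a pure
function of its configuration and seed.

What the generators do *not* emulate: droplet artefacts (ambient RNA,
doublets), batch effects, inter-animal heterogeneity beyond i.i.d.
replicate noise, cross-species homologue mapping, or misspecification of
the ODE structure itself. Passing tests therefore demonstrate that the
machinery is correct and well calibrated under the stated model, not that
the model is true of any particular real dataset.

## Problem sizes used by the tests and the acceptance script

The bundled checks run at deliberately modest sizes chosen as part of the
package's design: noise-free recovery on one dataset with an 8-start
search; confidence-interval calibration over 25 simulated replicates at
5% CV with profiles of the four immune turnover rates (100 coverage
events); wiring selection over 20 simulated replicates with 3 starts per
candidate and slightly relaxed integrator tolerances (ranking only needs
chi-squared ordering, not tight optima); 20 noisy deconvolution mixtures;
and a 100-start waterfall for the multi-start robustness fraction. These
sizes give stable pass/fail behaviour with comfortable margins under the
seeds used.

## Known limitations

* The turnover parametrization couples stimulus gain and decay through a
  single constant; data preferring independent gain and loss rates will
  fit poorly, and that misfit is informative.
* Profile CIs use the pointwise 1-dof threshold; simultaneous coverage
  over many parameters is not targeted.
* The SD floor (5% of the observable level) is a pragmatic guard against
  degenerate 3-replicate SDs; with many replicates it is essentially
  inactive, with few it mildly down-weights the best-measured records.
* The structural initializer covers the murine variants; human fits rely
  on random starts plus the prior, which is adequate because the human
  model's disease variables relax to closed-form equilibria.
* The deconvolution model is linear in the signature; strongly non-linear
  platform effects between reference and bulk are only partially absorbed
  by the per-gene standardization.
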