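# colitisdyn

Deterministic modelling of colonic cell-population dynamics in
inflammatory bowel disease (IBD). The package fits small ordinary
differential equation (ODE) models of immune and epithelial cell
abundances during DSS-induced murine colitis and human IBD remission,
quantifies parameter identifiability with profile likelihoods, selects
among alternative stimulus wirings with the corrected Akaike criterion
(AICc), and links the models to transcriptomics through signature-based
deconvolution of bulk expression and gene-module scoring. It is written
for systems biologists and computational immunologists who want a
self-contained, testable re-implementation of this modelling workflow.

## The model

Each cell population `X` (B cells, macrophages, neutrophils, T cells,
and optionally epithelium) follows first-order mass-action kinetics with
a single *turnover rate* `k_turnX` — the ratio of proliferation to death
rate:

```
dX/dt = (k_turnX * driver − 1 / k_turnX) * X
```

In the murine variants the DSS concentration in the drinking water is a
piecewise-constant input (e.g. 2.5% on days 0–7) feeding a tissue damage
compartment that heals at rate `k_heal`:

```
dDamage/dt       = DSS − k_heal * Damage
dhealedMucosa/dt = k_heal * Damage
```

B cells are driven by healed mucosa; whether macrophages, neutrophils
and T cells respond to DSS itself or to accumulated damage is decided by
fitting all 2³ = 8 candidate wirings and ranking them by AICc computed
from the data χ² (`χ² = Σ ((y_ij − y_i(k, t_j)) / σ_ij)²`, the weighted
sum of squared residuals, equal to −2 log L up to a constant). The human
remission variant replaces DSS by a decaying internal `Cue` and damage
by relaxing `ActiveIBD` / `Resolution` variables. Parameters are
estimated on the log10 scale by multi-start trust-region least squares
with an optional Gaussian prior (mean 1e0, width one decade), and 95%
confidence intervals come from profile likelihoods at the χ²(1 dof)
threshold 3.84.

## Worked example

Everything is runnable offline: the synthetic-data module generates
datasets with the same design as the study protocols from known ground
truth.

```r
library(colitisdyn)

model <- ibd_model("core")            # Neutr<-DSS, Mac/Tcell<-Damage
synth <- synth_counts_dataset(model, cv = 0.05, seed = 1)

# two-stage estimation: prior-regularized search, then pure-ML polish
search <- fit_ibd(model, synth$data, frede_protocol(), n_starts = 8, seed = 1)
fit    <- fit_ibd(model, synth$data, frede_protocol(), prior = NULL,
                  n_starts = 1, seed = 1, init = search$best_log10)
print(fit)
#> Multi-start ML fit of the 'core' colitis model
#>   9 free parameters, 20 data records
#>   best objective: 0.225875  (1/1 starts converged, 100% at the optimum)
#>   best-fit parameters:
#>  k_heal k_turnB k_turnM k_turnN k_turnT Bcell_0   Mac_0 Neutr_0 Tcell_0
#>  0.1977  0.3610  0.4283  0.8024  0.4190  1.9570  1.0400  0.4719  1.4990

profile(fit, which = c("k_turnN", "k_turnB"))
#> Profile likelihood of 2 parameter(s)
#>   k_turnN    identifiable                 CI [0.7801, 0.8375]
#>   k_turnB    identifiable                 CI [0.3566, 0.3655]
```

The fitted turnover rates sit within a few percent of the generating
values (`true_params_core()`: `k_turnB = 0.36`, `k_turnN = 0.8`, ...),
and the profile intervals cover them. Model selection and deconvolution
work the same way:

```r
sel <- select_wiring(enumerate_wirings(model), synth$data,
                     frede_protocol(), n_starts = 3, seed = 1)
head(as.data.frame(sel)[, c("candidate_id", "wiring", "aicc", "rank")], 2)
#>   candidate_id                                wiring      aicc rank
#> 1            6 Mac<-Damage Neutr<-DSS Tcell<-Damage  36.22879    1
#> 2            5    Mac<-Damage Neutr<-DSS Tcell<-DSS 392.74613    2

ref <- synth_reference_scrnaseq(seed = 1)
sig <- build_signature(ref$counts, ref$labels)   # genes x cell types, cp10k
mix <- synth_bulk_mixtures(sig, rbind(s1 = c(.2, .1, .25, .15, .2, .1)))
round(deconvolve(sig, mix)$fractions, 4)         # recovers the mixture
#>    Bcell Epi  Mac Neutr Other Tcell
#> s1   0.2 0.1 0.25  0.15   0.2   0.1
```

(Exact numbers above are what the code prints under these seeds on this
machine; your platform's floating-point details may differ in the last
digits.)

An end-to-end run — fit, waterfall, profiles, selection or deconvolution,
with JSON/CSV outputs — is available through a single YAML configuration
via `run_workflow()`.

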