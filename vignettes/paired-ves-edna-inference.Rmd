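---
title: "Paired VES and eDNA inference: models, design choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired VES and eDNA inference: models, design choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednaoccu)
```

This vignette is the package's own account of the statistical machinery it
implements: the models and their assumptions, the parameters that matter and
their defaults, what the synthetic-data generator does and does not emulate,
and the numerical and design choices that were genuinely open.

## The inference chain

A paired monitoring study visits $n$ stream sites. At each site a crew
performs $J$ visual encounter surveys (VES), counting turtles, and collects
$K$ water filter replicates assayed for the species' DNA. The package chains
four stages:

1. **VES occupancy.** Detection/nondetection histories feed a single-season
   occupancy model; two-stage selection finds the influential covariates and
   model averaging yields occupancy $\psi$ and per-survey detection $p$.
2. **Abundance and density.** Counts at the VES-confirmed sites feed a
   zero-inflated Poisson N-mixture model; model-averaged expected abundance
   divided by per-site stream volume (m$^3$/km) gives turtle density.
3. **eDNA occupancy and detection.** Filter-replicate positives feed the
   same occupancy machinery: an all-sites model with the VES-influential
   site covariates, and an occupied-sites (OS) model with occupancy fixed at
   one and density added as a detection covariate.
4. **Comparison and planning.** Naive rates with $\pm 1$ SE Wald bands, a
   g-test of method independence, cumulative detection curves
   $p^\ast = 1-(1-p)^n$, minimum replicate counts, and the cost ledger.

## Models and assumptions

**Occupancy.** Per site $i$, with logit-linked
$\psi_i$ (site covariates) and $p_{ij}$ (site- or observation-level
covariates),
$$L_i = \psi_i \prod_{j \in \mathrm{obs}(i)} p_{ij}^{y_{ij}}(1-p_{ij})^{1-y_{ij}} + (1-\psi_i)\,\mathbf{1}[\text{all } y_{ij}=0].$$
Missing occasions drop out of the product; a site with no usable occasion
contributes a likelihood factor of one. Assumptions: closure over the
season, no false positives, independent detections given the latent state.
The OS variant fixes $\psi_i \equiv 1$ and is used both for stage-one
covariate screening and for the eDNA detection model at occupied sites.

**N-mixture.** Latent abundance is zero-inflated Poisson:
$P(N=0)=\phi+(1-\phi)e^{-\lambda_i}$,
$P(N=n>0)=(1-\phi)\,\mathrm{Pois}(n;\lambda_i)$, with $\log \lambda_i$
linear in site covariates and $\phi$ shared across sites (no covariates on
the inflation — nothing in the data of interest identifies more). Counts
are binomial thinnings $c_{ij}\sim\mathrm{Binom}(N_i, p_{ij})$. The site
likelihood sums $N$ over $0\ldots K_{\max}$; detection here is
individual-level (the fraction of animals counted), which is why VES
per-survey detection of *occupancy* can be high (≈0.86) while per-survey
detection of *individuals* is low (≈0.28).

**Selection and averaging.** AICc uses the number of sites as effective
sample size — this choice reproduces the published candidate-table
arithmetic exactly (e.g. $-2(-35.07)+2\cdot4+2\cdot4\cdot5/15=80.81$ at
$n=20$). Akaike weights are computed over the **full** candidate set, not a
printed top set: the published top-four VES weights sum to 0.93, which
identifies the larger denominator. Averaging happens on the link scale,
with the unconditional standard error
$\sum_m w_m\sqrt{se_m^2+(\hat\theta_m-\bar\theta)^2}$, then back-transforms,
so averaged probabilities and their intervals stay inside $(0,1)$.

**Two-stage protocol.** Stage one evaluates every observation-covariate
subset of size 0–3 with the state model held constant (occupancy fixed to
one on the detected-site subset; abundance intercept-only). The covariates
of the stage-one best model — "most influential" is operationalized as
exactly that — are then held fixed while every site-covariate subset of
size 0–2 is evaluated on the full data. Intercept-only models are included
in both enumerations; they cost nothing and keep "every combination" true.

## Parameters that matter

| Parameter | Default | Units / scale | Why |
|---|---|---|---|
| `delta_threshold` | 4 | AICc units | conventional cut for a competitive model |
| `z` | 1.96 | link-scale SEs | ≈95% intervals; `z = 1` reproduces the ±1 SE naive bands |
| `max_obs`, `max_site` | 3, 2 | covariates/model | guards against overparameterization at n ≈ 37 |
| `K_max` | max count + 100 | individuals | truncation of the latent-N sum; doubled automatically until the log-likelihood moves < 1e-6 |
| Spearman threshold | 0.7 | \|rho\| | screening warns, never drops — the choice stays with the analyst |
| naive-band `z` | 1 | SEs | labelled ±1 SE; **not** a 95% interval |

## Numerical choices

- **Links**: logit for $\psi$, $p$, $\phi$; log for $\lambda$. Standard for
  these models and unbounded for optimization.
- **Optimization**: BFGS from five deterministic starts (all-zero
  coefficients plus $\pm1$ shifts of each intercept), a coarse pass
  (`reltol` 1e-6) from every start and a tight polish (`reltol` 1e-10) from
  the best. For the N-mixture the exploration pass runs at a reduced
  truncation (max count + 20) purely to locate the basin; every reported
  likelihood uses the full bound, and stability to doubling the bound is
  checked at the optimum.
- **Covariance**: inverse of the numerically differentiated observed
  information. A singular information matrix yields `NA` standard errors
  and intervals reported as unavailable — never fabricated.
- **Boundary fits**: an intercept beyond $\pm10$ on the link scale (fitted
  probabilities within ~5e-5 of 0/1) flags the fit. Flagged fits stay in
  the ranking tables but are excluded from model averages exactly like
  unconverged ones, with weights renormalized and a warning: a quasi-separated
  occupancy submodel otherwise contributes a divergent link-scale estimate
  that dominates the average. If every candidate is flagged, the average
  falls back to the converged set so a result is still reported.
- **Ties** in ranking break deterministically: smaller $K$, then model
  label.
- **`min_replicates`** subtracts 1e-9 inside the ceiling so an exactly
  attained target is not pushed up a replicate by floating-point error.
- **Missing data** are `NA` end to end — never 0, which is a real outcome.

## The synthetic-data generator

`simulation_scenario()` fixes the full generative model;
`simulate_study()` draws from it with one mandatory seed (no hidden
state; same seed, bit-identical data). The latent chain is
$z_i\sim\mathrm{Bern}(\psi_i)$; $N_i=0$ if $z_i=0$, else zero-truncated
Poisson$(\lambda_i)$ — so $z_i=\mathbf 1[N_i>0]$ holds by construction and
the occupancy and abundance stages see coherent data, with marginal
zero-inflation $1-\psi_i$. VES counts are $\mathrm{Binom}(N_i, p^{ves}_{ij})$
with detection $y_{ij}=\mathbf 1[c_{ij}>0]$; eDNA replicates are
$\mathrm{Bern}(z_i\,p^{edna}_{ik})$ with standardized true density
$N_i/\mathrm{volume}_i$ available as a covariate. Covariate families:
standard normal for continuous covariates; water clarity and surveyor rank
ordinal 1–3 uniform; days-since-rain geometric (mean 3 days); rain
accumulation exponential. Ordinal and skewed covariates are standardized by
their theoretical moments inside linear predictors, so effects are always
per SD. Field blanks are structurally negative and not generated — no
false-positive mechanism exists in the model.

`wood_turtle_scenario()` freezes a reference parameterization emulating a
37-site wood turtle study: 3 VES occasions, 3 filter replicates,
marginal occupancy 0.54 (logit intercept 0.18828 with a +0.9 SD forest
effect), occupied-site abundance averaging ≈9 ($\lambda$ intercept
$\log 8.5$ with negative flow-accumulation and embeddedness effects),
individual VES detection 0.28 (giving per-survey occupancy detection
≈0.86), and per-filter eDNA detection averaging 0.57 among occupied sites
(intercept 0.12 with effects density +0.8, days-since-rain +0.6,
temperature −0.6, flow accumulation −0.5 per SD). The two intercepts were
calibrated once by 60 000-site simulation and then frozen; the directions
mirror the qualitative field findings (more animals and drier weather help
eDNA detection; warm water and high flow hurt).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: spatial correlation along stream networks, eDNA
transport and decay mechanics, qPCR technical replicates and laboratory
false positives, observer heterogeneity beyond the covariates, and
violations of closure. Recovery results certify the estimators under the
model's own assumptions, nothing more.

## Problem sizes used by the test-suite

Parameter recovery runs at 500 sites × 3 occasions × 100 replicates for the
occupancy and N-mixture intercepts (bias, RMSE, 95%-interval coverage);
effect-sign recovery in the eDNA OS model at 200 sites × 50 replicates; the
brute-force likelihood oracles enumerate every latent state on instances up
to 3 × 3 with counts ≤ 4. These sizes give Monte-Carlo error comfortably
below the tolerances being checked while keeping a full run on a single CPU
to a few minutes.

## Open design decisions, resolved

- **Occupied sites for the OS stage** = union of VES-confirmed and
  eDNA-positive sites (20 = 17 + 3 in the reference margins), matching the
  published sample size.
- **Density for eDNA-only sites** cannot come from their own counts (they
  have none that matter); it is imputed from the abundance model's covariate
  prediction and flagged `imputed` in the density table.
- **eDNA all-sites models** carry the site covariates of the VES best model
  only (the published table shows forest alone), configurable via
  `site_covariates`.
- **Density averaging** uses all fitted candidates with renormalized
  weights, not just the top set.
- **The naive "CI's"** in the comparison table are ±1 SE Wald bands
  (`z = 1`): that choice reproduces the published 17/37 interval
  (0.38, 0.54) exactly at two decimals, and the output is labelled as ±1 SE
  rather than 95%.

## Known limitations

Small-sample quasi-separation can drive occupancy submodels to the
boundary at n ≈ 37 with two site covariates; such fits are flagged and
excluded from averages (see above) but their presence in the ranking is
itself a warning sign worth inspecting. The g-test and Pearson chi-square
agree only near the independence null; for strongly associated tables the
two statistics differ by a constant factor however large the counts. The
N-mixture likelihood assumes the zero-inflation is shared across sites;
site-level inflation covariates are out of scope, as are open-population
dynamics, negative-binomial mixtures, and Bayesian fitting.
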