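---
title: "Methods: Bayesian analysis of eDNA detection experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian analysis of eDNA detection experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical methods implemented by
`ednadetect`, the modelling conventions the package adopts, and the known
limits of reproducing the published analysis of the bundled four-pond
African jewelfish experiment.

## The data and the bundled study

One record per 1-L water sample: pond, study day, pond section (1–3),
transect (1–9, three per section), water-column position (surface, middle,
bottom), pond-level fish density (fish/m³), pond-day mean water
temperature (°C), and a binary qPCR detection outcome.

The bundled study (`builtin_pond_study()`) reconstructs the published
324-sample experiment — 4 ponds (one fishless control; stocked densities
0.32, 1.75 and 5.24 fish/m³) × 3 days × 27 samples — from the published
per-pond-day-position detection counts (28 detections in total, all in
stocked ponds). Which of the nine samples in a cell were the detections
was not recorded; the package assigns them deterministically to the lowest
transect indices. For any model without section or transect random
effects the likelihood depends on the data only through the per-cell
counts, so this choice is inferentially neutral for the models analysed
below; random-effect fits on the fixture are approximate in this one
respect.

## The detection model

For sample $i$ with detection indicator $y_i$,

$$y_i \sim \text{Bernoulli}(p_i), \qquad
\text{logit}(p_i) = \beta_0 + \beta_d z_{d,i} + \beta_t z_{t,i}
 + \beta_m \mathbb{1}[\text{middle}_i] + \beta_b \mathbb{1}[\text{bottom}_i]
 + \beta_{day}\, day_i + u_{s(i)} + v_{tr(i)},$$

where $z_d$ and $z_t$ are standardized density and temperature, surface is
the baseline position, and $u_s \sim N(0, \sigma_s^2)$,
$v_{tr} \sim N(0, \sigma_{tr}^2)$ are optional section- and
transect-level random intercepts (`variance_structures()` enumerates the
four structures). Fixed effects get independent $N(0, 10^2)$ priors by
default (`prior_spec()`; a standard-logistic option gives a prior flat on
the probability scale for intercept-only models), and random-effect SDs a
Uniform(0, 10) prior.

### Standardization

Two conventions for scaling density are supported and documented because
they matter:

* `std_from_data(x, "data-distinct-values")` — SD over the distinct pond
  densities {0.32, 1.75, 5.24}, which is 2.53 fish/m³, the constant quoted
  in the published methods;
* `std_from_data(x, "data-all-rows")` — SD over all 243 stocked sample
  values, 2.07 fish/m³.

`paper_standardization()` (the package default for the bundled analysis)
uses the **all-rows** scale for density and explicit constants
(mean 29.60 °C, SD 1.02 °C) for temperature. The all-rows convention is
adopted because it is the one that makes the published numbers cohere:
under it, the published coefficients reproduce the published per-sample
detection probabilities (≈3%, 7%, 54–55% across the stocked densities at
28 °C, surface), the sum of fitted probabilities over the 243 samples
equals the 28 observed detections, and the >100-samples result at the
lowest density follows (111 samples for 95% certainty). Under the
distinct-values (2.53) scale none of these hold. The per-stratum
temperature measurements behind the 1.02 °C constant were not published,
so temperature is carried as an explicit constant rather than recomputed.

## Posterior inference

`fit_detection_model()` runs several independent chains of an adaptive
componentwise random-walk Metropolis sampler written for this package:

* one scalar Gaussian proposal per fixed effect, per log random-effect SD
  (with the Jacobian term) and per random intercept;
* proposal scales adapt every 50 iterations toward a 0.44 acceptance rate
  during burn-in only, and are frozen afterwards so the retained chain is
  a valid Markov chain;
* the likelihood is evaluated on data collapsed to unique (covariate row,
  section, transect) patterns as binomial counts, which is exactly equal
  to the record-level Bernoulli log-likelihood and makes the default
  3 × 200,000-iteration profile run in minutes;
* the linear predictor is updated incrementally with a periodic full
  recomputation to kill round-off drift, and `log(1 + e^x)` is evaluated
  with an overflow-safe branch;
* chains start over-dispersed ($\beta \sim N(0, 2)$) from sub-seeds
  derived from one user seed, so every fit is bit-reproducible.

Convergence is assessed with the Gelman–Rubin potential scale reduction
factor (`gelman_rubin()`, flagging values above 1.1). The sampler is
validated in the test suite against deterministic grid integration of the
intercept-only posterior and the conjugate Beta posterior of the control
data, and by parameter recovery across simulated studies; during
development it was also cross-checked against an independent Gibbs/JAGS
fit of the same model, agreeing on posterior means to ~0.01.

## Model selection

`dic()` computes $\bar D$ (posterior mean deviance),
$p_D = \bar D - D(\bar\theta)$ with $\bar\theta$ the posterior means of
all sampled quantities, and $\mathrm{DIC} = \bar D + p_D$. Candidate sets
are every subset of the supplied predictors (`enumerate_candidates()`,
16 models for four predictors). DIC weights are
$w_i \propto \exp(-\Delta_i/2)$; `confidence_set()` keeps models whose
weight is within 10% of the best and renormalizes;
`plausibility_ratios()` reports best-to-competitor weight ratios using the
published convention of rounding weights to two decimals first (the
unrounded ratios are attached as an attribute).

## Posterior-predictive checking

`bayesian_p_value()` simulates replicate datasets at retained draws and
reports $\Pr\{T(y^{rep}) \ge T(y)\}$. Three discrepancies are provided.
The per-observation Pearson and deviance measures are standard but, for
binary data under an intercept-only model, are functions of the total
detection count alone — which the model always matches — so they have
essentially no power against structural misfit. The `pearson_cell`
discrepancy therefore aggregates to pond-day-position cells before
computing the Pearson statistic; in the test suite it flags an
intercept-only fit to the strongly density-structured bundled data
(p ≈ 0) that the per-observation measures score as adequate (p ≈ 0.5).

## False positives

Any detection in the fishless control pond is a false positive.
`fit_false_positive()` fits the intercept-only model to the 81 control
samples and `expected_false_positives()` projects the posterior of the
per-sample rate onto a chosen number of samples (expected count and a
predictive interval of Binomial counts). With zero detections the
posterior is dominated by the prior, so `false_positive_report()`
mandatorily refits under several prior SDs and reports the estimate under
each; the per-sample rate roughly halves as the prior SD doubles, which is
why no single number is offered as "the" false-positive rate.

## Survey design

With per-sample detection probability $p$, the cumulative probability of
at least one detection in $n$ independent samples is $1 - (1-p)^n$, and
the smallest $n$ reaching a target certainty $c$ is
$\lceil \log(1-c)/\log(1-p) \rceil$ (`samples_required()`; 42 samples at
$p = 0.07$ for 95%). `detection_curve()` evaluates the fitted model over a
density grid and tabulates the curves plus samples-required, and
`per_sample_probability()` / `posterior_mean_probability()` give the
plug-in and posterior-averaged probabilities at arbitrary covariate
settings.

## What does and does not reproduce

Reproduced exactly (given the published inputs): the density-SD constant
2.53 over distinct densities; odds ratios of the published coefficients;
DIC weights {0.39, 0.27, 0.16, 0.11, 0.07} and plausibility ratio 1.44
from the published ΔDIC values; samples-required 42 at p = 0.07 and ≥95%
cumulative detection at p = 0.55 with n = 5; per-sample probabilities
0.027 / 0.076 / 0.540 and samples-required 111 / 39 / 4 at the published
coefficients under `paper_standardization()`.

Not reproduced, deliberately left honest:

* **Refit density coefficient.** Refitting the best model to the
  reconstructed 243 samples yields a posterior mean of ~1.78 (SD ~0.36)
  for the density slope versus the published 1.58. The temperature
  coefficient falls inside the published 95% interval, the published
  ranking of models is reproduced, and the survey-design numbers implied
  by the published coefficients are reproduced, so the gap is attributed
  to unpublished details of the original fit — the per-stratum
  temperature measurements (only pond-day means are published) and the
  original prior/sampler settings. The corresponding acceptance assertion
  (1.58 ± 0.15) is kept as stated and fails honestly in the test suite
  rather than being tuned away.
* **Absolute DIC / pD values.** These depend on the same unpublished
  details; the package checks the published *ranking* (density +
  temperature models outrank density-only) instead.
* **Zero-detection false-positive summaries.** The published intercept
  (−4.20), rate (0.014) and expected count (3.62) are prior-dependent;
  the package reproduces them qualitatively and always attaches the
  prior-sensitivity table.
* **A published goodness-of-fit p-value (0.58)** for the global model is
  not recovered on the reconstructed data under any of the three
  discrepancies (values 0.11–0.38); the package instead demonstrates by
  simulation that its p-values are calibrated and have power.
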