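---
title: "Inferring group resource holding potential from dyadic intergroup contests"
author: "contestRHP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring group resource holding potential from dyadic intergroup contests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

When two social groups fight, which properties of the groups and of their
members decide who wins? In behavioral ecology this question is framed as
identifying proxies of *resource holding potential* (RHP): the measurable
properties that best predict competitive success. contestRHP implements,
as a reusable and tested pipeline, an inference design developed for
long-term observational data on dyadic intergroup contests in a
cooperatively breeding mongoose population: roughly a dozen social groups
of ~20 adults each, a male-biased adult sex ratio (~1.6 males per female),
contests with a clear winner and loser, and body-weight records collected
opportunistically over many years.

The pipeline answers the question with fifteen *relative predictors*: for
each of three member classes (all adults, males, subordinate males), the
focal-minus-rival difference in member count, mean weight, maximum weight,
mean age and maximum age. A male is *dominant* when he mate-guarded an
estrus female within 180 days before the contest, and *subordinate*
otherwise; adults are individuals older than 6 months; an individual's
weight is usable when it was measured within 120 days before the contest.

# The contest model

Contest outcomes are modeled with binomial mixed models on the logit
scale,

$$\mathrm{logit}\, P(\text{focal wins}) = \mathbf{x}^\top \beta +
u_{\text{focal}} + v_{\text{rival}},$$

where $\mathbf{x}$ holds unit-variance-scaled relative predictors and
$u, v$ are random intercepts for focal and rival group identity. Because
the focal/rival designation is an arbitrary label (it is randomized once,
with outcomes flipped on swap), the data-generating structure is really
antisymmetric: a single latent ability $a_g$ per group entering as
$a_{\text{focal}} - a_{\text{rival}}$. The maximum-likelihood pipeline
follows the field convention of two independent intercepts; the package's
Bayesian module refits the chosen model under the correct constraint
(equal variances, correlation $-1$), which is equivalent to the
$a_{\text{focal}} - a_{\text{rival}}$ form. The consequences of this
mismatch are real and are quantified below under *Known limitations*.

## Multimodel inference

Rather than one regression, the pipeline compares twelve *global* models,
one per combination of member class (3) x weight aggregation (mean or
max) x age aggregation (mean or max). Each global model contains the
class's relative count, one weight aggregate and one age aggregate, so
every global is free of within-model mean/max collinearity and the twelve
together span all fifteen predictors. The exact composition is a
reconstruction (the original's model list is not recoverable from the main
text) and is exposed via `global_model_catalog()`, so an alternative
catalog can be substituted without touching the rest of the stack.

All subsets of each global model (including the intercept-only model) are
pooled and deduplicated by term set — 52 unique candidates for the default
catalog — and each candidate is fitted by maximum likelihood. Candidates
are then ranked by AICc,

$$\mathrm{AICc} = -2\ell + 2k + \frac{2k(k+1)}{n-k-1},$$

with $k$ counting fixed effects plus variance components and $n$ the
number of contests. The *top set* keeps models with $\Delta\mathrm{AICc} <
6$ (strict) from the best candidate; a *nesting rule* then removes any
model that fits no better than a strictly simpler model nested inside it
(ties removed by parsimony). Within the final set, model likelihoods are
$l_i = e^{-0.5\Delta_i}$, weights $w_i = l_i / \sum_j l_j$, model-averaged
coefficients $\bar\beta = \sum_i w_i \hat\beta_i$ with $\hat\beta_i = 0$
where a predictor is absent, and a predictor's *variable importance* is
the summed weight of the models containing it.

## Missing weights and the iterated loop

Weights are the one chronically missing covariate. A contest enters the
analysis only when both groups have at most 20% of members with missing
weight (inclusive boundary). Each remaining missing weight is imputed by
one draw from a truncated normal distribution parameterized by the mean
and SD of a *reference set*: weight observations of same-group, same-sex
individuals (same pregnancy status for females) taken when the observed
individual was within 60 days of the target's age. This is an age-matched
query against the group's weight *history* — it is what ties imputation to
the group's growth curve and why the validity check below compares growth
curves. A contemporary-roster variant (`reference_mode = "contemporary"`)
is available; under realistic age structures it produces almost
universally empty reference sets and exists mainly for comparison. Default
truncation bounds are the reference minimum and maximum (draws stay
biologically plausible); `"nonnegative"` and `"none"` are selectable. A
reference set of size one is used verbatim (its SD is undefined), and a
member with an empty reference set causes its contest to be dropped and
logged. Observed weights are never modified.

Because imputation is random, the whole model-comparison procedure is
repeated (default 200 iterations here; the scale of the original design is
10,000), each iteration re-imputing, re-scaling and refitting every
candidate containing a weight predictor (weight-free candidates have
identical data in every iteration and are fitted once — an exact
memoization, not an approximation). Models appearing in fewer than 50% of
iterations (strictly) are discarded as imputation artifacts; each
iteration's weights, averaged coefficients and importances are then
recomputed over the surviving models, and 2.5/50/97.5 empirical
percentiles (type-7 estimator, configurable) are reported across
iterations. Every iteration's randomness derives from
`derive_seed(base_seed, i)`, so results are independent of execution
order.

The imputation-validity check fits the three-parameter asymptotic growth
curve $w(\text{age}) = c + (d - c)(1 - e^{-\text{age}/e})$ per group with
and without imputed values (via `nls` and the self-starting `SSasymp`,
which is the same model reparameterized) and compares parameters against
their joint standard errors.

# Mixed-model machinery

All models — binomial (with optional trial sizes, e.g. pups sired out of a
litter), Poisson with a log link, and Gaussian — are fitted by one
compiled engine: Laplace-approximate maximum likelihood with crossed
random intercepts, maximizing jointly over the fixed effects and
log-standard-deviations by quasi-Newton iteration with analytic gradients
(including the third-derivative correction terms from the log-determinant)
and an inner Newton solver for the random-effect modes. Poisson models can
add an observation-level random effect (OLRE) to absorb overdispersion.
Everything is ML (no REML), so log-likelihoods are comparable across
fixed-effect structures for AICc and for single-term-deletion
likelihood-ratio tests (`drop1_lr`).

Numerical choices that matter:

* Convergence requires a gradient infinity-norm below `1e-5`, relaxed
  proportionally for objectives of large magnitude (response-scale
  Gaussian likelihoods), with BFGS restarts on stalled line searches.
* Log-SDs are optimized in a box: the lower bound (sigma ~ 5e-5) is the
  variance-zero boundary, at which the Laplace likelihood provably equals
  the plain GLM likelihood (tested to 1e-6). The upper bound is
  family-dependent: latent logit/log scales cannot support SDs above
  `exp(4)` without degenerating, while Gaussian response scales (grams)
  get a wide bound.
* Wald covariance of the fixed effects is the inverse of the profiled
  information `X'WX - X'WZ H^{-1} Z'WX` at the joint mode, the same
  convention as the standard mixed-model engines; fits agree with
  `lme4::glmer`/`lmer` (the independent cross-check in the test suite) to
  ~1e-4 in log-likelihood.
* Fits with any |scaled coefficient| > 15 are flagged as separation;
  non-converged fits are excluded from model sets and logged.

# The Bayesian cross-check

`fit_constrained_contest()` refits the chosen model with the symmetry
constraint imposed exactly: `logit P = X beta + sigma_a (z_f - z_r)` with
`z_g ~ Normal(0, 1)` (non-centered). Priors are Normal(0, 2.5^2) on
scaled-metric coefficients and half-Normal(0, 1) on `sigma_a` — the
original's priors are not recoverable, so these weakly-informative
defaults are declared and config-exposed. The sampler is random-walk
Metropolis-within-Gibbs with per-coordinate step adaptation during warmup
(target acceptance 0.2–0.4), plus two structural moves that this posterior
needs: an interweaving (centered-parameterization) update of `sigma_a`
holding the abilities fixed, and an exact Gibbs draw of the mean of `z`
along the all-ones direction, where the likelihood is flat and only the
prior identifies the level. Convergence demands split-R-hat < 1.05 for
every parameter; `compare_to_ml()` reports sign agreement and
standardized differences against the ML fit.

# The synthetic-data generator

The generator is first-class, tested code with known ground truth. Its
defaults emulate the study conditions: 11 groups x 20 adults, male
fraction 1.6/2.6, male/female growth asymptotes 1440/1293 g (lower limit
300 g, rate scale 200 d — chosen to reproduce the reported adult means;
the real population's weighing cadence is unreported, so the 30-day
interval is a free parameter), 30% of males mate-guarding per ~90-day
breeding cycle, ~5% immigrants (assumed 2 years old at immigration and
weighed on arrival), and contests whose outcomes follow the logistic model
above with default true effects `rel_n_males = 1.0`, `rel_max_age_males =
0.6` and latent-ability SD 0.5 (the magnitudes fixed by the package's own
recovery benchmarks).

Two structural features were added after inspecting what the analysis
pipeline *requires* of realistic data:

* **Synchronous communal litters.** Births happen in per-group cohorts at
  90-day intervals, recent cohorts larger (exponential decay, scale 2.5
  y). Exact same-age groupmates are what make age-matched reference sets
  non-empty and what produce the multi-senior-male ties the follow-up
  analyses count.
* **Group-clustered missingness.** Masking weights completely at random
  at the study's 22% marginal rate would leave essentially every group
  with a missing member and almost no contest passing the 20% rule,
  contradicting the study's reported attrition. The `"clustered"` mode
  draws a per-contest-side masking probability from a Beta distribution
  with mean equal to the marginal rate and shape calibrated so ~72% of
  group-sightings contain at least one missing member — after which the
  pipeline's analyzed set lands at ~90–100 of 300 generated contests,
  matching the study's final dataset size. Plain MCAR and an
  age-dependent missing-at-random mode remain available.

What the generator does *not* emulate: group fission/formation, territory
geometry, pup care dynamics, observation effort varying over time,
non-random contest initiation, and any correlation between ability and
group composition beyond what the outcome model induces. Passing
validation on synthetic data therefore demonstrates that the *machinery*
is correct and calibrated under the stated model; it cannot certify the
model's adequacy for any particular field dataset.

# Validation design and problem sizes

The test suite validates each layer against an independent route:
closed-form arithmetic for the growth curve, AICc, Akaike weights and
model averaging; brute-force enumeration oracles for the candidate set,
the nesting rule and the exact binomial test; numerical integration for
truncated-normal moments; `glm`/`lm` in the variance-zero limit and
`lme4` on mixed fits; null-calibration (uniform p-values) for the LR
tests; and Monte-Carlo recovery of generator truth throughout. The
deeper experiments run at these sizes: coefficient recovery at 500
contests x 200 replicates; the end-to-end pipeline at 300 generated
contests, 22% clustered missingness, 200 iterations x 50 replicates;
growth-curve preservation over 200+ imputed groups; liability-threshold
recovery over 100 replicates.

# Known limitations

* **Wald coverage under the symmetry mismatch.** With latent abilities of
  SD 0.5 entering antisymmetrically, 95% Wald intervals from the
  two-intercept ML contest model cover the true coefficients ~83–86% of
  the time (at 500 contests; ~97% when abilities are absent). `lme4`
  reproduces the same coverage on identical data to within a percentage
  point, so this is a property of the conventional model specification,
  not of the optimizer — and it is the quantitative reason the constrained
  Bayesian refit exists.
* **Importance rankings need strong effects.** At the generator's default
  effect sizes (1.0 and 0.6 on scaled predictors), the weaker driver's
  median importance outranks its correlated proxies (`rel_max_age_all`,
  `rel_mean_age_males`, r ~ 0.5–0.9) in only about half of study-scale
  replicates, and about 70% even with no missingness and all 300 contests
  analyzed. Reliable top-2 dominance of both drivers requires either
  larger effects or materially more contests than the emulated study
  provides; single-dataset importance intervals (which reflect only
  imputation noise, as in the original design) are much tighter than
  across-dataset sampling variation, and the two should not be conflated.
* The LMM module is ML-only; REML is not implemented (model comparison
  and LR tests all require ML here).
* A member whose pregnancy status is unknown (no usable weight
  observation) is treated as non-pregnant when matching references.
* The nesting rule is applied pairwise over the retained set in a single
  pass, with ties removing the more complex model; other published
  variants (iterative removal, log-likelihood comparison) are not
  implemented.
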