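---
title: "Location-scale beta-binomial models for bounded longitudinal scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Location-scale beta-binomial models for bounded longitudinal scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Repeated cognitive testing in ageing cohorts produces bounded counts: a
word-recall task scored 0–20 (two passes over a 10-word list), measured at
up to seven biennial waves. Interest increasingly lies not only in a
person's *average* performance but in their *intraindividual variability*
(IIV) — how much they fluctuate around their own trajectory. Deriving a
per-person SD and regressing on it ignores the sampling noise of a handful
of observations and is biased by the floor and ceiling of the score: a
person whose mean sits near 0 or 20 cannot show much spread no matter how
variable they really are.

`melsbb` fits a mixed-effects location-scale (MELS) beta-binomial model
that addresses both problems. The score is beta-binomial: each count is
`n` Bernoulli trials whose success probability is drawn from a beta
distribution with mean `p` and dispersion `theta` (shape parameters
`p*theta` and `(1-p)*theta`). Both parameters get their own linear
predictor:

* location: `logit(p_ij) = x_ij' beta_p + u0_i + u1_i * age_ij`
* scale: `log(theta_ij) = w_ij' beta_theta + v0_i`

with `(u0, u1, v0)` trivariate normal across persons, free correlations.
Small `theta` means the underlying probability is widely dispersed — high
IIV; at `theta = 2` and `p = 0.5` every probability is equally likely and
the 0–20 count is uniform; as `theta` grows the count approaches the
binomial. Because the dispersion submodel carries both fixed effects and
a person intercept, IIV can be regressed on time-varying covariates while
floor/ceiling effects are handled by the bounded likelihood itself rather
than biasing a derived summary statistic.

## Covariate encodings

`build_design()` applies the conventions the model expects:

* age centred at 74.2 years and scaled to decades (both configurable);
  the location predictor uses a restricted cubic spline in centred age
  (Harrell's quantile knot placements for 3–5 knots; explicit knot
  locations can be supplied), while the dispersion predictor and the
  random slope use linear centred age;
* cohort = the year the person turned 65, centred at 1999, in decades;
* sex and education dummy-coded with male and no-qualifications reference
  levels;
* the ADL-difficulty count (0–5) and interviewer test-issue indicator are
  split into a person mean ("between" effect) and the wave deviation from
  it ("within" effect); the two components reconstruct the covariate
  exactly and the within part averages to zero inside every person.

The spline basis is the truncated-power restricted cubic form, linear
beyond its boundary knots (verified in the tests by numerical second
differences), with the nonlinear columns scaled by the squared knot span
so all columns live on the scale of the linear term.

## Priors

The published analysis does not state its priors in the main text, so the
defaults here are the package's own weakly-informative choice, not a
reproduction: normal(0, 5) on the two intercepts, normal(0, 2.5) on every
other fixed effect, half-Student-t(3, 0, 2.5) on the three random-effect
SDs, and LKJ(1) — uniform over valid correlation matrices — on the
random-effect correlation. All are configurable through `mels_priors()`.
The LKJ prior is implemented through canonical partial correlations
(`z21, z31 ~ 2 Beta(3/2, 3/2) - 1`, `z32 ~ 2 Beta(1, 1) - 1` for the
3-dimensional case), a construction checked in development against
rejection sampling of uniformly distributed positive-definite correlation
matrices.

## Inference paths

`fit_map_laplace()` is the fast deterministic path: the person effects are
integrated out by a Laplace approximation (automatic differentiation
through TMB, the same machinery glmmTMB builds on; the model template is
the package's own), and the posterior mode of the fixed effects, SDs and
correlation parameters is found by quasi-Newton optimization with a
binomial-GLM warm start. Standard errors come from the curvature at the
mode, delta-method transformed for SDs (log scale) and correlations
(Fisher-z scale). If the optimizer reports false convergence with a large
score — which in practice means an inner Laplace solve was poisoned — the
fit retries and then falls back to a two-phase schedule (variance block
held fixed while the regression coefficients settle, then everything
free).

`fit_mcmc()` is the full-Bayes path, running Gibbs/slice sampling in JAGS
with the marginal beta-binomial likelihood entered through the standard
Poisson-zeros device. A latent per-observation beta probability would be
conjugate but places an unbounded density in the graph whenever
`theta < 1` (the U-shaped beta), which stalls the slice sampler; the
marginal form is finite everywhere. One-at-a-time slice updates mix
slowly on panel-sized designs with 20+ correlated fixed effects, so this
path is intended for small-to-moderate problems or long runs; defaults
are 4 chains of 1000 post-warmup draws, and the fit fails loudly if any
split-chain R-hat exceeds 1.05 unless `permissive = TRUE`.

Both predictors are clamped before the inverse links: `logit p` at ±15
and `log theta` at ±16. The clamps are inactive at any plausible
parameter value; they exist because beyond them the likelihood is
numerically degenerate (p rounds to exactly 0/1, and at `theta` beyond
~e^16 the log-pmf becomes a difference of enormous log-gamma values whose
cancellation error would corrupt gradients long before the distribution
differs detectably from the binomial).

Pointwise log-likelihoods for PSIS-LOO are *conditional* on the sampled
person effects — the common observation-level convention for hierarchical
models; marginalized LOO is out of scope. Draws generated from a Laplace
fit hold the person effects at their conditional modes, so downstream
summaries ignore residual person-effect uncertainty; this is the
documented approximation of the fast path.

## PSIS-LOO

`psis_loo()` smooths each observation's importance ratios (`1/p(y_i |`
draw`)`) by fitting a generalized Pareto distribution to the largest
20%/`3*sqrt(S)` ratios with the Zhang–Stephens profile-posterior
estimator, replacing them with fitted order statistics, truncating at the
raw maximum, and reporting the Pareto-k diagnostic per observation
(values above 0.7 are flagged). The implementation is tested against the
closed-form leave-one-out predictive of a conjugate normal model.
`compare_models()` ranks candidates by elpd and applies an explicit
parsimony rule — a more complex candidate is selected only when its elpd
improvement over the current choice exceeds the standard error of the
pointwise elpd difference — because the published analysis states only
that PSIS-LOO guided selection, not its decision rule.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of a large English ageing
panel so every stage is testable without access-restricted data: ~9,873
persons by default, baseline age truncated-normal(70.5, 6.4) above 65,
54.5% female, education 47.9/28.9/23.2% (none/secondary/higher), ADL
counts with the observed baseline distribution, 12.5% baseline
test-issue rate; waves two years apart with monotone dropout tuned to a
mean of 3.4 observed waves (MCAR, or a logistic hazard in age, education,
ADL count and test issues whose non-completers are older, less educated
and frailer). ADL counts and test issues evolve across waves by simple
Markov transitions — the published tables give only baseline marginals,
so the transition rates are package choices producing realistic
within-person variation (ADL up/down 0.15/0.05 per wave; issue onset
0.08, persistence 0.45, stationary rate ≈ 0.127). The cohort variable is
derived as baseline calendar year (2002) minus years since 65.

Scores are simulated through the generative model itself. The default
truth (`mels_truth()`) sets every coefficient that has a published
posterior mean to that value — location odds ratios 1.24 (female),
1.30/1.52 (secondary/higher education), 1.17 (cohort/decade), 0.94/0.98
(ADL between/within), 0.58/0.82 (issue between/within); dispersion
effects −2.25 (age/decade), +0.45 (secondary), −0.43 (female),
−0.26/−0.25 (ADL), −3.93/−2.51 (issues), −1.51 (cohort); random-effect
correlations 0.37/0.45/0.31 — and chooses the rest once for realism:

* location intercept −0.10 (≈ 9.4/20 at the reference profile) and age
  spline (−0.22, −0.55, 1.00) with knots 66/71/77.5/86, a decline that
  steepens from about age 80;
* dispersion intercept 4.50, making scores near-binomial at 65 and
  strongly overdispersed by the late 80s given the −2.25/decade effect;
* higher-education dispersion effect +0.65 (not publicly printed;
  plausibly above the secondary-education +0.45);
* random-effect SDs 0.55 (location intercept), 0.25 (age slope/decade),
  1.00 (log-dispersion intercept), giving a cross-sectional score SD
  near the observed ~3.7.

What the generator does *not* emulate: mortality as a distinct process,
proxy respondents, refresher sampling (everyone enters at wave 1, so the
generated cohort variable never exceeds 2002), survey weights, and any
dependence of dropout on the *outcome* (dropout is MCAR or
covariate-dependent only). Passing recovery tests on these cohorts shows
the estimation machinery is correct under the stated generative model;
it cannot validate the model against selection-on-outcome or the
non-independence of recall trials in real data.

## Numerical and design choices

* Shape parametrization pinned to `alpha = p*theta`, `beta = (1-p)*theta`
  (the convention under which `theta = 2`, `p = 0.5` is uniform); all
  density work in log-gamma space.
* `theta` inside the raw distribution functions is clamped to
  [1e-8, 1e12] with clamping events counted in
  `getOption("melsbb.theta.clamped")`.
* Equal-tailed percentile credible intervals throughout (the published
  intervals do not state HPD vs percentile).
* The odds-ratio table omits the intercept and spline columns — a spline
  basis column has no single-OR reading — and the age effect is reported
  through the predicted age curve at a reference covariate profile
  (reference categories, centred continuous terms at zero; configurable),
  which is not stated in the source figures and is a package default.
* The age-curve profile applies person-mean-centred conventions: the
  "within" columns are zero at prediction time.
* Knot placement follows Harrell's published quantiles per knot count;
  the dispersion predictor uses linear age only (its published summary is
  a single per-decade coefficient).
* Trials within an observation are treated as independent; the immediate
  and delayed recall phases of the real test violate this mildly, and no
  correction is attempted (none is specified in the source).

## Problem sizes used by the shipped checks

The test-suite recovery check fits 1,000 persons (MCAR dropout, ~3,400
observations) and asks that at least 18 of the 19 published-value
parameters fall inside their 95% intervals, consistent with nominal
coverage. The model-selection study runs 20 replicates of 200 persons for
the spline-vs-linear comparison and 6 for the interaction screen; at a
few hundred persons the conditional elpd is insensitive to mild
population-level curvature (the person-level random slopes absorb it), so
the harness truth uses a pronounced interior bend (nonlinear component
RMS ≈ 0.4 on the logit scale) together with a mild dispersion profile —
the published extreme test-issue dispersion effects at small n create
low-`theta` persons whose conditional posteriors are bimodal and
needlessly stress the inner optimizer in a study that is about the age
term. The acceptance script's recovery run uses the study-scale cohort
(9,873 persons) for precision on the dispersion-age slope and the
location–dispersion correlation.

## Known limitations

* Laplace point estimates are posterior modes; for variance and
  correlation parameters these can differ from MCMC posterior means at
  small n (the cross-method test budgets 3 SE for this).
* The Gibbs path is slow on large panels; the paper-scale model wants an
  HMC backend, which this package treats as out of environment scope.
* Conditional LOO compares one-observation-ahead prediction given the
  person; it is the stated convention but is weak evidence about
  population-level structure at small n.
* A joint inner mode can fail to exist cleanly for persons with extreme
  all-or-nothing score patterns under very small `theta`; the fitting
  ladder recovers most such cases, and the remainder error loudly rather
  than returning silently wrong results.
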