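---
title: "Modelling metabolic-syndrome progression with a six-state Markov model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling metabolic-syndrome progression with a six-state Markov model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsmarkov)
```

## The scientific problem

Metabolic syndrome (MetS) is not a switch that flips once: people drift
between having none of its five component abnormalities, one or two of
them, and the full syndrome, and each stage carries its own risk of
cardiovascular disease (CVD) and death. Community screening programmes
observe this drift only at visits — the state between screens is
unobserved — while cardiovascular events and deaths are usually
exactly dated through insurance and mortality registries. `metsmarkov`
models this mixture of interval-censored panel states and exactly-dated
events with a six-state continuous-time Markov model and estimates all
transition intensities jointly by maximum likelihood.

## Staging: the refined metabolic classification

A screen is staged from the five harmonized criteria: central obesity
(waist $\ge 80$ cm for women, $\ge 90$ cm for men — the Asian waist
cutoffs), triglycerides $\ge 150$ mg/dL, HDL $< 50$ (women) / $< 40$
(men) mg/dL, blood pressure $\ge 130/85$ mmHg, and fasting glucose
$\ge 100$ mg/dL. Subjects under treatment for hypertension, diabetes or
hyperlipidemia count as positive on the elevated-blood-pressure,
hyperglycemia and hypertriglyceridemia criteria respectively; we map
hyperlipidemia treatment to the triglyceride criterion only (it is one
treated category, not two), with
`hyperlipidemia_sets_low_hdl = TRUE` available for the broader reading.
Zero positives is *free of metabolic disorder* (FMD), one or two *mild
metabolic disorder* (MMD), three or more MetS. The widely used
definition is "three or more of five", and that is the cutoff
implemented (`MET_S_MIN_CRITERIA = 3`), exposed as a named constant
because some texts write "more than three" while operating at $\ge 3$.
Thresholds are applied exactly as written — `>=` inclusive, `<`
exclusive — and the boundary behaviour is pinned by tests. A missing
biomarker without a covering treatment flag is a hard error by default;
`permissive = TRUE` stages on the observed criteria and flags the
record, mirroring the usual practice of excluding incomplete screens.

## The six-state model

States: 1 FMD, 2 MMD, 3 MetS, 4 CVD, 5 CVD death, 6 other-cause death
(OCD). Eleven transitions are allowed:

* 1→2 and 2→1: the FMD–MMD exchange (progression and regression);
* 2→3: entry into MetS, only through MMD;
* 1→4, 2→4, 3→4: CVD incidence from each metabolic stage;
* 4→5: CVD death, only from the CVD state;
* 1→6, 2→6, 3→6, 4→6: other-cause death from every living state.

Regression out of MetS is structurally forbidden: the model describes
the natural course, and observed regression from MetS reflects
intervention. Data that show it anyway are handled by the retain-as-MetS
carry-forward rule at validation (the default) or rejected with row
numbers. The two death states are absorbing.

Each intensity follows a proportional-hazards form
$\lambda_{rs}(x) = \lambda^0_{rs}\,
\exp\{\beta^{age}_g (a - a_{ref}) + \beta^{sex}_g\, \mathbb{1}[male]\}$,
with one $(\beta^{age}, \beta^{sex})$ pair per transition for the seven
specific transitions and a single pooled pair for the OCD intensities
(which by default also covers OCD from CVD; `ocd_from_cvd_own = TRUE`
frees it). Baseline rates apply at the reference covariates — female,
age 50 by default — which travel with every parameter object so
simulated truth and fitted baselines are always on the same scale; the
reference is a package choice, since baseline tables of this kind
rarely state theirs.

Transition probabilities are $P(t;x) = \exp\{Q(x)\,t\}$. The public
`transition_probability()` uses scaling-and-squaring (`Matrix::expm`);
tests compare it against an independent integration of the Kolmogorov
forward equations (`deSolve`) at tolerance $10^{-6}$.

## The likelihood

Within a subject, consecutive observations form independent interval
contributions (Markov property). Covariates are piecewise-constant and
evaluated at the interval start. With $r$ the state at the start of an
interval of length $\Delta t$:

* next screen in metabolic state $s$: $\log P_{rs}(\Delta t)$;
* exactly-dated CVD onset: $\log \sum_{m\in\{1,2,3\}}
  P_{rm}(\Delta t)\,\lambda_{m4}$;
* exactly-dated death: the analogous sum with the death intensity
  ($P_{44}(\Delta t)\,\lambda_{45}$ for CVD death, which requires a
  recorded onset);
* censoring: the probability of still being alive in a state consistent
  with the registry. Because onsets and deaths are exactly ascertained,
  a censored subject without a CVD record is known CVD-free, so the sum
  runs over the metabolic states only; summing over state 4 as well
  would contradict the data-generating process and bias the CVD
  intensities downward.

Because the CVD and death states never return to the metabolic states,
every contribution above needs only the $3\times 3$ living-metabolic
block of the generator (post-onset intervals are scalar exponentials).
The block's eigensystem has a closed form — the MetS row decouples and
the FMD–MMD $2\times 2$ exchange block has real roots — so the cohort
log-likelihood is evaluated by aggregating intervals into identical
cells (origin, outcome, length at 1/365-year resolution, age in whole
years, sex) and computing all cells of a covariate stratum from the
spectral form in one vectorized pass. Strata within $10^{-7}$ of an
eigenvalue degeneracy fall back to the generic eigen/`expm` path. A
per-interval reference implementation (`interval_loglik`, full
$6\times6$ `expm`) is kept and tested equal to the fast path.

## Estimation

`fit_msm6()` maximizes over log-intensities (positivity by
construction) and raw log rate-ratios with BFGS, by default from three
starting points (counting-based crude inits plus jittered copies,
jitter seed 20210211) to guard against ridges created by the 1↔2
exchange cycle. Recovery harnesses use `multi_start = 1`: with crude
inits the likelihood has proved unimodal in practice and the harness
fits hundreds of cohorts. Convergence is declared when the optimizer
reports success and the finite-difference gradient, scaled per
interval, has max-norm below $10^{-3}$; an absolute gradient norm of
$10^{-5}$ is not meaningful at cohort log-likelihood magnitudes with
finite-difference derivatives. The observed-information variance matrix
(`stats::optimHess`) gives Wald intervals; rate intervals are computed
on the log scale and exponentiated (positive, asymmetric bounds), with
a natural-scale delta-method option.

The `equal_cvd_risk` variant ties the three CVD incidence baselines to
one rate, leaving covariate effects transition-specific, so the
likelihood-ratio test against the full model has 2 degrees of freedom —
matching the df printed for this comparison in the motivating
literature; `tie_covariates = TRUE` gives the 6-df full tie.

## The synthetic-cohort generator

Simulated cohorts are the package's test bed; their defaults are the
study conditions the rest of the package is validated under:

* 35.55% FMD / 47.33% MMD / 17.12% MetS at baseline, 60% women;
* ages drawn in whole years from six 10-year bands (20–79) with
  screening-population weights 0.100/0.248/0.284/0.179/0.125/0.063;
* default truth: the `default_intensity_params()` rates (FMD→MMD
  44.82%/yr, MMD→FMD 29.11%/yr, MMD→MetS 6.15%/yr, CVD incidence
  1.62/4.74/20.22%/yr by stage, CVD death 6.1/1,000/yr, OCD
  1.1–9.1/1,000/yr) with age rate ratios 0.97–1.10 per year and sex
  rate ratios 0.50–3.63;
* four years of annual screens, full attendance; an `irregular`
  schedule draws whole-year gaps uniformly from 1–4 years (the
  inter-screen-interval distribution of real programmes is not pinned
  down beyond that range, so the uniform choice is a documented
  invention), and `attendance_prob` thins visits.

Trajectories are simulated by competing exponentials. While a subject
is in a metabolic state the intensities refresh at integer years since
entry; after CVD onset they are frozen at onset age. Under annual
fully-attended screens this matches the likelihood's interval-start
covariate convention *exactly*, so recovery tests are free of
model-mismatch bias; under irregular or missed screens the conventions
diverge for multi-year intervals and the match is approximate. Baseline
ages in whole years (as screening records report them) make the
likelihood's integer-age stratification exact rather than a rounding.

The observation layer samples the trajectory at attended screens, emits
CVD onset and deaths as exactly-dated events, censors survivors at the
horizon, and applies the retain-as-MetS rule. The central oracle
binding simulator to model is distributional: occupancy over 50,000
trajectories matches the matrix-exponential prediction within three
binomial standard errors in every cell (and, with age effects active,
matches the product of one-year matrices).

An optional biomarker layer (`simulate_biomarkers()`) dresses RMRC
states in raw screen values: the five criteria are drawn as correlated
binaries from a Gaussian copula (latent correlation 0.3 by default)
with per-state marginal prevalences typical of screening populations,
rejected until the positive count matches the state class, and values
are placed on the flagged side of each threshold. The joint
distribution beyond the margins is invention; the layer exists so the
classifier can be tested end-to-end, not to emulate real biomarker
physiology.

## Prediction

`cumulative_risk()` propagates the occupancy distribution on a 0.1-year
grid, refreshing the generator at integer ages. The cumulative risk of
*developing* CVD is computed on an internally expanded seven-state
chain that splits other-cause death by prior-CVD status, because
$P_{r4}+P_{r5}$ alone is not monotone once CVD cases can die of other
causes — ever-entered-CVD is the quantity that is a true cumulative
incidence. `include_death_in_cvd = FALSE` instead returns the
prevalence-style probability of currently living with CVD.

One known tension, documented rather than patched: under the default
rates the implied 10-year CVD-death risks from MetS (about 7.7% for a
45-year-old man, 14% for a 65-year-old) are several-fold higher than
the 1.3%/6.0% sometimes quoted alongside rate tables of this kind. No
choice of covariate reference near the cohort mean reconciles a
20%/yr CVD incidence and a 6.1/1,000/yr CVD case fatality with
single-digit 10-year mortality from MetS, so the risk-curve tests
assert qualitative structure (monotonicity, severity and age ordering,
boundedness), not those narrative values.

## Validation sizes and numerical choices

Problem sizes in the test suite are chosen to exercise each property at
useful power while keeping the default run on one CPU comfortably
inside half an hour:

* baseline-rate and rate-ratio recovery: ten cohorts of 10,000
  subjects, four annual screens, full covariate generation and refit
  (medians over seeds within 10% of truth; every seed within 3
  Monte-Carlo SEs);
* LRT power: 20 cohorts of 2,000 under severity-specific CVD rates —
  the effect implied by 1.62/4.74/20.22%/yr is so large that rejection
  at $\alpha = 0.001$ is saturated well below that size; null
  calibration: 60 cohorts of 600 with truly equal CVD rates, compared
  to $\chi^2_2$ by a Kolmogorov–Smirnov check;
* CI coverage: 80 cohorts of 350 under a dense parameter set (all
  transitions common enough to keep the information matrix
  well-conditioned at that size), pooled coverage required in
  [0.90, 0.99];
* oracle equivalence: 100 random generators against the ODE oracle at
  $10^{-6}$; 50,000-trajectory occupancy checks.

Other numerical choices: interval lengths keyed at 1/365 years and ages
at whole years in the likelihood cache (error far below sampling
noise); optimizer relative tolerance $10^{-10}$ with at most 500 BFGS
iterations; crude-init rates floored at $10^{-4}$ and capped at 2 per
year; probabilities are never silently repaired beyond $10^{-8}$
row-stochasticity tolerance — larger violations raise errors.

## What passing tests do and do not show

The simulator generates exactly the process the model assumes (up to
the documented covariate-refresh approximation under irregular
schedules). Recovery under it validates the estimation machinery — the
likelihood, its fast spectral evaluation, the optimizer and the
variance estimates — but says nothing about whether real screening
cohorts follow time-homogeneous Markov dynamics, whether attendance is
independent of health state (it is not, in general), or whether
misclassification at staging is ignorable. Those are modelling
assumptions a real analysis must defend separately.

## Limitations

No hidden-Markov misclassification layer; no time-inhomogeneous
(age-as-time-scale) intensities; no frailty; covariates limited to age
and sex; no bootstrap intervals. A sensitivity mode treating CVD onset
and deaths as panel-observed at the next screen (rather than exactly
dated) was considered and not implemented: the observation model here
assumes registry ascertainment, the simulator generates it, and a
panel-event variant would need its own generator and validation to be
more than decoration.
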