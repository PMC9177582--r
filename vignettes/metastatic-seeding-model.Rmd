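---
title: "A continuous-time Markov chain model of metastatic seeding in de novo metastatic breast cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A continuous-time Markov chain model of metastatic seeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaseed)
```

## The model

`metaseed` models the natural (untreated, pre-diagnosis) development of
distant metastases in breast cancer as a continuous-time Markov chain over
the $2^4 = 16$ combinations of metastatic involvement of four sites: bone,
lung, liver and brain. A state is a vector of four 0/1 flags; state 1 is
metastasis-free, state 16 has all four sites involved. Metastases are
assumed never to regress, so each transition adds exactly one site and
state 16 is absorbing; this yields exactly 32 allowed transitions.

Transitions are driven by six constant dissemination rates (per year):

* four **primary seeding** rates from the tumor — `tubo` (bone), `tulu`
  (lung), `tuli` (liver), `tubr` (brain);
* two **secondary seeding** rates from an established lung metastasis —
  `luli` (liver) and `lubr` (brain).

Each rate is a composite of circulating-tumor-cell release, survival in the
circulation, and the probability of founding a metastasis downstream. When
the originating state has a lung metastasis, the rate of adding liver is
`tuli + luli`, and of adding brain `tubr + lubr`; otherwise only the primary
rate applies. The state-index-to-flag mapping used throughout (see
`met_states()`) is the unique one consistent with the canonical transition
listing of this network (e.g. state 7 is bone+brain, "1001"); two entries
of that listing that conflict with the single-site-addition rule
(10&rarr;13, which adds the lung, and 15&rarr;16, which adds the bone) are
taken to carry the rates the rule implies, `tulu` and `tubo`.

The state-occupancy probabilities obey the master equation
$\frac{d\mathbf P}{dt} = Q\,\mathbf P$, with the generator oriented
column-to-row: $Q_{ij}$ is the rate of moving *from* state $j$ *to* state
$i$ and columns sum to zero. This is the orientation the balance equations
of the network are usually written in, and `build_generator()` states it
explicitly; it is the transpose of the convention many Markov-chain texts
use.

### Model assumptions

* dissemination rates are constant in time and (within one fit) shared by
  all patients;
* metastases have constant volume, so secondary seeding rates are constant;
* the four sites are conditionally independent given the lung status (no
  other secondary routes);
* the primary tumor grows deterministically by the Gompertz law below,
  identically for all molecular subtypes.

## Tumor age from diameter

Tumor volume follows Gompertzian growth
$$V(t) = V(0)\,e^{\frac{\alpha}{\beta}\left(1 - e^{-\beta t}\right)},$$
with defaults $\alpha = 0.0359\,\mathrm{d^{-1}}$ (initial instantaneous
growth rate), $\beta = 0.0013\,\mathrm{d^{-1}}$ (decay rate of growth), a
single spherical founder cell of diameter 10&nbsp;µm, and a lethal diameter
of 100&nbsp;mm. With these values the asymptotic diameter
$d_0 e^{\alpha/3\beta}$ is 99.49&nbsp;mm, just below the lethal size —
`calibrate_alpha()` computes $\alpha$ from exactly this closure. For
comparison, constant-doubling growth at the literature's 150-day doubling
time reaches the $10^{12}$-cell lethal size in 16.4 years
(`time_to_lethal_constant_doubling()`), which the decelerating Gompertz law
is calibrated against.

A patient's tumor age (time since initiation) is imputed by inverting the
law at their recorded diameter:

```{r}
diameter_to_age(c(5, 10, 40))
```

i.e. 2.4, 2.9 and 4.9 years. Numerical choices made here:

* **Year length** is 365 days. Both 365 and 365.25 reproduce every
  1-decimal age above; we fix 365.
* **Tumors are spheres** for all diameter/volume/cell-count conversions;
  `cell_count(d)` is $(d/d_0)^3$, so a 100&nbsp;mm tumor holds $10^{12}$
  cells.
* **Diameters at or above the asymptote.** The inclusion cut (≤ 100 mm)
  admits diameters the growth law cannot reach. For those we clamp
  $3\ln(d/d_0)$ to $(1-10^{-6})\,\alpha/\beta$ before inverting, giving a
  large finite age (about 29.1 years) and a logged warning with the patient
  ids. Any monotone choice here affects well under 0.1% of a realistic
  cohort.

## Solving the master equation

`solve_master()` integrates the chain by forward Euler,
$P(t+\Delta t) = P(t) + \Delta t\,QP(t)$, on a uniform grid with default
$\Delta t = 10^{-3}$ years, guarded by the stability condition
$\Delta t \max_i |Q_{ii}| < 0.1$. The matrix exponential
(`exact_state_distribution()`, via `Matrix::expm`) is kept as an
independent oracle and as an alternative propagator
(`method = "expm"`, exact at the grid nodes). At the default step the
Euler error is below $10^{-6}$ for registry-scale rates, and the test suite
checks the error halves when the step is halved. Output probabilities are
clamped to $[0,1]$; column sums stay within $10^{-6}$ of one.

Patient likelihood lookups read the grid column nearest to the patient's
age, i.e. ages are binned at $\Delta t$; identical (state, age-bin)
patients are grouped with multiplicities, which makes the likelihood cost
independent of cohort size once the grid is built. Probabilities are
floored at $10^{-300}$ before taking logs.

**Units.** All rates are per year and all chain times in years. At
registry-scale estimates (`tulu` $\approx 0.0027$), per-year rates imply
roughly 1% lung involvement at typical imputed ages of 2–7 years, matching
observed diagnosis-time prevalences; a per-day reading would be off by two
orders of magnitude.

## The likelihood and its optimizer

Each patient contributes the probability of their observed state at their
imputed age: $L(\theta) = \prod_j P_{s_j}(t_j, \theta)$. `fit_mle()`
minimizes $-\log L$ with Nelder–Mead after the sinusoidal box transform
$\theta_k = lo_k + (hi_k - lo_k)\sin^2 x_k$ (the classical bounded-simplex
construction), with defaults:

* bounds $[0, 10]$ per year for every rate — generous on both sides of any
  plausible estimate;
* initial value 0.01 per year for all six rates;
* up to 5000 evaluations per start, objective tolerance $10^{-8}$;
* optional multi-start (default 5: the supplied start plus log-uniform
  draws in $[10^{-4}, 1]$), and a simplex restart at the incumbent optimum
  until the objective stops improving — Nelder–Mead simplices can collapse
  prematurely on flat likelihoods.

Confidence intervals come from a parametric bootstrap
(`bootstrap_ci()`, default $B = 50$): holding every patient's imputed age
fixed, states are re-simulated from the fitted chain, each resample is
refitted from the point estimate, and percentile 2.5/97.5 bounds are
reported. Resampling states at fixed ages (rather than redrawing
diameters) matches the conditional structure of the likelihood, which
treats ages as covariates. With 50 resamples the percentile bounds are
coarse; they are reported as-is, and a resample whose refit fails to
converge is dropped and counted.

## The synthetic cohort generator

`generate_cohort()` produces registry-like diagnosis-time cohorts with the
statistical structure the analysis assumes:

* **diameters** from empirical bin weights over
  [0,20), [20,40), [40,60), [60,80), [80,100) mm (defaults are the printed
  registry bin proportions 57.4/25.9/6.2/2.2/0.9%, normalized; uniform
  within bins), or a truncated lognormal;
* **ages** imputed from those diameters by the growth law;
* **states** by exact (Gillespie) stochastic simulation of the seeding
  chain up to each patient's age;
* **subtypes** drawn independently with the registry shares of
  HR−/HER2+, HR+/HER2+, HR+/HER2−, HR−/HER2−.

Default true rates are `tulu` = 0.00269, `luli` = 0.126, `lubr` = 0.0404
per year — the whole-dataset estimates — completed by `tubo` = 0.006,
`tuli` = 0.0015 and `tubr` = 0.0004, which preserve the estimated ordering
`luli > lubr > tubo > tulu > tuli > tubr` and give diagnosis-time
prevalences close to registry values (about 2.2% bone, 1.0% lung, 0.8%
liver, 0.2% brain). One seed controls the run; sub-seeds (seed+1, +2, +3)
drive the diameter, state and subtype draws so each component is
independently reproducible.

What the generator deliberately does **not** emulate: measurement error in
recorded diameters; correlation between subtype and either tumor size or
dissemination rates (real subtypes differ in both); registry reporting
artifacts (rounding of sizes, under-ascertained brain metastases);
treatment effects and survival. Passing tests on synthetic cohorts
therefore demonstrate the estimator's self-consistency — that the pipeline
recovers the rates that generated the data at realistic prevalences — not
that the model is correctly specified for any real registry.

## Validation

`cross_validate()` randomly splits a cohort into $k = 10$ near-equal folds,
fits on nine, and compares cumulative site-positive patient counts on the
held-out fold: the data curve counts patients with age $\le t$ and the site
involved; the model curve sums, over patients with age $\le t$, the fitted
marginal probability of that site at each patient's own age. Agreement is
measured by the mean absolute percentage error with the **model** count in
the denominator,
$$\mathrm{MAPE} = \frac{100}{M}\sum_{t_k}\left|
\frac{x^{data}_{t_k} - x^{model}_{t_k}}{x^{model}_{t_k}}\right|,$$
evaluated in 0.25-year increments over the fold's age range; points with a
zero model count are skipped (and $M$ reduced), and a fold with no
site-positive patients gets an undefined (NA) MAPE for that site.

A caution on interpreting MAPE for rare sites: with brain involvement near
0.2%, a tenth of a $10^5$-patient cohort holds only ~20 brain-positive
patients, so the binomial fluctuation of the held-out count alone is of
order $1/\sqrt{20} \approx 22\%$ relative, and the cumulative curve carries
that single fluctuation across most of its grid. Per-site average MAPE at
this scale therefore has a hard stochastic floor of roughly
$\sqrt{2/\pi}\,/\sqrt{n_{site}/k}$ even for a perfectly specified model;
the liver (~0.8%) sits near 10% and bone (~2.2%) near 6% by the same
arithmetic.

`metastasis_probability()` turns a rate vector into per-state occupancy
probabilities at a tumor age or diameter ($P(\text{any}) = 1 - P_1$); the
"risk within 10 years" of a tumor of a given diameter is the probability
at (imputed age + 10 years). `derived_ratios()` reports the
secondary-to-primary ratios `luli/tuli` and `lubr/tubr`, the lung's seeding
influx (`tulu`) versus outflux (`luli + lubr`), and the relative
liver-versus-brain colonizing ability — the secondary rates normalized by
each organ's share of cardiac output (6.5% liver, 12% brain),
$(luli/0.065)/(lubr/0.12)$.

## Problem sizes used by the test and acceptance suites

Chosen as the package's reference experiment sizes: parameter recovery and
tenfold cross-validation run on cohorts of $10^5$ patients; the bootstrap
coverage replicate uses $10^4$ patients with $B = 50$; Gillespie-versus-
master-equation frequency checks use $10^4$–$10^5$ simulated patients and
4-binomial-SE bands. At $10^5$ patients the Fisher information of the
default rates puts the relative standard errors near 3% (`tulu`), 8%
(`luli`) and 12% (`lubr`), so recovered secondary rates fluctuate by
several percent between seeds; this is inherent to the experiment, not an
optimizer artifact.

## Known limitations

* The four-site topology is fixed; other secondary routes (e.g. from bone)
  and user-defined networks are out of scope.
* Rates are time-constant; no subtype-specific growth law (subtype enters
  only through stratified fitting).
* The age imputation is deterministic, so all patients with equal diameter
  share an age; likelihood information about timing comes entirely from
  the diameter distribution.
* Percentile bootstrap at $B = 50$ gives coarse intervals; the interval
  endpoints themselves carry Monte-Carlo noise of a few percent.
* The clamp at the Gompertz asymptote makes ages of near-100 mm tumors
  essentially a single large constant (~29 years); fits are insensitive to
  this because such patients are ~0.02% of realistic cohorts.
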