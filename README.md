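# metaseed

A stochastic network model of metastatic seeding for *de novo* metastatic
breast cancer. `metaseed` is aimed at biostatisticians and modellers who
want to estimate organ-to-organ tumor-cell dissemination rates from
diagnosis-time cancer-registry cohorts, and to predict the probability of
metastatic involvement as a function of tumor age or size.

## The model

Metastatic involvement of **bone, lung, liver and brain** is a vector of
four 0/1 flags, giving a continuous-time Markov chain over the
2<sup>4</sup> = 16 states (state 1 = no metastases, state 16 = all four;
bone+brain is state 7, "1001"). Metastases never regress, so each
transition adds one site and state 16 is absorbing. Six constant rates
(per year) drive the chain:

| rate | route | kind |
|------|-------|------|
| `tubo` | tumor → bone | primary seeding |
| `tulu` | tumor → lung | primary seeding |
| `tuli` | tumor → liver | primary seeding |
| `tubr` | tumor → brain | primary seeding |
| `luli` | lung → liver | secondary seeding |
| `lubr` | lung → brain | secondary seeding |

From a state with a lung metastasis, liver is added at rate `tuli + luli`
and brain at `tubr + lubr`. State probabilities obey the master equation
*d***P**/*dt* = *Q***P** with the generator oriented column-to-row
(*Q<sub>ij</sub>* = rate *j* → *i*); two entries of the commonly printed
transition listing that contradict the single-site-addition rule are
implemented as the rule requires — 10 → 13 adds the lung and carries
`tulu`, and 15 → 16 adds the bone and carries `tubo`.

Tumor age at diagnosis is imputed from recorded diameter by inverting
Gompertzian growth
*V(t) = V(0) exp[(α/β)(1 − e<sup>−βt</sup>)]* with α = 0.0359 d⁻¹,
β = 0.0013 d⁻¹, a 10 µm founder cell and a 100 mm lethal diameter, so a
5 / 10 / 40 mm tumor is 2.4 / 2.9 / 4.9 years old. The six rates are then
estimated by maximum likelihood,
*L(θ) = ∏<sub>j</sub> P<sub>s_j</sub>(t_j, θ)* over patients, with
bounded Nelder–Mead; confidence intervals come from a parametric bootstrap
(states re-simulated at fixed ages), and validation from tenfold
cross-validation scored by MAPE on cumulative site-positive patient
counts. A Gillespie-based generator produces registry-like synthetic
cohorts (diameter-bin proportions, subtype mix and metastasis prevalences
on the registry scale) and doubles as the bootstrap engine.

## Worked example

```r
library(metaseed)

# a registry-like synthetic cohort, 20,000 patients, default true rates
coh <- generate_cohort(sim_config(20000, seed = 123))
cohort_summary(coh)$site
#>        site count percent
#> bone   bone   426     2.1
#> lung   lung   184     0.9
#> liver liver   155     0.8
#> brain brain    35     0.2

fit <- fit_mle(coh, n_starts = 1)
fit
#> Dissemination-rate fit (n = 20000 patients, nll = 4077.7908, converged)
#>  rate  estimate
#>  tubo 0.0060652
#>  tulu 0.0026012
#>  tuli 0.0016102
#>  tubr 0.0003127
#>  luli 0.1324014
#>  lubr 0.0367175
```

The site prevalences (2.1% bone, 0.9% lung, 0.8% liver, 0.2% brain) are on
the diagnosis-time registry scale, and the fit recovers the generating
rates (`tulu` = 0.00269, `luli` = 0.126, `lubr` = 0.0404) within a few
percent for the well-identified components. Secondary seeding out of the
lung (`luli + lubr` ≈ 0.17/y) exceeds seeding into it (`tulu` ≈ 0.0026/y)
roughly sixty-fold, and the blood-flow-normalized liver-versus-brain
colonizing ability is

```r
derived_ratios(fit$theta_hat)$colonizing_ability  # ~5.9 on this fit
```

Metastasis risk by tumor size — the probability of any metastasis within
10 years of the imputed age of a 5 / 10 / 40 mm tumor:

```r
ages <- metastasis_probability(fit$theta_hat, diameter_mm = c(5, 10, 40))$time_years
round(100 * metastasis_probability(fit$theta_hat, t = ages + 10)$p_any, 1)
#> [1] 12.3 12.8 14.6
```

Cross-validation and bootstrap intervals:

```r
cv <- cross_validate(coh, k = 10, seed = 1, n_starts = 1)  # minutes
fit_ci <- bootstrap_ci(fit, coh, B = 50, seed = 1)         # minutes
```

A thin command-line wrapper with `simulate` / `fit` / `validate` /
`predict` subcommands and a YAML run configuration is installed at
`system.file("cli", "metaseed.R", package = "metaseed")`.

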