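# mbmasurv

Model-based meta-analysis (MBMA) of aggregate survival and response data,
built for the setting where many small single-arm oncology trials publish
Kaplan-Meier figures but no patient-level data — the motivating use case
is comparing anti-CD19 CAR-T co-stimulatory domains (4-1BB vs CD28) in
relapsed/refractory B-cell acute lymphoblastic leukemia.

Digitized (time, survival-fraction) points from each trial are pooled in
one nonlinear mixed-effects survival model:

- **Structural model** — log-normal survival
  `S0(t) = 1 - Φ((ln t - μ)/σ)` with group-specific `μ_g`, `σ_g`
  (log-months scale; `exp(μ)` is the median survival time).
- **Inter-trial random effects** — `μ_i = μ_g·exp(η_μ)`,
  `σ_i = σ_g·exp(η_σ)` with `η ~ N(0, ω²)`.
- **Covariate model** — proportional hazards,
  `h_i(t) = h_0(t)·exp(θ·(x_i − r))`, hence `S_i = S0^m` with
  `m = exp(θ(x_i − r))`; the morphological-relapse fraction is centered
  at `r = 0.85`.
- **Residual model** — additive Gaussian error of SD `ε` on
  `logit(S)`.

Estimation maximises a Laplace-approximated marginal likelihood (compiled
inner Newton per trial; OFV = −2 log L), with RSE% from the OFV Hessian,
empirical-Bayes trial effects, shrinkage, stepwise covariate selection on
ΔOFV (3.84 forward / 6.63 backward), bootstrap, VPC, leave-one-out and
GOF diagnostics, Monte-Carlo simulation of typical curves with 95% CIs,
two-step subgroup pooling (DerSimonian-Laird over single means),
random-effects meta-analysis of proportions on the logit scale, and
trial-level surrogacy regression (weighted least squares, `R² ≥ 0.8`
high / `0.6–0.8` moderate / `< 0.6` low).  A synthetic-trial generator
with known ground truth exercises the whole pipeline.

## Worked example

```r
library(mbmasurv)

gen <- generate_survival_dataset(generator_config(), seed = 42)
fit <- fit_model(gen$arms, gen$curves, "OS",
                 included_covariates = "morph_relapse_frac")
print(fit)
#> MBMA survival model fit (OS), OFV = 659.889, converged
#> MBMA log-normal survival model parameters
#>   4-1BB  mu = 2.668  sigma = 1.574
#>   CD28   mu = 1.972  sigma = 1.288
#>   theta[morph_relapse_frac] = 2.569 (ref 0.85)
#>   omega_sigma = 0.4209  omega_mu = 0.2854  epsilon = 0.39
#> RSE%:
#>          mu(4-1BB)           mu(CD28)       sigma(4-1BB)        sigma(CD28)
#>                5.8               13.0                8.8               19.5
#> morph_relapse_frac        omega_sigma           omega_mu            epsilon
#>               21.2               14.8               14.2                3.6
#> Shrinkage %: eta_sigma 6.3, eta_mu 3.1, epsilon 6.0
```

`mu = 2.668` for the 4-1BB group means a typical-trial median overall
survival of `exp(2.668) ≈ 14.4` months; the positive `theta` says trials
enrolling more morphologically relapsed (high disease-burden) patients
have proportionally higher death hazards.  Shrinkage below 20% indicates
the corpus is informative about trial-level variability.

```r
sim <- simulate_typical_curves(fit$estimates, "4-1BB", n_sim = 1000, seed = 42)
print(sim)
#> Typical curve (4-1BB, 1000 simulations)
#>   median survival: 14.1 months (95% CI 4.6-> 72)
#>   12-month rate: 53.9% (25.2-95.2)
#>   24-month rate: 37.5% (7.5-85.8)
#>   60-month rate: 19.6% (0.7-64.9)
```

The 95% interval reflects inter-trial variability: a typical future trial
could land anywhere in that band.  Pooling a response endpoint across
domains:

```r
pr  <- generate_proportion_dataset(generator_config(), arms = gen$arms, seed = 42)
orr <- pr$props[pr$props$endpoint == "ORR", ]
sm  <- subgroup_meta(orr, gen$arms, "domain_group")
print(sm$per_level[["4-1BB"]])
#> ORR [4-1BB]: 82.37% (95% CI 77.91-86.08), k = 26, tau2 = 0.202, I2 = 39.8%
print(sm$per_level[["CD28"]])
#> ORR [CD28]: 66.55% (95% CI 55.13-76.31), k = 5, tau2 = 0.188, I2 = 62.7%
sm$comparisons$flag
#> [1] "significantly different (CIs disjoint)"
```

`run_pipeline()` chains generate → validate → fit → diagnose → simulate →
meta-analysis → surrogacy from one config (R list or YAML) and writes
tidy CSV/JSON outputs plus a manifest with per-file checksums; reruns
with the same config and seed are bit-identical.

## Package layout

- `R/trial_data.R` — CSV readers/writers and dataset validation
- `R/survival_model.R` — closed-form log-normal / PH mathematics
- `R/nlme_estimation.R` + `src/laplace.cpp` — marginal-likelihood engine,
  fitting, covariate search, shrinkage
- `R/diagnostics.R` — bootstrap, VPC, leave-one-out, GOF residuals
- `R/simulation.R` — Monte-Carlo typical curves and subgroup pooling
- `R/meta_proportions.R`, `R/surrogacy.R` — proportion meta-analysis and
  surrogate-endpoint regression
- `R/synthetic_data.R` — ground-truth corpus generator
- `R/pipeline.R` — end-to-end orchestration
- `vignettes/mbma-methods.Rmd` — model, assumptions, design choices and
  known limitations
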