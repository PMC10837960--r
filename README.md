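# alsmbma

Model-based meta-analysis (MBMA) of the placebo-group disease course in
amyotrophic lateral sclerosis (ALS), for trial statisticians and
pharmacometricians who need a quantitative historical placebo: fit
parametric disease-course models to *aggregate, arm-level* placebo data
pooled across published trials, simulate the typical course with
uncertainty, and use the result as an external control for single-arm
trials or as a prior for Bayesian borrowing in small placebo groups.

Two structural models carry the analysis:

* **Overall survival** — a log-normal base hazard under proportional
  hazards,

  S_i(t) = S0(t)^exp(θ_Dur·(DURATION_i − 17.8) + θ_Ril·RILUZOLE_i),
  S0(t) = 1 − Φ((ln t − MU_i)/SIGM_i),

  fitted to survival proportions digitized from Kaplan–Meier curves,
  with study-level lognormal random effects on MU and SIGM.

* **ALSFRS-R** — a sigmoid-Emax time course of the mean change from
  baseline, Δ(t) = −Emax·t^γ / (ET50^γ + t^γ), with random effects on
  Emax and γ.

Arms of size n contribute observations (logit survival / raw score
change) with residual SD ε·√(75/n), 75 being the corpus-median arm
size. Estimation maximizes a Laplace-approximated marginal likelihood;
covariate selection, empirical-Bayes study estimates, a nonparametric
bootstrap, goodness-of-fit/VPC diagnostics, Monte-Carlo typical-course
simulation, DerSimonian–Laird subgroup pooling, and the two
historical-control applications are built on top. A synthetic-corpus
generator reproduces the structure of the published 30-arm OS /
29-arm ALSFRS-R corpus so the whole pipeline runs without any data
download. The published final-model estimates are available as
`als_reference_params()`.

## Worked example

```r
library(alsmbma)

p <- als_reference_params("ALSFRS")
typical_change(c(12, 24, 48), p)
#> [1] -10.18411 -15.55330 -20.18554

os <- als_reference_params("OS")
median_os(covariate_profile(duration_months = 17.8, riluzole_frac = 0), os)
#> [1] 20.90524
median_os(covariate_profile(17.8, 1), os)
#> [1] 25.22996
```

A typical placebo arm loses about 10.2 ALSFRS-R points in the first
year and 20.2 by four years; treating the whole arm with riluzole
instead of none extends the model's median OS from 20.9 to 25.2 months
— about 0.4 months per 10 percentage points of riluzole use.

Bayesian borrowing for a small placebo group (19 subjects), combining
the historical prior with the observed arm by precision weighting:

```r
post <- conjugate_update(arm_summary(-8.07, -9.57, -6.72),
                         arm_summary(-10.1, -12.75, -7.45))
post
#> posterior: -8.525 (95% CI -9.780, -7.270), sd 0.640
#> prior contributes 78% of the posterior precision
borrow_report(post, arm_summary(-7.1, -9.04, -5.16))
#> drug declines 16.7% less than placebo (95% CIs overlap)
```

End-to-end on synthetic data:

```r
corpus <- generate_corpus(generator_config(seed = 1))
fit <- mbma_fit(corpus, endpoint = "ALSFRS", n_starts = 2, seed = 1)
summary(fit)           # estimates, SEs, RSE%, OFV
vpc(fit, n_sim = 500, seed = 1)
mbma_bootstrap(fit, n_reps = 200, seed = 1)
```

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "mbma", package = "alsmbma")` with subcommands
`simulate-data`, `fit`, `select-hazard`, `bootstrap`, `gof`, `vpc`,
`typical`, `scenarios`, `subgroups`, `compare` and `borrow`.

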