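# bayesaft

Bayesian lognormal accelerated failure time (AFT) analysis of
treatment-effect heterogeneity for first-line chemotherapy in advanced
gastric cancer: docetaxel triplets (DPF) versus platinum–fluoropyrimidine
doublets (PF), as analysed in multicentre registries where the triplet is
preferentially given to younger, fitter patients (confounding by
indication).

The package is aimed at biostatisticians and clinical researchers who want
the full pipeline — not just the model fit — under test:

* a **synthetic registry generator** calibrated to published baseline
  tables (n = 1376, ~17% DPF with age/fitness-dependent assignment, ~21–24%
  missing histology fields, median OS ≈ 10.2 months) with known ground
  truth, so every downstream stage is verifiable without patient-level data;
* **restricted cubic splines** and **multiple imputation by fully
  conditional specification** (20 datasets by default; covariates with
  \> 25% missingness are discarded first);
* **evidence-synthesis priors** for the treatment effect, elicited from a
  meta-analytic hazard ratio, and **skeptical priors** N(0, 0.05) for
  treatment-by-covariate interactions;
* the package's own **adaptive MCMC sampler** (preconditioned MALA mixed
  with a Student-t independence kernel), split-Rhat/ESS diagnostics with the
  \< 1.1 reporting rule, and mixture pooling of posteriors across imputed
  datasets;
* posterior **effect summaries on the time-ratio scale** — credible
  intervals, P(TR > 1.15), P(TR > 1.30), ROPE mass — conditional subgroup
  effects, effect-by-age/year curves, and an **individualized
  median-survival calculator**;
* descriptive helpers: relative dose intensity, adverse-event relative
  risks (Katz intervals), spline-logistic age-probability curves.

## The model

For event time `T` (months, right censored),

    log T = x'beta + sigma * eps,     eps ~ N(0, 1)

so `exp(beta_j)` is a **time ratio** (TR): TR = 2 doubles the median time to
event. The treatment prior maps a protective hazard ratio HR (95% CI) to the
log-TR scale as mean `-log(HR)` and sd `(log(hi) - log(lo)) / (2 * 1.96)`;
for the reference OS meta-analysis HR 0.86 (0.78–0.95) this gives mean 0.15.
Interactions get N(0, 0.05), which leaves only ~0.5% prior mass on subgroup
effects beyond ±15%.

## Worked example

```r
library(bayesaft)

cohort <- generate_cohort(registry_config(seed = 20080101))  # 1376 rows

screen_missingness(cohort, columns = c("lauren", "grade"))$report
#>        column n_missing  fraction dropped
#> lauren lauren       290 0.2107558   FALSE
#> grade   grade       312 0.2267442   FALSE

imp <- impute_fcs(cohort, m = 5, n_iter = 5, seed = 1)
spec <- model_spec()                      # splined age, lauren interaction
fit <- fit_imputed(imp, spec = spec, endpoint = "OS",
                   prior_mode = "informative",
                   n_chains = 2, n_warmup = 400, n_iter = 600, seed = 1)

effect_summary(fit$draws, "arm=DPF")
#> arm=DPF: TR 1.199 (95% CrI 1.128-1.284); P(TR>1.15) 0.917; P(TR>1.30) 0.013; ROPE mass 0.002

conditional_effect(fit$draws, fit$design, list(lauren = "intestinal"))
#> arm=DPF | lauren=intestinal: TR 1.184 (95% CrI 1.068-1.310); P(TR>1.15) 0.735; P(TR>1.30) 0.035; ROPE mass 0.063

prof <- list(age = 58, ecog = "1", lauren = "intestinal", grade = "2",
             ascites = 0, stage = "metastatic", liver_burden = "none",
             n_organs = 1, platin = "cisplatin", nlr = 3, year = 2016)
predict_median_survival(fit$draws, fit$design, prof, "PF")
#> PF: median 9.6 months (95% CrI 8.5-10.9)
predict_median_survival(fit$draws, fit$design, prof, "DPF")
#> DPF: median 11.4 months (95% CrI 9.9-13.2)
```

Reading the output: on this synthetic registry (generated with a true OS
treatment log-TR of ln 1.19), the pooled posterior puts the triplet's time
ratio at 1.20 with a 92% probability that the benefit exceeds 15%, and the
calculator translates that into per-arm median survival for one patient
profile. Convergence is summarised per imputed dataset (`fit$reports`); all
split-Rhat values here are below 1.1.

A thin command-line wrapper over the same functions ships in
`inst/scripts/aft-cli.R` with `fit`, `summarize` and `predict` subcommands.

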