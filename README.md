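# claimrisk

Multimodal neural survival models for predicting epilepsy comorbidity risk
from longitudinal administrative claims histories.

## What problem this solves, and for whom

Epilepsy patients face elevated, strongly individual risks of comorbidities
such as anxiety, bipolar disorder/schizophrenia, type-2 diabetes, migraine,
overweight/obesity, and stroke. Administrative claims data — coded
diagnoses, prescriptions with duration, demographics — record each
patient's medical history longitudinally and at scale, but are noisy,
sparse and irregular. `claimrisk` is for biostatisticians and
pharmacoepidemiologists who want to go from raw coded event tables to a
validated, explainable, per-patient *time-dependent* risk model, without
hand-assembling the dozen pipeline stages in between.

The package provides, as composable R functions:

* **Cohort construction** — a rule engine for the five claims-based
  epilepsy inclusion criteria (345.xx / 780.39 / AED combinations over
  separate encounter dates), index dates, history/follow-up/age/AED
  filters, rare-code pre-filtering, and incident-comorbidity survival
  labelling with prior-observation and six-month-lag exclusions.
* **Feature augmentation** — pluggable code-mapping machinery (ICD→PheWAS,
  ICD-10 crosswalks, substance→target/side-effect tables) expanding raw
  codes into a domain → subdomain → feature hierarchy.
* **Tensorization** — 30-day binning of each patient's 456-day history
  (T = 15 bins) into per-subdomain data cubes plus a static vector.
* **The risk network** — per-subdomain bottleneck encoders applied
  position-wise over time, temporal max/mean pooling with optional
  temporal convolutions, per-domain bottlenecks, fusion, and a single
  linear risk output; batch norm before every activation, dropout on input
  and hidden layers.
* **Survival core** — Cox partial log-likelihood (Breslow ties),

  ```
  l(W) = Σ_i δ_i [ N_W(x_i) − log Σ_{j: y_j ≥ y_i} exp N_W(x_j) ]
  ```

  minimized as −l plus groupwise elastic-net penalties
  `Σ_s (λ_s^ℓ1 ||W_s||₁ + λ_s^ℓ2 ||W_s||₂²) + λ_D^ℓ1 ||W_D||₁ + λ_D^ℓ2 ||W_D||₂²`;
  Breslow baseline hazard, patient survival curves
  `S(t|x) = exp(−e^{N_W(x)} H₀(t))`, Kaplan–Meier.
* **Evaluation** — Harrell's C, Uno's IPCW C-index `Ĉ_τ` (pair weights
  `Ĝ(X_i)⁻²`, truncation at τ, score ties counting ½), time-dependent
  AUC(t), Bayesian hyperparameter search (GP + expected improvement), and
  nested cross-validation.
* **Explanation** — exact Shapley values (subset enumeration) as oracle, a
  kernel-based approximation for real use, 30×5% subsampling robustness
  reports, and per-feature/subdomain/domain/origin aggregation.
* **Synthetic data** — a seeded claims simulator with a planted
  proportional-hazards signal, emitting the exact table formats the cohort
  module reads, so the whole chain is testable without licensed data.

## Worked example

```r
library(claimrisk)
set.seed(1)

# simulated claims: event/patient tables -> cohort -> labels -> cubes
dat <- synthetic_training_data(sim_config(n_patients = 600, seed = 7))
print(dat$cubes)
#> cube_set: 475 patients, T = 15 bins
#>   phewas             30 x 15 x 475
#>   substance          15 x 15 x 475
#>   demographics       6 x 475
#>   region             4 x 475

n <- n_patients(dat$cubes)
test <- sample(n, 120); tr <- setdiff(seq_len(n), test)
hp <- hyperparams(enc_units = 16, dom_units = 16, fin_units = 16,
                  pooling = "mean", dropout_hidden = 0.2, batch_size = 128)
model <- build_network(dat$cubes$schema, hp, T_bins = dat$cubes$T_bins, seed = 7)
model <- train(model, subset_cubes(dat$cubes, tr), dat$labels[tr, ],
               epochs = 40, patience = 10)

scores <- risk_score(model, dat$cubes, idx = test)
uno_c(scores, dat$labels[test, ])
#> Uno's C = 0.6374 (tau = 56, 5550 comparable pairs)
```

Out of 600 simulated patients, 475 survive the inclusion rules, filters and
label exclusions. On the 120 held-out patients the model's censoring-robust
concordance is 0.64: in about two of three comparable pairs the patient the
model calls riskier is the one diagnosed earlier. Risk scores convert to
absolute statements through the Breslow hazard:

```r
h0 <- breslow_cumulative_hazard(risk_score(model, dat$cubes, idx = tr),
                                dat$labels[tr, ])
hazard_ratio(max(scores), min(scores))
#> 19.48  — the riskiest test patient's hazard vs the least risky's
survival_curve(max(scores), h0)   # P(comorbidity-free at 24 months) = 0.00
survival_curve(min(scores), h0)   # P(comorbidity-free at 24 months) = 0.73
```

For tuning and honest performance estimates, `bayesian_hpo()` +
`nested_cv()` tune hyperparameters strictly inside each outer training
fold; `subsampled_shap()` and `aggregate_importance()` attribute a trained
model's scores to features, subdomains and domains. A thin CLI over these
functions lives at `inst/cli/claimrisk.R` (subcommands `simulate`,
`cohort`, `featurize`, `fit`, `evaluate`, `explain`, `run-all`).

## Acceptance script

`scripts/acceptance.R` recomputes the package's reference quantity from
scratch using the installed package — it simulates right-censored survival
data, scores every subject identically (the featureless null model), and
evaluates Uno's IPCW C-index with ties counted one half — and writes the
result as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
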