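---
title: "Methods: multimodal neural survival modelling of claims histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal neural survival modelling of claims histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Epilepsy patients carry elevated risks of comorbidities — anxiety,
bipolar disorder and schizophrenia, type-2 diabetes, migraine,
overweight/obesity, stroke and ischemic attacks — and those risks vary
strongly between individuals. Administrative claims data (coded diagnoses,
prescriptions with duration and quantity, demographics) record each
patient's longitudinal medical history as a byproduct of billing, which
makes them a cheap but noisy substrate for individualized risk prediction.
`claimrisk` implements the full modelling chain from raw coded event tables
to a per-patient, time-dependent risk of developing one target comorbidity,
together with explanation machinery and a synthetic data generator that
makes every component testable without access to licensed claims databases.

## Cohort construction

Epilepsy patients are identified by a rule engine over five claims-based
criteria combining epilepsy diagnoses (ICD-9-CM 345.xx, with grand-mal
status 345.3 handled by its own rule), convulsions (780.39) and
antiepileptic-drug (AED) prescriptions, evaluated over separate encounter
dates. Design choices where the criteria under-specify behaviour:

* "Separate medical encounters" means distinct calendar days — dates are
  the only encounter key the data model retains.
* The index date is the day of the first qualifying epilepsy diagnosis.
  For the convulsions-plus-AED rule, whose qualifying codes are not
  themselves epilepsy codes, the first 780.39 day is used; for the
  grand-mal-status rule, whose three alternative branches may qualify
  simultaneously, the earliest day participating in any qualifying pair is
  used.
* The AED-treatment filter is evaluated over the patient's coverage
  interval (configurable to the history-plus-follow-up window instead).

Patients then need 365 days of history before and 365 days of follow-up
after the index date, age 18–65 inclusive at index, and any AED treatment.
Because a confirmed epilepsy diagnosis often takes several visits, a 91-day
*diagnosis period* after the index date absorbs diagnostic uncertainty;
features are collected over the resulting 456-day window.

Rare codes — carried by at most 10 patients *or* with patient frequency at
most 1% — are removed before modelling; either condition suffices for
removal.

**Labels.** For a target comorbidity (a set of PheWAS concepts), each
cohort patient is exactly one of: *excluded* (any defining concept observed
before the end of the diagnosis period — a model must not see its own
outcome in the history; observations before the formal history window count
too, since they are equally part of the patient's known history),
*excluded/lag* (first defining concept within six months after the
diagnosis period: counting these as incident would contradict the
incident-case definition, and keeping them as censored would leak events),
*incident* (`status = 1`, time = months from index to first diagnosis), or
*censored* (`status = 0`, time = months to end of coverage). Months are
30-day bins, rounded up to the next whole month, with the index date as
time origin.

## Feature augmentation and tensorization

ICD codes are mapped to PheWAS concepts (several codes per concept; an
optional user-supplied ICD-10 to ICD-9 crosswalk is applied first), and
pluggable mapping tables fan events out into knowledge-derived subdomains
(drug targets, side effects with frequencies, pathways, ...). The package
ships the mapping *machinery* only; table content is user-supplied, and the
bundled simulator generates synthetic tables for testing.

The feature space is a three-level hierarchy: domains (diagnosis, drug,
general) contain subdomains, each with an ordered (lexicographic) feature
vocabulary. Diagnosis and drug subdomains are time-dependent; general
(demographics, region) subdomains are static.

Each patient becomes a multimodal data cube: per time-dependent subdomain a
binary `d × T` matrix over `T = floor(456 / 30) = 15` monthly bins
(presence per bin; weighted subdomains keep the maximum weight per bin;
prescriptions mark every bin their duration covers), plus a static vector.
The 6 remainder days of the 456-day window are merged into bin 14 so that
`T = 15` holds without discarding events. Continuous static features (age,
hospital days) are min–max scaled on the training split with the constants
persisted in the model checkpoint; categorical statics are one-hot.
Prescription quantity is retained in the event stream but does not modulate
the encoding (presence only).

## The network

The scorer $N_W$ mirrors the hierarchy:

1. one bottleneck encoder (1–4 dense layers) per subdomain, applied
   position-wise over time with weights shared across bins — a single
   encoder per subdomain keeps the parameter count independent of `T`;
2. latents concatenated within each domain; per domain a temporal stage:
   max or mean pooling over the entire time axis per latent component,
   optionally augmented by temporal convolutions (valid padding, stride 1,
   several kernel sizes, outputs max-pooled over positions and
   *concatenated* with the pooled latents — concatenation rather than
   summation keeps the two information streams separable);
   general-domain features bypass this stage;
3. a per-domain bottleneck, concatenation across domains, a fusion
   bottleneck, and one linear output unit: the patient's risk score.

Batch normalization precedes every activation; dropout acts on inputs and
hidden layers; the activation is rectified-linear (the architecture leaves
this open; ReLU is the field default). There is no deep-learning framework
in the target environment, so layers, batch norm, temporal convolution and
Adam are implemented directly in matrix code, with the backward pass
verified against finite differences in the test suite. Max-pooling has tie
subgradients (common with sparse one-hot inputs, where empty bins produce
identical latents); the finite-difference check therefore uses the smooth
mean-pooling configuration at tolerance `1e-4` and only verifies
finiteness for max pooling.

## Loss and survival mathematics

Training minimizes the negative Cox partial log-likelihood

$$-l(W) = -\sum_i \delta_i \Big[ N_W(x_i) - \log \sum_{j: y_j \ge y_i}
e^{N_W(x_j)} \Big]$$

plus groupwise elastic-net penalties
$\sum_s (\lambda_s^{\ell 1}\|W_s\|_1 + \lambda_s^{\ell 2}\|W_s\|_2^2) +
\lambda_D^{\ell 1}\|W_D\|_1 + \lambda_D^{\ell 2}\|W_D\|_2^2$, where $W_s$
are the first-layer weights of subdomain $s$ and $W_D$ the weights feeding
the output unit. Numerical conventions:

* tied event times use Breslow's convention (one shared risk-set
  denominator); no Efron correction;
* the $\ell_2$ term is the *squared* norm (classical elastic net), with an
  unsquared group-lasso variant available;
* risk sets are formed within each minibatch, the standard practice for
  this loss in stochastic training — batch size is therefore a modelling
  hyperparameter, not only a throughput knob;
* the per-batch likelihood is normalized by its event count before the
  gradient step, which decouples the learning rate from batch composition;
* log-sum-exp terms are computed stably via a running maximum.

The Breslow estimator turns fitted scores into a cumulative baseline hazard
$H_0$, giving patient-specific event-free curves
$S(t \mid x) = \exp\{-e^{N_W(x)} H_0(t)\}$ and time-free hazard ratios
$e^{s_1 - s_2}$ between patients. The Kaplan–Meier estimator is
hand-implemented (the IPCW machinery needs a censoring-mode variant
evaluated at arbitrary times) and cross-checked against
`survival::survfit()` in the tests.

## Evaluation

Harrell's C is used during training (early-stopping metric, evaluated on a
held-out 20% of each training split, since the stopping rule only states
"cross-validated prediction performance"); Uno's IPCW C-index
$\hat C_\tau$ — with pair weights $\hat G(X_i)^{-2}$, truncation at $\tau$,
and tied scores counting 1/2 — is the reported test metric, alongside a
cumulative/dynamic AUC(t) using the same weighting restricted to cases
$X_i \le t$ versus controls $X_j > t$. The published formula's numerator
indicator compares a risk score with itself, an evident typo; the
implementation compares $\mathrm{risk}_i > \mathrm{risk}_j$ as in the
underlying estimator. The default $\tau$ is the largest event time whose
censoring-survival estimate remains positive, avoiding the unstable tail.

Hyperparameters are tuned by sequential model-based search (random
initialization block, then a Gaussian-process surrogate with
expected-improvement acquisition over unit-cube-encoded configurations),
maximizing inner-cross-validated Harrell's C, inside an outer
cross-validation whose test folds stay untouched (nested CV). Training runs
at most 100 epochs with patience 10 by default.

## Shapley explanation

`exact_shapley()` enumerates all $2^{|F|}$ coalitions and is the oracle.
The practical path is a kernel-based weighted-least-squares formulation:
with all coalitions enumerated it reproduces exact Shapley values; with
sampled coalitions it is the model-agnostic fallback for larger feature
sets. One deliberate deviation: coalition *players are whole features*
(a feature's entire time row is switched on or off), rather than
per-(feature, bin) attributions summed over bins. Both conventions satisfy
additivity ($\sum_i \Phi_i = f(x) - f(\mathrm{ref})$, which holds here by
construction) and report per-feature values; the grouped-player version
needs a factor `T` fewer coalition players, which is what makes desk-scale
exactness (full enumeration) reachable in tests. Features already at their
reference value are exact dummies and receive zero without evaluation.

The reference ("average") patient is all-zero for one-hot features and the
background mean for continuous statics. Robustness follows the subsampling
scheme: 5% of patients drawn with replacement, 30 times, re-aggregated each
time, with across-repeat variances reported. Group importances are computed
by summing attributions within the group per patient *first*, then taking
the absolute value, then averaging — the order that makes additivity-based
aggregation coherent; domain and origin shares each normalize to 1.
Attributions are associations, not causal effects.

## The synthetic world

The generator emulates the structure (not the marginal realism) of
commercial claims: per patient an index date, qualifying epilepsy codes
(90% two-code rule, 10% convulsions-plus-AED rule), AED refills,
demographics, and monthly Bernoulli presence of vocabulary codes over the
15 history bins, each code entering the event table as one of its mapped
ICD synonyms. Ground-truth risk is proportional-hazards: the linear
predictor is $\beta^\top e_i$ over the first five PheWAS concepts'
*exposures* (fraction of history bins present), event times are exponential
in days after the incident-lag boundary, censoring is independent
exponential plus an administrative coverage horizon. Event and censor times
are generated in days so the label pipeline — not the generator — owns the
monthly rounding.

Defaults and why:

* `beta = 2` on 5 signal concepts with per-patient signal propensities
  uniform on [0, 0.6]: chosen so the *oracle* (true linear predictor)
  concordance lands in the low-to-mid 0.7s, the range reported for this
  kind of model on real claims; a trained network then has genuine but not
  trivial headroom.
* `censor_rate = 1/700` per day: set once, with the administrative horizon
  of 2200 days, to realize approximately 30% censoring among *labelled*
  patients — the follow-up filter removes early-censored patients, which a
  naive exponential-competing-risks calculation misses.
* Small planted fractions of ineligible ages (2%), prior-comorbidity
  carriers (4%) and lag-window diagnoses (3%) keep every exclusion path of
  the cohort module exercised.

What a green test does *not* establish: the generator has no coding noise,
no irregular enrollment gaps, no correlated comorbidity clusters, no
realistic US-claims marginals; recovery of a planted proportional-hazards
signal says nothing about performance on real claims data.

## Known limitations

* No time-varying-covariate Cox extensions; the monthly grid is fixed.
* No recurrent or attention variants, and one model per comorbidity (no
  multi-task head).
* The Gaussian-process search is a lightweight single-kernel surrogate,
  adequate for the ~10-dimensional spaces used here, not a general HPO
  framework.
* Kernel-based attributions with sampled coalitions inherit sampling error;
  the exact path is limited to ~12 active players per patient.
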