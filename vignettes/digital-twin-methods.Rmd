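---
title: "Methods: a generative digital twin for oropharyngeal cancer treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a generative digital twin for oropharyngeal cancer treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`hnctwin` implements a patient digital twin for oropharyngeal squamous cell
carcinoma treatment with two coupled components:

1. **A generative component** — a heterogeneous-data variational autoencoder
   (VAE) that learns the joint distribution of *pre-treatment features*
   (PTF: demographics, smoking history, tumour site and staging, HPV/p16
   status, and baseline MDASI-HN symptom scores) and samples new synthetic
   patients from it.
2. **A predictive component** — a chain of gradient-boosted decision-tree
   ensembles (XGBoost), one per downstream variable, that forecasts how a
   patient's record unfolds after the three first-cycle treatment actions:
   definitive surgery (no/yes), induction chemotherapy (no/yes), and
   radiotherapy (no / yes / yes with concurrent chemotherapy).

Variables are organised into five groups — PTF, ACTIONS, post-intervention
outcomes (PIO: surgical pathology `ENE` and `Margin`; radiotherapy
`rt_type`, `rt_dose`, `rt_fraction`), patient-reported scores (PRS: the
four modelled MDASI-HN symptoms *fatigue, drymouth, swallow, taste* at end
of radiotherapy, week 6, month 3, month 12, each on the 0–10 integer
scale), and the treatment-plan outcome (TPO: `relapse_yr3`, relapse within
three years). The chain orders them chronologically,

PTF → definitive → (ENE, Margin) → induction → radio/chemo →
(rt_type, rt_dose, rt_fraction) → PRS~endrt~ → PRS~wk6~ → PRS~m3~ →
PRS~m12~ → relapse_yr3,

with each node conditioned on **all** earlier variables (the
all-ancestors convention). The published benchmark listing places the
relapse outcome between the end-of-RT and week-6 scores; we adopt the
chronological ordering (relapse last) instead, since year-3 relapse cannot
causally precede week-6 symptoms. Two structural rules are enforced
throughout: surgical pathology exists only after definitive surgery, and
radiotherapy parameters only when radiotherapy is given.

## Timeline simplification

Raw treatment histories are event logs `(day, category, procedure)`. A
*cycle* is a maximal run of action events followed by status events,
closed by a relapse/recurrence status. Multi-cycle histories are
simplified to the first cycle's actions plus a year-3 outcome.

Numerical choices, all configurable:

* **Concurrency window, 45 days.** A chemotherapy and a radiation action
  within 45 days merge into one concurrent-chemoradiotherapy action. The
  bundled case studies bracket the choice: patient 1's pair is 5 days
  apart (clearly concurrent), while distinct actions in patient 2's
  history are separated by far more. Chemotherapy *more* than the window
  before radiation counts as induction.
* **Outcome horizon, 1095 days, strict.** `relapse_yr3` is `True` iff a
  relapse occurs at day ≤ 1095; `False` only when the log demonstrably
  extends past the horizon without one; otherwise missing.
* **Status grace window, ±90 days.** The year-3 status takes the status
  nearest day 1095 within ±90 days (patient 2's year-3 assessment falls at
  day 1113), falling back to the latest status before the horizon.
* Unrecognised action labels (e.g. "Other Therapies") map to a catch-all
  kind that sets none of the three action variables, with a warning.
* `elapsed_months()` uses the mean month length 30.44 days.

## The synthetic-cohort generator

No public accession exists for the reference registry, so the package
generates cohorts whose *marginals equal the published summary tables*:
category probabilities are printed counts normalised within each variable
(`ENE`/`Margin` conditional on surgery, `rt_type` conditional on
radiotherapy), numerical features carry the printed (mean, sd), and the
three action variables are drawn jointly from the eight mined first-cycle
sequence patterns with probabilities proportional to their printed counts
(total 651).

Distributional choices:

* **Bounded symptom scores** are drawn as clip-and-round normals on
  [0, 10]. Naively clipping a Normal(printed mean, printed sd) shifts the
  mean — substantially for near-floor baselines — so the generator
  *inverts the clipped-normal moment map* (closed-form clipped moments,
  Nelder–Mead) and draws from the underlying normal whose clipped moments
  equal the printed ones. Integer rounding adds variance ≈ 1/12 and a
  negligible mean shift; tests allow a documented 0.1 mean tolerance.
* **Tobacco covariates** (packs/day, years used, pack-years) use
  moment-matched lognormals: non-negative and right-skewed, with the
  printed mean and sd exact.
* **Age, rt_dose** are Gaussians; **rt_fraction** is a rounded Gaussian.
* The four symptoms are modelled at a baseline assessment too; the source
  tables print moments only for fatigue and drymouth, so swallow/taste
  means are package defaults chosen as clinically plausible, with sds set
  to the test-set standard deviation implied by the published
  constant-mean benchmark errors (the MSE of a constant mean predictor
  equals the label variance).

**Planted dependencies.** So that the predictor chain has learnable
structure, the generator plants effects that mirror clinical reality, all
*centred or calibrated so the marginals stay at their printed values*:

* Treatment propensity: early T-stage tilts toward surgery, nodal burden
  toward induction, overall stage toward concurrent chemoradiotherapy.
  Tilts are exponential reweightings of the pattern distribution whose
  per-category log-offsets are solved by fixed-point iteration so the
  *population-average* pattern probabilities equal the mined frequencies
  (a mean-preserving tilt).
* Pathology: stage raises P(ENE positive) and tilts margins toward
  positive classes (same calibration, within the surgical stratum).
* Radiotherapy: younger age tilts toward IMPT; concurrent chemotherapy
  shifts dose (+300 cGy) and fractions (+1.3), centred on
  P(chemo | radiotherapy) so conditional means stay printed.
* Symptoms: each phase couples to the centred baseline score, to the
  previous phase (symptom persistence), and to centred treatment
  intensity (0–4 scale over the three actions); residual noise is scaled
  so the marginal variance matches the moment-inverted target.
* Relapse: a logistic model in centred intensity (protective), stage, and
  p16 positivity (protective), with the intercept solved numerically so
  the mean probability equals the printed prevalence 35/188 among
  labelled patients. Only a 188/676 fraction of patients carries a
  relapse label; the rest are missing, mirroring the published outcome
  table.

Default effect sizes are documented constants chosen once so the planted
structure is detectable by the chain at the study scale (676 patients);
they are generator parameters, not estimates of any real-world effect.
`zero_effects()` switches every dependency off, leaving pure independent
marginals. Pre-treatment features are mutually independent by design —
the generative component of the twin makes the same assumption — which is
also the generator's main departure from real cohorts: passing
marginal-recovery tests says nothing about real-world correlation
structure.

## Preprocessing

* z-scoring uses the **population (divide-by-n) sd**; constant columns
  pass through unscaled with a flag. Transforms are fitted on training
  rows only and invert exactly (tested to 1e-10), and a leakage test
  asserts that perturbing test rows leaves fitted parameters unchanged.
* Imputation is family-specific: the VAE and MLP receive mean-imputed
  numericals and most-frequent-category categoricals (the conventional
  reading of "median imputation" for nominal labels — for opaque codes
  like the smoking-status categories a true median is undefined); the
  boosted family receives missing values untouched, which the trees route
  natively.
* The default split is the literal 539/137 when the cohort has 676 rows
  (0.8 × 676 = 540.8, so rounding would not reproduce the reference
  sizes), otherwise 80/20.

## The VAE

Encoder: two fully connected rectified-linear layers of 64 units, then
linear heads for the latent mean and log-variance (16 dimensions).
Decoder mirrors the encoder, ending in a linear head for the z-scored
numericals and a softmax head per categorical feature. Categorical inputs
are one-hot. Sampling uses the reparameterization trick
`z = mu + exp(logvar/2) * eps`. The loss is

* squared-error reconstruction for numericals,
* cross-entropy for categoricals,
* plus `kl_weight ×` the closed-form KL against the standard normal
  prior, `0.5 Σ (μ² + σ² − 1 − log σ²)`,

each **averaged over the batch and summed over features** — the scale on
which `kl_weight` (default 1) acts. Training is Adam (rate 0.001, batch
64), implemented with hand-derived backpropagation over base-R matrix
algebra and verified against finite-difference gradients in the test
suite; given a seed, training is bit-reproducible. The reference training
schedule is 10,000 epochs; the package default is 300, which reaches a
stable loss at desk scale (the loss-versus-epoch history is stored on the
model). Decoded categoricals are *sampled* from the softmax by default to
preserve diversity (`mode = "argmax"` available); decoded numericals are
denormalized, clipped to schema bounds, and rounded where integer-valued.

## The predictor chain and baselines

Each node is an XGBoost model: `binary:logistic`, `multi:softprob`, or
squared-error regression on the z-scored target (predictions
denormalized, and all reported MSEs are on the natural scale).
Classification uses balanced class weights, `w_c = n/(k·n_c)`, so each
class contributes equal total weight. Rows missing the target are dropped
per node; missing parents are consumed natively. Hyperparameters are
selected by stratified 3-fold cross-validation (macro-F1 / negative MSE),
ties broken toward fewer trees then shallower depth. The `"paper"` preset
spans the full published grid (learning rate {0.01, 0.1, 0.3}, depth
{4, 6, 8}, min child weight {1, 3, 5}, 100–300 trees, column subsample
{0.3, 0.5}); the `"fast"` preset keeps one value per hyperparameter for
classification and adds a second, conservative learning rate (0.01) for
regression nodes, where small-sample overfitting otherwise lets a plain
mean prediction win on weak-signal targets.

Rollout fills downstream variables in chain order, feeding predictions
forward and honouring the structural rules. `"expected"` mode (modal
class / regression mean) is deterministic; `"sampled"` mode draws classes
from predicted probabilities and adds Gaussian noise with the node's
training residual sd to regression predictions — the twin itself
specifies no stochastic mechanism, so this is the package's documented
choice.

Baselines: a constant **median/mean** rule (categoricals: training median
of integer-coded labels in schema order — deterministic but arbitrary for
nominal features, with a modal-category alternative; numericals: training
mean), a **random** predictor proportional to training frequencies (or
the empirical distribution for numericals), and a grid-searched **MLP**
(two rectified-linear hidden layers, Adam/SGD, trained on imputed
z-scored inputs) built on the same network core as the VAE.

## Evaluation

* **Fidelity**: per-feature order-1 Wasserstein distance between real and
  synthetic samples on the raw (denormalized) scale, computed exactly as
  the integral of |F̂_a − F̂_b|; categorical features enter as
  total-variation distance, which is W1 under the 0/1 ground metric (the
  distance is otherwise undefined for nominal labels). Feature distances
  are averaged; the implementation agrees with an exhaustive
  minimum-cost-matching transport oracle to 1e-9 on small samples.
* **Prediction**: macro-F1 averaged over *schema-declared* classes
  (absent rare classes score 0 — deliberately harsh under class
  imbalance) and MSE on the natural scale, one benchmark row per chain
  target, missing test labels scored on the observed subset.

Because several targets are observed only in tiny test strata (surgical
pathology reaches ~15 test patients at the 539/137 split), single-split
benchmark comparisons are noisy; the package's acceptance check therefore
pools the chain-versus-baseline win rate over three replicate cohorts and
requires ≥ 80% per task family, which is the study-scale analogue of the
reference framework winning 22 of 25 variables.

## The decision environment

A three-step episodic environment wraps the two components: `env_reset()`
samples a synthetic patient's PTF (observation: one-hot categoricals plus
z-scored numericals, fixed ordering); steps take the surgery, induction,
and radiotherapy decisions in order, intermediate steps filling the
stage-appropriate predicted outcomes (pathology becomes visible after the
surgery decision, so later decisions can be state-dependent). The final
step completes the rollout and returns

reward = − relapse_weight · P(relapse) − symptom_weight · burden / 10,

where burden is the mean predicted end-of-RT score over the four
symptoms. No reward is specified by the source framework; weights
(defaults 1 and 0.5) and the burden normalization are package choices.
`compare_plans()` evaluates two plans on a shared (paired) synthetic
population; with the default generator the aggressive plan (surgery +
induction + chemoradiotherapy) shows lower predicted relapse and higher
symptom burden than radiotherapy alone.

## Problem sizes and runtime choices

Tests and the bundled pipeline run at the study scale of 676 patients
(539/137 split) with the fast preset: 300 VAE epochs, one-point
classification grids, two-point regression grids, 500 synthetic patients
for fidelity, and 100 paired episodes for plan comparison. Monte-Carlo
marginal checks use n = 10,000 with 4·sd/√n tolerances. The full pipeline
completes in a few minutes on a single CPU.

## Known limitations

* Pre-treatment features are generated (and modelled) as independent; an
  optional correlation mode is not implemented.
* The generator emits no time-to-event outcomes beyond the binary year-3
  relapse, and only the four modelled symptoms of the 28-item inventory.
* Clip-and-round symptom sampling reproduces printed means and sds but
  not higher moments (real MDASI distributions are zero-inflated).
* Four printed percentages in the source demographic tables are
  internally inconsistent with their counts at N = 676; counts are
  treated as authoritative everywhere.
* Rollouts are associational simulations of the fitted chain, not causal
  counterfactuals; treatment-by-stage confounding planted in the
  generator is only partly adjusted for by conditioning on staging.
* The aggressive extreme plan (surgery + induction + chemoradiotherapy)
  lies outside the support of the mined sequence patterns — no observed
  first-cycle pattern combines surgery with induction — so its rollouts
  are extrapolations of the fitted chain.
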