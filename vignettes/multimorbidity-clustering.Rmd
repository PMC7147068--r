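---
title: "Methods: age-stratified latent class clustering of multimorbidity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-stratified latent class clustering of multimorbidity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmlca)
```

## The problem

Multimorbidity — a patient living with two or more long-term
conditions — is heterogeneous: patients differ widely in which
conditions co-occur, how much care they use, and how likely they are
to die. `mmlca` implements a patient-centred clustering analysis for
this setting: given a cohort in which each patient carries a binary
flag for each of 38 long-term conditions, it groups *patients* (not
diseases) into clusters with similar condition profiles, separately
within four age strata (18–44, 45–64, 65–84, 85+), validates the
clusters on a held-out split, and relates cluster membership to
service use and mortality.

The intended data source is a primary-care electronic health record
extract (one row per patient: demographics, 38 condition flags,
one-year service-use counts, 2- and 5-year death indicators). Such
data are licensed and cannot ship with a package, so `mmlca` includes
a synthetic cohort generator with known ground truth; every stage of
the pipeline is exercised and tested against that generator.

## The model

Within an age stratum, condition vectors
$y_i \in \{0,1\}^J$ are modelled by a latent class model: patient $i$
belongs to one of $K$ unobserved classes with prior (mixing)
probabilities $\pi_k$, and conditions are independent Bernoulli given
the class, with item-response probabilities
$\rho_{kj} = \Pr(y_{ij} = 1 \mid z_i = k)$:

$$\Pr(y_i) = \sum_{k=1}^{K} \pi_k \prod_{j=1}^{J}
  \rho_{kj}^{y_{ij}} (1 - \rho_{kj})^{1 - y_{ij}}.$$

Conditions are "present (recorded) or not" by construction, so there
is no missing-data machinery in the clusterer. The model is fitted by
maximum likelihood via EM (`fit_em()`):

* **E-step** — posterior membership probabilities
  $p_{ik} \propto \pi_k f_k(y_i)$, computed in log space with a
  log-sum-exp, so extreme patterns cannot underflow.
* **M-step** — $\pi_k = \bar p_{\cdot k}$ and
  $\rho_{kj} = \sum_i p_{ik} y_{ij} / \sum_i p_{ik}$.

Numerical choices worth knowing:

* $\rho$ is clamped to $[10^{-6}, 1 - 10^{-6}]$ after every M-step so
  log-densities stay finite. A class whose posterior mass collapses
  to zero is re-seeded from Uniform(0.05, 0.95).
* EM restarts: 20 random initialisations by default
  ($\pi \sim$ Dirichlet(1), $\rho_{kj} \sim$ Uniform(0.05, 0.95));
  the highest final log-likelihood wins. The log-likelihood is
  asserted non-decreasing within every run (a decrease beyond
  rounding noise is an error, not a warning).
* Convergence: relative log-likelihood change below `tol`
  (default $10^{-8}$), capped at `max_iter = 1000`.
* Label switching is resolved by sorting classes by descending
  $\pi_k$; modal assignment takes the posterior argmax with ties to
  the lowest class index. Both conventions matter downstream: they
  make profiles, labels, and the train/test matching stable.
* The inner EM loop is compiled (RcppArmadillo). A pure-R
  reference implementation of the log-likelihood, E-step and M-step
  is exported and the compiled path is tested against it; a further
  exhaustive grid-search maximiser (`exhaustive_loglik_k2()`) bounds
  the two-class optimum on tiny instances.

## Choosing the number of classes

`select_k()` scans a range of $K$ and tabulates, per fit:
log-likelihood, parameter count $p = (K-1) + KJ$,
$\mathrm{BIC} = -2\ell + p\ln N$,
$\mathrm{aBIC} = -2\ell + p\ln\frac{N+2}{24}$, and the relative
entropy

$$E = 1 + \frac{\sum_i \sum_k p_{ik}\ln p_{ik}}{N \ln K} \in [0,1],$$

which is 1 for one-hot posteriors (perfect classification), 0 for
uniform posteriors, and defined as 1 when $K=1$. A parametric
bootstrap likelihood-ratio test of $K$ vs $K+1$ is available
(`bootstrap_lrt()`); the naive $-2\Delta\ell$ statistic has no
chi-square reference distribution for mixtures, so the null is
simulated from the fitted $K$-class model. One alternative-model
restart is warm-started by splitting the largest null class, which
guarantees a non-negative observed statistic. The default is `B = 19`
replicates in tests and a larger `B` (e.g. 99) for analysis runs.

The published analysis combined these statistics with clinical
judgement, a step no package can automate. The default rule here is
explicit and configurable: **choose the aBIC minimiser among fits
with relative entropy ≥ 0.8**; if no fit reaches the floor, fall back
to the overall aBIC minimiser and flag it. The full selection table
is always emitted for human review. The floor of 0.8 encodes
"adequate classification quality" — posteriors sharp enough that the
modal assignment used downstream is a faithful summary.

## Stratification, splitting, and profiling

Age strata are closed-open intervals $[18,45), [45,65), [65,85),
[85,\infty)$ on integer age. The train/test split is drawn
independently within each stratum (`split_train_test()`), with
$\lfloor 0.8\, n_s \rfloor$ training patients per stratum, seeded and
reproducible.

Cluster profiles use **modal-assignment prevalences** (not
posterior-weighted means), because patients are allocated to a single
cluster before profiling. Each cluster is labelled by its most
*distinctive* conditions: those maximising within-cluster prevalence
minus stratum prevalence, keeping only positive differences
(`key_conditions()`). The first three are the key conditions; the
first is the lead condition. Ties are broken by higher
within-cluster prevalence, then registry order. Ranking by
distinctiveness (rather than raw within-prevalence) is a deliberate
choice: a condition that is universal in a stratum can be 100%
prevalent in a cluster without characterising it. The two orderings
usually coincide for well-separated clusters; the full profile is
returned so users can inspect raw prevalences when they differ.

## Hold-out stability

`replicate_on_test()` refits the model on the held-out 20% with $K$
fixed to the training choice, then matches every test cluster to a
training cluster under two criteria (`match_clusters()`):

* **Jensen–Shannon distance** between profiles normalised to
  probability distributions, with base-2 logarithms so the distance
  is bounded by 1 (and "smallest JSD" is scale-free):
  $\mathrm{JSD}(P,Q) = \sqrt{H(M) - \tfrac12(H(P)+H(Q))}$,
  $M = (P+Q)/2$.
* **Pearson correlation** on the raw, un-normalised prevalence
  vectors.

Normalising for JSD but not for Pearson is intentional: JSD compares
the *shape* of the disease mix, Pearson the co-variation of absolute
prevalences; together they are robust to each other's blind spots.
Matching is per-test-cluster and deliberately not forced one-to-one —
the test split contains fewer disease patterns, so several test
clusters may legitimately share a training partner. When the two
criteria disagree the disagreement is reported, not resolved.
Relative entropy is computed on both splits and expected to be
similar for stable solutions.

## Outcome models

Patients with missing smoking status or BMI are excluded
(`complete_case_filter()`), with a warning once the exclusion reaches
5%. The reference cluster is the one with the *lowest impact* on the
outcomes, operationalised as the smallest rank sum across mean GP
consultations, mean hospitalisations, mean regular medications and
5-year mortality (ties to the larger cluster); the rule is
configurable and the choice is logged. A sensitivity option takes a
supplied reference instead (e.g. the non-multimorbid group).

The design matrix (`build_design()`) codes cluster, gender (reference
female) and smoking (reference never) as indicators, IMD as a single
ordinal 1–5 numeric term, and BMI and age as continuous. Service-use
counts are modelled with a log link, by default as **negative
binomial** — the generating family for real consultation counts is
unknown but such counts are reliably overdispersed; Poisson is
available as a sensitivity. Exponentiated coefficients are adjusted
incidence rate ratios (aIRR). Mortality at 2 and 5 years is logistic,
giving odds ratios. Intervals are Wald 95% CIs, matching standard
aIRR [95% CI] reporting. Fitting is delegated to `stats::glm` and
`MASS::glm.nb`; the package owns the design, reference logic and
reporting. These associations are descriptive, not causal.

## The synthetic cohort generator

`default_simulation_truth()` encodes the study conditions the package
is tested under:

* Four strata whose sizes are the study-scale multimorbid stratum
  sizes (15,306 / 36,097 / 49,494 / 12,314) times `n_scale`
  (default 0.01 → 153/361/495/123 — small enough for fast tests
  while preserving the size imbalance).
* Per stratum, a generating latent class model whose classes mirror
  the published cluster structure: a lead condition at high
  prevalence, two key conditions at moderate prevalence, and a low
  background prevalence elsewhere that rises with age (0.02 → 0.08).
* Demographics (female proportion, IMD distribution, smoking,
  BMI mean/SD, smoking/BMI missingness) matching the published
  stratum summaries.
* Outcome coefficients reproducing the published per-cluster mean
  service use and 2/5-year mortality gradients, with small covariate
  effects (age, deprivation, smoking) on top.

Counts are drawn negative binomial (variance $\mu + \alpha\mu^2$;
Poisson when $\alpha = 0$), five-year death is generated
hierarchically from two-year death so `died_2yr == 1` always implies
`died_5yr == 1`, ages are uniform within stratum, and true class
labels live in a side table so the cohort file has exactly the
fields a real extract would.

What the generator does **not** emulate: longitudinal condition
accrual, calendar-time incidence, condition onset ordering,
correlated demographics (e.g. smoking–deprivation dependence), or
informative missingness. Passing tests therefore demonstrate that the
machinery recovers known structure under the stated model — not that
real EHR data satisfy that model.

## Problem sizes and test design

The test-suite and acceptance studies use sizes chosen to make
Monte-Carlo noise small relative to the tested tolerances while
keeping a full run comfortable on one CPU: parameter recovery and
class-count selection at $N = 5{,}000$, $J = 20$, $K = 3$ with
block-separated response probabilities (0.8 vs 0.1); exhaustive
grid-search comparison at $N = 50$, $J = 3$, step 0.05; matching
recovery at $K = 5$, $J = 38$ with Gaussian profile noise (SD 0.02);
GLM coverage with 200 replicates at $n = 5{,}000$; and end-to-end
pipeline runs on cohorts of roughly 1,000–11,000 simulated patients.

## Known limitations

* The independence-given-class assumption of the latent class model
  is a modelling convenience; real comorbidity data violate it to
  some degree, which tends to inflate the selected $K$.
* The selection rule is a documented stand-in for a
  statistics-plus-judgement decision; different weightings of BIC,
  aBIC, LRT and entropy can defend different $K$.
* aBIC at very small $N$ (≤ 22) has a non-positive penalty and is
  not meaningful there.
* Bootstrap LRT p-values are granular at small `B`
  (minimum $1/(B+1)$).
* The quantile convention is linear interpolation (R type 7); the
  chi-square test applies the Yates correction for 2×2 tables only.
  Both choices reproduce the published descriptive statistics.
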