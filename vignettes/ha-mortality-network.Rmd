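---
title: "Modelling inpatient mortality risk in hereditary angioedema with a discrete Bayesian network"
author: "habnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling inpatient mortality risk in hereditary angioedema with a discrete Bayesian network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habnet)
```

## The problem

Hereditary angioedema (HA, ICD-10 D84.1) is a rare C1-esterase-inhibitor
disorder whose attacks can be fatal when they involve the airway. For
hospitalised HA patients, the question this package addresses is: given a
patient's demographics (age group, race, income quartile, census region,
payer), comorbidities (hypertension, autoimmune disease, diabetes) and
APR-DRG admission severity, what is the probability that the admission
carries *high* mortality risk, and how does that probability move when we
condition on individual factors or combinations of them?

A discrete Bayesian network is a natural fit. The joint distribution over
the ten categorical variables factorises along a directed acyclic graph
(DAG) as

$$P(X_1,\dots,X_{10}) \;=\; \prod_{v} P(X_v \mid \mathrm{pa}(X_v)),$$

with one conditional probability table (CPT) per node. The network supports
exactly the operations an epidemiological what-if analysis needs: exact
posterior queries under observed ("hard") evidence, probabilistic
("virtual") evidence in Pearl's sense, and record-level classification for
validation.

## Model and estimation

**Structure.** The DAG is configuration, not an estimate: no structure
learning is performed. The shipped default (see
`default_ha_dag()` and `inst/extdata/ha_model_config.yaml`) encodes the
narrative dependency story — demographics feed comorbidities, demographics
and comorbidities feed admission severity, and all nine predictors feed the
mortality-risk outcome. Whether severity should inherit from the
comorbidities is genuinely open; we keep those edges because a sicker
baseline plausibly raises admission acuity, and because removing them is a
one-line config change for any analyst who disagrees.

**Parameters.** For child state $k$ under parent configuration $j$, with
count $n_{jk}$, row total $n_j$, and $K$ child states, the stored estimate
is the Dirichlet posterior mean with a symmetric per-cell concentration
$\alpha$ (default 1):

$$\hat\theta_{jk} \;=\; \frac{n_{jk} + \alpha}{n_j + K\alpha}.$$

This is the conjugate Bayes estimator: unobserved rows fall back to the
uniform vector and no cell is ever exactly 0 or 1 when $\alpha>0$, which is
what keeps sparse strata from generating impossible records. We store the
posterior mean, not a MAP estimate or posterior draws — it is the standard
point estimate and the one a `bayes`-method CPT fit produces elsewhere.
$\alpha = 0$ is allowed and gives maximum likelihood; `log_likelihood()`
then reports $-\infty$ (with a warning) for records that hit a zero cell.

The fitter warns when a node's parent-configuration count exceeds $n/5$:
the estimate is then dominated by the prior. With the default DAG the
outcome node has $4^5\times 2^3\times 4 = 32{,}768$ parent configurations,
so *any* cohort of a few hundred records trips this guard — see
"Smoothing at cohort scale" below, because the consequences are visible in
every downstream number.

## Inference

Two exact engines answer every query:

* `enumerate_query()` sums the factorised joint over all completions
  consistent with the evidence. It is exponential and deliberately
  transparent — the ground-truth oracle.
* `eliminate_query()` runs sum-product variable elimination with a min-fill
  elimination order; ties are broken by schema declaration order so runs
  are bit-reproducible. The test suite holds it to within $10^{-9}$ of the
  oracle across a thousand random (structure, CPT, evidence) triples.

Hard evidence slices factors; virtual evidence multiplies a likelihood
vector into the factor set before normalisation (Pearl's construction), so
a uniform vector is vacuous and an indicator vector reproduces hard
evidence exactly. `soft_observation(schema, var, cat, w)` builds the
one-parameter family used for "conservative" conditioning: weight $w$ on
the observed category, $(1-w)/(K-1)$ elsewhere. The default scenario mode
is hard evidence with `--soft w` ($w = 0.9$ by default) available, because
the likelihood strengths behind published soft-evidence analyses are
rarely reported and we prefer the unambiguous default. Zero-mass evidence
raises an "impossible evidence" error rather than returning NaN.

Risk is reported against the **model baseline**: the fitted network's
no-evidence marginal of `mortality = high`. This is deliberately not the
raw prevalence — smoothing and the factorisation both move it — so the raw
prevalence is always reported alongside. Deltas are signed percentage
points (`+8.5 pp` style).

## The synthetic cohort generator

Real NIS/HCUP discharge records cannot be redistributed, so the package
ships a fully specified ground-truth network (`default_ha_ground_truth()`)
and samples cohorts from it ancestrally (`sample_cohort()`, vectorised,
seed-reproducible). The generator is first-class, tested code: it defines
the study conditions under which every end-to-end claim in this package is
verified.

Calibration is closed-form and deterministic, never rejection-tuned:

* Root CPTs are set directly to the published cohort frequencies where
  printed — 58% White, 40% private insurance, 37% South / 23% West, and
  39% aged 40–64.
* Binary comorbidity nodes are logit-additive in age and race with the
  intercept solved by 1-D root finding (tolerance $10^{-12}$) so the exact
  enumerated marginal hits its printed target: hypertension 48%, diabetes
  21%.
* Admission severity tilts a moderate/major-heavy base distribution
  log-linearly along a severity score; the outcome node is
  logistic-additive in all nine predictors with its intercept solved
  against the printed 38.7% high-risk marginal.

`verify_calibration()` audits all seven printed marginals by exact
enumeration; the shipped net passes at ±0.01 with headroom.

Not everything is published. The non-White race split, income quartiles,
northeast/midwest shares, payer mix beyond private, the 12% autoimmune
prevalence and the severity base distribution are package assumptions,
chosen once as plausible for a US inpatient cohort. Dependence *strengths*
are likewise unconstrained by any published joint frequency; we fixed the
logit-additive effect scales so that the enumerated single-category risk
deltas reproduce the reported qualitative pattern — elevated risk for age
≥65, Black race, hypertension, autoimmune disease, major/extreme severity;
reduced risk for younger ages and the South; a near-null diabetes effect —
at single-digit percentage-point magnitudes. Passing tests on these
cohorts therefore demonstrates correctness of the machinery under a
realistic dependence structure, not agreement with any particular
hospital population: the generator does not emulate survey weights,
hospital clustering, within-region correlation, or coding noise.

## Smoothing at cohort scale

A point that shapes every cohort-scale number: with the default DAG the
outcome CPT has 32,768 rows, and a 441-record cohort (or even a
20,000-record one) observes only a sliver of them. Under $\alpha = 1$ the
unobserved rows sit at 0.5, so the fitted baseline is pulled from the
sample prevalence toward one half, conditional deltas are strongly
attenuated (fractions of a percentage point at $n = 441$), and held-out
discrimination sits well below the ground-truth ceiling while training
discrimination is near-perfect (the observed rows essentially memorise
their records). None of this is a defect of the estimator — it is what
Bayesian smoothing honestly reports about a CPT that large — but it means
parameter "recovery" on such a node is only meaningful for rows the data
actually reaches. The test suite therefore checks estimator consistency at
the binomial error rate of each row's observation count (rows with ≥2,000
observations within 0.05; at $n=441$, rows with ≥100 observations within
0.15), and checks the cohort-scale analysis for its *directional* claims
averaged over 30 seeds: positive deltas for age ≥65, hypertension and
autoimmune disease, and train AUC ≥ test AUC.

## Validation

`split_cohort()` draws a simple random 70/30 partition (no
stratification), `predict_proba()` computes each record's full-evidence
posterior (vectorised closed form: with every predictor observed the
posterior is proportional to the joint at each outcome state), and
`classify()` thresholds at 0.5 by default, boundary-inclusive. The
threshold is exposed because a published operating point is not always
derivable from reported detection prevalence.

`confusion_metrics()` reports counts plus accuracy, balanced accuracy,
sensitivity, specificity, PPV, NPV, detection rate ($TP/N$) and detection
prevalence ($(TP+FP)/N$) — the names are stated explicitly because they
vary across ecosystems — with zero-denominator ratios returned as `NaN`
with a warning, never silently 0. `roc_auc()` groups tied scores (a
discrete classifier yields a few straight ROC segments) and integrates by
trapezoid, which equals the tie-corrected Mann–Whitney statistic; the
suite verifies that identity to $10^{-12}$ and cross-checks against pROC.

## Numerical choices

* CPT rows must sum to 1 within $10^{-9}$; construction renormalises
  exactly, and queries normalise once at the end.
* Category order always comes from the schema declaration, never from data
  order, so count tables, CPT layouts and serialisations are deterministic.
* Model JSON is written with 17-significant-digit shortest-exact decimals,
  so doubles round-trip bit-for-bit.
* All seeds are explicit; sampling restores the caller's RNG state, and
  the pipeline derives each stage's seed deterministically from the master
  seed, so `run_analysis()` is a pure function of its configuration.
* Problem sizes in the test suite were chosen to keep the full run in a
  few minutes on one core: 1,000 random oracle-equivalence triples over
  nets of 4–8 nodes, 100 soft-evidence parameterisations, cohorts of
  441–50,000 records, and 30 pipeline seeds for the directional checks.

## Limitations

* The DAG is fixed, not learned, and encodes one defensible reading of how
  demographics, comorbidities and severity interact; conclusions about
  edge directions are assumptions, and nothing here supports causal
  interpretation.
* The nine-predictor network is exactly tractable; no approximate
  inference is provided, and none is needed at this scale.
* Cohort-scale fits with the default DAG are prior-dominated at the
  outcome node (see above); analyses that need sharper cohort-scale
  estimates should supply a sparser outcome parent set via the model
  config.
* The generator's dependence strengths are assumptions; agreement with it
  validates the machinery, not any real-world population.
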