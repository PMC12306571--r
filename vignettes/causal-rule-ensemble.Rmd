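---
title: "Interpretable CATE decomposition with causal rule ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable CATE decomposition with causal rule ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The model

In an observational study with outcome $y_i$, binary treatment $z_i$ and
covariates $x_i \in \mathbb{R}^p$, treatment effects often vary across
subgroups. `causalrules` assumes that this variation has a sparse,
interpretable structure: the conditional average treatment effect (CATE)
decomposes linearly as

$$
\tau(x) \;=\; \bar\tau \;+\; \sum_{m=1}^{M} \alpha_m \, r_m(x),
$$

where $\bar\tau$ is the average treatment effect (ATE), each $r_m$ is a
decision rule — a conjunction of threshold conditions such as
`x1>0.5 & x2<=0.3` evaluated as a 0/1 subgroup indicator — and $\alpha_m$,
the rule's *additive average treatment effect* (AATE), is the shift in the
expected treatment effect for units inside the subgroup. Identification
rests on the usual assumptions for observational causal inference:
unconfoundedness given $x$, overlap of the propensity score
$e(x) = P(z = 1 \mid x)$, and SUTVA.

Working with an ensemble of rules rather than a single tree addresses two
well-known weaknesses of tree-based subgroup discovery: a single tree's
subgroups are unstable under small data perturbations, and factors that
drive heterogeneity independently tend to surface only as interactions
along one tree's branches. Rules harvested from many trees, screened for
stability, can represent independent drivers as separate additive terms.

## The two-step procedure

`cre()` splits the sample once, at random, into a *discovery* and an
*inference* subsample (fraction `ratio_dis`, default 0.5, to discovery);
each observation is used in exactly one step. This honest split means the
rules tested in the inference step were chosen without looking at the data
they are tested on, so the reported intervals and p-values are not
contaminated by selection.

**Discovery.** The individual treatment effects are estimated on the
discovery half (see below), and a gradient-boosted ensemble of shallow
regression trees is fit to those estimates — a *fit-the-fit*: the trees
model an estimate, not the raw outcome. Every root-to-node path of every
tree, internal nodes included, becomes a candidate rule; conditions are
canonicalized (per-variable interval intersection, fixed ordering,
thresholds on binary covariates snapped to 0.5) and deduplicated. Each
candidate is then *decay-pruned*: its last condition is dropped whenever
the relative increase in the rule's two-group-means MSE for predicting the
IATE estimates stays below `t_decay`. Candidates with support outside
$[t_{ext}, 1 - t_{ext}]$ are discarded, near-duplicates are removed by an
indicator-correlation scan at threshold `t_corr`, and at most `max_rules`
survive, ranked by importance (the MSE reduction of the rule's two-group
predictor over the global mean). Finally, LASSO-based stability selection
keeps the rules selected in at least a `cutoff` fraction of `B` small
subsamples.

**Inference.** On the held-out half the individual effects are estimated
afresh, and the decomposition is fit by ordinary least squares of those
estimates on the selected rule indicators with an intercept: the intercept
estimates $\bar\tau$ — in the decomposition's convention, the treatment
effect where no rule applies — and the slopes the AATEs. Percentile confidence
intervals and normal-approximation p-values come from a row-resampling
bootstrap, and rules whose p-value exceeds `t_pvalue` are pruned
iteratively — dropping a rule changes the others' estimates, so the fit
and bootstrap are repeated until every survivor is significant or none
remain. An empty final set is a valid outcome: the model reduces to the
ATE.

## Individual treatment effect estimation

Both steps need per-unit effect estimates $\hat\tau_i$. The default is the
doubly robust AIPW pseudo-outcome

$$
\hat\tau_i = \hat m_1(x_i) - \hat m_0(x_i)
 + z_i \frac{y_i - \hat m_1(x_i)}{\hat e(x_i)}
 - (1 - z_i)\frac{y_i - \hat m_0(x_i)}{1 - \hat e(x_i)},
$$

whose conditional mean equals the CATE if either the propensity model
$\hat e$ or the outcome models $\hat m_z$ are consistent. Nuisance models
are fit by cross-fitting with `n_folds = 2` folds — each unit's prediction
comes from a model not trained on it, which prevents overfit
pseudo-outcomes at modest cost — and the propensity score is clipped to
$[\varepsilon, 1 - \varepsilon]$ with `clip_eps = 0.01` for stable inverse
weighting. S-, T- and X-learner meta-estimators are available as
alternatives, and all estimators sit behind one fit/predict learner
contract (`"gbm"` gradient boosting by default; `"rf"`, `"linear"`,
`"logistic"`, `"constant"`, or any user-supplied fit/predict pair).

Passing `ite =` to `cre()` bypasses internal estimation entirely in both
steps — useful for external estimators (causal forests, causal BART, ...)
or for computing the estimate once during hyper-parameter exploration.
Downstream results then depend only on the supplied vector.

## Stability selection details

Each of the `B = 50` subsamples holds `subsample = 0.05` of the discovery
half, drawn without replacement. On each subsample the LASSO path of the
IATE estimates on the (internally standardized) rule indicators is
followed from the largest penalty downwards, and a rule counts as selected
if it becomes active before the active set first exceeds a cap $q$; the
selection frequency of a rule is the fraction of subsamples selecting it.

* `"vanilla"` (default): the cap is fixed at $q = 10$ entered rules, and
  rules with frequency $\ge$ `cutoff` (default 0.9) are kept. The cap is
  deliberately liberal: overlapping rules extracted from tree paths are
  strongly correlated, and a penalty tuned for prediction (for example by
  cross-validation on a 50-observation subsample) tends to admit only one
  member of a correlated group per subsample, splitting frequencies and
  leaving every rule below the cutoff. Letting the first ten rules enter
  lets a true rule accumulate frequency even when variants of it are
  competing, while rules unrelated to the signal still enter too
  erratically to reach 0.9.
* `"error_control"`: the cap is instead derived from the per-family error
  rate target, $q = \lceil \sqrt{\text{pfer} \cdot (2 \cdot
  \text{cutoff} - 1) \cdot M} \rceil$, the largest $q$ for which the
  stability-selection bound $E(V) \le q^2 / ((2c - 1) M)$ keeps the
  expected number of falsely selected rules below `pfer`.
* `"no"`: a single LASSO on the full discovery half with a 5-fold
  cross-validated penalty (`lambda.min`).

Subsampling aborts with a clear error when a subsample would hold fewer
than 10 observations or fewer than 2 distinct target values.

## The synthetic-data generator

`simulate_cre_data()` produces datasets whose CATE is *exactly* a known
rule decomposition, so that every stage of the pipeline can be scored
against ground truth. The template is fixed: rules
`x1>0.5 & x2>0.5`, `x5>0.5 & x6>0.5`, `x4>0.5`, and
`x5>0.5 & x7>0.5 & x8>0.5`, with AATEs alternating
$+\text{effect\_size}, -\text{effect\_size}, \ldots$; the first `n_rules`
(1–4) are used. Covariates come from a Gaussian copula with exchangeable
latent correlation `rho` (thresholded at 0 for binary covariates,
hence marginal probability 0.5; mapped through the normal CDF onto
$[0,1]$ otherwise). Treatment is Bernoulli with propensity 0.5 under
`confounding = "no"`, $\text{logit}^{-1}(-1 + x_1 + x_2)$ under `"lin"`,
and $\text{logit}^{-1}(-1 + x_1 x_2 + x_3)$ under `"nonlin"`. The
continuous outcome is $y = \sum_j x_j + z \cdot \text{ite} +
\varepsilon$ with standard normal noise; the unit slope on every covariate
gives the outcome model real structure to learn without dominating the
effect sizes of interest, and the unit noise scale puts effect sizes on a
signal-to-noise scale where an `effect_size` of 5 is strong and of 1 is
subtle. A binary outcome thresholds the latent continuous one at its
median, giving prevalence 0.5.

What the generator does *not* emulate about real data: covariate
measurement error, non-exchangeable correlation structures, continuous
effect modifiers (the true CATE is exactly piecewise constant on rule
regions), heavy-tailed or heteroscedastic outcome noise, and missing
data. Pipeline tests passing on this generator therefore demonstrate
correctness of the machinery and calibration under the stated model, not
robustness to those departures.

## Numerical and design choices

* **Tree ensemble**: gradient boosting (xgboost) with learning rate 0.1,
  row subsampling 0.7 between rounds for rule diversity, `ntrees = 20`
  rounds, `max_depth = 3`, `min_child_weight = node_size = 20`, single
  threaded for reproducibility.
* **Rule canonicalization**: at most one `<=` and one `>` condition per
  variable (binding thresholds kept); contradictory conjunctions are
  rejected at construction; the dedup key sorts conditions so it is
  order-invariant.
* **Decay pruning**: the error functional is the two-group-means MSE with
  an $\varepsilon = 10^{-6}$ guard in the denominator; `t_decay <= 0`
  disables pruning (a pruned rule's error is not nested in the full
  rule's, so a strictly negative relative increase is possible and should
  not trigger a drop at threshold zero).
* **Importance ties**: broken toward shorter rules, then toward rules
  with fewer complemented (`<=`) conditions — between a rule and an
  equally informative complement the affirmative subgroup statement is
  kept; the intercept absorbs the sign flip either way — then
  lexicographic rule text. All orderings are deterministic.
* **Collinearity**: the inference design keeps columns greedily in
  importance order while the intercept-augmented design stays full rank;
  dropped columns are warned about. Bootstrap replicates that lose rank
  are redrawn up to 10 times, then skipped with a warning.
* **Degenerate bootstrap**: on exactly linear data the bootstrap
  distribution collapses; intervals then have zero width and p-values are
  0 for nonzero coefficients, 1 otherwise.
* **Seeds**: one top-level seed drives a single derivation of per-stage
  seeds (split, discovery IATE, trees, stability, inference IATE,
  bootstrap), so a fitted object can be reproduced bit-identically from
  its echoed configuration.
* **`offset`**: accepted and echoed in the configuration for interface
  completeness but not consumed by any computation.

## Worked example

```{r, eval = FALSE}
library(causalrules)

d <- simulate_cre_data(n = 5000, p = 10, rho = 0, n_rules = 4,
                       effect_size = 5, binary_covariates = TRUE,
                       binary_outcome = FALSE, confounding = "no",
                       seed = 2024)
fit <- cre(d$y, d$z, d$X, seed = 1)
summarize(fit)
predict(fit, d$X[1:5, ])
plot(fit)
```

With these settings the final rule set is the full 4-rule template and
each AATE estimate falls within a few tenths of its true value of $\pm 5$;
the range bar plot orders subgroups from the highest AATE (most
vulnerable) down, with the ATE in the header.

## Validation problem sizes

The test suite exercises the pipeline at the scales it is designed for
while staying quick to run: template recovery and AATE accuracy over 20
generator seeds at $n = 2000$, $p = 10$, 2 rules, effect size 5; bootstrap
coverage of the AATE intervals over 100 datasets of the same shape
(200 intervals); stability-selection null behaviour over 100 pure-noise
designs with $M = 50$ rules at $n = 1000$; and exact small-sample oracles
(normal-equations solves, exhaustive pattern enumeration at $p \le 6$)
for the deterministic pieces.

## Limitations

* Rules are axis-aligned conjunctions; smoothly varying or oblique
  heterogeneity is approximated by step functions.
* The decomposition is fit to *estimated* individual effects; severe
  nuisance-model misspecification biases both discovery and inference,
  although AIPW gives protection when one nuisance is correct.
* Bootstrap p-values use a normal approximation with the bootstrap
  standard error; with very few inference-side observations per subgroup
  the approximation degrades (the subsample-size guard catches the worst
  cases).
* Causal forests and causal BART are not implemented internally; plug
  them in through `ite =` or a custom learner.
* `offset` and survey weights are not supported.
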