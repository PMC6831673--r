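---
title: "Fuzzy-forest screening for correlated survey data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-forest screening for correlated survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method it implements: the
model at each stage, the tunable parameters and why their defaults are what
they are, what the synthetic generator does and does not emulate, and the
numerical conventions adopted where the design was genuinely open.

## Why a two-stage screen

Permutation importance from a single random forest is a marginal measure:
when a block of features is mutually correlated, each member serves as a
partial proxy for the others, and the block as a whole can dominate the
importance ranking even when the scientifically interesting predictor is an
*independent* feature of moderate effect. The screen implemented here
confines that competition: features are first partitioned into
approximately independent modules using only their correlation structure,
each module is screened internally, and only the survivors — a bounded
number per module — compete in the final selection forest. An independent
feature is its own pseudo-module member and can never be crowded out before
the final round.

## Stage 1: the weighted correlation network

**Model.** The adjacency between features $i$ and $j$ is the unsigned
soft-thresholded Pearson correlation $a_{ij} = |\mathrm{cor}(x_i,
x_j)|^\beta$. Raising to the power $\beta$ suppresses small, noisy
correlations continuously rather than imposing a hard cutoff, and produces
a network whose connectivity distribution approximates a power law. The
quality of that approximation is summarized by the $R^2$ of regressing
log bin frequency on log mean bin connectivity over a connectivity
histogram (`scale_free_fit()`); `pick_soft_power()` returns the smallest
candidate power reaching the target $R^2$ (default 0.8) and otherwise the
best-fitting power with a warning.

Defaults and rationale:

* **power = 7** — the conventional choice for unsigned networks on
  survey-scale feature sets; config-exposed, and `power = NULL` activates
  the grid search.
* **Unsigned (not signed) network** — at the screening stage the *sign* of
  an association carries no information about whether two items measure the
  same construct; unsigned is the common default.
* **Pearson (not robust) correlation** — survey features here are
  ordinal-numeric encodings or 0/1 indicators, for which the efficiency
  loss of robust correlation buys little; nominal items enter through their
  reference-coded indicators.

**Topological overlap.** Clustering operates on the topological-overlap
dissimilarity rather than on $1 - a_{ij}$ directly (a flag restores the raw
option). TOM credits two features for *shared neighbourhoods*, which
stabilizes module boundaries when individual pairwise correlations are
noisy.

**Tree cut.** Modules are read off an average-linkage dendrogram with a
*static* cut — dynamic tree cutting is deliberately out of scope — at a
fixed fraction of the maximum merge height, with clusters below
`min_module_size = 5` left unassigned (label 0). The default fraction is
**0.99**: with $\beta = 7$, the overlap between unrelated features is
driven to nearly zero, so their dissimilarities pile up just below 1 while
genuine modules (within-correlation 0.6–0.8) close between roughly 0.76 and
0.98. A mid-range cut such as 0.75 of the maximum sits *below* the heights
at which moderately correlated modules assemble and orphans every feature;
the near-ceiling cut separates the two regimes cleanly. Features are
clustered in lexicographic name order, making the partition invariant to
column permutation, and ties in any ranking are broken by feature name.

**Eigenfactors and merging.** Each module is summarized by its eigenfactor:
the unit-norm first principal component of the standardized member block,
sign-fixed so that it correlates nonnegatively with the module's mean
standardized feature. Modules whose eigenfactors correlate above
`merge_similarity = 0.5` ("more than 50% similar") are merged iteratively,
most-similar pair first, recomputing eigenfactors after each merge; the
loop terminates after at most $K - 1$ merges. Similarity between modules is
*defined* as eigenfactor correlation; dendrogram-height similarity was the
other plausible reading and is not implemented.

**Unassigned features are kept.** Label-0 features are screened as a
pseudo-module in stage 2. Discarding them would throw away precisely the
independent predictors the method exists to protect.

## Stage 2: module-wise recursive feature elimination

Importance is the **unscaled** mean decrease in out-of-bag classification
accuracy under feature permutation (dividing by its standard error is
available behind `scale_importance`, but re-introduces instability when the
standard error is near zero). Each RFE round drops the lowest-ranked
`ceiling(drop_fraction × p)` features, never descending below the target
count, and the final round truncates exactly to target by rank. Per-module
targets are `max(1, ceiling(0.35 × size))`; the pooled survivors enter one
final RFE whose target is 20.

Forest engine defaults (all config-exposed through `ff_control()`):

* `ntree = 150` with a floor of `3 × p_current` trees; combined with
  `mtry = ⌈√p⌉` and depth-8 trees, every feature receives thousands of
  split opportunities per forest, which is what the tree-count caution is
  about.
* `max_depth = 8`, `min_node_size = 25` — screening-oriented forests; the
  quantity being consumed is the importance *ranking*, which stabilizes far
  earlier than individual tree predictions. These sizes keep a full
  repeated-screening study (50 stability runs on 2000 × ~200 data) in the
  ten-minute range on a single CPU.
* 0.632 subsampling **without replacement** rather than bootstrap: the
  out-of-bag fraction is the same (~37%), and subsampling avoids the mild
  selection bias that with-replacement resampling induces in importance
  measures.
* `drop_fraction = 0.5` — geometric halving, the classic RFE schedule; the
  exact terminal count is guaranteed by the final rank-truncation, so the
  schedule affects only the path, not the contract.
* Forests are **unweighted** by default: survey weights describe the
  sampling design, not the conditional outcome distribution, and belong to
  the confirmatory model. `weighted_bootstrap = TRUE` grows trees on
  weight-proportional resamples for sensitivity analysis.

All stage-2 randomness flows from one master seed through a name-based
derivation (`derive_seed(master, "module_3")` etc.), so results cannot
depend on the order in which modules are screened, and `n_permutations > 1`
averages importance over independently seeded replicate forests.
`stability_selection()` repeats stage 2 under derived seeds — stage 1 is
deterministic and computed once — and reports per-feature selection
frequencies.

## The confirmatory model

`weighted_logit()` maximizes the weighted pseudo-log-likelihood
$\sum_i w_i [y_i \log p_i + (1 - y_i)\log(1 - p_i)]$ by IRLS (convergence
when $\max|\Delta\beta| < 10^{-8}$, at most 100 iterations), with weights
normalized to mean 1 for numerical stability. The variance is the
weights-only sandwich $A^{-1} M A^{-1}$ with $A = \sum_i w_i p_i(1-p_i)
x_i x_i^\top$ and $M = \sum_i (w_i(y_i - p_i))^2 x_i x_i^\top$ — a
with-replacement approximation to the survey design. Stratum/PSU Taylor
linearization and replicate weights are out of scope, so interval estimates
will differ modestly from a full design-based fit; point estimates do not.
Wald limits are z-based, $\exp(\beta \pm z_{0.975}\,\mathrm{se})$, and
factor levels are labelled against their first (reference) level.

Quasi-complete separation — the signature failure mode of a factor level
observed once or twice — is detected by non-convergence combined with a
coefficient magnitude above 15 and reported as an error naming the term,
rather than silently returning a nonsensical estimate.
`drop_rare_language(min_n = 2)` removes single-respondent language levels
*before* fitting, which reproduces this cleanup without hard-coding any
language name. Whether a held-out accuracy should be attributed to the
selection forest or to the logistic refit is ambiguous in general, so
`run_pipeline()` computes and labels both.

## The synthetic generator

`simulate_survey()` emulates, at desk scale, the structure that makes
multilingual health-survey data hard: five latent-factor modules
(equicorrelation $x_j = \sqrt{\rho} f + \sqrt{1-\rho}\,\varepsilon_j$, so
the population within-module correlation is exactly $\rho$), independent
features, five planted predictors with coefficient 1.2 (three inside
modules, two independent), a seven-level interview-language factor whose
shares mirror a mostly-English survey with a one-in-2000 rare level, a
binary good-health outcome from a logistic link, a five-level self-rated
health item consistent with that binary truth, and log-normal(0, 0.5)
weights. Equicorrelation is the simplest covariance that exercises the
correlation-bias phenomenon; an intercept of 0.5 puts good-health
prevalence near 0.6 and the realized Bayes accuracy near 0.83, so a correct
end-to-end fit lands near 0.83 held-out accuracy — the yardstick used in
tests rather than any external dataset.

What it does **not** emulate: multi-stage sampling (strata, PSUs, raking),
item nonresponse, discreteness of Likert items (a quantile-cut option would
not change the planted truth and is omitted), or real marginal
distributions. Passing tests therefore demonstrate correctness of the
machinery under a known truth, not performance claims about any particular
survey.

## Numerical conventions and edge cases

* Percentages in published-style tables round half-away-from-zero to two
  decimals (`round_half_up()`), the convention survey tables use; R's
  banker's rounding differs at exact halves.
* A degenerate connectivity distribution (all equal) yields scale-free
  $R^2 = 0$ with an explicit flag rather than `NaN`.
* A single-feature module's eigenfactor is its standardized column with
  variance-explained 1.
* Empty cells in conditional proportion tables are `NA` (undefined), never
  0.
* Constant features receive importance ~0 without error; a single-class
  outcome is an error.
* AUC uses midranks, giving ties half credit; it equals exhaustive
  pairwise enumeration exactly.

## Known limitations

* The static tree cut assumes modules denser than their surroundings at a
  common scale; nested or chained correlation structures that dynamic
  cutting resolves will be merged or orphaned.
* The decoy property — an independent signal selected at least as often as
  under a plain single forest — is a statement about *null* correlated
  blocks. When a correlated block is itself strongly predictive, per-module
  screening legitimately favours it, and a weak independent signal may rank
  lower than under a plain forest, whose importance dilution across block
  members incidentally protects the signal. This boundary of the property
  is worth keeping in mind when interpreting selections.
* Calibration checks that require *every* one of 50 null importances to sit
  inside a simultaneous ±3 standard-error band fail a perfect null in
  roughly one realization in six by multiplicity alone; the package's
  checks report the maximum standardized deviation so that a marginal
  exceedance can be distinguished from systematic bias.
* Regression and multi-class outcomes, conditional-inference forests, and
  importance p-values are out of scope.

## Problem sizes used by the packaged studies

The repeated-screening studies run 50 stage-2 repetitions on the default
2000 × ~200 synthetic configuration; the decoy comparison uses 50 seeded
500 × 31 designs; null calibration uses 100 independent 500 × 50 null
datasets; closed-form and enumeration checks use toy sizes where the exact
answer is computable by hand. These sizes were chosen so the full study
suite completes in well under half an hour on a single CPU while leaving
each statistical check comfortably powered.
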