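# fuzzyscreen

Two-stage "fuzzy forest" variable screening for high-dimensional, correlated
survey data, with a survey-weighted logistic validation workflow and a
synthetic survey generator.

## The problem

Permutation-importance variable selection with random forests is biased when
predictors are correlated: blocks of mutually correlated survey items crowd
out genuinely independent predictors. Public-health surveys such as the
California Health Interview Survey (CHIS) are exactly this kind of data —
hundreds of items, organized by topic, highly intercorrelated within topic —
and screening them for heterogeneity signals (for example, whether the
*language of interview* predicts self-rated health) requires a selector that
is honest under correlation.

`fuzzyscreen` implements the two-stage strategy:

1. **Unsupervised module detection.** Build a weighted correlation network
   with soft thresholding, `a_ij = |cor(x_i, x_j)|^β` (default β = 7, chosen
   for approximate scale-free topology), transform to topological-overlap
   dissimilarity, cluster with average linkage, and merge modules whose
   eigenfactors (first principal components) correlate above 0.5. The
   outcome plays no role in this stage.
2. **Supervised screening.** Within each module — including the
   pseudo-module of unassigned features — recursive feature elimination
   (RFE) with out-of-bag permutation importance keeps the top
   `max(1, ⌈0.35 · size⌉)` features; the pooled survivors enter one final
   RFE forest and the top 20 predictors are selected.

Downstream, a survey-weighted logistic regression (IRLS on the weighted
pseudo-likelihood, sandwich variances, Wald odds-ratio intervals) refits the
selected predictors plus forced adjusters, and the model is validated on a
held-out survey wave by accuracy and Mann–Whitney AUC.

## Worked example

```r
library(fuzzyscreen)

sim <- simulate_survey(seed = 1)   # 2000 train + 2000 test respondents,
                                   # 5 planted modules, 5 true predictors,
                                   # 7-language factor with one rare level
rep <- run_pipeline(sim$train, sim$test, sim$codebook, seed = 99)
print(rep)
```

```
Fuzzy-forest survey pipeline
  train n = 1999, test n = 1999, seed = 99
  dropped rare language level(s): Tagalog (n=1)
  selected predictors: m2_f01, ind_01, ind_02, m1_f01, m3_f01, m1_f12, m3_f23, m2_f18 ...
  held-out accuracy: logistic 0.829, forest 0.793
  held-out AUC:      logistic 0.910, forest 0.873
```

All five planted predictors (`m1_f01`, `m2_f01`, `m3_f01`, `ind_01`,
`ind_02`) are in the selected set; the interview language observed exactly
once was dropped before the logistic refit, mirroring how a one-respondent
level destabilizes a weighted logistic fit; held-out accuracy 0.829 matches
the generator's Bayes rate (0.826 on this realization) — the screen found
the true model. Odds ratios for the planted features centre on
`exp(1.2) ≈ 3.3`:

```r
head(odds_ratios(rep$glm_fit), 3)
#     term  label    point       lo       hi
# 1 m2_f01 m2_f01 3.451721 2.671111 4.460458
# 2 ind_01 ind_01 3.104875 2.657968 3.626925
# 3 ind_02 ind_02 2.838228 2.386524 3.375427
```

Lower-level entry points mirror the stages: `build_network()`,
`screen_modules()`, `select_final()`, `fuzzy_forest()`,
`stability_selection()`, `module_importance_summary()` (the "modplot"),
`weighted_logit()`, `evaluate_predictions()`, and the descriptive helpers
`recode_good_health()`, `chronic_condition_indicator()`,
`drop_rare_language()`, `language_summary()`, `conditional_proportions()`.
A thin command-line front end lives at `inst/cli/fuzzyscreen-cli.R`
(`simulate`, `fit`, `report` subcommands).

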