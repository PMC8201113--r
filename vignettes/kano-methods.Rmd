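---
title: "Kano-model quality evaluation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kano-model quality evaluation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kanoqual)
```

## The model

The Kano model treats service quality as two-dimensional: how a customer
feels when an attribute **is** present (the *functional* item) and when it
**is not** (the *dysfunctional* item). Each attribute of a service is probed
by such a pair, both answered on the same five-point scale
(`likert_scale()`): *I like it*, *I hope it is so*, *I am neutral*,
*I can accept it being that way*, *I dislike it that way*.

A pair of codes $(f, d) \in \{1..5\}^2$ is mapped to one of six quality
categories by a 5×5 **evaluation matrix**:

* **A** (attractive) — presence delights, absence does not hurt;
* **O** (one-dimensional) — satisfaction rises when met, falls when unmet;
* **M** (must-be) — taken for granted; absence causes strong dissatisfaction;
* **I** (indifferent) — no preference either way;
* **R** (reverse) — presence dissatisfies, absence satisfies;
* **Q** (questionable) — contradictory answers (e.g. liking both presence
  and absence).

The package ships the canonical matrix (`kano_matrix()`): row 1 (presence
liked) gives A for neutral-ish absence answers and O when absence is
disliked; column 1 and row 5 are reverse; the middle 3×3 block is
indifferent; (1,1) and (5,5) are questionable. Published Kano studies rarely
print their matrix, and minor variants exist, so the matrix is an explicit,
replaceable argument of every classification function
(`read_kano_matrix()` loads one from CSV) rather than a constant.

Per attribute, the category counts $(n_A, n_Q, n_I, n_R, n_M, n_O)$ over all
respondents with a complete pair are tallied, and the attribute is assigned
the **modal** category. The Berger coefficients summarise the counts:

$$CS = \frac{n_A + n_O}{n_A + n_O + n_M + n_I} \in [0, 1], \qquad
  DS = -\frac{n_M + n_O}{n_A + n_O + n_M + n_I} \in [-1, 0].$$

CS is the expected gain in satisfaction when the attribute is provided, DS
the expected loss when it is not; reverse and questionable responses are
excluded from the denominator. DS is conventionally reported with a negative
sign, which this package follows.

## Worked reference data

The package bundles the per-attribute category counts of a published
250-user satisfaction survey of outpatient services at two hospitals
(31 attributes in four HEALTHQUAL-derived dimensions: 10 health-personnel,
4 non-health-personnel, 6 facilities/equipment/tangibles, 11 efficiency).
`hospital_survey_counts()` returns the counts;
`hospital_survey_responses()` expands them deterministically into a
250-respondent table so the whole respondent-level pipeline can be
exercised even though the raw survey data are not public.

```{r}
res <- kano_analyze(hospital_survey_responses())
summarize_classifications(res)
res[c(1, 21, 31), c("attr_id", "classification", "cs", "ds")]
```

27 of the 31 attributes come out one-dimensional, 3 must-be (arranging an
appointment, bureaucracy, complaint resolution) and 1 reverse (side effects
of medicines).

## Numerical and design choices

* **Tie-break.** The modal rule can tie. The default priority is the
  conservative must-be-first convention **M > O > A > I > R > Q**
  (`kano_tie_order()`), configurable everywhere it is used. No ties occur in
  the bundled reference counts, so the choice does not affect them.
* **Rounding.** Reported CS/DS are rounded to two decimals **half away from
  zero** (`round_half_up()`); base R's round-half-even disagrees with the
  reference tables on exact halves (e.g. 144/250 = 0.576 is unaffected, but
  0.575-type halves are not). Exact rationals are kept in the `cs_exact` /
  `ds_exact` columns.
* **Missing data.** An answer pair enters the tally only if *both* codes are
  present and in 1..5, so per-attribute valid *n* may differ. A code outside
  1..5 is a validation error (naming row and column), not a missing value.
* **Undefined coefficients.** If all of an attribute's responses are
  reverse/questionable the CS/DS denominator is zero; the coefficients are
  returned as `NA` (distinct from 0) while the modal classification is still
  made. Quadrant charts skip such attributes with a warning.
* **Degenerate inputs.** An attribute with zero valid pairs gets all-zero
  counts and an `NA` classification from `kano_analyze()`;
  `classify_attribute()` called directly on all-zero counts is an error.
* **Reliability.** `standardized_alpha()` implements standardized Cronbach's
  alpha, $k\bar r / (1 + (k-1)\bar r)$ with $\bar r$ the mean pairwise
  Pearson correlation, after listwise deletion (`item_matrix()`). Which
  items enter alpha is selectable; the default is all 62 paired items, since
  questionnaire-level reliability is usually quoted for the whole
  instrument. The reference survey's alpha (0.75) cannot be recomputed here:
  it requires the raw respondent-level answers, which were never published.
  The expansion in `hospital_survey_responses()` reproduces every category
  count exactly but not the inter-item correlation structure, so an alpha
  computed on it says nothing about the real survey.

## The synthetic-respondent generator

`simulate_responses()` draws surveys with a controllable Kano structure so
that every pipeline stage is testable without real data. A
`kano_profile()` specifies, per attribute, either a full 25-cell
distribution over answer pairs or a 6-category distribution realised
through one designated *representative cell* per category
(`representative_cells()`: A→(1,3), O→(1,5), M→(3,5), I→(3,3), R→(5,1),
Q→(1,1) — each maps back to its category under the canonical matrix, which
makes count→table→count round trips exact, the property `expand_counts()`
relies on).

Defaults follow the reference survey's study conditions: 250 respondents,
and demographic strata taken from its printed margins — ages
67/101/60/22 (18–34/35–54/55–74/75+), 122 male/128 female, 128/122 across
the two hospitals. The exact count fractions (67/250 etc.) are used rather
than the rounded printed percentages so that deterministic quota assignment
reproduces the printed margins exactly at *n* = 250. The default
per-attribute category mix (O 0.50, M 0.20, I 0.15, A 0.10, R 0.03, Q 0.02)
mirrors the one-dimensional-dominated pattern of the reference survey.

What the generator deliberately does **not** model, and hence what passing
tests do not establish about real data: dependence between attributes
(respondents who are critical on one attribute tend to be critical on
others — this is exactly what drives a high questionnaire alpha),
dependence of answers on demographics, and nonresponse mechanisms. Answers
are i.i.d. across respondents and independent across attributes given the
profile.

Simulation is seeded and the seed is part of the contract: the same profile
and seed give the identical table (`withr::with_seed` is used internally, so
the caller's RNG state is untouched).

## Problem sizes used in the test suite

The randomized checks run at desk scale: oracle-equivalence tests use
tables of up to 20 respondents and 5 attributes against a naive
loop-and-lookup reimplementation; goodness-of-fit checks use one attribute
at *n* = 5000 over 20 seeds; parameter-recovery checks use 200 replicates of
*n* = 250 with 0.6 of the probability mass on the dominant category's cell.
These sizes give the multinomial margins cited in each test while keeping
the whole suite in the tens of seconds.

## Limitations

The classification rule is the simple mode over six counts; significance
testing of the modal category (Fong's test), importance-weighted or fuzzy
Kano variants, and finer splits of the one-dimensional band are out of
scope. The quadrant chart's axis convention (x = |DS|, y = CS, split at
0.5) is stated on the chart; published figures do not always document
theirs, so visual comparisons across studies need care.
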