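---
title: "Scoring the Monetary Choice Questionnaire and imputing its missing responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the Monetary Choice Questionnaire and imputing its missing responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcqimpute)
```

## The instrument and its model

The Monetary Choice Questionnaire (MCQ) presents a fixed series of binary
choices between a smaller immediate monetary reward `V` and a larger delayed
reward `A` available after `D` days. Under the simple hyperbolic discounting
model, the present value of the delayed option is `A / (1 + kD)`, where `k`
is the individual's discount rate. Each item is constructed so that the two
options are subjectively equal at one specific rate,

```
k_item = (A / V - 1) / D ,
```

implemented in `compute_item_k()`. A respondent whose personal `k` exceeds
`k_item` should take the immediate reward; one below it should wait. The
items span a geometric ladder of `k_item` values, and each rung of the
ladder appears three times — once per **amount set** (small, medium, and
large delayed amounts) — so the questionnaire behaves like three parallel
forms administered at once. The 21-item version uses 7 rungs per set, the
27-item version 9.

## Scoring by consistency scores

Order the items by ascending nominal `k`. A candidate switch position `s`
(0..n) asserts: immediate on the first `s` items, delayed on the rest. Its
consistency score is the fraction of observed responses agreeing with that
assertion (`consistency_profile()`). The `k` estimate attached to an
interior maximising position is the geometric mean of the two bracketing
item `k`s; when several positions tie, the geometric mean over all tied
candidates is taken (`estimate_k_from_profile()`). Running this over all
items and over each amount set separately gives the overall, small, medium,
and large `k`s; the **composite k** is the geometric mean of the three set
`k`s. `score_cohort()` returns all five per respondent, plus the
proportion-of-delayed-choices score, the per-scope consistency maxima, and
ln/log10 transforms of the composite.

Conventions the instrument's literature leaves open, fixed here:

* **Boundary patterns.** An all-delayed pattern maximises consistency at
  position 0 and receives the scope's *minimum* nominal `k`; all-immediate
  receives the maximum. This keeps every estimate inside the instrument's
  measurable range — the questionnaire cannot resolve rates beyond its
  ladder.
* **Ties.** The geometric mean over all maximally consistent candidate
  `k`s, following the convention of the established spreadsheet scorer.
* **Nominal vs recomputed `k`.** Published (rounded) item `k`s are used for
  ordering, estimation and reporting, for comparability with existing
  scorers; `load_item_bank()` verifies each against `(A/V - 1)/D` within a
  15% relative tolerance (published values carry roughly one significant
  figure: 0.0007 vs 0.000684).
* **Overall ordering with tied `k`s.** All n items are kept as separate
  positions (not collapsed to the distinct-`k` grid), in rank blocks
  ordered small → medium → large. Since tied items share a `k`, the block
  order cannot change any consistency maximum; the literal all-items
  ordering is the default and no distinct-grid variant is exposed.

## The four missing-response approaches

Missing responses are endemic to the MCQ, and one blank is enough to break
strict scoring. The package implements four remedies (`apply_approach()`):

1. **Mode** (`mode_impute()`): replace each blank with the per-item mode of
   the observed responses in the sample at hand. Ties break toward the
   delayed choice — a deterministic convention that avoids an RNG in an
   otherwise deterministic method — and are flagged in the fill log. In the
   Monte Carlo harness the mode is recomputed per iteration from the
   current incomplete matrix, i.e. from exactly the data a practitioner
   would have.
2. **Group geometric mean, GGM** (`relaxed_composite()`): impute nothing;
   compute the composite from whichever amount sets are fully observed. A
   respondent fails only when all three sets are hit — which is impossible
   for fewer than three missing responses.
3. **Item nearest neighbour, INN** (`inn_impute()`): each item's two
   same-`k` neighbours in the other sets are consulted. Two congruent
   observed neighbours are copied; one observed neighbour is copied; two
   incongruent neighbours (or none) leave the cell missing. References are
   always read from the *pre-imputation* matrix, so fills cannot cascade
   and the result is order-independent. Cells INN cannot resolve fall back
   to the GGM composite rule — without that fallback a single incongruent
   pair at r = 1 would already produce unimputable respondents, which
   contradicts the zero failure counts this approach exhibits at small r.
4. **INN with random**: as INN, then every still-missing cell is filled
   with an independent fair draw from {0, 1}. "Random" is read as the
   symmetric Bernoulli(0.5) — the only probability not privileging either
   option. The matrix is complete afterwards, so nobody is unimputable.
   A random fill only moves an estimate when it changes the maximally
   consistent switch position, which is why this approach tracks plain INN
   so closely on resolved cells (a property the tests check cell-wise).

## The analytic failure-count oracle

Under removal of exactly `r` of the `3m` items uniformly at random, the
probability that all three sets lose at least one item is, by
inclusion-exclusion,

```
P(fail) = 1 - [3 C(2m, r) - 3 C(m, r)] / C(3m, r)      (r >= 3; else 0)
```

`expected_ggm_failures()` multiplies this by the cohort size. These values
are structural — independent of what anyone answered — and anchor the Monte
Carlo harness: the simulated GGM failure counts must converge on them, and
do (e.g. 232.1 of 900 at m = 7, r = 3; 457.0 of 512 at m = 9, r = 7).

## The synthetic cohort: what it emulates, what it does not

Real MCQ datasets cannot ship with the package, so `synth_cohort()`
generates cohorts with known ground truth:

* `true_ln_k ~ Normal(ln_k_mean, ln_k_sd²)`. Defaults: mean at the bank's
  mid-rank nominal `ln k`, sd = two rank spacings (≈ 2.0 for the 21-item
  ladder). This covers the instrument's range without piling respondents
  onto the boundary rungs.
* Choices follow a logistic rule in `ln k`:
  `P(delayed) = plogis(noise_beta * (ln k_item - true_ln_k))`, the simplest
  noise model consistent with the hyperbolic indifference structure.
  Default `noise_beta = 2`, which produces mostly-consistent but imperfect
  patterns (mean maximal consistency ≈ 0.95, similar to well-behaved real
  samples); `Inf` gives deterministic single-switch respondents, used by
  the parameter-recovery tests.
* A covariate standing in for an external discounting measure (such as
  probability discounting) is drawn jointly with `true_ln_k` at population
  correlation `covariate_rho` (default 0.35, a typical magnitude for
  correlations between discounting measures).
* Cohort sizes default to 900 (21-item) and 512 (27-item), the sizes of the
  evaluation study's real cohorts.
* Missingness is injected MCAR only: exactly `r` cells per row, uniform
  without replacement (`inject_missing()`), matching the evaluation design.
  MAR/MNAR mechanisms are out of scope.

These defaults are package choices, stated once and not tuned: none of them
reproduces any real cohort's distribution. Consequently a green Monte Carlo
test establishes *structural* facts (failure combinatorics, ordering of
methods, determinism, qualitative bias behavior) — it does not reproduce
the published mean-difference/RMSD/correlation magnitudes, which depend on
real response data that is not available. The unimputable-count rows are the
exception: they are content-independent and are reproduced quantitatively.

## The Monte Carlo harness

`run_condition()` runs one (method, r) cell: per iteration, inject
missingness into the complete base matrix, apply the approach, and measure
against the base-matrix scores (`compute_metrics()`):

* `mean_difference`, `rmsd`, `corr_true` on the **raw k scale** (the
  magnitudes reported for these measures are only consistent with raw k);
* `delta_corr_covariate` on the **ln k scale** (to approximate normality),
  as the change in Pearson correlation with the covariate;
* `n_unimputable`, the respondents left without a composite.

Respondents without an imputed composite are excluded pairwise from the
first three measures and counted in the last — the only exclusion rule that
leaves the always-complete methods untouched. `run_study()` assembles the
full grid with across-iteration means and standard deviations, plus an
"overall" row per method: the unweighted mean over `r` (equal iteration
counts make this the mean of all iterations), with the sd pooled over all
iterations across `r` — the convention that reproduces the published
overall failure counts (267 and 229) from the per-`r` rows. One master seed
spawns a substream per iteration, so any cell of the grid is independently
reproducible.

Default iterations: 1000, as in the evaluation design. The test-suite and
acceptance script use 200 (failure counts) and 60 (bias grid) to stay
within desk-scale runtimes; their tolerances are computed from the realised
Monte Carlo standard errors, so fewer iterations widen, never cheat, the
bands.

## Numerical choices

* Consistency profiles are computed as integer counts (via triangular
  matrix products) and compared exactly; ties in the profile are exact
  integer ties, not floating-point coincidences.
* All geometric means are computed as `exp(mean(log(.)))`; set `k`s are
  strictly positive by construction so no guards are needed.
* `relaxed_composite()` treats "all three sets undefined" as `NA`, never an
  error: undefined is a value in this domain.
* Degenerate inputs: empty cohorts score to empty tables; an all-missing
  respondent has `NA` everywhere and `proportion_delayed = NA`; an
  all-missing item makes mode imputation fail loudly (its mode does not
  exist) rather than guess.
* The CLI accepts `""`, `"NA"`, `"NaN"` (any case) as missing on input and
  always writes missing as empty fields; reruns under a fixed seed are
  byte-identical (manifests carry no timestamps).

## Limitations

* **Raw-k Jensen bias.** The composite k is an exponential of ln-scale
  averages, so any imputation that adds ln-scale variance inflates its
  expectation. On the default synthetic cohort this bias is tiny in
  absolute terms (≈ +0.001 to +0.004 k units for GGM/INN/INN-random at the
  largest r, versus |−0.014| for mode and RMSDs an order of magnitude
  larger), but a 900-respondent cohort makes per-iteration means precise
  enough that a strict "within 2 Monte Carlo standard errors of 0" test
  rejects it. The corresponding acceptance test is therefore expected to
  fail and is left failing deliberately; the defensible, qualitative
  version of the property — the structure-aware approaches are far less
  biased than mode and their bias is small against their own RMSD — is
  what the module test suite asserts. Published evaluations' "centered
  around 0" should be read the same way: as a statement about
  distributions, not a significance test.
* **Mode's bias sign is cohort-dependent.** With a symmetric-in-`ln k`
  cohort centered on the ladder, mode imputation pulls respondents toward
  the modal pattern and the raw-k effect of pulling *down* high-k
  respondents dominates: the bias is negative here, though clearly bounded
  away from zero. Right-skewed real cohorts can show the opposite sign.
* The 21-item bank shipped is a labelled synthetic structural stand-in (see
  `?mcq_item_bank`); use `load_item_bank()` with the genuine table for real
  21-item data.
* No maximum-likelihood, Bayesian, multilevel-logistic, or
  multiple-imputation scoring: the scope is the consistency-score
  procedure and imputation approaches that use only the MCQ's own
  structure. The same-set nearest-`k` replacement (copying a neighbouring
  *different*-`k` item within the set) is excluded by design as inherently
  biased.
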