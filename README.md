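# mcqimpute

Scoring and missing-response imputation for the 21- and 27-item Monetary
Choice Questionnaire (MCQ), with a Monte Carlo harness for evaluating how
each imputation approach distorts the recovered discount rates.

## Who this is for

The MCQ is a fixed battery of binary choices between a smaller immediate
reward and a larger delayed reward ("$34 tonight or $35 in 43 days?"). It is
one of the standard instruments for measuring **delay discounting** — the
decline of a reward's present value with the delay to its receipt — which is
studied as a behavioral marker in addiction, obesity, and other clinical
research. Researchers who collect MCQ data routinely face blank responses,
and the conventional scorers simply drop those respondents. This package
scores the MCQ, imputes missing responses using the questionnaire's own
structure, and quantifies what each imputation strategy does to the
estimates.

## The model and the scoring statistic

Under Mazur's hyperbolic model the present value of a delayed reward is

    V = A / (1 + kD)

where `A` is the delayed amount, `D` the delay in days, and `k` the
individual discount rate. Each MCQ item is built around the `k` at which its
two options are subjectively equal: `k = (A/V − 1)/D`. The items form three
**amount sets** (small, medium, large delayed amounts), each spanning the
same ladder of nominal `k` values, so every item has two "nearest
neighbours" with the same `k` in the other sets.

Scoring orders the items by ascending `k` and evaluates every candidate
switch point `s` by its **consistency score**: the proportion of responses
that are immediate before `s` and delayed at or after it. The estimate is
the geometric mean of the item `k`s bracketing the maximally consistent
switch (geometric mean over ties; the scope's min/max `k` at the
boundaries). This yields five estimates per respondent — overall, small,
medium, large, and the **composite k** (geometric mean of the three set
`k`s) — plus the proportion-of-delayed-choices score.

Four missing-response approaches are implemented:

| approach | idea | residual missingness |
|---|---|---|
| `mode` | fill with the per-item sample mode | none |
| `ggm` | no fill; composite from whichever sets are complete | respondents missing in all 3 sets |
| `inn` | copy congruent same-`k` responses from the other sets | incongruent / unreferenced cells |
| `inn_random` | `inn`, then fair random fills for the rest | none |

## Quick example

```r
library(mcqimpute)

bank   <- mcq_item_bank(27)                 # published 27-item parameter table
cohort <- synth_cohort(bank, seed = 1)      # 512 synthetic discounters
incomplete <- inject_missing(cohort$responses, r = 4)  # MCAR, 4 blanks/row

res <- apply_approach(incomplete, bank, "inn_random")
res$report
#> MCQ imputation report: method 'inn_random'
#>   cells filled: 2048  residual missing cells: 0
#>   respondents without composite k: 0
#>   fill provenance:
#>
#>  congruent-copy          random single-ref-copy
#>            1446             178             424

head(res$scores$composite_k, 3)
#> [1] 0.002131385 0.009905530 0.001157094
```

The report says: of the 512 × 4 = 2048 removed responses, 1446 were
restored from two congruent same-`k` neighbours, 424 from a single
neighbour, and 178 had incongruent or absent neighbours and were filled with
fair coin flips — after which every respondent has a composite `k`.

The analytic companion for the group-geometric-mean approach:

```r
expected_ggm_failures(900, 7, 3)   # 232.1 of 900 respondents unimputable
expected_ggm_failures(512, 9, 7)   # 457.0 of 512
```

A full Monte Carlo evaluation (mean difference, RMSD, correlation with the
true composite `k`, unimputable counts, covariate-correlation shift):

```r
study <- run_study(cohort$responses, bank, iterations = 1000,
                   covariate = cohort$truth$covariate, seed = 7)
study$table
```

Command line (same functionality as the R API):

```sh
Rscript $(Rscript -e 'cat(system.file("cli","mcq.R",package="mcqimpute"))') \
  impute --method inn-random --bank 21 --seed 7 \
  --in responses.csv --out scores.csv --report report.csv
```

## A note on the 21-item bank

`mcq_item_bank(27)` is the published 27-item parameter table, re-verified
against `k = (A/V − 1)/D` on load. `mcq_item_bank(21)` is a **synthetic
structural stand-in** (file `mcq21_synthetic.csv`): only its three rank-1
items are the documented instrument items; the rest were constructed to the
instrument's design (3 sets × 7 shared `k` ranks, ladder 0.0007–0.25). All
structural behavior (set combinatorics, scoring conventions, unimputable
counts) is faithful, but to score real 21-item data load the genuine table
with `load_item_bank()`.

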