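# kanoqual

Kano-model analysis of paired functional/dysfunctional quality
questionnaires, built for service-quality studies (the bundled reference
data come from a hospital patient-satisfaction survey, but nothing is
specific to healthcare).

In a Kano questionnaire every service attribute is probed twice — "how do
you feel if X is present?" (functional) and "... if X is not present?"
(dysfunctional) — on a five-point scale from *I like it* to *I dislike it
that way*. Each answer pair is mapped by a 5×5 evaluation matrix to one of
six quality categories: **A**ttractive, **O**ne-dimensional, **M**ust-be,
**I**ndifferent, **R**everse, **Q**uestionable. Per attribute the package
tallies the six categories, assigns the modal category, and computes the
Berger coefficients

    CS = (A + O) / (A + O + M + I)        in [0, 1]
    DS = -(M + O) / (A + O + M + I)       in [-1, 0]

— the average impact of providing (CS) or withholding (DS) the attribute on
satisfaction, with reverse/questionable answers excluded from the
denominator.

The package covers the full workflow: instrument definition (a 31-attribute
HEALTHQUAL-derived hospital instrument is bundled), respondent-table I/O
with validation, classification and aggregation, standardized Cronbach's
alpha, a seeded synthetic-respondent simulator, a deterministic
count-to-respondent expander, CS–|DS| quadrant charts, and a small CLI
(`fixtures | simulate | analyze | report`).

## Worked example

Analyse the bundled reference survey — 250 outpatients of two hospitals,
31 attributes in four dimensions:

```r
library(kanoqual)

responses <- hospital_survey_responses()   # 250 x (4 + 62) table
results   <- kano_analyze(responses)
results[c(1, 21, 31), c("attr_id", "classification", "cs", "ds")]
#> # A tibble: 3 × 4
#>   attr_id classification    cs    ds
#>     <int> <chr>          <dbl> <dbl>
#> 1       1 O               0.58 -0.82
#> 2      21 M               0.48 -0.98
#> 3      31 R               0    -0.03

summarize_classifications(results)
#> # A tibble: 6 × 2
#>   classification     n
#>   <chr>          <int>
#> 1 A                  0
#> 2 O                 27
#> 3 M                  3
#> 4 I                  0
#> 5 R                  1
#> 6 Q                  0
```

Attribute 1 (professionalism of health personnel) is one-dimensional:
providing it raises satisfaction by 0.58 of the maximum, withholding it
costs 0.82. Attribute 21 (ease of arranging an appointment) is must-be —
low upside (0.48), near-maximal downside (−0.98). Attribute 31 (side
effects of medicines) is reverse: its *presence* dissatisfies. Overall, 27
of 31 attributes are one-dimensional, 3 must-be, 1 reverse.

Plot the Berger quadrant chart (x = |DS|, y = CS, split at 0.5) and check
reliability machinery on simulated data:

```r
plot_quadrants(results)

sim <- simulate_responses(kano_profile(n_respondents = 250, seed = 1))
standardized_alpha(item_matrix(sim))
```

Or from a shell:

```sh
Rscript inst/cli/kanoqual.R fixtures --out survey.csv
Rscript inst/cli/kanoqual.R analyze --responses survey.csv --out out/
Rscript inst/cli/kanoqual.R report --results out/results.csv --out out/
```

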