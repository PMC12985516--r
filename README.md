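# npcnodes

Paired diagnostic accuracy, TNM N-staging and cost-effectiveness analysis
of cervical lymph-node imaging in nasopharyngeal carcinoma (NPC).

## The problem

Elective *upper-neck-only* irradiation is now recommended for N0–N1 NPC,
so the nodal work-up decides who may safely have the lower neck spared.
Two imaging modalities are in play — MRI (the staging standard) and FDG
PET/CT (metabolic, more resource-intensive) — and they frequently
disagree. This package implements, for biostatisticians and
health-economics analysts working on such questions, the full three-layer
evaluation:

1. **Node level** — paired comparison of two modalities scored on an
   ordinal 0–4 confidence scale against a biopsy reference standard:
   confusion matrices at a score cutoff (primary ≥ 2), accuracy /
   sensitivity / specificity / PPV / NPV with Wilson 95% CIs, McNemar
   tests (continuity-corrected, clamped) for paired sensitivity and
   specificity, a weighted generalized score test for paired predictive
   values, and the DeLong test for correlated AUCs.
2. **Patient level** — a table-driven 8th-edition TNM nodal staging
   engine (N0–N3 from level, laterality, size and the caudal-cricoid
   landmark), biopsy adjudication of each modality's N stage, and the
   accuracy of upper-neck-only recommendations (eligibility = N0–N1).
3. **Economic level** — a decision tree (TP/FN/TN/FP) feeding a
   four-state Markov cohort model (1-year cycles, 10-year horizon,
   3%/year discounting, half-cycle correction) with
   ICER = ΔCost/ΔQALY, a tornado analysis and a probabilistic
   sensitivity analysis with cost-effectiveness acceptability curve at a
   US$100,000/QALY willingness-to-pay threshold. The false-negative
   branch converts a 3-year regional-recurrence probability of 25.44%
   into per-cycle risk via the constant-hazard map 1 − (1 − p)^(1/3).

Because the underlying patient data are not distributable, the package
ships exact fixture generators (reproducing the study's printed summary
counts cell-for-cell) and a stochastic paired-cohort simulator with a
Gaussian-copula agreement model, so the entire pipeline is testable
offline.

## Worked example

```r
library(npcnodes)
library(dplyr)

# Exact fixture: 694 nodes, PET (TP,FN,FP,TN) = (533,22,50,89),
# MRI (514,41,57,82)
cohort <- generate_fixture_cohort_a()
compare_modalities(cohort, cutoff = 2) |>
  select(metric, estimate_a, estimate_b, p_value)
#> # A tibble: 6 × 4
#>   metric      estimate_a estimate_b      p_value
#>   <chr>            <dbl>      <dbl>        <dbl>
#> 1 accuracy         0.896      0.859 NA
#> 2 sensitivity      0.960      0.926  0.0000364
#> 3 specificity      0.640      0.590  0.0233
#> 4 ppv              0.914      0.900  0.000984
#> 5 npv              0.802      0.667  0.000000525
#> 6 auc              0.800      0.756  0.0457
```

Column `estimate_a` is PET/CT, `estimate_b` MRI: PET/CT classifies 89.6%
of nodes correctly versus 85.9%, with the largest gap in NPV (80.2% vs
66.7%) — the quantity that matters when a negative read is used to spare
the lower neck. (The p-values here reflect the fixture's
maximum-agreement joint allocation; the real joint cells are
unpublished.)

```r
# Patient-level adjudication on the staging fixture (503 patients)
adjudicate_staging(generate_staging_fixture_b())
#> Paired correctness (pet_n vs mri_n), n = 503:
#>   both correct 423 | pet_n only 40 | mri_n only 21 | both incorrect 19
#>   McNemar (cc) p = 0.02104

# Base-case economics under the shipped illustrative parameter set
evaluate_strategies(cea_parameters())
#> Cost-effectiveness (PET/CT-first vs MRI-first)
#> # A tibble: 2 × 4
#>   strategy   cost  qaly     nmb
#>   <chr>     <dbl> <dbl>   <dbl>
#> 1 pet      26400.  6.61 634577.
#> 2 mri      26070.  6.59 633121.
#>
#> # A tibble: 1 × 6
#>   comparison incremental_cost incremental_qaly   icer dominant nmb_difference
#>   <chr>                 <dbl>            <dbl>  <dbl> <chr>             <dbl>
#> 1 pet_vs_mri             330.           0.0179 18466. none              1456.
```

The PET/CT-first strategy buys 0.018 QALYs for an extra US$330 — about
US$18,500 per QALY under the illustrative cost/utility defaults, well
below the US$100,000/QALY threshold. `tornado()` and `psa()` probe the
robustness of that conclusion; `autoplot()` methods draw the tornado,
CE-plane and acceptability curve, and `tidy()`/`glance()` return every
result as a tibble.

A thin command-line wrapper with subcommands (`simulate`, `diagnostics`,
`staging`, `cea`, `tornado`, `psa`, `reproduce`) lives at
`inst/cli/npcnodes.R`.

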