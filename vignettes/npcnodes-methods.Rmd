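---
title: "Paired nodal diagnostics, N-staging and cost-effectiveness: methods"
author: "npcnodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired nodal diagnostics, N-staging and cost-effectiveness: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npcnodes)
```

## The problem

In nasopharyngeal carcinoma (NPC), guidelines now permit sparing the lower
neck from elective irradiation in N0–N1 disease. That makes the nodal
work-up load-bearing: a metastatic node read as benign can place a patient
in the upper-neck-only group and leave disease outside the treated volume,
while a benign node read as metastatic drives unnecessary whole-neck
irradiation and its toxicity. `npcnodes` implements the three analysis
layers such a question needs:

1. **node level** — paired diagnostic accuracy of two modalities (FDG
   PET/CT and MRI) against a biopsy reference standard on the *same*
   nodes;
2. **patient level** — TNM N-category assignment, biopsy adjudication of
   discordant stages, and the accuracy of upper-neck-only recommendations;
3. **decision/economic level** — tabulation of how a second modality
   changes radiotherapy prescriptions, and a decision-tree + Markov
   cost-effectiveness comparison of MRI-first versus PET/CT-first staging
   strategies.

Because no patient-level data are distributable, the package ships two
kinds of synthetic cohorts: *exact fixture generators*, which reproduce a
requested set of summary counts cell-for-cell, and a *stochastic
generator* with a controllable joint model for the two modalities' calls.
Everything downstream is tested against these.

## Node-level diagnostics

Readers score each node on a 5-point confidence scale (0 definitely
benign … 4 definitely metastatic). The primary analysis binarizes at
**cutoff ≥ 2** (a deliberately sensitive threshold; ≥ 3 is the secondary
analysis). `confusion_at_cutoff()` cross-tabulates the binarized call
against pathology; `diagnostic_metrics()` derives accuracy, sensitivity,
specificity, PPV and NPV.

**Confidence intervals.** All proportions use the Wilson score interval
(`wilson_ci()`), i.e. the score-test inversion without continuity
correction. Metrics with a zero denominator are reported as `NA`, never
as 0, so degenerate fixtures cannot silently masquerade as informative.

**Paired comparisons.** Three tests cover the three metric families:

* *Sensitivity / specificity*: McNemar's test on the discordant calls
  within the relevant pathology class. The continuity-corrected statistic
  $(\max(|b-c|-1,0))^2/(b+c)$ is the default, with the correction term
  clamped at zero so $b=c$ yields $p=1$; $b+c=0$ is degenerate and also
  yields $p=1$. The clamp matters: the uncorrected statistic at the
  patient-level discordance (40, 21) gives $p = 0.015$, the corrected one
  $p = 0.021$.
* *PPV / NPV*: predictive values of paired tests are correlated (the same
  subjects, overlapping call sets), so `compare_predictive_values()`
  implements a weighted generalized score test: the score statistic of
  the identity-link marginal model $P(\text{diseased}\mid\text{positive
  call}) = p + \beta\,[\text{test} = B]$, with the common null value
  estimated as the positives-weighted pooled PPV and a cluster-robust
  variance (each subject contributes one record per positive call). The
  NPV version applies the same construction to negative calls and benign
  outcome. The statistic is referred to $\chi^2_1$, two-sided. Tests
  verify it against a 10,000-replicate cluster bootstrap of the PPV/NPV
  difference and against structural cases (identical calls → $p=1$,
  forced separation → $p < 0.001$).
* *AUC*: `delong_paired_auc()` uses the Mann–Whitney estimator on the
  ordinal scores (ties count ½) with DeLong structural components for the
  paired variance. It is checked against brute-force pair counting
  (to $10^{-12}$) and against `pROC::roc.test()`.

All tests are two-sided and invariant to row order.

## Patient-level staging

`assign_n_stage()` is a small table-driven engine for the 8th-edition TNM
nodal rules in NPC: N0 with no positive nodes; N3 for any node with short
axis > 60 mm or extension below the caudal border of the cricoid; N2 for
bilateral cervical involvement; otherwise N1 (unilateral cervical and/or
retropharyngeal — level VII never triggers bilaterality-based upstaging).
A positive cervical node with unknown laterality is an error rather than
a guess. The level→class map (`tnm_level_classes()`) is replaceable, so a
different staging edition can be swapped in. Exhaustive enumeration over
descriptor subsets verifies monotonicity: adding a positive node never
lowers the category.

`adjudicate_staging()` scores each modality per patient as correct iff
its N category equals the biopsy-adjudicated truth (exact equality, not
the N0–1/N2–3 binning), then tallies the 2×2 paired-correctness table
whose discordant cells feed McNemar. `recommendation_accuracy()` is the
binned counterpart: a recommendation is correct when the modality's
upper-neck-only eligibility (N0–1 → upper-neck-only) matches the
eligibility implied by the true category.

**The staging fixture.** The published patient-level summaries
over-determine much of the joint (truth, PET, MRI) stage allocation:
the paired-correctness table (423/40/21/19 of 503) and its $p=0.021$,
the binned recommendation accuracies (472/503 and 447/503) and their
$p = 0.003$ (which pins the binned discordant cells to 45 vs 20), and
the N0/N1 margins (PET 21/179, MRI 19/170). `cohort_b_layout()` is an
integer allocation satisfying *all* of these simultaneously; only the
N2/N3 split is genuinely free and fixed by choice. Degenerate or custom
cell counts fall back to a minimal generic layout.

## Decision impact

`decision_impact()` reduces before/after prescriptions (dose category
low < 60 Gy, intermediate 60–66 Gy, radical ≥ 66 Gy; field upper-neck-only
vs whole-neck) to per-oncologist transition matrices and rates. Dose
rates use the pathology-class node denominator (24 metastatic, 43 benign
in the shipped fixture); field-expansion rates use the patient
denominator (62), since a field decision is per patient. The fixture
spec (`cohort_c_spec()`) encodes the printed rates exactly — escalation
up to 4/24, de-escalation 2/43 for every oncologist, expansion 4, 5 and
7 of 62 — while the identity diagonals and before-distributions, which
are not printed, are fixed by choice.

## The synthetic cohorts: what they do and do not emulate

The exact generators reproduce marginal and joint *counts*; they are the
right tool for verifying arithmetic that depends only on those counts
(every metric, interval and test statistic above). The stochastic
generator (`sample_paired_cohort()`) adds a latent joint model: per node
a bivariate standard-normal suspicion pair with correlation `agreement_rho`
(a Gaussian copula), thresholded so each modality's marginal
positive-call probability equals its sensitivity (metastatic) or
1 − specificity (benign), then banded into scores 0–4. Band proportions
default to 20/30/50% across scores 2/3/4 within positives and 50/50
across 0/1 within negatives; the cutpoints always place the ≥ 2 boundary
at the binary call, so banding never perturbs the confusion table.

Neither generator emulates: reader-to-reader variability or consensus
reading, node size/SUV distributions, within-patient correlation of
multiple nodes, spectrum effects of biopsy selection, or the missing
joint (PET × MRI) cell counts of the real cohort — those joint cells are
unpublished, so the fixture default is the maximum-agreement allocation
and the tests that depend on joint cells are property-based rather than
value-based. Passing tests therefore certify the statistical machinery
and the printed marginal summaries, not the unpublished joint structure
of the real data.

## The economic model

`evaluate_strategies()` couples a four-branch decision tree with a
four-state Markov cohort model (1-year cycles, 10-year horizon):

* **Tree.** With pre-test probability $p$ of nodal metastasis, a
  strategy with sensitivity $se$ and specificity $sp$ splits the cohort
  into TP $p\,se$ (whole-neck RT), FN $p(1-se)$ (upper-neck-only —
  undertreated), TN $(1-p)sp$ (upper-neck-only), FP $(1-p)(1-sp)$
  (whole-neck — overtreated).
* **States.** recurrence-free → regional recurrence → post-salvage →
  dead (absorbing); salvage completes within one cycle. The main text of
  the source study never enumerates its states; four is the minimum
  supporting recurrence, salvage and mortality with per-state utilities
  and costs, and the transition structure is parameter-driven so a
  richer structure can replace it.
* **Recurrence.** The FN branch converts the 3-year probability 0.2544
  to a per-cycle value by the constant-hazard map
  $1-(1-p)^{1/3}$ (`prob_to_cycle()`, = 0.09322); correctly managed
  disease uses the baseline 3-year probability (default 0.0744); benign
  branches never recur. Three undisturbed cycles recompose 25.44%
  exactly — a round-trip the tests check to $10^{-9}$.
* **Rewards.** Utilities and per-state costs accrue per cycle,
  discounted at 3%/year (both costs and QALYs; the source is silent, so
  the conventional rate is the default and it is configurable).
  Half-cycle correction is on by default (occupancy averaged over cycle
  start/end); the closed-form checks in the tests switch it off to keep
  the geometric-series identity $\sum_{t=1}^{10} 1.03^{-t} = 8.5302$
  exact. Treatment cost (upper vs whole neck) is incurred at time zero,
  the strategy's test cost once per patient.
* **Overtreatment harm.** FP patients carry a per-cycle utility
  decrement (`u_tox_whole_neck`), not excess mortality — overtreatment
  is a toxicity burden. The decrement applies only to the FP branch, so
  with the undertreated and treated recurrence probabilities equalized
  and test costs equal, the sensitivity channel carries no QALY benefit;
  the tests assert exactly that structural null.

**Parameter provenance.** Accuracy inputs and the pre-test probability
(0.691, range 0.632–0.796) and the FN recurrence probability (0.2544)
are study-reported. Costs, utilities and mortality lived in an appendix
that is not available, so the shipped defaults are an **illustrative
set** chosen once for plausibility in a Chinese tertiary-care setting
(PET/CT US$1,000 vs MRI US$400; radiotherapy US$14,000/17,000; salvage
US$40,000; utilities 0.85/0.55/0.70; background mortality 1.2%/year with
15%/5% excess during/after recurrence). Consequently the package does
*not* claim to reproduce the published base-case cost/QALY pairs; the
certified quantities are the ICER arithmetic on those published pairs
(US$68,000/QALY), the recurrence round trip, and the structural
properties. Under the shipped defaults the base-case ICER evaluates to
about US$18,500/QALY and stays below the US$100,000/QALY threshold
across the reported prevalence range, which the tests assert as a
property.

**Sensitivity analyses.** `tornado()` re-evaluates the ICER at each
parameter's bounds (accuracy parameters over their study confidence
intervals, costs ±25%, recurrence over a wide band), sorted by swing.
`psa()` draws beta distributions for probabilities/utilities and gamma
for costs, each matched by (mean, 95% range): the mean fixes one moment
and a one-dimensional root search on the concentration/shape matches the
central interval width. The gamma search is restricted to shapes ≥ 0.5,
where the width is monotone; wider requests fail loudly. The
acceptability curve is the fraction of iterations with positive net
monetary benefit difference at each WTP; it is provably non-decreasing
in WTP when every iteration gains QALYs, and the tests assert that.

## Numerical and design choices

* Ties in the AUC count ½; paired variance via structural components.
* McNemar's correction clamps at zero (see above); degenerate tables
  give $p=1$ rather than `NaN`.
* The weighted generalized score statistic returns 0 with $p=1$ when the
  cluster-robust variance is exactly zero (identical calls).
* Largest-remainder apportionment converts published level proportions
  into exact integer counts (ties broken by category order).
* Fixture score assignment within a call band is a seeded permutation of
  a fixed 20/30/50 (positives) / 50/50 (negatives) allocation —
  deterministic given the seed.
* Validation is fail-fast and names the offending row and field; unknown
  extra columns pass through untouched.
* Every output directory gets a `run_metadata.json` embedding the seed,
  a configuration hash, the package version and the file list.

## Problem sizes

The shipped analyses run at the study's own sizes (694 nodes, 503
patients, 3 × 67 decision records, 1,000 PSA iterations). Test-suite
simulations use 10,000 nodes for generator-calibration checks, 10,000
bootstrap replicates for the predictive-value oracle, and 100–300 PSA
iterations for distributional properties — sizes chosen so each check is
statistically decisive for the property it tests.

## Known limitations

* The joint (PET × MRI) confusion cells, the appendix cost/utility
  table, the PSA distribution parameters and the score distributions
  behind the published AUCs are unavailable; the corresponding printed
  p-values (sensitivity 0.001, NPV < 0.001), AUCs (0.864/0.841), DSA
  flip thresholds and the 79.6% PSA acceptability are treated as
  qualitative references, not reproduction targets.
* The Markov structure is the minimal four-state chain; competing
  non-regional failure (e.g. distant metastasis) is not modelled.
* The staging engine implements the nodal rules needed here; it is not a
  general TNM calculator.
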