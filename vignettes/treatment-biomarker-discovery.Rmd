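---
title: "Discovering treatment-success biomarkers with txmarker"
author: "txmarker authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering treatment-success biomarkers with txmarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txmarker)
```

## The problem

A *predictive* (treatment-specific) biomarker tells a clinician that a
particular therapy will work for a particular patient; a *prognostic*
(universal) biomarker merely tells them how the disease will progress under
any therapy. Retrospective molecular cohorts -- patient metadata linked to
expression and methylation profiles and to survival follow-up -- contain both
kinds of signal, and the central statistical task is separating them.
`txmarker` implements a screening pipeline for this task: it finds features
that differ between good- and poor-outcome patients, dichotomises patients by
each feature, and then uses two layers of survival analysis to keep only
features whose survival association is specific to a chosen treatment.

## The pipeline

For a chosen list of cancer projects and drug combinations:

1. **Case sets** (`buildCaseSets`). Per project one patient set per sex
   present, plus a combined set when both sexes are present; with several
   projects, pooled "basket" sets over all projects. Each set is crossed
   with every survival *cutoff* (below). A project with only female cases
   contributes a single set, so two projects (one female-only) give
   $1 + 3 + 3 = 7$ sets at the default cutoff and $21$ with three cutoffs.
2. **Treatment partition** (`partitionByTreatment`). A patient is *treated*
   when their harmonized drug set equals one of the requested combinations
   (exact-set matching; a flag switches to subset matching). Drug names are
   lower-cased, trimmed and passed through a synonym map
   (`harmonizeDrugNames`), because clinical metadata spells the same agent
   many ways.
3. **Outcome groups** (`applyCutoff`). By default alive = positive outcome,
   dead = negative. A cutoff of $c$ years reclassifies dead patients who
   survived longer than $c$ into the positive group; the default $c = 0$ is
   always computed as well. Alive patients with short follow-up are *not*
   reclassified -- only the dead-to-alive turnover direction is supported,
   which matches how turnover is usually tabulated.
4. **Differential features** (`testDE`, `callDMRs`). On the *treated*
   members of a set (untreated patients are reserved for validation), genes
   are scored by a two-sided rank-sum test between outcome groups on the
   log2(CPM+1) scale, and methylated regions by a seed-and-merge caller on
   beta values with a rank-sum test on per-patient region means.
   Benjamini-Hochberg adjustment is applied per analysis; features need
   adjusted $p < 0.05$, and at most 60 per direction (up/down) enter the
   survival stage, smallest adjusted $p$ first. These built-in scorers are
   deliberately simple stand-ins honouring a backend contract: results from
   dedicated differential tools can be supplied as a TSV
   (`readFeatureResults`) instead.
5. **Pivot stratification** (`meanOfMedians`, `stratifyByPivot`). Patients
   are split at the *mean of the outcome-group medians*,
   $\mathrm{mom} = (\mathrm{median}(v_{pos}) + \mathrm{median}(v_{neg}))/2$,
   which unlike the overall median is not dragged toward the larger outcome
   group. A percent *threshold* $t$ defines an exclusion band
   $[\mathrm{mom}(1 - t/100),\ \mathrm{mom}(1 + t/100)]$; patients inside the
   band sit too close to the pivot to classify confidently and are excluded
   from the survival analysis for that feature.
6. **Base and validation plots** (`basePlot`, `validationPlots`). The *base*
   analysis compares UP vs DOWN strata among treated patients with a Cox
   proportional-hazards model; its label names the stratum that lives
   longer. The *validation* analyses recompute the pivot on the full cohort
   and, within each stratum, compare treated vs untreated patients; a
   validation plot is labelled UP when the treated arm lives longer. Every
   configured threshold is scanned and the smallest $p$ per plot is kept.
7. **Filtering and ranking** (`consistencyFilter`, `vpProduct`,
   `rankCandidates`). An UP-labelled base plot must be confirmed by an
   UP-labelled UP-validation (and DOWN by DOWN-validation); exactly four of
   the eight label compositions survive. The ranking score is the
   *vp-product*: base $p$ times the direction-matching validation $p$, with
   candidates requiring $\mathrm{vp} < 0.0025 = 0.05^2$ -- so a very strong
   result in one plot can offset a $p$ above 0.05 in the other. For DMRs,
   every CpG position is scanned per threshold (`bestDmrPositions`) and each
   recorded best position is validated separately. Per set, candidates are
   aggregated by the geometric mean of their vp-products.

`runPipeline` drives all stages and `renderReport` writes a TSV/HTML bundle;
`inst/scripts/txmarker.R` exposes the same interface on the command line.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cutoffs` | `0` (always included) | years; dead patients surviving longer are counted as positive outcome |
| `thresholds` | `0` (always included) | percent half-width of the pivot exclusion band; values above 20 warn, since excluding more patients makes significance unlikely |
| `alpha` | 0.05 | adjusted-p gate for differential features |
| `maxPerDirection` | 60 | cap per direction entering survival analysis |
| `vpLimit` | 0.0025 | strict upper bound on the vp-product |
| `minCpgs`, `maxGap`, `minDelta` | 5, 300 bp, 0.1 | DMR stand-in: minimum seeds per region, merge distance, minimum group beta difference |

## Numerical and design choices

* **Cox fitting** uses `survival::coxph` with Efron tie handling; the
  reported $p$ is the two-sided Wald test of the group coefficient. When the
  fitter flags a degenerate likelihood (e.g. complete separation), the
  result is marked non-converged and the score-test $p$ (equal to the
  log-rank without ties) is used instead. Which $p$ the original tooling
  reports is not documented anywhere authoritative; Wald is the common
  default.
* **Tie-breaks** are deterministic everywhere: equal best $p$ across
  thresholds keeps the smallest threshold; equal adjusted $p$ in candidate
  selection prefers larger absolute effect, then the lexicographically
  smaller id; equal base-plot $p$ across DMR positions keeps the leftmost
  position; a zero Cox coefficient labels a plot DOWN.
* **Boundary conventions**: at threshold 0 a value exactly equal to the
  pivot goes DOWN; for positive thresholds the band is inclusive on both
  bounds, so exact-boundary values are excluded. A negative pivot (possible
  only with user-transformed values) uses |mom| for the band half-width.
* **Determinism and reuse**: the analysis stages use no random numbers, and
  result blocks are normalised through a text round-trip, so a rerun into
  the same output directory with an added cutoff reuses the cached blocks
  and is byte-identical to a fresh run with the union of cutoffs. Earlier
  results are never overwritten.

## The synthetic-data generator

`generateCohort` emulates the structure of a multi-project tumour cohort so
that every stage is testable without any external download: two projects by
default, one with female cases only; negative-binomial counts with
log-uniform means in [20, 2000] and per-gene size in [2, 10] (dispersion
0.1--0.5, the typical bulk RNA-seq range); Beta-distributed methylation with
concentration 30 on synthetic chromosomes; exponential survival with
baseline hazard 0.15/year (median about 4.6 years) and independent
exponential censoring at 0.1/year; half the patients treated with one of
three platinum/taxane combinations, with drug-name corruption (case, spacing
and known synonyms) at a configurable rate so harmonization is exercised.

Planted markers come in three mechanisms. A *treatment-specific* marker
multiplies the hazard of high-stratum patients by 0.25 only when treated; a
*universal* marker multiplies the hazard of high-stratum patients by 0.4
regardless of treatment -- a strong prognostic program of the
proliferation/stage-surrogate kind, which is precisely the signal the
validation stage exists to reject, and strong enough for the differential
step to discover; *null* markers carry no effect. Planted genes are shifted
by 2 log2 units (4-fold) between latent strata, planted DMRs by a beta
difference of 0.3 over 8 CpGs.

Two structural choices deserve emphasis:

* **Shared program strata.** Non-null markers of the same mechanism share a
  single latent high/low stratum (one "treatment-response program", one
  "prognostic program"). Independent strata with strong effects would stack
  into a per-patient log-hazard frailty with standard deviation above 2,
  which erases every marginal association -- no marker would be recoverable
  and the cohort would be degenerate. Co-regulated signatures are also the
  realistic structure for multiple strong markers.
* **Hazard recentring.** The product of planted hazard factors is recentred
  by its cohort geometric mean, so the overall death rate stays at the
  configured baseline however many markers are planted. Cox comparisons are
  scale-invariant, so planted ratios are unaffected.

What a green test on synthetic data does establish: the pipeline's
combinatorics, arithmetic, calibration under the null, and its ability to
separate planted predictive from prognostic programs at realistic effect
sizes. What it does not establish: robustness to batch effects, tumour
purity, probe-level artifacts, correlated null genes, non-proportional
hazards or informative censoring -- none of which the generator attempts to
model.

## Known limitations

* The built-in differential scorers are intentionally much simpler than
  negative-binomial GLMs or segmentation-based region callers; for real
  analyses, feed backend results in via the TSV contract.
* The vp-product deliberately applies a fixed limit, not a
  false-discovery-rate control across candidates, and a very small base $p$
  can carry an uninformative validation $p$ over the line; the
  label-consistency filter is the only guard. This mirrors the screening
  character of the method.
* Only the dead-to-alive direction of cutoff reclassification is supported,
  and validation against "all other therapies" pools regimens that may be
  molecularly similar to the one under study.
* Per-marker detection at cohort sizes around 400 sits near the
  Benjamini-Hochberg decision boundary, so single-cohort results are noisy;
  the discrimination test in this package pools three replicate cohorts.
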