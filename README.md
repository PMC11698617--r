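# txmarker

Screening tumour cohorts for **treatment-success biomarkers**: molecular
features (gene expression or DNA methylation) whose association with
survival is *specific to a chosen therapy*, as opposed to universal
prognostic markers that predict outcome under any therapy.

`txmarker` is aimed at bioinformaticians working with retrospective cohorts
of the TCGA kind: a patient metadata table (sex, vital status,
survival/follow-up time, drug names), a gene-level count matrix and/or a CpG
beta-value matrix.

## Method

For each cancer project, one patient set per sex plus a combined set is
built, together with pooled basket sets when several projects are analysed;
each set is crossed with survival **cutoffs** *c* (dead patients surviving
longer than *c* years count as positive outcome; *c* = 0, the raw vital
status, is always included). Per set:

1. Differential features between outcome groups are detected on the treated
   members (rank-sum tests with Benjamini–Hochberg adjustment, or results
   imported from external backends); at most 60 up- and 60 down-regulated
   features with adjusted *p* < 0.05 proceed.
2. Patients are dichotomised at the **mean of medians**
   `mom = (median(v_pos) + median(v_neg)) / 2`, optionally excluding a band
   of ±*t* % around the pivot (the **threshold**).
3. The **base plot** compares UP vs DOWN strata among treated patients with
   a Cox proportional-hazards model; **validation plots** compare treated vs
   untreated patients within each stratum over the full cohort. Labels must
   be consistent (an UP base plot needs an UP UP-validation, a DOWN base
   plot a DOWN DOWN-validation).
4. Candidates are ranked by the **vp-product** — base *p* × matching
   validation *p* — and accepted when it is strictly below
   0.0025 = 0.05²; sets are summarised by the geometric mean of their
   candidates' vp-products.

A seeded synthetic-cohort generator with planted treatment-specific,
universal and null markers makes every stage testable offline; see the
methods vignette (`vignettes/treatment-biomarker-discovery.Rmd`) for the
model, parameter defaults and limitations.

## Worked example

```r
library(txmarker)

cfg <- simulationConfig(seed = 42)        # two projects, one female-only
cohort <- generateCohort(cfg)
res <- runPipeline(
  cohortMetadata(cohort),
  counts     = cohortCounts(cohort),
  betas      = cohortBetas(cohort),
  betaCoords = cohortCoords(cohort),
  drugCombos = cfg$drugCombos,            # cisplatin / carbo+paclitaxel / carbo
  cutoffs    = 5, thresholds = 5)
res
```

```
Biomarker pipeline result
  case sets: 14 (14 with treated patients)
  evaluated features: 20; candidates: 18
                    set_id        feature_id base_label   vp_product
 SYN-A-SYN-B_both_cutoff-5 chrS1:13901-15174         UP 3.171681e-16
 SYN-A-SYN-B_both_cutoff-0         gene_0175         UP 1.354203e-15
 SYN-A-SYN-B_both_cutoff-5         gene_0175         UP 1.985434e-15
 SYN-A-SYN-B_both_cutoff-0         gene_0082         UP 2.112299e-15
       SYN-B_both_cutoff-5 chrS1:13901-15174         UP 4.221442e-15
```

14 case sets = 7 project/sex/basket selectors × 2 cutoffs {0, 5}. Each
ranked row is one feature in one set: `base_label UP` means the
high-expression (or high-methylation) stratum lives longer among treated
patients, and the vp-product is the base-plot Cox *p* times the UP-validation
Cox *p* (treated vs untreated inside the UP stratum). The planted
treatment-specific gene and DMR markers of the simulation dominate the
ranking. `aggregateCandidates` output (`res$summary`) lists, per set, the
candidate count and the geometric mean of the vp-products, most-populated
sets first; `renderReport(res, "out/")` writes the TSV tables plus a
self-contained `index.html`.

The same run from a shell:

```sh
Rscript inst/scripts/txmarker.R --synthetic --seed 42 \
  -d cisplatin -d carboplatin,paclitaxel -d carboplatin \
  -C 5 -t 5 -o out/
```

## Acceptance script

`scripts/acceptance.R` regenerates a synthetic metadata table whose project
structure has one female-only project and one project with both sexes, runs
the package's case-set construction on it, and writes the resulting set
counts for the default cutoff and for cutoffs {0, 5, 8} as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
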