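# gliomaCNS5

Adult diffuse gliomas used to be diagnosed from histology alone
(astrocytoma, oligoastrocytoma, oligodendroglioma grades II–III;
glioblastoma grade IV). The 2021 WHO classification of CNS tumors
("WHO CNS5") made molecular markers part of the diagnosis itself: IDH1/2
hotspot mutations, 1p/19q codeletion, ATRX, TERT promoter, EGFR
amplification, chromosome 7 gain / 10 loss, CDKN2A/B homozygous deletion
and histone H3 hotspots now determine both the tumor type and its grade.
Large legacy archives (TCGA-LGG, TCGA-GBM) still carry the old labels, so
any biomarker or survival analysis built on them inherits outdated
diagnoses.

`gliomaCNS5` is an R package for researchers working with such cohorts. It
provides:

* **A total, traceable rule engine** mapping each case's molecular
  annotation to a WHO CNS5 diagnosis — oligodendroglioma (IDH-mutant,
  1p/19q-codeleted, grade 2–3), astrocytoma (IDH-mutant, grade 2–4),
  glioblastoma (IDH-wildtype, grade 4), the two pediatric-type H3-altered
  exits, or `NA` with an explicit reason when the molecular data cannot
  support a diagnosis. Every decision records its rule path (`R0`–`R3e`).
* **MAF hotspot extraction**: IDH1 R132 / IDH2 R172 and H3 K27M / G34R
  status from Mutation Annotation Format tables, accepting both
  mature-protein and initiator-Met residue numbering.
* **Pathway activation level (PAL) scoring**
  `PAL_p = 100 * Σ_n ARR_n log10(CNR_n) / Σ_n |ARR_n|`, where `CNR_n` is a
  gene's case-to-normal expression ratio against the cohort-average
  reference and `ARR_n ∈ {−1, −0.5, 0, 0.5, 1}` is its activator/repressor
  role in pathway `p`.
* **Unsupervised structure**: consensus k-means and Ward (`ward.D2`)
  dendrograms for expression and gene-level methylation (probe-to-gene
  aggregation included), with adjusted-Rand / NMI agreement between
  clusters and diagnosis labels.
* **Glioblastoma transcriptional subtypes** (Proneural / Classical /
  Mesenchymal) from 50-gene signatures by Ward clustering plus algorithmic
  cluster labeling.
* **Survival analytics**: Kaplan–Meier medians with log-log CIs, Cox hazard
  ratios against a reference group, the all-pairs log-rank grid with star
  coding and the significant-fraction summary, and a risk-score
  median split (default gene set FN1, ITGA5, OSMR, NGFR).
* **ROC-AUC biomarker evaluation** (rank-statistic AUC, exact complement
  symmetry, Wilcoxon significance) over all diagnosis-group pairs.
* **A synthetic TCGA-like cohort generator** that draws a latent CNS5 class
  per case *first* and then emits legacy histology, molecular features, MAF
  records, expression, methylation and survival consistent with it — so the
  whole pipeline is testable offline against a known ground truth.

## Worked example

Classify the small cohort shipped with the package, rescuing unknown
IDH/H3 statuses from a MAF first:

```r
library(gliomaCNS5)
coh <- read_cohort(system.file("extdata", "example_cohort.tsv", package = "gliomaCNS5"))
maf <- read_maf(system.file("extdata", "example_mutations.maf", package = "gliomaCNS5"))
coh <- apply_maf_statuses(coh, maf)
fit <- classify_cohort(coh)
print(fit)
```

```
WHO CNS5 reclassification
  cases: 13 analyzed, 1 excluded (unknown histology)
  changed diagnosis (definite categories): 5
  categories:
    OLIGO_IDH_MUT_CODEL          3
    ASTRO_IDH_MUT                4
    GBM_IDH_WT                   4
    PEDIATRIC_H3_K27             1
    NA                           1
    EXCLUDED_UNKNOWN_HISTOLOGY   1
```

Of the 14 cases, one has unknown histology and is excluded; one
IDH-wildtype astrocytoma with unknown H3 status stays `NA` (reason
`h3_unknown`); three legacy grade-IV glioblastomas keep a grade-4
diagnosis as `GBM_IDH_WT`, while an IDH-mutant, non-codeleted legacy
astrocytoma with CDKN2A/B deletion becomes grade-4 astrocytoma and the
K27M-mutant case exits to the pediatric-type diffuse midline glioma
entity. `summary(fit)` prints the full legacy-by-CNS5 cross table;
`rule_coverage_report(fit)` shows which rules fired, and
`fit$diagnoses$rule_trace` the per-case decision path.

Downstream, `diagnosis_groups(fit)` yields grade-stratified survival
groups for `survival_summary()`, `compute_cnr()` + `batch_pal()` score
pathway activation, and `biomarker_panel()` evaluates gene/PAL markers by
pairwise AUC.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline end to end on a freshly simulated 1122-case
cohort: reclassification with exclusion of unknown-histology cases, MAF
rescue of unknown statuses, legacy-vs-CNS5 survival comparison (pairwise
log-rank grids and significant fractions), consensus clustering of
expression and aggregated methylation with cluster-label agreement,
glioblastoma subtype assignment, PAL scoring and the biomarker AUC panel,
then writes the JSON report to `--out`.
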