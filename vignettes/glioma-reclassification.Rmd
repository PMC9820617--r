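---
title: "Molecular reclassification of adult diffuse gliomas: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular reclassification of adult diffuse gliomas: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomaCNS5)
```

# The problem

Histology-only glioma diagnoses (WHO 2000/2007: astrocytoma,
oligoastrocytoma, oligodendroglioma grades II–III; glioblastoma grade IV)
disagree substantially with the integrated molecular diagnoses of the 2021
WHO CNS5 classification. Archives annotated under the old scheme therefore
mislabel many cases — most dramatically the "molecular glioblastomas"
(histologically lower-grade tumors that carry glioblastoma-defining
molecular features) and the mixed oligoastrocytoma entity, which CNS5
abolished entirely. This package reimplements the reclassification as a
deterministic rule engine and wires it to the analyses that depend on the
labels: clustering, survival comparison and biomarker evaluation.

# The rule engine

`classify_case()` is a *total* function on the molecular feature space:
every combination of feature levels maps to exactly one diagnosis, and the
decision path is recorded as a trace of stable rule identifiers.

| rule | condition | outcome |
|------|-----------|---------|
| R0 | histology unknown | excluded from reclassification |
| R1 | IDH status unknown | `NA` (`idh_unknown`) |
| R2a | IDH-mutant, 1p/19q codeleted | oligodendroglioma, grade 2–3 |
| R2b | IDH-mutant, not codeleted — or codeletion unknown with ATRX mutation | astrocytoma, grade 2–4 |
| R2c | IDH-mutant, codeletion unknown, no ATRX shortcut | `NA` (`codel_unresolvable`) |
| R3a/R3b | IDH-wildtype, H3 K27M / G34R | pediatric-type H3-altered entities |
| R3c | IDH-wildtype, H3 unknown | `NA` (`h3_unknown`) |
| R3d | IDH-wildtype, H3-wildtype, any GBM feature (grade IV histology, TERTp mutation, EGFR amplification, +7/−10) | glioblastoma, grade 4 |
| R3e | IDH-wildtype, H3-wildtype, no GBM feature | `NA` (`nec_no_gbm_markers`) |

Grading: oligodendrogliomas take grade 2/3 from the legacy histological
grade; astrocytomas additionally become grade 4 on CDKN2A/B homozygous
deletion or legacy grade IV histology; glioblastoma is always grade 4; the
pediatric-type entities carry no adult grade.

Design choices worth stating explicitly:

* **ATRX shortcut scope.** ATRX mutation substitutes for 1p/19q testing
  only when codeletion is *unknown*. A measured codeletion always wins,
  because codeletion is the defining oligodendroglioma marker and the
  shortcut exists precisely to spare the codeletion assay.
* **Rule order R3c before R3d.** An IDH-wildtype tumor with unknown H3
  status goes to `NA` even if it carries TERTp/EGFR/+7−10 features. The
  CNS5 glioblastoma definition requires H3-wildtype status, and the
  reference behavior this engine reproduces reports such cases as `NA`
  rather than rescuing them.
* **`NA` reasons.** The reason taxonomy covers the two dominant groups
  (unknown IDH; unknown H3 in IDH-wildtype tumors), the unresolvable
  codeletion case, and a fourth value, `nec_no_gbm_markers`, for
  lower-grade IDH-wildtype tumors without molecular glioblastoma features
  (the "not elsewhere classified" bucket). The fourth value is an
  extension of the minimal three-reason scheme so that *every* `NA` case
  carries a machine-readable reason; a distinct NEC output category was
  considered and rejected to keep the category set identical to the
  reference scheme.
* **Codeleted legacy grade IV.** CNS5 oligodendroglioma has no grade 4.
  An IDH-mutant, codeleted case with legacy grade IV histology is emitted
  as grade 3 with the `oligo_grade4_capped` flag rather than inventing a
  grade outside the entity's range.
* **Unknown legacy grade.** Where a lower-grade type's II/III grade is
  unrecorded, grade 2 is assigned (the conservative choice); this affects
  no simulated case and only malformed real input.
* **Changed-diagnosis flag.** "Changed" compares legacy type+grade to the
  CNS5 category+grade under the obvious label correspondence;
  oligoastrocytomas always count as changed because the entity no longer
  exists. `NA` and excluded cases have an undefined changed status.

# MAF hotspot extraction

`extract_idh_status()` and `extract_h3_status()` scan missense records
only. IDH-mutant means IDH1 codon 132 or IDH2 codon 172; IDH2 R172 is
included per the CNS5 definition even though hotspot screens are sometimes
described by the IDH1 codon alone. H3 hotspots accept both numbering
conventions (K27M/G34R mature-protein, K28M/G35R initiator-Met) because
annotation pipelines emit the latter while the nomenclature uses the
former; K27M outranks G34R if both ever appear, with a warning. A sample
*absent* from the MAF universe has unknown status (no genomic data); a
sample *present* with no qualifying row is confirmed wildtype.
`apply_maf_statuses()` applies exactly this distinction cohort-wide.

# Pathway activation level

For pathway $p$ with activator/repressor roles $ARR_n \in \{-1, -0.5, 0,
0.5, 1\}$ and case-to-normal ratios $CNR_n$:

$$PAL_p = \frac{\sum_n ARR_n \cdot \log_{10}(CNR_n) \cdot 100}{\sum_n |ARR_n|}.$$

The denominator is the sum of *absolute* roles. A literal signed sum
(available as `denominator = "signed"`) is zero for any balanced pathway
and is provided only for comparison. The reference profile defaults to the
"artificial normal": gene-by-gene averaging over all samples of the cohort
under analysis, so PAL is exactly 0 at the reference by construction. The
cohort boundary for that average is the full analyzed cohort; pass an
explicit reference vector to use any other control. CNR uses a pseudocount
(default 1, appropriate for normalized count scales) added to numerator
and reference alike, keeping ratios finite at zero counts. Pathway members
absent from the matrix are dropped from numerator and denominator and
reported as a coverage fraction. The three-depth pathway topologies used
as biomarkers are consumed as input files; the package ships small
*synthetic* pathway fixtures and generates nested synthetic variants in
its simulator — it does not reconstruct interaction-network topologies.

# Glioblastoma subtypes

`preprocess_signature_matrix()` restricts to signature genes and
standardizes each gene. The default transform is $\log_2(x+1)$ *then*
per-gene Z-score. The alternative order (Z-score, then a shifted log)
exists behind `order = "z_log"` because some published pipelines describe
standardizing before logging; taken literally that operation is undefined
on negative Z-scores, so the package shifts values to $\ge 1$ first and
treats the mode as a comparison option, not the default.
`assign_subtypes()` clusters samples by Ward (`ward.D2`) linkage on
Euclidean distances, cuts at $k = 3$, and labels each cluster with the
subtype whose signature genes have the highest mean standardized
expression in it — an algorithmic stand-in for the visual heatmap
assignment such analyses usually rely on. Duplicate claims are resolved
greedily by score (stronger cluster keeps the subtype) with a warning.
Samples are processed in lexicographic id order, making the result
independent of input column order.

# Clustering and agreement

`consensus_kmeans()` repeats k-means on random 80% subsamples (1000
iterations by default; tests and the acceptance script scale this down to
100–200 for time) and records, for each sample pair, the co-clustering
frequency among iterations where both were drawn. The final assignment
cuts a Ward tree of $1 - \text{consensus}$ at $k$. Rows are pre-filtered
to the 2000 most variable by default, since cohort-scale matrices carry
mostly uninformative genes; both parameters are exposed. Reference cluster
counts for cohort-scale runs are 5 (expression) and 7 (methylation),
matching the structure such cohorts typically show; they are configuration,
not constants. Agreement between an assignment and diagnosis labels is
quantified by the adjusted Rand index (primary) and normalized mutual
information (secondary, arithmetic-mean normalization); the claim that
clusters agree better with updated diagnoses than with legacy ones is
tested as `ARI(clusters, CNS5) > ARI(clusters, legacy)` on synthetic
cohorts. Aliquots of one case are free to land in different clusters;
`split_aliquot_report()` lists the cases where they do.

# Survival

Kaplan–Meier medians are the first time the product-limit estimate drops
to $\le 0.5$, reported `NA` when the curve never reaches it (heavily
censored groups legitimately have undefined medians); CIs use the log-log
(exponential Greenwood) transform — a choice this package fixes because no
single convention is universal. Cox hazard ratios are univariate with
group indicators against a configurable reference (glioblastoma in the
standard workflow, chosen because its median survival is insensitive to
the reclassification). Pairwise log-rank p-values are *unadjusted* by
default, matching how pairwise survival grids are conventionally starred;
Benjamini–Hochberg adjustment is available side by side. The
significant-fraction summary reports `round(100 * n_sig / n_pairs)` as a
whole percent. The 4-gene risk model scores patients as a
coefficient-weighted expression sum, splits at the median score and
reports the high-vs-low hazard ratio; coefficients are inputs (the
originating publication's values are not redistributed here), and tests
use synthetic coefficients.

# Biomarker AUC

AUC is computed from the rank statistic ($U/(n_1 n_2)$, ties counted
half), which the tests verify against exhaustive pair counting;
orientation is explicit (first-listed group positive), so
$AUC(A,B) = 1 - AUC(B,A)$ holds exactly. Significance comes from the
two-sided Wilcoxon rank-sum test (normal approximation with tie
correction); star thresholds are 0.05/0.01/0.001, and an AUC above the
configurable 0.7 bar is flagged as practically useful.

# The synthetic cohort: what it emulates and what it does not

Generation is **truth-first**: each case's latent CNS5 class is drawn
conditionally on its legacy histology, then the molecular fields are
filled in consistently with the rule engine, then missingness masks
fields, then survival/expression/methylation/MAF are emitted from the
latent class. Truth-first generation is what gives every pipeline stage a
gold standard; the real cohort has none beyond its own rules.

Defaults state the emulated world once:

* Legacy composition 174/114/169/590 + 75 unknown-histology cases (the
  combined TCGA-LGG/TCGA-GBM printed composition); grade II fractions
  within lower-grade types from the per-group survival table counts.
* Class-conditional probabilities chosen so the reclassified composition
  lands near the reported one (about 40% of legacy glioblastomas' NA/
  astro-4 erosion, oligoastrocytomas split across oligo/astro/GBM,
  a percent-scale pediatric-type contamination among adult histologies).
* Missingness: IDH 10% (the reported unknown-IDH share of analyzed
  cases), H3 15% (the unknown-H3 share among IDH-wildtype tumors), 5% for
  the remaining fields. With these defaults the NA bucket's composition
  reproduces the reported two-group structure (unknown IDH dominating,
  unknown H3 second).
* Survival: exponential event times with per-class medians 140 (grade-2
  oligodendroglioma — unreached in the source cohort, so a finite
  stand-in above its reported CI floor), 90.5, 105.1, 67.4, 38.7 and 14.0
  months, 40% censoring (drawn uniformly on the event time). Exponential
  hazards reproduce medians and HR orderings, not the late-plateau shapes
  of real KM curves.
* Expression: log-normal baseline (log2 means uniform on [3, 8], unit
  log2 SD), one 40-gene block per major class shifted +2 SD, marker
  analogues (CRNDE up in IDH-mutant classes, FREM2/SPRY1 up in
  glioblastoma), activator/repressor pathway blocks moving with
  glioblastoma, three 50-gene subtype blocks shifted within glioblastoma
  by a latent uniform subtype, and 18 cases with a second, noisier
  aliquot. `subtype_effect_size = 0` yields a pure three-block cohort —
  the configuration used when testing three-class recovery, since with
  subtype structure on, glioblastoma legitimately splits into sub-clusters
  exactly as real cohorts do.
* Methylation: logit-normal gene states with one shifted block per class
  (a G-CIMP-like IDH contrast), three probes per gene, logistic transform
  to (0, 1).

A green test on this world establishes that the *pipeline* recovers
planted structure at stated effect sizes; it does not establish anything
about real TCGA distributions, batch effects, array geometry or the
biology of specific genes — the generator makes no attempt at those.

# Known limitations

* The engine covers adult-type diffuse gliomas plus the two H3-altered
  pediatric-type exits only; ependymomas and other CNS5 families are out
  of scope.
* Survival analysis is univariate by design; no age/sex adjustment.
* MVP/necrosis are not separate inputs — legacy grade IV histology proxies
  the histological glioblastoma phenotype.
* The module interfaces are R functions (plus `scripts/acceptance.R`);
  the package does not install a shell executable, as its natural use is
  scripted analysis.
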