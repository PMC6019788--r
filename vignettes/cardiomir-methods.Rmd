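---
title: "Methods: integrative miRNA and mRNA differential expression with cardiomir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative miRNA and mRNA differential expression with cardiomir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomir)
```

# The analysis problem

cardiomir implements an integrative transcriptomics workflow for very small
case-control studies, of the kind used to profile cardiac stromal cells from
arrhythmogenic cardiomyopathy (ACM) patients against healthy controls: a
TaqMan low-density-array (TLDA) miRNA screen quantified as Cq values, an
RNA-seq gene expression experiment, and downstream integration — gene-set
enrichment, a permutation test asking whether the targets of the deregulated
miRNAs are coordinately repressed, miRNA host-gene detection, and network
module discovery over functional-similarity and protein-interaction graphs.

Every stage is runnable on synthetic data with planted ground truth, so the
whole pipeline is testable without patient material or database downloads.

# miRNA screen (Cq) stage

## Normalization

Cq is the PCR cycle at which fluorescence crosses threshold; one cycle is one
doubling, so Cq lives on a log2 scale and **lower Cq means higher abundance**.

* `normalize_cq_global_mean()` implements global geometric-mean scaling: on
  the linear scale the normalizer is the geometric mean over all detected
  assays of a sample, which on the Cq scale is the arithmetic mean. Each
  sample's valid Cq values are centred by that mean, giving ΔCq values
  comparable across samples. The operation is idempotent (centred columns
  have mean zero), which the tests assert. A consequence worth knowing: with
  few detected assays, strong planted effects leak into the per-sample mean
  and bias ΔCq slightly; this is a property of global-mean scaling itself,
  not of the implementation.
* `normalize_cq_reference()` is the validation-experiment normalizer:
  ΔCq against a housekeeping assay (TBP for genes, a stably expressed miRNA
  for miRNA panels). The reference must be valid in every sample; the error
  names the offending sample.

Replicate handling: `average_replicates()` collapses technical replicates to
per-individual means. A cell stays valid when **at least one** replicate is
valid, because the detection filter below operates on individuals, not
wells. The order — normalize, then average — is a choice (both orders are
expressible with the exported functions); normalizing first ensures each
well is scaled by its own card's content.

## Detection filter

`filter_detection()` keeps an assay when it has at least `min_valid` valid
per-individual measurements in one group (`any-group`, the default) or in
both groups (`both-groups`). The published 2-of-3 rule generalizes to
`min_valid = ceiling(2/3 * group size)`. We default to `any-group` because a
miRNA expressed in only one group is biologically meaningful (and testable
one-sidedly); the stricter reading is one argument away.

## Moderated t-test

With three individuals per group, per-feature variance estimates are
unusable on their own. `moderated_t_test()` implements the empirical-Bayes
moderated t: per-feature pooled variances \(s_g^2\) (degrees of freedom
\(d_g = n_1 + n_2 - 2\)) are assumed drawn from a scaled inverse-chi-square
prior \((d_0, s_0^2)\), estimated by the method of moments on
\(\log s_g^2\) (the digamma/trigamma representation; the trigamma inverse is
solved by Newton iteration). The posterior variance
\(\tilde s^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)\) replaces \(s_g^2\), and
the statistic gains \(d_0\) degrees of freedom. Two limits anchor the
implementation and its tests: \(d_0 = 0\) reproduces the ordinary pooled
t-test exactly, and \(d_0 = \infty\) gives every feature the common
variance. On shared fixtures the estimates agree with the limma
implementation to within a few percent on \(d_0\) and 0.05 on the t
statistics; exact numerical identity is not a goal.

The effect size follows the qPCR sign convention,
\(M = \overline{\Delta Cq}_{control} - \overline{\Delta Cq}_{case}\):
positive M means higher expression in cases, and \(2^M\) is the linear fold
change (`delta_cq_to_m()`). Significance on the screen is `p_adj < 0.05`
(Benjamini-Hochberg, `adjust_bh()`); no M cut-off is applied there.
`plain_t_test()` — the moderated test with \(d_0\) pinned at zero — is the
validation-experiment test.

# RNA-seq stage

## Read filtering and counting

`filter_and_trim_reads()` applies, in order: drop pairs with ≥ 7 undetermined
nucleotides in either mate; truncate each read at the first base of the
first 5-nt window containing ≥ 3 bases below Q20 (the strictest reading of
"as soon as"); drop pairs in which either mate ends up shorter than 41 nt.
Mate pairing is preserved throughout, and the report records per-rule
counts.

`count_exon_contained()` counts a fragment for a gene only when **every
aligned base of both mates** lies within the union of that gene's exons —
junction reads whose N-gap matches an intron count, exon-boundary-crossing
reads do not. Pairs with MAPQ < 30, multi-mappers (NH tag > 1 or secondary
flag), and fragments compatible with more than one gene are excluded, each
tallied separately so that counted + ambiguous + low-MAPQ + multi-mapped +
not-contained equals the total processed — an invariant the tests assert.
Containment is evaluated with GenomicRanges interval machinery; the test
suite cross-checks the counts against
`GenomicAlignments::summarizeOverlaps(mode = "IntersectionStrict")` as an
independent oracle.

## Size factors, filtering, confounder

`size_factors_median_ratio()` is the median-of-ratios estimator (per sample,
the median ratio to per-gene geometric means over all-nonzero genes),
rescaled to geometric mean 1. `low_count_filter()` removes genes whose mean
normalized count stays below 10 in **both** groups; the group summary (mean)
is a declared choice, as the rule's published wording does not fix it.

`pca_confounder()` runs PCA on gene-centred log2(normalized count + 1). In
small designs PC1 often captures a technical factor rather than the
condition; the sign of the PC1 score yields a two-level covariate for the
DE model (the continuous score is available via
`covariate_type = "continuous"`). When the PC1 sign coincides exactly with
the condition there is no separate factor to absorb — the design would be
rank deficient — so the pipeline drops the covariate with a message;
`nb_wald_test()` itself refuses aliased designs with an error.

## Negative-binomial Wald test

`nb_wald_test()` fits, per gene, an NB GLM with log link,
\(\mu_{gj} = s_j q_g e^{x_j^T\beta_g}\), \(\mathrm{Var} = \mu + \alpha\mu^2\),
by IRLS with fixed gene-wise dispersion; the Wald statistic on the condition
coefficient gives the p-value, BH-adjusted. This is a deliberately
simplified relative of the established count-based DE methods: no Cox-Reid
adjustment, no MAP dispersion curve, no fold-change shrinkage. Acceptance is
by parameter recovery and error-rate control, plus a test-suite cross-check
against DESeq2 fold changes (correlation > 0.999 on a shared fixture).

Dispersion: the per-gene method-of-moments estimate on normalized counts,
pooled within condition groups, is shrunk on the log scale halfway
(`dispersion_shrink = 0.5`) toward a trend. Two numerical choices matter
here. The trend is the **arithmetic** mean of the raw moment estimates —
a log-scale mean would be dominated by the floor applied to the frequent
non-positive raw estimates and would drag every shrunk dispersion far below
truth, inflating the null. Raw estimates are floored at trend/50 before the
log-scale shrinkage. With this estimator the normal Wald reference is
calibrated on simulated nulls at ten samples per group (rejection at
nominal 0.05 ≈ 0.05); at three per group it remains mildly anticonservative
(≈ 0.08), a known small-sample property of count-based Wald tests that
applies equally to the study design this emulates.

The reported DE call requires `p_adj < 0.05` **and** `|M| > 1` (more than
two-fold), mirroring how such screens report genes.

# Enrichment

`hypergeom_enrich()` is flat over-representation: the one-sided upper-tail
hypergeometric probability \(P[X \ge k]\) with the expressed genes as the
universe, categories intersected with the universe first, categories with
fewer than 2 background members skipped, Bonferroni adjustment for category
screens and BH for module annotation. GO-graph-aware conditional testing is
deliberately out of scope: category structure enters only through the GMT
file. `mirna_target_background()` builds the special universe used for
miRNA-target enrichment: expressed, validated targets of expressed miRNAs.

# Integration

`select_targets()` filters a validated target map by evidence level
("strong" = high-confidence interactions) and expression; miRNAs without
targets are reported with empty sets, never dropped silently — a miRNA with
no annotated targets is itself a finding.

`target_repression_test()` is the permutation test for coordinate
repression: the observed mean M over a miRNA's expressed targets is compared
with `n_perm = 1000` same-sized random subsets of the target universe;
\(p_{perm}\) is the fraction of subsets with mean M at or below the observed
one (one-tailed, repression = negative M). The observed set is part of the
sampling universe and no (k+1)/(n+1) correction is applied by default — the
p-value is the plain fraction, as the test is usually described; the
correction sits behind `plus_one = TRUE`. On universes small enough to
enumerate, the sampled p converges to the exhaustive value (tested within
binomial error); under a simulated null its rejection rate is nominal; and
lowering every target M can only decrease it (monotonicity, also tested).
`target_repression_ttest()` is the companion one-sample, one-sided t against
zero, and `repression_table()` adds the union-of-all-targets row.

`find_host_genes()` implements primary-transcript logic: a gene hosts a
miRNA when its transcription-unit **span** (not its exon union) contains the
locus on the same strand, since most miRNAs are intronic and co-transcribed.
Containment in the exon union is tagged "exonic", otherwise "intronic";
multiple hosts are allowed; antisense hosts are reported only behind
`include_antisense = TRUE`.

# Network modules

`build_functional_network()` connects genes by the Jaccard similarity of
their biological-process annotation sets, keeping edges with weight ≥ τ
(default 0.5). Jaccard-on-annotations is a declared choice: published
functional-similarity measures vary, and information-content measures
needing the ontology DAG are out of scope. `build_interaction_network()`
merges tagged edge lists, keeps "string"-tagged edges only at confidence
≥ 0.9, restricts nodes to the expressed set, and collapses duplicate edges
keeping the maximum weight.

Clustering follows the cohesiveness formulation:
\(f(C) = w_{in} / (w_{in} + w_{bound} + p\,|C|)\) with penalty \(p = 2\).
`cluster_graph()` seeds from the highest-weighted-degree unclustered node
and repeatedly applies the single vertex addition or removal that most
increases \(f\), requiring strict improvement; ties are broken by
lexicographic node name, which makes two runs bit-identical (tested).
Clusters below the minimum size (4 for interaction networks, 5 for
functional networks) or below weighted density 0.5 are discarded; clusters
whose overlap score \(\omega(A,B) = |A \cap B|^2/(|A||B|)\) reaches 0.8 are
merged transitively (`merge_modules()`) and re-scored. These parameter
values are the published defaults of the cohesiveness-clustering method;
all are arguments. Reproducing any particular published module membership is
not a goal — the merge criterion used in the original analyses is not fully
specified, so recovery is validated on planted dense subgraphs instead.

# The synthetic study

`sim_config()` fixes the study conditions the generators emulate:

| parameter | default | rationale |
|---|---|---|
| `n_per_group` | 3 | individuals per group in the emulated screens |
| `n_assays` | 768 | two 384-well TLDA cards |
| `n_de_mirnas` | 3 | deregulated miRNAs in the emulated screen |
| `ddcq_effect_range` | 3.0–7.0 Cq | spans the screen's reported M-values (6.8, 3.0, 4.0) |
| `cq_noise_sd` | 0.5 Cq | typical TLDA technical-replicate noise |
| `dropout_midpoint` | 26 Cq | calibrated so ~200/768 assays survive the detection rule, matching the emulated screen's 768 → 208 |
| `dropout_scale` | 1.5 Cq | width of the logistic detection-failure curve |
| `n_genes` | 2000 | desk-scale transcriptome |
| `n_de_genes` | 100 | planted DE genes |
| `log2fc_range` | 1–4 | at least two-fold, as reported DE genes are |
| `nb_dispersion` | 0.05 | typical bulk RNA-seq biological dispersion |
| `confounder_fraction` | 0.3 | genes carrying the batch shift |
| `confounder_log2fc` | 1.5 | batch shift large enough to own PC1 |
| `library_size_range` | 0.5–1.5 M | three-fold library-size spread |

Dropout is logistic in the true Cq because weakly expressed (high-Cq)
assays are the ones real instruments flag as undetermined. The confounder
is a two-level batch factor assigned as orthogonally to condition as odd
group sizes allow, matching the practice of adding a factor to the DE
model. The planted DE miRNAs are placed in the well-detected Cq range, and
the knowledge generator reuses exactly those assay ids as its repressed
miRNAs so that the integrated stages line up end to end. Toy genome
coordinates are 1-based closed intervals throughout (GFF3 convention).

What the generators do **not** emulate: realistic sequence content (reads
are synthetic and never realigned), hairpin structure, genome-scale
annotation, correlated gene-gene expression beyond the planted batch, or
miRNA-mediated causality — target "repression" is planted directly in the
fold changes. Passing tests therefore demonstrate correctness of the
computations and calibration of the statistics under the assumed models,
not robustness to everything real data can do.

# Problem sizes and determinism

The test suite and the acceptance script run at the study's own scale:
2000-feature null screens for type-I error of the moderated t, 2000-gene
nulls at ten samples per group for the NB Wald calibration, 500 replicates
for the permutation-test null, 20 seeds for planted-subgraph recovery, and
the full default synthetic study (3 vs 3, 768 assays, 2000 genes, 1000
permutations) end to end. Every random draw is seeded; identical configs
produce bit-identical outputs, and `run_pipeline()` writes a manifest with
seed, row counts and file checksums so reruns can be verified byte for
byte.

# Known limitations

* Global-mean Cq normalization biases ΔCq when strong effects sit in a
  small detected fraction (see above).
* The NB Wald test is anticonservative at three samples per group; the
  moderated t does not have this problem and the calibration regime of each
  is stated in its documentation.
* Enrichment ignores category hierarchy; strongly overlapping categories
  will co-appear.
* Host-gene detection uses gene spans, not transcript models; a miRNA in a
  long intron of a gene with short transcripts is still reported.
* The greedy clusterer is deterministic but, like all greedy cohesiveness
  growth, can split very weakly bridged dense regions differently than an
  exact optimizer would.
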