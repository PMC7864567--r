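---
title: "Methods: mapping tumor cells onto fetal adrenal medullary states"
author: "medullamatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping tumor cells onto fetal adrenal medullary states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medullamatch)
```

# The scientific problem

Neuroblastoma arises from the developing sympathetic lineage of the fetal
adrenal medulla. Four normal populations define that lineage: Schwann cell
precursors (SCPs), bridge cells, chromaffin cells, and sympathoblasts. The
package implements the analytical machinery needed to decide, cell by cell
and cohort by cohort, which of these states tumor cells occupy: similarity
scoring against a normal reference, genotype-based identification of which
tumor-derived cells are actually cancerous, marker statistics, bulk
validation, and genomic corroboration. Every component is exercised on
synthetic data with known ground truth, because the interesting failure
modes (miscalibrated posteriors, leaky marker filters, anticonservative
permutation tests) are invisible without a truth to compare against.

# Quality control

Cells are filtered by platform presets:

| preset | max mito | min genes | min UMIs | doublet | cluster rule | cycling |
|---|---|---|---|---|---|---|
| `adrenal` | 0.30 | 300 | 1000 | 0.2 | > 50% failing | score > 0 |
| `tumor10x` | 0.20 | 300 | 1000 | — | — | — |
| `tumorplate` | 0.20 | 200 | 500 | — | — | — |

All comparisons are strict: a cell at exactly a boundary passes. The
cluster rule marks an entire high-resolution cluster as failed when
strictly more than half of its members fail an individual rule; only
individual failures count toward the fraction, which makes the rule
idempotent. The cycling filter removes any cell with an S or G2M score
strictly above zero, restricting a reference to G0/G1 cells so clusters
reflect cell type rather than cycle phase. The cluster and cycling rules
belong to the reference (adrenal) preset only; tumor data keep their
cycling cells because proliferation is part of the biology under study.

Excluded gene families (nuclear-mitochondrial genes, heat-shock proteins,
ribosomal genes) are handled as an input gene blacklist rather than a
hard-coded symbol list, because any such list is genome-annotation
specific; `subset_cells`/standard matrix subsetting covers this. The
high-resolution clustering that feeds the cluster rule is plumbing, not a
contribution: `cluster_cells()` wraps PCA plus seeded k-means, and any
graph-clustering routine could stand in its place.

Expression is depth-normalized to 10,000 counts and transformed with
`ln(1 + x)`. The natural log with pseudocount one keeps zeros at zero,
preserves within-cell gene ranking, and matches the convention of the
standard single-cell toolchains.

# Similarity scoring

`train_reference_model()` fits one elastic-net logistic regression per
reference cell type (one-vs-rest) on log-normalized expression, with mixing
parameter α = 0.99 — almost pure lasso, so each class keeps a small,
interpretable marker-driven coefficient set, while the ridge component
keeps the fit stable when markers are correlated.

Three choices were genuinely open and are resolved as follows:

* **Penalty strength**: cross-validated binomial deviance with a seeded,
  fixed fold assignment; the default rule is the strongest penalty within
  one standard error of the minimum (`lambda.1se`), the conservative
  standard. `lambda.min` is available.
* **Feature scaling**: models are trained on the same log-normalized
  matrix used everywhere else (with glmnet's internal standardization for
  the penalty path); no additional per-gene z-scoring is applied at
  scoring time, so a query matrix only needs depth normalization.
* **One-vs-rest rather than multinomial**: omitting softmax is only
  meaningful if each class's logit stands on its own; per-class binomial
  fits make that exact.

Scores are raw logits. A cell resembling none of the reference types —
the package's simulations include an extrinsic "podocyte" control
population for exactly this check — scores negative for every class.
Cluster scores are arithmetic means of member-cell logits. For splitting a
score distribution (e.g. high-risk tumor cells with strong versus weak
sympathoblast signal), `kmeans_split_scores()` runs seeded multi-start
k-means with k = 2 and labels the lower-mean group `"low"`.

# Genotyping from allelic imbalance

A copy-number segment with unequal haplotype copy numbers shifts the
expected major-haplotype mRNA allele fraction to
f = major/(major + minor), and to 1 for a one-copy loss. The package
phases heterozygous SNPs across each segment by pooled majority: the
allele with the larger pooled count over all cells is assigned to the
major haplotype (ties go to the reference allele, deterministically, and
are flagged with confidence 0.5).

Per cell, counts are aggregated per segment and scored under two
hypotheses — binomial with success probability clip(f, ε, 1−ε) (tumor) or
0.5 (diploid) — multiplied across segments, and combined with a flat prior
by Bayes' rule. The error clip (default ε = 0.01, a typical mRNA
base-call/mapping error scale, and a free parameter) keeps a loss segment
from assigning zero likelihood to a single stray minor-allele read.
Likelihoods are computed in log space, so thousands of reads per cell do
not underflow. A cell with no informative reads keeps the prior: logit 0,
"no information". Calls are definitive above 0.99 or below 0.01, and a
cluster is called tumor only when definitive tumor cells strictly
outnumber definitive normal cells.

SNPs are treated as independent given the haplotype, at the granularity
emitted by the upstream allele counter; UMI-level duplication is not
re-modelled. Segments without allelic imbalance carry no signal under this
likelihood and are excluded by construction (the segment validator requires
f ≥ 0.5, and f = 0.5 contributes identically to both hypotheses).

# Marker statistics and differential expression

For gene g and cluster c, with "expressed" meaning count > 0:
tf = expressing fraction inside c, global\_rate = expressing fraction
overall, and tfidf = tf · ln(1/global\_rate). The natural logarithm is
forced by the cutoff identity — a gene passes cutoff t exactly when
global\_rate < exp(−t/tf) — which the suite verifies over a parameter
grid. Significance is the upper-tail hypergeometric probability of drawing
the observed number of expressing cells into the cluster, BH-adjusted over
all gene-cluster pairs (BH matches the FDR language used throughout;
the correction method was not otherwise pinned down).

Stringent marker sets add two filters: tfidf strictly above 1, and
expression in at most 20% of any other single cluster, computed with an
extrinsic negative-control population present. Tumor marker lists from two
datasets are merged by averaging tf-idf over the lists where a gene
appears — a gene in only one list contributes its single value, the only
reading under which "present in either or both lists" is meaningful —
with a strict 0.85 cutoff and removal of genes expressed by more than 25%
of leukocytes.

Rank-sum DE tests log-normalized expression two-sided per gene, after
removing genes whose detection frequency reaches 25% in neither group
(i.e. a gene is kept when at least one group detects it at ≥ 25%, the
semantics of the standard single-cell implementations of this prefilter).
Constant genes get p = 1.

Negative binomial DE comes in two modes, both through edgeR:

* `nb_de_genewise()` estimates dispersion per gene with `prior.df = 0` —
  no information sharing — and applies a quasi-likelihood F test. This is
  appropriate when both groups have enough cells (default minimum 10) to
  estimate genewise overdispersion; below that the function refuses and
  points to the fixed-dispersion mode. An optional G1-only filter (both
  cycle scores ≤ 0) removes proliferation as a confounder.
* `nb_glm_fixed_dispersion()` fixes the dispersion at
  (√φ)² with √φ = 0.4 — bulk cohorts have no genuine biological
  replicates to estimate it from — and fits age, MYCN status, and risk
  group as covariates, testing the risk coefficient with a
  quasi-likelihood F test. Significance reporting uses |log2FC| > 1 at
  FDR < 0.05. The function refuses TPM-only input: the NB model needs raw
  counts. In the small-dispersion limit the fit agrees with Poisson
  regression, which the suite checks against `glm`.

# Bulk presence signal

The presence threshold is the mode (argmax of a Gaussian KDE, Silverman's
bandwidth — the standard deterministic default) of log2(TPM) pooled over
all strictly positive entries. Zeros are excluded without a pseudocount:
log2(0) is undefined and the zero mass would otherwise dominate the
density. "Present" and "above average marker expression" are treated as
the same rule — presence above the distribution peak. Per-gene presence
fractions are computed per stratum and summarized per marker set by the
median and IQR **over genes** (the genes-then-samples order of summary was
ambiguous; summarizing per-gene fractions over genes is the choice made
here, and it is stable under resampling samples within a stratum).

Risk stratification for cohorts without curated labels uses only the two
printed rules — low: age < 18 months and MYCN negative; high: age > 18
months and MYCN positive — with stage 4S always unclassified and every
other combination (including exact age 18) unclassified. Extra-adrenal
tumors are selected by excluding absent site descriptions and seven
case-insensitive stop-words (kidney, adrenal, abdominal, abdomen, unknown,
retroperitoneum, other).

Fetal cancer transcripts are ranked for therapeutic interest by ascending
mean log2(TPM + 1) across non-brain normal tissues, after requiring
detection in ≥ 50% of cancer cells in every tumor dataset, ≤ 20% in any
other cluster, and ≥ 10% of adrenal medullary reference cells. The +1
pseudocount handles zero TPM entries in the panel; "outside the brain" is
a configurable tissue-label pattern because the exact tissue partition is
a property of the panel, not of the method.

# Genomic smoothing and permutation tests

A cell type's expression topography is the Gaussian kernel sum
track(x) = Σ\_g w\_g φ\_σ(x − tss\_g) with σ = 200 kb, evaluated on a grid
of σ/10 (quadrature error far below the resolution of the test). The
weight w\_g is the **mean** over the type's cells of depth-normalized
expression — mean, not sum, so tracks are comparable between types with
different cell counts, which is the comparison the method exists for.
Tracks are linear in the weights and conserve total weight, both checked.

Recurrently altered regions are maximal runs of bins altered in at least
`min_samples` samples (inclusive threshold, default 200), separately for
gains and losses; breakpoint regions are 2 Mb windows around a transition
point, clipped to the chromosome. The region test compares the mean of
(track\_a − track\_b) **over the region's grid points** (mean rather than
integral: invariant to grid refinement) against the same statistic in
randomly placed windows of the same grid length, drawn uniformly over all
chromosomes long enough to contain them — random windows are not
restricted to the tested region's chromosome, the broader of the two
readings of "randomly selected regions of the genome". The p-value is the
plain fraction of null windows at or above the observed difference, which
can legitimately be zero; an (s+1)/(n+1) correction is available but off
by default to match the plain-fraction definition.

# The synthetic-data generator

The generator defines the study conditions for every test:

* **Counts**: per-cell depth Poisson around `mean_umis` (default 5000;
  scaled-down runs use 2000 over 1000 genes to reproduce single-cell
  sparsity); genes NB with variance μ + φμ², φ = (√φ)², √φ = 0.4 by
  default — matching the dispersion convention of the DE models, so DE
  calibration can be validated against the generator.
* **Cell types**: drawn from sympathoblast, chromaffin, SCP, bridge,
  leukocyte, mesenchyme. Each type owns a disjoint marker block expressed
  `marker_log2fc` log2-fold higher in the owner than in every other type.
  The default of 6 emulates near-binary lineage markers (the SOX10/PHOX2B
  kind of on/off pattern that detection-based tf-idf statistics rely on);
  similarity-recovery checks deliberately use the much harder log2FC = 2.
  Marker baselines are drawn tighter and higher than the genome-wide
  lognormal so markers are reliably detected in their own type. Tumor
  cells express the sympathoblast program plus a tumor-specific block —
  the cell-state hypothesis the package is built to test.
* **QC violations** are planted at a configurable rate, cycling through
  high mitochondrial fraction, high doublet score, low depth, and positive
  cycle scores, and recorded in the ground truth.
* **Allele counts**: per cell and segment, Poisson total depth split
  uniformly across SNPs; binomial per SNP with success probability
  f + ε(1 − 2f) for tumor cells and 0.5 for normal cells; the ref/alt
  orientation of the major haplotype is randomized per SNP and recorded.
* **Bulk cohorts**: NB counts TPM-normalized to 10⁶ per sample; 45%
  low-risk, 45% high-risk, 10% stage 4S; age skews older and MYCN
  amplification commoner (40% versus 3%) in high-risk disease without
  determining it — covariates correlate with risk, as in real cohorts,
  but remain separable in a GLM; 5% unknown MYCN; site descriptions drawn
  from a realistic vocabulary including empty and stop-word entries.
* **Genome**: one or two 10 Mb chromosomes, distinct ordered TSSs
  (0-based, half-open coordinates throughout, BED-compatible), with an
  optional planted region that can be populated with a chosen gene set
  (e.g. sympathoblast markers) to give one cell type a genuinely elevated
  topography there.

What the generator does **not** emulate: ambient RNA, doublet expression
profiles (only a score column), gene length and GC effects, batch
structure, UMI saturation, or subclonal copy number. Passing tests
therefore demonstrate correctness of the statistical machinery under the
declared generative model, not robustness to every artifact of real data.

# Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run, per invocation: an
exhaustive genotyping-oracle grid (all k ≤ n ≤ 20 over two segments, three
major fractions); 500 + 500 simulated cells for genotyping recovery; a
3 × 200-cell similarity experiment with 150 training cells per class;
500 replicates × 200 permutations for permutation-test calibration plus a
1000-permutation planted-region test; 2000-gene bulk cohorts with
40 + 40 contrasted samples for DE power and calibration; 10⁵ entries for
presence-threshold recovery; and a full pipeline run executed twice for
byte-identical outputs. These sizes were chosen so each property is
measured with comfortable Monte-Carlo margins while the whole suite stays
a desk-scale computation.

# Known limitations

* The genotyping likelihood treats reads as independent binomial draws;
  UMI duplication and allele-specific mapping bias are not modelled.
* Pooled-majority phasing assumes tumor cells dominate the pooled signal
  within imbalanced segments; at low tumor purity phase confidence drops
  and should be inspected.
* The similarity model transfers across datasets only as well as the
  shared gene space allows; genes missing from a query are imputed as
  zero, which shrinks logits toward the intercept.
* The presence threshold is a single global mode; cohorts with strongly
  sample-dependent detection limits would need per-sample thresholds.
* Random windows in the permutation test are placed uniformly over
  chromosomes long enough to contain them; genomes with very heterogeneous
  chromosome lengths weight long chromosomes accordingly.
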