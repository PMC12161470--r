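---
title: "Multi-omics consensus subtyping with MOSubtype: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics consensus subtyping with MOSubtype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MOSubtype)
```

# The problem

Acute myeloid leukemia (AML) is molecularly heterogeneous, and no single
omics layer captures that heterogeneity: transcriptional programs, DNA
methylation states, somatic mutations and copy-number instability each carry
partially independent prognostic information. MOSubtype discovers molecular
subtypes from matched multi-omics profiles of one cohort, summarizes each
subtype as a transcriptomic template, classifies new expression-only cohorts
against those templates, reduces the signature to a small diagnostic panel,
and characterizes the subtypes immunologically and clinically.

This vignette explains the models behind each stage, the tunable parameters
that matter, the numerical conventions, and what the synthetic-data tests do
and do not demonstrate.

# Feature selection

Each omics layer is reduced before clustering:

* **Continuous layers** (mRNA, lncRNA, methylation beta values): the top
  1000 features by sample standard deviation (denominator $n-1$). Ties at
  the cutoff break lexicographically by feature id so that selection is
  deterministic and invariant to input order.
* **Methylation** is optionally restricted first to *demethylation probes*:
  probes whose mean beta in a normal reference exceeds 0.8 and whose SD
  across the tumor cohort exceeds 0.2 (both strict inequalities). The
  intuition: probes methylated in normal blood that become variably
  demethylated in tumors mark an epigenetic "demethylator" phenotype.
  `selectDemethylationProbes(keepNormalHigh = )` exposes the direction of
  the background rule, because the two ways of phrasing the rule (retain
  versus exclude normally hypermethylated sites) are both seen in practice;
  the default retains them, which is what the demethylator concept requires.
* **Mutations**: binary gene-level calls are kept when mutated in at least
  3% of samples (boundary equality kept).

# The consensus ensemble

Six integrative clustering algorithms are implemented natively, chosen to
span the main methodological families at desk scale. Others can be attached
with `registerAlgorithm()`.

| algorithm | family | layers used |
|---|---|---|
| `snfCluster` | kernel fusion + cross-diffusion | continuous |
| `montiConsensus` | subsampling consensus | continuous (Euclidean) + mutations (Jaccard) |
| `cocaCluster` | meta-clustering of per-layer partitions | all |
| `intNmfCluster` | joint non-negative matrix factorization | continuous + binary |
| `lraCluster` | low-rank projection + k-means | continuous |
| `nemoCluster` | averaged kNN kernels + spectral | continuous |

The binary mutation layer is deliberately excluded from z-score/Euclidean
methods (SNF, LRA, NEMO): Euclidean geometry on sparse binary vectors is
dominated by overall mutation count rather than mutation identity. It enters
through Jaccard distance (Monti, COCA's per-layer partition) and as a
non-negative block (IntNMF), where it is meaningful.

Each algorithm returns one partition; the **consensus matrix** entry
$M_{ij}$ is the fraction of algorithms co-assigning samples $i$ and $j$.
Final labels cut average-linkage hierarchical clustering of $1-M$ at $k$,
and subtypes are renumbered 1..k by descending size (ties by smallest member
sample id) so runs are comparable. All algorithms derive their RNG streams
from one master seed, so ensembles are bit-reproducible.

Numerical conventions worth knowing:

* Spectral clustering uses the symmetric normalized Laplacian and k-means
  with 10 restarts; eigenvectors are row-normalized.
* SNF kernels use the locally scaled bandwidth
  $\varepsilon_{ij} = (\bar d_i + \bar d_j + d_{ij})/3$ with
  $\bar d_i$ the mean distance of $i$ to its 20 nearest neighbors, scale
  multiplier $\alpha = 0.5$, and 20 diffusion iterations.
* IntNMF shifts each feature to be non-negative, weighs layers by
  $1/\lVert X_d\rVert_F^2$, runs multiplicative updates to relative
  tolerance $10^{-6}$ (maximum 500 iterations), and keeps the best of 10
  restarts. A run that exhausts the iteration cap returns its best iterate
  and says so.
* A constant layer (zero distances) is an error in SNF; an algorithm that
  fails inside the ensemble is excluded with a warning, and the ensemble
  itself requires at least two survivors.

# Choosing the number of clusters

Two criteria are computed and combined:

* **Gap statistic**: $\mathrm{Gap}(k) = \frac1B\sum_b \log W^*_{kb} - \log W_k$
  with $W$ the total within-cluster sum of pairwise squared distances
  (k-means, 10 restarts) and reference data drawn uniformly over each
  feature's observed range. The selected k is the smallest with
  $\mathrm{Gap}(k) \ge \mathrm{Gap}(k{+}1) - s_{k+1}$, where
  $s_k = \mathrm{SE}\sqrt{1 + 1/B}$. The computation delegates to
  `cluster::clusGap` with exactly these settings (`d.power = 2`,
  `spaceH0 = "original"`). With a single reference draw the SE is undefined
  and treated as 0.
* **Partition-stability index** (`cpi`): for each k, every algorithm is run
  on repeated 80% subsamples and the index is the mean adjusted Rand index
  over all pairs of partitions, restricted to shared samples. 1 means the
  clustering at k is indifferent to both resampling and methodology. The
  index has no closed-form null; values are compared across k, not tested.
  The default algorithm set for the index is `snf`, `lra`, `nemo` — the
  three fastest members — because the index needs dozens of runs per k;
  any registered algorithm can be substituted.

`chooseK` min-max-normalizes both criteria over $k \ge 2$ and takes the k
maximizing their sum, ties to the smaller k. A completely flat criterion
normalizes to all zeros and simply drops out. Silhouette widths on
$1 - M$ describe the quality of the final consensus; singleton clusters
score 0, as does the degenerate all-ones consensus.

# Subtype templates and nearest template prediction

One-vs-rest differential expression uses a moderated t-statistic: per-gene
pooled variances are shrunk toward an empirical-Bayes prior whose degrees of
freedom and scale are estimated by method of moments on $\log s_g^2$
(the classical hierarchical model for gene-level variances; the test suite
cross-checks it against an independent implementation). Genes with
no within-arm variance have an undefined t and are reported flagged with
p = 1. Per subtype, genes with BH FDR < 0.05 and log2 fold change ≥ 1
qualify; a gene qualifying in several subtypes goes to the one with the
largest fold change; each list is ranked by fold change and cut at 50,
giving a 150-gene signature when all three lists fill. Lists are disjoint by
construction. Templates are derived from the mRNA layer only; lncRNAs are
excluded by default because cross-platform coverage of lncRNAs is poor in
exactly the external cohorts templates are meant for.

`ntpClassify` z-scores each gene across the cohort and assigns each sample
to the template minimizing cosine distance between the sample's z-vector
(restricted to the template-gene union) and the template's indicator vector
(optionally fold-change-weighted; the default is binary because weights do
not transfer well across platforms). Significance comes from resampling:
the same distance computed on random gene sets of identical size, p = the
fraction of null distances at or below the observed one (floor
$1/(R+1)$), BH-adjusted across samples. Unconfident samples keep their
argmin label but are marked, so downstream analyses can filter on
confidence without losing calls.

# The compact panel

`pamScores` computes nearest-shrunken-centroid standardized scores
$d_{gk} = (\bar x_{gk} - \bar x_g) / (m_k (s_g + s_0))$ with
$m_k = \sqrt{1/n_k - 1/n}$, $s_g$ the pooled within-class SD and
$s_0$ the median of $s_g$ by default. One point deserves emphasis: although
the acronym PAM often expands to *Partitioning Around Medoids*, the score
used for panel selection here is the *Prediction Analysis of Microarrays*
(shrunken-centroid) construction — per-gene, per-class signed scores
thresholded at fixed positive values. Medoid partitioning produces no such
per-gene score, so the shrunken-centroid reading is the only consistent one.
No shrinkage is applied before thresholding ($\Delta = 0$); `reducePanel`
keeps genes with score strictly above their subtype's threshold (positive
associations only) and unions them into the panel.

Thresholds are data-scale-dependent and must be retuned per cohort. On real
AML cohorts, thresholds of 0.2/0.5/0.2 have been used to obtain a 16-gene
panel; on the synthetic reference conditions the package uses 3.0 for every
subtype, derived *a priori* from the generator's geometry: null scores are
approximately $N(0, 0.5^2)$, so their expected maximum over ~4500
gene-class pairs is ≈ 2.2, while planted markers score ≈ 4.5 ± 0.5; 3.0
separates the two populations with margin on both sides.

Panel validation trains bagged decision-tree (random forest) classifiers on
stratified 50% sample draws, 10 000 repetitions by default. The default
evaluation is on the held-out half (`out_of_bag`): evaluating on *all*
samples includes the training half and leaks, inflating accuracy; that mode
(`all_samples`) exists for comparability with published protocols that used
it, but is not the default.

# Profiling

* `geomeanScore`: geometric mean of signature expression with pseudocount 1,
  computed on the linear scale; log2-tagged input is back-transformed first.
  Whether such scores should be computed on TPM or log2(TPM+1) is
  convention-dependent; the linear default plus an explicit `scaleTag`
  argument makes the choice visible and overridable.
* `ssgsea`: single-sample enrichment as the summed difference between the
  rank-weighted in-set ECDF (weights rank^0.25) and the out-of-set ECDF.
  Scores are not range-normalized by default (a `normalize` flag exists);
  the immune and stromal enrichment scores (IES/SES) are this statistic on
  an immune and a stromal set. The package ships small *synthetic* stand-in
  marker lists (`ies_ses_synthetic.gmt`) so the machinery runs out of the
  box — for real analyses supply published signatures. The functional
  orientation lists (immunosuppression, T-cell activation, MHC-I, ...) are
  shipped as-is since they are short, published gene lists.
* `prerankedGsea`: weighted KS running sum on a fold-change-ranked list with
  a gene-label permutation null (appropriate for preranked input, where
  phenotype permutation is unavailable). NES divides ES by the mean |null
  ES| of the same sign.
* `genomeBurden`: FGA/FGG/FGL from segment tables with 1-based inclusive
  lengths ($end - start + 1$) at |log2 ratio| ≥ 0.3 — the boundary value
  counts as altered, and FGG + FGL = FGA holds exactly by construction.
  Overlapping per-sample segments are a hard error rather than silently
  double-counted.

# Survival statistics

Kaplan-Meier curves, log-rank tests (overall and pairwise with BH
adjustment) and Harrell's concordance delegate to the `survival` package;
the test suite pins them to hand-tallied oracles on small tables. Subtype
labels enter the C-index as ordinal risk, ordered worst to best by observed
median survival. Two risk scores are compared by paired bootstrap over
samples (two-sided p from the bootstrap distribution of the C difference) —
a deliberately assumption-light choice since the sampling distribution of a
C difference on correlated risks is awkward analytically.

# The synthetic cohort generator

`simulateCohort` emulates the statistical shape of a 90-sample multi-omics
AML discovery cohort with three planted subtypes:

* **Expression / lncRNA**: Gaussian log2 baseline (SD 1); each subtype has
  50 disjoint marker mRNAs (30 lncRNAs) shifted by +2 in its own samples.
* **Methylation**: hypermethylated Beta(8,2) background with per-subtype
  blocks of 50 probes at Beta(2,8) in that subtype — demethylator blocks.
  The normal reference puts Beta(12,2) on the block probes (mean beta > 0.8
  with high probability) and uninformative Beta(2,2) elsewhere. Beta values
  are simulated directly on the beta scale because the pipeline consumes
  beta values only.
* **Mutations**: Bernoulli(0.02) background, 5 genes per subtype at 0.30 in
  that subtype — rates chosen so that the 3% frequency filter is actually
  exercised (most background genes fall below it, all enriched genes pass).
* **Copy number**: 10 chromosomes × 10 bins of 10 Mb; subtype 1 is
  copy-number unstable (15% of bins altered at |log2| ≥ 0.35, loss-biased,
  versus 4% elsewhere), mirroring a high-FGA/poor-karyotype subtype.
* **Survival**: exponential event times with per-subtype hazards
  log(2)/{18, 27, 45} months — medians ordered worst (subtype 1) to best
  (subtype 3) as reported for AML multi-omics subtypes. Censoring is
  administrative: with probability `censorRate` (default 0.3) a subject is
  censored at a uniform fraction of its event time, which makes the
  expected censored fraction exactly `censorRate`.

`effectSize` doubles as the master switch: at 0 all planted structure (in
every layer, including copy number) is disabled, giving the fully null
cohort used for negative controls. Every layer draws from a named substream
of the master seed, so cohorts are bit-reproducible and layers are
independently perturbable.

**What the generator does not emulate**: batch effects, library-size or
GC biases, probe cross-hybridization, mutational signatures, linkage between
layers beyond shared subtype labels, realistic CNA breakpoints, competing
risks, or an APL-like outlier subtype. Passing tests on this generator
demonstrate that the algorithms recover the kind of structure they model,
under favorable noise assumptions — not that any particular real cohort
will yield three subtypes.

# Problem sizes used in the automated checks

The acceptance checks run the full pipeline on cohorts of 90 samples with
1500 mRNAs / 800 lncRNAs / 1500 probes / 80 mutation genes, reduced to at
most 1000/500/1000 features plus the frequency-filtered mutations — the
scale at which every algorithm, including the resampling-based ones, runs
in seconds. Stability and recovery statistics aggregate 5–10 seeded
replicates; the bagged-classifier distributions use 500 repetitions (the
10 000-repetition default is for real analyses).

# Known limitations

* Four of the ten published-ensemble algorithm families (Bayesian latent
  models, multi-view kernel learning variants, perturbation clustering,
  grade-of-membership factorizations) are not built in; the plug-in
  interface is the supported path.
* The stability index has no absolute scale; it supports comparing k
  values, not hypothesis tests.
* NTP assumes the template genes vary in the new cohort; a cohort where a
  template gene is constant contributes a zero z-score for it.
* No batch correction is performed before cross-cohort classification;
  templates and z-scoring absorb location/scale differences per gene but
  not more complex batch structure.
* Survival utilities cover group separation and concordance, not Cox
  modeling, time-dependent covariates or competing risks.
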