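---
title: "Regional identity analysis for cerebral organoids: models and methods"
author: "cerebroid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional identity analysis for cerebral organoids: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Cerebral organoids derived from pluripotent stem cells are regionally
heterogeneous: depending on the derivation protocol (inhibitor-free culture,
Dual SMAD inhibition, or combined SMAD and WNT inhibition, "Triple-i"), the
neural stem cells they contain may adopt cortical, diencephalic, cerebellar
or other regional identities. Deciding *which* region an organoid
transcriptome resembles requires (i) a reference catalogue of region-specific
genes from a developmental brain atlas, (ii) a way to embed organoid and
atlas samples in one space despite their technical differences, and (iii)
statistics that quantify regional signal in differential-expression results.
This package implements that computational chain for bulk RNA-seq, a
matching single-cell chain (clustering, doublet handling, cross-dataset
annotation, conservative marker tests), and deterministic steady-state RNA
velocity for spliced/unspliced layers — together with a synthetic-data
generator that plants every structure the analyses are meant to detect, so
the whole pipeline is testable against known truth.

# Bulk chain

## Normalization

Counts are converted to RPKM (count divided by gene length in bp and by the
per-sample depth, times $10^9$); mitochondrial genes, when flagged, are
removed beforehand. Samples are then rescaled to a common RPKM sum. The
common target is not fixed by convention, so we use the **mean of the
original column sums**: it is symmetric in the samples and preserves the
overall scale (`equalSumNormalize(target=)` makes it configurable). Log
transforms use base 2 with a pseudocount of 1 throughout; wherever "log" is
ambiguous we use log2, consistent with log2 fold-change reporting. When two
datasets are merged, the joint matrix is quantile normalized (every column
receives the row-wise mean of the sorted columns; ties share the mean of
their quantile values, the limma convention).

## Regional marker derivation

For region $r$, week $w$, the regional log2 fold change of gene $g$ is

$$\mathrm{lfc}_{g,r,w} \;=\; \log_2\frac{\bar x_{g,r,w}+1}{\bar x_{g,\neg r,w}+1},$$

where $\bar x_{g,\neg r,w}$ averages the per-region means of all other
regions, excluding striatum and amygdala. A gene is a marker of $r$ if
$\mathrm{lfc}_{g,r,w} \ge 2$ (i.e. at least 4-fold) in **every** week of the
window (weeks 12–21 by default). A confound filter then removes genes whose
fold change in striatum or amygdala versus all other regions reaches the
threshold; since the quantifier over weeks is not canonically fixed, the
default is **any** week (conservative against confounds) with an `"all"`
option. Replicates of one region/week are averaged on the RPKM scale before
logging. A gene qualifying in two regions (impossible on clean data, but
possible in principle) is assigned to the region with the largest mean
across-week fold change so the sets stay disjoint.

## Batch adjustment and correspondence analysis

Dataset-of-origin effects between atlas and organoid matrices are removed
with an empirical-Bayes location/scale model (`fitComBat`/`applyComBat`):
genes are standardized with the batch-size-weighted grand mean and pooled
batch-regressed variance; per-(batch, gene) locations and scales are shrunk
toward batch-level normal and inverse-gamma priors by iterating the
conditional posterior means to a $10^{-4}$ tolerance. The implementation is
written from first principles and agrees with the reference implementation
in the sva package to numerical precision (this is verified in a test; sva
is never called by the pipeline itself). The model uses parametric priors,
a full-rank batch design and no covariates.

Correspondence analysis decomposes a non-negative matrix $X$ through the SVD
of its standardized residuals
$S = D_r^{-1/2}(P - r c^\top)D_c^{-1/2}$ with $P = X/N$. Principal
coordinates are reported for genes and samples (both scaled by the singular
values, the symmetric biplot); total inertia equals Pearson's $\chi^2/N$,
and each axis carries the fraction $\sigma_i^2/\sum_j \sigma_j^2$. Axis
signs are fixed by making the largest-magnitude column coordinate positive,
so plots are reproducible. Zero-margin rows/columns are dropped with a
warning rather than erroring: they carry no information for the
decomposition.

The integration (`integrateAtlasOrganoids`) merges shared genes, quantile
normalizes, keeps the 10,000 most variable genes, batch-adjusts with the EB
model and runs the correspondence analysis on the adjusted values. Whether
the original analysis used normalized or log values for the CA is not
stated; we run it on the (non-negative) quantile-normalized scale because
the decomposition requires non-negativity, clipping the few small negative
values introduced by batch adjustment to zero (counted and reported).

## Differential expression and enrichment

`nbWaldDE` is a deliberately compact stand-in for the canonical
negative-binomial workflow: median-of-ratios size factors; method-of-moments
gene dispersions shrunk on the log scale toward a trimmed parametric
mean-dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$ (prior weight 10); a
Wald test on the log ratio of group means with the delta-method standard
error $\mathrm{Var}(\log\hat\mu) \approx \frac{1}{n^2}\sum_i (1/(s_i\mu) +
\alpha)$. P-values are referred to a $t$ distribution with $2(n_1+n_2-2)$
degrees of freedom: the normal reference is anti-conservative at typical
bulk replicate numbers, while the naive residual-df $t$ over-corrects
because the EB-stabilized dispersion contributes prior information; the
chosen reference holds the nominal level on negative-binomial nulls across
the dispersion range 0.05–0.5 (verified in the test suite). There is no
outlier filtering, independent filtering or fold-change shrinkage, and the
output is documented as not numerically identical to heavier
implementations. Genes with zero counts everywhere are dropped with a
message. BH correction is the standard step-up (via `p.adjust`), and
significance calls use strict `q < 0.05` with `|log2FC| >= 1` (a late-stage
variant 0.1/0.1 is a parameter).

Gene-set enrichment is provided both as a two-sided Fisher exact test
(p-value from `fisher.test`, i.e. the sum of table probabilities no larger
than the observed; the reported odds ratio is the sample cross-product
ratio, so an empty overlap gives 0) and as a weighted Kolmogorov–Smirnov
permutation GSEA whose null permutes gene labels — per-sample phenotype data
may be absent at the stage where rankings exist, which is why gene-label
permutation is the default.

## Venn-category z-scores

For each regional gene set, genes are partitioned by DE outcome: one
category per protocol of genes consistently upregulated in that protocol in
every pairwise comparison it appears in, plus a "shared" category of genes
significant in no comparison. Per gene, expression is summed over the atlas
samples of the set's own region across weeks 12–21; sums are averaged per
category; averages are z-scored across the categories **within that set**
(matching one Venn diagram per regional set) using the population (divide by
$n$) standard deviation, configurable to the sample convention. Categories
with fewer than 5 genes are reported with `NA` z-scores.

# Single-cell chain

QC removes barcodes with $\ge$ 10,000 total UMIs, $\ge$ 40% mitochondrial
UMIs, and optionally $\ge$ 15% ribosomal UMIs (all exclusive-keep). The
reading of "at least 10,000 UMIs … were filtered" as *removal* of high-UMI
barcodes (a doublet proxy) is genuinely ambiguous; removal is the default
and `removeHighUMI = FALSE` provides the other reading. Normalization
scales each cell to the median pre-normalization total and applies natural
log1p. Highly variable genes use 20 equal-frequency mean bins with
within-bin z-scores of the dispersion (variance/mean of the expm1 values),
eligibility bounded by mean in (0.005, 1.5) — the Seurat-v1-flavored scheme
of the cited toolchain. Scaling z-scores each gene and truncates values
above 10 (no lower truncation; deliberately not idempotent). PCA takes the
top components of the centered matrix with a deterministic sign convention.

The kNN graph is either plain Euclidean or batch-balanced
($\lceil k/\#\text{batches}\rceil$ nearest neighbors per batch per cell);
edges carry a Gaussian kernel weight with the median k-th-neighbor distance
as bandwidth. For the cross-study merge the upstream work used a panoramic
stitching algorithm; this package substitutes the batch-balanced kNN on
per-batch PCA as its single integration primitive — a documented
simplification, full panoramic stitching is out of scope. Louvain
clustering delegates to igraph (the contract — modularity at a given
resolution, seed determinism, size-ordered labels from 0 — is what the
tests pin down).

Doublet scoring simulates synthetic doublets by summing the counts of
random cell pairs (two per observed cell), subsamples the summed UMIs at
rate 0.5 so the simulated profiles carry singlet-like sampling noise (the
cited tool exposes the same subsampling option; without it, homogeneous
data get flagged at the low-noise center of the cloud), co-embeds observed
and simulated profiles, and converts each observed cell's simulated-neighbor
fraction $q$ into a calibrated likelihood
$q\rho/r \,/\, (q\rho/r + (1-q)(1-\rho))$ with expected rate $\rho = 0.05$
and simulation ratio $r$; cells above 0.2 are flagged, per sample.

The conservative marker test (`ttestOverestimVar`) is a Welch-style t-test
of one group against the rest in which **both** variance terms are divided
by the focal group's size. The exact variance-overestimation formula of the
cited implementation is not printed anywhere we could verify, so this
declared interpretation is used; it guarantees $|t|$ never exceeds the
standard Welch statistic (a tested property) and is conservative whenever
the comparison group is larger — the usual cluster-versus-rest situation.
Log2 fold changes are computed on expm1 means with a $10^{-9}$ guard.

Cross-dataset annotation computes Pearson correlations between cluster-mean
scaled expression vectors over the union of per-dataset HVGs (each dataset
scaled and clipped on its own) and assigns each query cluster its
best-correlated reference label.

# RNA velocity

Genes need $\ge 30$ total spliced **and** $\ge 30$ total unspliced counts.
Layers are median-total normalized independently; log1p is the pipeline
default. Moments average each layer over the cell's kNN neighborhood
(k = 30), focal cell included — the standard moment convention, which also
stabilizes isolated cells. Per gene, the steady-state slope is the
least-squares fit through the origin over all cells,
$\gamma_g = \langle M_u, M_s\rangle / \langle M_s, M_s\rangle$, and the
velocity of a cell is its deviation $M_u - \gamma_g M_s$. All cells enter
the fit (no extreme-quantile subsetting), matching the deterministic mode
of the cited method on moments. Negative fitted slopes are floored at zero
with a warning (`clipNegativeGamma = FALSE` disables this); removal of
non-lineage cells (mesenchymal in the original analysis) is expressed as a
generic label-exclusion option upstream of the fit.

Kinetic-parameter **recovery** analyses (tests and the acceptance script)
fit on median-normalized, non-logged moments: the planted ratio
$\beta/\gamma$ is defined on the linear scale and log1p does not commute
with it; because the synthetic layers are generated at a common depth, even
the median normalization is a near-identity there and the raw layers are
used directly. The workflow applies the full normalize-and-log chain for
real data.

# The synthetic generator: what it emulates, and what not

`generateAtlas` emulates a fetal-atlas layout — one RPKM sample per
(region, week) over 16-region/weeks-8–37-like grids — with a heavy-tailed
lognormal baseline (meanlog 1, sdlog 1) shared across regions and markers
planted as an additive log2 offset (default 3) in their region in every
week. Planted marker/confounder baselines are floored at 16 RPKM (with a
spread): threshold-based fold-change recovery is only well defined away
from the pseudocount floor, and real regional markers are well-expressed
genes. Confound decoys are elevated by the marker offset in a target region
and by the offset + 2 in striatum or amygdala: the confound comparison runs
against *all* other regions, so the co-elevated target region dilutes it,
and the larger confound-region offset is what makes the planted decoy
clear the same threshold the filter uses — this follows from the filter's
arithmetic, not from tuning.

`generateBulkOrganoids` draws negative-binomial counts (dispersion 0.1, the
common bulk overdispersion scale) around mixture-weighted atlas profiles
times gene length, scaled to the sequencing depth, with additive log2 batch
shifts applied to the expected counts before the draw. The default study
mixtures are cortex-dominant (80%) for Triple-i, cerebellum-dominant (70%)
for Dual SMAD-i and uniform for inhibitor-free, mirroring the qualitative
regional biases the protocols are known for. Batch-shift recovery is
assessed on log2(count + 1) at fixed depth: a shift applied to *all* genes
is absorbed exactly by per-sample depth normalization, so an RPKM-scale
global shift is not an identifiable target; the residual per-gene batch
difference after adjustment is summarized as the mean absolute difference
across genes (individual noisy genes retain shrinkage-sized residuals under
any EB method).

`generateSCDataset` plants cell types as mean-expression programs (shared
baseline 0.2, markers at 3 per type — chosen so that marker means on the
median-normalized scale fall inside the (0.005, 1.5) HVG eligibility window,
as they do in real data), Poisson or NB counts with a mild lognormal size
factor, mitochondrial/ribosomal housekeeping genes for the QC flags, and
doublets as *sums* of two random singlets (UMIs add). Spliced/unspliced
layers follow $u = (\beta/\gamma)s$ at steady state with per-gene slopes
drawn from (0.3, 1.5); induction genes place the designated transient
population above the line at reduced spliced levels (unspliced leads),
repression genes below it. The transient population defaults to the first
type, remodeled into a progenitor-like program expressing every type's
markers at 40% of peak — transient kinetics must live in a population that
is separable in the embedding, otherwise neighborhood smoothing averages
the deviations away, and a progenitor that moderately expresses all lineage
markers is also the biologically natural choice. Velocity-sign calls in the
tests classify a gene by its mean velocity against a band of ±2% of its
mean unspliced moment.

All randomness flows from one integer seed through derived per-stage
streams; fixed seeds reproduce every artifact bit for bit. What the
generator does **not** emulate: read-level noise (FASTQ), realistic
gene-length/GC structure, ambient RNA, empty droplets, batch-specific
library chemistry, or continuous differentiation trajectories — passing
tests demonstrate the algorithms recover planted structure under the stated
noise models, not performance on real tissue.

# Fixture sizes, determinism and numerical choices

Simulated problem sizes are chosen to exercise the statistics at desk
scale: atlases of 400–5,050 genes over 5–7 regions and 5–10 weeks; bulk
cohorts of 6–8 samples per protocol at depth $2\times 10^6$ (and 50 per
batch for batch-model recovery); single-cell datasets of 400–600 cells with
4–5 types; 2,000 genes for DE calibration. Louvain tests run at resolution
1 because the fixtures plant 4–5 types — the workflow defaults keep the
reference resolutions (4 for the day-50-style stage, 2 for day-80) that
correspond to the ~45-cluster granularity of real organoid data. EB
iterations stop at a relative change of $10^{-4}$; variance floors of
$10^{-8}$ guard degenerate genes; HVG ties break on gene id; PCA/CA axis
signs follow the largest-loading convention; zero-variance genes scale to
zero rows; q-value thresholds are strict inequalities.

# Known limitations

The DE stand-in approximates but does not reproduce DESeq2 outputs (no
Cook's filtering, no apeglm). GSEA reports per-set permutation p-values,
not a cross-set normalized-ES FDR. The doublet scorer is a simplified
scrublet-style device; its flagged fraction at the 0.2 threshold is
conservative on synthetic data. The batch-balanced kNN stands in for
panoramic stitching. Velocity covers the deterministic steady-state model
only — no stochastic or dynamical variants, and no velocity-graph
embedding. UMAP visualization is out of scope throughout.
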