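---
title: "Discovering age-associated gene expression meta-programs with metaGEP"
author: "metaGEP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering age-associated gene expression meta-programs with metaGEP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaGEP)
```

## The problem

Human hematopoietic stem cells (HSCs) are transcriptionally heterogeneous,
and cross-study single-cell comparisons of young and aged donors disagree
on which molecular programs change with age, largely because dataset-level
technical variation swamps the biology. A robust strategy is to avoid
integrating cells across studies altogether during discovery: factorize
each *sample* separately into gene expression programs (GEPs), then keep
only the programs that recur across samples *and* datasets. The recurring
averages — meta-programs, or metaGEPs — are by construction reproducible
features of HSC biology rather than artifacts of any one study. Their
fixed spectra can then be projected back onto every cell, so that each
cell gets a predominant program and each sample a composition over
programs, which is the quantity compared between age cohorts.

`metaGEP` implements this pipeline end to end: per-sample QC, shared
variable-gene selection, per-sample consensus non-negative matrix
factorization (cNMF), cross-sample clustering of program spectra into
metaGEPs, nonnegative-least-squares (NNLS) usage projection, and
Mann–Whitney cohort tests on predominant-program fractions — plus the
supporting analyses (preranked GSEA with expression-matched random-set
nulls, gene-set recoverability, TF-activity rank aggregation, ortholog
overlap testing) and a synthetic multi-dataset generator with planted
programs that makes every stage testable without any data download.

## Model and procedure

### Per-sample consensus NMF

For one sample, let $X \in \mathbb{R}_{\ge 0}^{n \times G}$ hold counts of
$n$ cells over the $G$ shared variable genes, with each gene scaled to
unit variance (no centering, so nonnegativity is preserved). Each of $R$
replicate factorizations solves

$$\min_{W, H \ge 0} \lVert X - W H \rVert_F^2,$$

with $W$ ($n \times k$) the usages and $H$ ($k \times G$) the spectra, by
multiplicative updates from a seeded random start (tolerance $10^{-4}$ on
the relative-error change, at most 400 iterations — full-scale runs of
this kind of protocol typically inherit solver defaults; we fix explicit
values for reproducibility). Replicate component spectra are L2-normalized and
density-filtered: a component whose mean Euclidean distance to its
$K = \lfloor 0.3 R \rfloor$ nearest neighbors exceeds a distance threshold
(default 0.1, with 0.05/0.15 the standard alternatives to inspect) is
discarded as a non-reproducible solution. Survivors are clustered into $k$
groups (k-means on lexicographically sorted rows, which makes the result
invariant to replicate order), and each consensus spectrum is the
cluster-wise median. Usages are refit by NNLS of $X$ on the consensus
spectra; *stability* is the mean silhouette width of the component
clustering and *error* the relative Frobenius reconstruction error of the
refit.

Two spectra representations are kept per program: the expression-space
spectrum (the median spectrum mapped back through the gene scale factors
and renormalized to counts-per-10k units) and the Z-score spectrum, the
ordinary-least-squares coefficients of the per-gene z-scored
log-normalized expression on the row-normalized usage matrix. Z-score
spectra put every sample on a comparable scale and are what gets
clustered across samples.

$k$ is scanned (3–10 by default) and chosen by an explicit stand-in for
the visual stability-vs-error inspection used at full scale: among $k$
whose error is within 5% of the minimum, take the most stable, ties to
the smallest $k$. The diagnostics table is always returned so a caller
can override. Finally, programs driven by single cells are removed: a
program whose maximum usage exceeds 10 times its 75% usage quantile
(ratio $q_{100}/q_{75} > 10$, with $q_{75} = 0$ counting as $+\infty$) is
excluded.

### MetaGEP clustering

Programs from all samples are pooled on the shared variable-gene order
(genes dropped by one sample's QC are zero-filled — the cross-study
harmonization is not otherwise specified) and clustered agglomeratively
with average linkage on the Pearson correlation between Z-score spectra:
the pair of clusters with the highest average mutual member correlation
is merged until no pair reaches `corrThresh` (default 0.1); clusters with
at least two programs spanning at least `pctThresh` (default 0.1) of the
contributing samples are retained. Clusters carrying at least 4 programs
from at least 2 datasets become metaGEPs, summarized by arithmetic means
of member Z-score and expression-space spectra. The iterative-clustering
heuristic upstream tools use is underspecified, so this is a deliberate
concrete choice, and the linkage matters: a centroid-membership fixed
point at a threshold as low as 0.1 is unstable — a handful of spuriously
correlated programs pull the centroid toward the midpoint of two distinct
program families, after which both families join one runaway cluster (we
observed exactly this on synthetic fixtures whose family centroids
correlate at $-0.04$). Average linkage merges two families only if their
*average* mutual correlation clears the threshold, which cannot run
away. The two thresholds keep their natural meanings, and ties are broken
lexicographically so runs are deterministic.

### Projection and cohort testing

The metaGEP expression matrix (metaGEP × genes) is projected onto any
dataset by per-cell NNLS in that dataset's variance-scaled space (each
spectrum divided by the dataset's per-gene count standard deviation —
the projection space is chosen to match the cNMF input space; the
full-scale protocol does not state one). Usages are normalized to
fractions, each cell is labelled by its argmax program (ties to the
lowest index), and for every sample with at least 20 cells the fractions
of cells per predominant program are compared Young vs Aged by a
two-sided Mann–Whitney U test — exact when both cohorts have at most 12
samples and no ties (so small oracle checks enumerate), the
tie/continuity-corrected normal approximation otherwise (the study-scale
cohorts, 27 vs 17, use the approximation) — with Bonferroni adjustment
over the number of metaGEPs.

### Enrichment machinery

Preranked GSEA uses the classic weighted running sum (weight exponent 1)
with a seedable random gene-set permutation null:
$p = (1 + \#\{|ES_{null}^{same sign}| \ge |ES|\}) / (1 + \#ES_{null}^{same sign})$
and $NES = ES / \overline{|ES_{null}^{same sign}|}$. This is deliberately
simpler than adaptive multilevel estimation: permutation nulls are exact
to simulate, cacheable per set size, and sufficient at the thresholds
used here; the cost is a resolution floor of roughly $2/n_{perm}$ on p,
which matters for Bonferroni-corrected recoverability calls and is why
those analyses raise `nPerm`.

Expression-matched random sets split genes into 50 equal-width
("equidistant", read literally) bins of mean log-normalized expression
and draw, per bin, exactly the signature's occupancy without replacement,
excluding the signature's own genes when alternatives exist — so every
random set reproduces the signature's bin histogram and size exactly. A
gene set is "recovered" by one cNMF run when any program's Z-ranked GSEA
is significantly positively enriched after Bonferroni correction across
(sets × programs); recovery rates are fractions of runs per sample.
Module scores subtract bin-matched control-gene means (25
equal-occupancy bins, 100 controls per set gene, sampled once per seeded
call). Fisher overlap tests report the conditional-MLE odds ratio and
two-sided p (via `stats::fisher.test`, which implements exactly the
probability-summation definition) next to the cross-product estimate;
ORA is the upper hypergeometric tail.

### TF-activity aggregation

Regulon-activity matrices (TF × cell, AUC-like, computed upstream or
simulated) are an input contract. Within each dataset the Pearson
correlation of each TF's activity with the target (0/1 cohort — the
point-biserial special case — or a metaGEP usage) is ranked (rank 1 =
largest signed correlation; an option ranks by $|r|$), ranks and
correlations are averaged over datasets after intersecting TF sets, and
TFs with mean rank ≤ 10 and mean correlation ≥ 0.15 are selected.
Z-scored activities are winsorized at the 0.1/99.9 percentiles for
export.

## The synthetic cohort

The generator plants everything downstream stages are asked to recover.
Its defaults are fixed once and mirror the motivating study design:

| parameter | default | meaning |
|---|---|---|
| datasets | 3 | multi-study structure, lognormal per-dataset gene factors (σ = 0.15) |
| samples | 44 (27 Young / 17 Aged) | cohort sizes |
| cells/sample | 22 × 110 and 22 × 45 | 22 samples pass the ≥100-cell discovery rule (14 Young / 8 Aged) |
| genes | 500 | 25 disjoint anchor genes per program, 40 RPS/RPL decoys high in every program |
| programs | 4 | `aging` + `GMP`/`MEP`/`CLP` lineage programs |
| usage prior | Dirichlet α = 0.6 (aging), 0.8 (others) | sparse per-cell mixtures |
| agedBoost | 3 | multiplies the aging α in Aged samples |
| library size | lognormal, meanlog log(1500), sdlog 0.4 | realistic UMI depth |
| noise | Poisson | closed-form expectations; optional NB dispersion |

Counts for cell $j$ are Poisson with mean
$\ell_j \cdot (u_j^\top S) \odot b_{d(j)}$ (library size × mixture of
spectra × dataset batch factor), so every moment used in tests is exact.
TF activities couple affinely to planted usages
($0.15 + 0.7\,u + \mathcal{N}(0, \sigma)$, clipped to $[0,1]$), with 108
TFs shared across datasets to exercise the intersection step.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: ambient RNA, doublets, single-nucleus
chemistry differences, gene–gene correlation beyond program structure,
overdispersion under the Poisson default, non-disjoint program anchors,
and alias-level gene-name mismatches across studies.

## Numerical and design choices

- **"Mean absolute deviation"**: the QC window reads `median ±
  2.5 × mean(|x − median|)` literally; `madType = "median"` switches to
  the median absolute deviation. QC is exactly idempotent only when the
  first pass drops nothing or leaves a degenerate (zero-MAD) window —
  the window statistics of a second pass no longer see the removed
  outliers; in practice the second pass is a no-op on clean data.
- **Normalization convention**: counts per 10,000 then `log1p`,
  everywhere "normalized expression" is needed.
- **Variable genes**: standardized variance (variance z-scored within 20
  equal-occupancy mean bins of log-normalized expression) — a
  deterministic, dependency-free equivalent of common
  variance-stabilizing rankings. A caveat the tests surface: genes that
  monopolize a mean bin are z-scored against each other, so block-planted
  signals must be a per-bin minority to be fully recovered.
- **Degenerate inputs**: zero-variance genes are dropped with a warning
  before NMF; all-zero cells project to uniform usage with a warning;
  all-tied abundance fractions give p = 1; constant vectors z-clip to 0;
  `q75 = 0` makes the usage ratio +∞ (always excluded).
- **Determinism**: R's default Mersenne-Twister generator; every
  stochastic step takes a seed, child seeds are derived by a fixed
  integer recurrence kept below $2^{31}$, and consensus clustering sorts
  component rows lexicographically so results do not depend on replicate
  or input order.
- **Desk-scale problem sizes**: the bundled analyses run the full
  pipeline at 100 NMF replicates per k over k ∈ 3–5 on the default
  synthetic cohort (≈1 minute per cohort), 30 replicates and k ∈ 3–5 for
  recoverability (with `nPerm = 8000` so the Bonferroni threshold is
  reachable), and 150 shared variable genes — the same code paths as a
  full-scale run (500 replicates, k 3–10, 3000 variable genes), scaled to
  a desktop. All are arguments, not constants.

## Worked example

```{r example, eval = FALSE}
truth <- generateTruth(truthConfig(seed = 1))
sim <- simulateCounts(truth)
res <- discoverMetaGEPs(sim$samples, nTop = 150, minDatasetsVar = 2,
                        kRange = 3:5, nReplicates = 100, seed = 1)
res$metageps

usage <- projectUsages(
    do.call(cbind, lapply(sim$samples, function(s)
        SummarizedExperiment::assay(s, "counts"))),
    metagepExpressionMatrix(res$metageps))
labels <- predominantProgram(usage)
cohortFractionTest(labels,
                   truth@cellMeta$sample_id[match(rownames(usage),
                                                  truth@cellMeta$barcode)],
                   truth@config@samples, minCells = 20)
```

## Known limitations

- The iterative metaGEP clustering is a documented reading of an
  underspecified upstream heuristic, not a bit-for-bit reimplementation;
  on real data it may split or merge borderline clusters differently.
- Automatic k selection can disagree with human judgment on real
  samples; the diagnostics table exists for overriding it. In
  particular, stability-based selection counts every reproducible factor
  — on unnormalized input, strong library-size variation is itself a
  stable depth component, so the selected k can exceed the number of
  biological programs by one. This is harmless downstream (depth
  components do not recur coherently across samples and fail the metaGEP
  membership rules) but matters when interpreting a single sample's k.
- The permutation GSEA p-value floor (~$2/n_{perm}$) makes very small
  p-values expensive; analyses that Bonferroni-correct many tests must
  budget permutations accordingly.
- Projection assumes the target data's variance scaling is comparable to
  the discovery space; gross platform differences should be handled
  upstream.
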