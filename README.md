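# metaGEP

Consensus-NMF meta-programs and age-associated program abundance in
single-cell RNA-seq.

## What problem this solves

Single-cell studies of human hematopoietic stem cell (HSC) aging disagree
about which transcriptional programs change with age, largely because
dataset-level batch effects dominate naive cross-study integration.
`metaGEP` implements a discovery strategy that sidesteps integration:

1. **Per-sample consensus NMF.** Each sample with enough cells (≥ 100) is
   factorized independently — `min ‖X − WH‖_F, W,H ≥ 0` over the shared
   variable genes, repeated from many random starts — and only components
   that recur across restarts survive a density filter and are summarized
   by cluster medians (spectra `H`, usages `W`, stability/error
   diagnostics for choosing `k`). Programs whose usage is driven by a
   single cell (q100/q75 usage ratio > 10) are excluded.
2. **Meta-program (metaGEP) clustering.** Program Z-score spectra are
   clustered across samples by an iterative centroid procedure
   (Pearson r ≥ 0.1 membership); clusters with ≥ 4 programs from ≥ 2
   datasets become metaGEPs, so every reported program is reproducible
   across studies by construction.
3. **Projection and cohort testing.** The fixed metaGEP spectra are
   projected onto every cell by nonnegative least squares; each cell gets
   a predominant program; per-sample program fractions (samples with
   ≥ 20 cells) are compared Young vs Aged with two-sided Mann–Whitney
   tests, Bonferroni-corrected.

Supporting machinery: per-sample QC (gene/count filters with a
median ± 2.5·MAD depth window), shared variable-gene selection with
ribosomal exclusion, preranked GSEA with seedable permutation nulls and
expression-matched random gene-set controls, gene-set recoverability
rates over cNMF runs, TF-activity rank aggregation (mean rank ≤ 10, mean
r ≥ 0.15 selection), Fisher/hypergeometric overlap tests, and a synthetic
multi-dataset generator with planted programs that exercises every stage
offline.

The package is aimed at computational biologists analyzing multi-study
single-cell cohorts — HSC aging in the motivating case, but nothing in
the machinery is tissue-specific.

## Worked example

```r
library(metaGEP)

truth <- generateTruth(truthConfig(seed = 1))   # 3 datasets, 44 samples
sim   <- simulateCounts(truth)                  # per-sample sparse counts

res <- discoverMetaGEPs(sim$samples, nTop = 150, minDatasetsVar = 2,
                        kRange = 3:5, nReplicates = 100, seed = 1)
res$metageps
#> MetaGEPSet: 4 metaGEPs over 132 genes
#>   metaGEP1: 22 programs, 22 samples, 3 datasets
#>   metaGEP2: 22 programs, 22 samples, 3 datasets
#>   metaGEP3: 22 programs, 22 samples, 3 datasets
#>   metaGEP4: 22 programs, 22 samples, 3 datasets
```

Exactly four meta-programs are recovered, each supported by all 22
discovery-eligible samples from all three synthetic datasets — the four
planted programs. Projecting the fixed spectra back onto all cells and
testing predominant-program fractions between cohorts:

```r
counts <- do.call(cbind, lapply(sim$samples, function(s)
    SummarizedExperiment::assay(s, "counts")))
u   <- projectUsages(counts, metagepExpressionMatrix(res$metageps))
lab <- predominantProgram(u)
cohortFractionTest(lab,
                   truth@cellMeta$sample_id[match(rownames(u),
                                                  truth@cellMeta$barcode)],
                   truth@config@samples, minCells = 20)
#> CohortTestResult (samples with >= 20 cells):
#>   metagep n_young n_aged     U        p_raw       p_bonf
#>  metaGEP1      27     17   6.0 7.270320e-08 2.908128e-07
#>  metaGEP2      27     17   2.5 4.578854e-08 1.831542e-07
#>  metaGEP3      27     17   0.0 3.310775e-08 1.324310e-07
#>  metaGEP4      27     17 459.0 3.318134e-08 1.327254e-07
```

With the default 3× planted usage boost, the program matching the planted
aging program (metaGEP4 here: U = 459 = 27 × 17, complete separation
toward Aged) expands strongly in the aged cohort. Because
predominant-program fractions are compositional — they sum to 1 within
each sample — the three lineage programs shift correspondingly toward
Young, so all four Bonferroni-adjusted p-values are small; the direction
of each shift (the U statistic) identifies which program expands with
age.

The headline single-number check in the package reproduces the published
mouse/human aging-signature ortholog overlap:

```r
fisherOverlap(7, 119, 111, 11409)   # background 11,646 genes
#> $odds_ratio      6.043661
#> $p               0.0002864949
```

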