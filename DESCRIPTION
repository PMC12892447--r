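Package: metaGEP
Title: Consensus NMF Meta-Programs and Age-Associated Program Abundance in
    Single-Cell Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers recurrent gene expression programs (GEPs) in
    single-cell RNA-seq by per-sample consensus non-negative matrix
    factorization, clusters program Z-score spectra across samples and
    datasets into meta-programs (metaGEPs), projects fixed meta-program
    spectra onto cells by non-negative least squares, and tests cohort
    differences in predominant-program abundance. Includes per-sample QC
    and shared variable-gene selection, preranked GSEA with
    expression-matched random gene-set nulls, program-recoverability
    analysis, transcription-factor activity rank aggregation, Fisher
    ortholog-overlap testing, and a multi-dataset synthetic single-cell
    generator with planted programs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    cluster,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: SingleCell, GeneExpression, Transcriptomics, Clustering,
    DimensionReduction, GeneSetEnrichment
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'qc.R'
    'cnmf.R'
    'enrichment.R'
    'io.R'
    'metaGEP-package.R'
    'metagep.R'
    'usage.R'
    'pipeline.R'
    'synthetic.R'
    'tf.R'
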