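#' @import methods
#' @importFrom stats median quantile sd var cor kmeans p.adjust phyper
#'   fisher.test wilcox.test rnorm runif rpois rnbinom rgamma setNames
#'   complete.cases
#' @importFrom utils head read.delim write.table
NULL

#' Configuration of the synthetic multi-dataset study design
#'
#' A \code{TruthConfig} fixes every knob of the synthetic single-cell
#' generator: the gene universe, the number of planted expression programs,
#' the multi-dataset sample layout with Young/Aged cohorts, the strength of
#' the planted aging effect, dataset-level batch variation, and library-size
#' distribution. The defaults (see \code{\link{truthConfig}}) emulate a
#' multi-study human HSC aging design: 3 datasets, 4 programs (one aging
#' program plus three lineage programs), 27 Young and 17 Aged samples of
#' which 22 have at least 100 cells.
#'
#' @slot nGenes number of genes in the universe.
#' @slot nPrograms number of planted programs (>= 2).
#' @slot nAnchors number of disjoint anchor genes per program (>= 20).
#' @slot samples data.frame with columns \code{sample_id}, \code{dataset_id},
#'   \code{cohort} (\code{"Young"}/\code{"Aged"}), \code{n_cells},
#'   \code{age}, \code{sex}.
#' @slot agedBoost multiplier (>= 1) applied to the aging program's Dirichlet
#'   concentration in Aged samples.
#' @slot batchSd lognormal sigma of dataset-level multiplicative gene factors.
#' @slot libsizeMu,libsizeSd lognormal meanlog/sdlog of per-cell depth.
#' @slot nbDispersion optional negative-binomial dispersion (1/size); length
#'   zero means Poisson counts.
#' @slot seed integer RNG seed (R's default Mersenne-Twister generator).
#' @exportClass TruthConfig
setClass("TruthConfig", slots = c(
    nGenes = "integer", nPrograms = "integer", nAnchors = "integer",
    samples = "data.frame", agedBoost = "numeric", batchSd = "numeric",
    libsizeMu = "numeric", libsizeSd = "numeric", nbDispersion = "numeric",
    seed = "integer"))

setValidity("TruthConfig", function(object) {
    msg <- character()
    if (object@nPrograms < 2L) msg <- c(msg, "nPrograms must be >= 2")
    if (object@nAnchors < 20L) msg <- c(msg, "nAnchors must be >= 20")
    if (object@nPrograms * object@nAnchors > object@nGenes)
        msg <- c(msg, "nPrograms * nAnchors exceeds nGenes")
    need <- c("sample_id", "dataset_id", "cohort", "n_cells")
    if (!all(need %in% names(object@samples)))
        msg <- c(msg, paste("samples must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (any(object@samples$n_cells < 1L))
            msg <- c(msg, "all n_cells must be >= 1")
        if (!all(object@samples$cohort %in% c("Young", "Aged")))
            msg <- c(msg, "cohort must be 'Young' or 'Aged'")
        if (anyDuplicated(object@samples$sample_id))
            msg <- c(msg, "sample_id values must be unique")
    }
    if (object@agedBoost < 1) msg <- c(msg, "agedBoost must be >= 1")
    if (object@batchSd < 0) msg <- c(msg, "batchSd must be >= 0")
    if (length(object@nbDispersion) && object@nbDispersion <= 0)
        msg <- c(msg, "nbDispersion must be positive when given")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic study
#'
#' Holds the planted program spectra (rows sum to 1), the per-cell usage
#' matrix (rows sum to 1), program labels with one program flagged as the
#' aging program, per-program signature gene sets (the anchor genes), and
#' the names of decoy ribosomal-like genes (RPS/RPL prefixes).
#'
#' @slot spectra nPrograms x nGenes nonnegative matrix; rows sum to 1.
#' @slot usages nCells x nPrograms nonnegative matrix; rows sum to 1.
#' @slot cellMeta data.frame per cell: barcode, sample_id, dataset_id, cohort.
#' @slot programLabels character labels, one per program.
#' @slot agingProgram the label of the planted aging program.
#' @slot signatureSets named list of character vectors (anchor genes).
#' @slot decoyRibosomalGenes character; names starting with RPS/RPL.
#' @slot config the originating \linkS4class{TruthConfig}.
#' @exportClass GroundTruth
setClass("GroundTruth", slots = c(
    spectra = "matrix", usages = "matrix", cellMeta = "data.frame",
    programLabels = "character", agingProgram = "character",
    signatureSets = "list", decoyRibosomalGenes = "character",
    config = "TruthConfig"))

setValidity("GroundTruth", function(object) {
    msg <- character()
    if (any(object@spectra < 0)) msg <- c(msg, "spectra must be nonnegative")
    if (any(abs(rowSums(object@spectra) - 1) > 1e-9))
        msg <- c(msg, "spectrum rows must sum to 1 within 1e-9")
    if (any(object@usages < 0)) msg <- c(msg, "usages must be nonnegative")
    if (any(abs(rowSums(object@usages) - 1) > 1e-9))
        msg <- c(msg, "usage rows must sum to 1 within 1e-9")
    if (nrow(object@usages) != nrow(object@cellMeta))
        msg <- c(msg, "usages and cellMeta disagree on cell count")
    if (!object@agingProgram %in% object@programLabels)
        msg <- c(msg, "agingProgram must be one of programLabels")
    if (length(msg)) msg else TRUE
})

#' Per-sample QC parameters
#'
#' Cells are kept when they have at least \code{minGenesPerCell} detected
#' genes and a total count inside the sample-specific window
#' \code{median +/- madMultiplier * MAD} of per-cell totals (or inside
#' \code{fixedCountWindow} when given, the override used for samples whose
#' depth distribution has extreme outliers). Genes are then kept when
#' expressed in at least \code{minCellsPerGene} remaining cells. "MAD" is by
#' default the mean absolute deviation from the median; set
#' \code{madType = "median"} for the median absolute deviation.
#'
#' @slot minGenesPerCell minimum detected genes per cell (default 50).
#' @slot minCellsPerGene minimum cells expressing a kept gene (default 10).
#' @slot madMultiplier window half-width in MAD units (default 2.5).
#' @slot madType "mean" (mean |x - median|) or "median" (stats::mad-like).
#' @slot fixedCountWindow optional numeric(2) [low, high] override.
#' @exportClass QCParams
setClass("QCParams", slots = c(
    minGenesPerCell = "integer", minCellsPerGene = "integer",
    madMultiplier = "numeric", madType = "character",
    fixedCountWindow = "numeric"))

setValidity("QCParams", function(object) {
    msg <- character()
    if (object@minGenesPerCell < 0) msg <- c(msg, "minGenesPerCell must be >= 0")
    if (object@madMultiplier <= 0) msg <- c(msg, "madMultiplier must be > 0")
    if (!object@madType %in% c("mean", "median"))
        msg <- c(msg, "madType must be 'mean' or 'median'")
    if (length(object@fixedCountWindow) &&
        (length(object@fixedCountWindow) != 2L ||
         object@fixedCountWindow[1] >= object@fixedCountWindow[2]))
        msg <- c(msg, "fixedCountWindow must be numeric(2) with low < high")
    if (length(msg)) msg else TRUE
})

#' Variance-scaled input for consensus NMF
#'
#' Counts restricted to the shared variable-gene list with each gene scaled
#' to unit variance (no centering, preserving nonnegativity). Also carries
#' the per-gene scale factors (count-space standard deviations) needed to
#' re-express spectra in expression units, and the log-normalized matrix
#' used for Z-score spectra.
#'
#' @slot X cells x genes nonnegative variance-scaled matrix.
#' @slot geneSd per-gene count-space standard deviations (scale factors).
#' @slot logNorm cells x genes log1p(CP10K) matrix on the same genes.
#' @slot sampleId,datasetId provenance strings.
#' @exportClass CnmfInput
setClass("CnmfInput", slots = c(
    X = "matrix", geneSd = "numeric", logNorm = "matrix",
    sampleId = "character", datasetId = "character"))

#' Replicated NMF factorizations of one sample
#'
#' @slot k number of programs per replicate.
#' @slot spectra (nReplicates * k) x G matrix of L2-normalized component
#'   spectra (rows grouped by replicate).
#' @slot objective final relative Frobenius reconstruction error of each
#'   replicate.
#' @slot replicateSeeds the seeds used, one per replicate.
#' @exportClass FactorizationRun
setClass("FactorizationRun", slots = c(
    k = "integer", spectra = "matrix", objective = "numeric",
    replicateSeeds = "integer"))

setValidity("FactorizationRun", function(object) {
    msg <- character()
    if (any(object@spectra < 0)) msg <- c(msg, "spectra must be nonnegative")
    if (nrow(object@spectra) != length(object@replicateSeeds) * object@k)
        msg <- c(msg, "replicate count * k must equal spectra row count")
    if (length(msg)) msg else TRUE
})

#' Consensus NMF result for one sample at one k
#'
#' Component spectra from all replicates are density-filtered (mean
#' Euclidean distance to the K nearest neighbors on L2-normalized spectra,
#' K = floor(0.3 * nReplicates), must not exceed \code{distThreshold}),
#' clustered into k groups by k-means, and summarized by cluster-wise
#' medians. Usages are refit by nonnegative least squares; stability is the
#' mean silhouette width of the component clustering; error is the relative
#' Frobenius reconstruction error of the refit.
#'
#' @slot k number of consensus programs.
#' @slot distThreshold the density-filter threshold used.
#' @slot keptComponentMask logical over replicate components.
#' @slot spectraScaled k x G medians in the variance-scaled input space.
#' @slot spectraTpm k x G spectra re-expressed in normalized-expression
#'   units (rows sum to 1e4).
#' @slot spectraZ k x G Z-score spectra (OLS of z-scored log-normalized
#'   expression on normalized usages).
#' @slot usages cells x k nonnegative refit usages.
#' @slot stability mean silhouette width in [-1, 1].
#' @slot error relative Frobenius reconstruction error (>= 0).
#' @slot geneNames,cellNames dimension names.
#' @slot sampleId,datasetId provenance strings.
#' @exportClass ConsensusResult
setClass("ConsensusResult", slots = c(
    k = "integer", distThreshold = "numeric", keptComponentMask = "logical",
    spectraScaled = "matrix", spectraTpm = "matrix", spectraZ = "matrix",
    usages = "matrix", stability = "numeric", error = "numeric",
    geneNames = "character", cellNames = "character",
    sampleId = "character", datasetId = "character"))

setValidity("ConsensusResult", function(object) {
    msg <- character()
    if (any(object@spectraTpm < 0))
        msg <- c(msg, "consensus expression spectra must be nonnegative")
    if (any(object@usages < 0)) msg <- c(msg, "usages must be nonnegative")
    if (length(object@stability) &&
        (object@stability < -1 - 1e-9 || object@stability > 1 + 1e-9))
        msg <- c(msg, "stability must lie in [-1, 1]")
    if (length(object@error) && object@error < 0)
        msg <- c(msg, "error must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Catalog of per-sample programs pooled across samples and datasets
#'
#' All spectra share one gene order (programs whose sample-level QC dropped
#' a gene carry 0 there).
#'
#' @slot info data.frame: program_id, sample_id, dataset_id, k.
#' @slot zSpectra P x G matrix of Z-score spectra.
#' @slot tpmSpectra P x G matrix of expression-space spectra.
#' @slot geneNames shared gene order.
#' @exportClass ProgramCatalog
setClass("ProgramCatalog", slots = c(
    info = "data.frame", zSpectra = "matrix", tpmSpectra = "matrix",
    geneNames = "character"))

setValidity("ProgramCatalog", function(object) {
    msg <- character()
    if (anyDuplicated(object@info$program_id))
        msg <- c(msg, "program_id values must be unique")
    if (nrow(object@zSpectra) != nrow(object@info) ||
        nrow(object@tpmSpectra) != nrow(object@info))
        msg <- c(msg, "spectra row counts must match info")
    if (ncol(object@zSpectra) != length(object@geneNames))
        msg <- c(msg, "zSpectra columns must match geneNames")
    if (length(msg)) msg else TRUE
})

#' A set of meta-programs (metaGEPs)
#'
#' Each metaGEP is a retained cluster of per-sample programs carrying at
#' least \code{minPrograms} members from at least \code{minDatasets}
#' datasets, summarized by the arithmetic mean of member Z-score spectra and
#' of member expression-space spectra.
#'
#' @slot assignments data.frame: program_id, sample_id, dataset_id,
#'   metagep, r_to_centroid.
#' @slot meanZ M x G mean Z-score spectra.
#' @slot meanTpm M x G mean expression-space spectra.
#' @slot geneNames shared gene order.
#' @slot params list of the clustering parameters used.
#' @exportClass MetaGEPSet
setClass("MetaGEPSet", slots = c(
    assignments = "data.frame", meanZ = "matrix", meanTpm = "matrix",
    geneNames = "character", params = "list"))

setValidity("MetaGEPSet", function(object) {
    msg <- character()
    if (nrow(object@meanZ) != nrow(object@meanTpm))
        msg <- c(msg, "meanZ and meanTpm must have the same row count")
    if (nrow(object@meanZ) &&
        !all(object@assignments$metagep %in% rownames(object@meanZ)))
        msg <- c(msg, "assignments reference unknown metaGEPs")
    if (length(msg)) msg else TRUE
})

#' Cohort abundance test result
#'
#' Per-sample predominant-program fractions and per-metaGEP two-sided
#' Mann-Whitney statistics comparing Young vs Aged fractions, with
#' Bonferroni adjustment over the number of metaGEPs.
#'
#' @slot fractions data.frame: sample_id, cohort, metagep, fraction, n_cells.
#' @slot stats data.frame: metagep, n_young, n_aged, U, p_raw, p_bonf.
#' @slot minCells the included-sample rule used.
#' @exportClass CohortTestResult
setClass("CohortTestResult", slots = c(
    fractions = "data.frame", stats = "data.frame", minCells = "integer"))

setValidity("CohortTestResult", function(object) {
    msg <- character()
    fr <- object@fractions$fraction
    if (length(fr) && (any(fr < -1e-12) || any(fr > 1 + 1e-12)))
        msg <- c(msg, "fractions must lie in [0, 1]")
    st <- object@stats
    if (nrow(st) && any(st$p_bonf + 1e-12 < st$p_raw))
        msg <- c(msg, "adjusted p must be >= raw p")
    if (length(msg)) msg else TRUE
})

#' TF-activity association result
#'
#' Per-TF per-dataset correlations with a target (binary cohort or
#' meta-program usage), within-dataset ranks (rank 1 = largest correlation,
#' ties averaged), their across-dataset means, and the selection flag
#' (mean rank <= rankMax and mean correlation >= rMin).
#'
#' @slot r TF x dataset correlation matrix (NA where undefined).
#' @slot ranks TF x dataset rank matrix.
#' @slot table data.frame: tf, mean_rank, mean_r, selected.
#' @slot params list(rankMax, rMin, absRank).
#' @exportClass TFAssociation
setClass("TFAssociation", slots = c(
    r = "matrix", ranks = "matrix", table = "data.frame", params = "list"))
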