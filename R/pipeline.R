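#' @include AllClasses.R qc.R cnmf.R metagep.R usage.R
NULL

#' Samples eligible for program discovery
#'
#' Programs are discovered only in samples with at least \code{minCells}
#' cells (small samples yield unstable factorizations); smaller samples
#' still contribute to usage projection and abundance testing.
#'
#' @param samples named list of \code{SingleCellExperiment}s.
#' @param minCells eligibility threshold (default 100).
#' @return the eligible subset of \code{samples}.
#' @export
discoveryEligible <- function(samples, minCells = 100L) {
    Filter(function(s) ncol(s) >= minCells, samples)
}

#' End-to-end meta-program discovery
#'
#' Runs the full discovery pipeline on a multi-dataset collection of
#' per-sample count matrices: per-sample QC
#' (\code{\link{qcFilterSample}}), shared variable-gene selection across
#' datasets (\code{\link{selectSharedVariableGenes}}), per-sample
#' consensus NMF over a k grid with automatic k selection and the
#' usage-ratio program filter (\code{\link{runCnmfSample}}), pooling into
#' a program catalog, iterative Z-spectra clustering
#' (\code{\link{clusterPrograms}}) and the metaGEP membership rules
#' (\code{\link{defineMetaGEPs}}).
#'
#' @param samples named list of \code{SingleCellExperiment}s (counts
#'   assay; colData columns sample_id, dataset_id).
#' @param qc \linkS4class{QCParams} for the per-sample filter.
#' @param nTop,minDatasetsVar variable-gene parameters (per-dataset top
#'   list size and the minimum datasets a gene must be variable in).
#' @param kRange k grid for per-sample consensus NMF.
#' @param nReplicates NMF restarts per k.
#' @param distThreshold consensus density-filter threshold.
#' @param maxUsageRatio q100/q75 program-exclusion threshold.
#' @param corrThresh,pctThresh iterative-clustering thresholds.
#' @param minPrograms,minDatasets metaGEP membership rules.
#' @param minCellsDiscovery per-sample cell minimum for discovery.
#' @param seed integer base seed.
#' @return list: \code{metageps} (\linkS4class{MetaGEPSet}),
#'   \code{catalog}, \code{perSample} (per-sample \code{runCnmfSample}
#'   output), \code{varGenes}, \code{eligibleSamples}.
#' @export
discoverMetaGEPs <- function(samples, qc = qcParams(), nTop = 3000L,
                             minDatasetsVar = 4L, kRange = 3:10,
                             nReplicates = 100L, distThreshold = 0.1,
                             maxUsageRatio = 10, corrThresh = 0.1,
                             pctThresh = 0.1, minPrograms = 4L,
                             minDatasets = 2L, minCellsDiscovery = 100L,
                             seed = 1L) {
    eligible <- discoveryEligible(samples, minCellsDiscovery)
    if (!length(eligible)) stop("no sample passes the discovery ",
                                "cell-count rule")
    byDataset <- split(seq_along(samples), vapply(samples, function(s)
        as.character(s$dataset_id[1]), character(1)))
    datasets <- lapply(byDataset, function(idx)
        do.call(cbind, lapply(samples[idx], function(s)
            SummarizedExperiment::assay(s, "counts"))))
    varGenes <- selectSharedVariableGenes(datasets, nTop = nTop,
                                          minDatasets = minDatasetsVar)
    perSample <- vector("list", length(eligible))
    names(perSample) <- names(eligible)
    for (i in seq_along(eligible)) {
        filtered <- qcFilterSample(eligible[[i]], qc)
        input <- prepareCnmfInput(filtered, varGenes)
        perSample[[i]] <- runCnmfSample(
            input, kRange = kRange, nReplicates = nReplicates,
            distThreshold = distThreshold, maxUsageRatio = maxUsageRatio,
            seed = .childSeed(seed, i))
    }
    catalog <- buildProgramCatalog(lapply(perSample, `[[`, "programs"),
                                   geneOrder = varGenes)
    clusters <- clusterPrograms(catalog, corrThresh = corrThresh,
                                pctThresh = pctThresh)
    metageps <- defineMetaGEPs(catalog, clusters, minPrograms = minPrograms,
                               minDatasets = minDatasets,
                               corrThresh = corrThresh)
    list(metageps = metageps, catalog = catalog, perSample = perSample,
         varGenes = varGenes, eligibleSamples = names(eligible))
}
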