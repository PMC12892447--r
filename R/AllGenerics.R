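#' @include AllClasses.R
NULL

#' Accessors for metaGEP classes
#'
#' Small accessor family: \code{consensusSpectra} returns program spectra of
#' a \linkS4class{ConsensusResult} or \linkS4class{MetaGEPSet} in the
#' requested space, \code{consensusUsages} the (optionally row-normalized)
#' usage matrix, \code{stabilityScore} and \code{reconError} the k-selection
#' diagnostics, \code{truthSpectra}/\code{truthUsages}/\code{signatureSets}
#' the planted ground truth, and \code{metagepAssignments} the program
#' membership table.
#'
#' @param x the object.
#' @param type for spectra: one of \code{"tpm"} (normalized-expression
#'   units), \code{"z"} (Z-score spectra) or \code{"scaled"}
#'   (variance-scaled input space; \code{ConsensusResult} only).
#' @param normalized for \code{consensusUsages}: renormalize rows to sum 1.
#' @return a matrix (spectra, usages) or data.frame (assignments), numeric
#'   scalar for the diagnostics.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("consensusSpectra", function(x, type = c("tpm", "z", "scaled"))
    standardGeneric("consensusSpectra"))

#' @rdname accessors
#' @export
setGeneric("consensusUsages", function(x, normalized = TRUE)
    standardGeneric("consensusUsages"))

#' @rdname accessors
#' @export
setGeneric("stabilityScore", function(x) standardGeneric("stabilityScore"))

#' @rdname accessors
#' @export
setGeneric("reconError", function(x) standardGeneric("reconError"))

#' @rdname accessors
#' @export
setGeneric("truthSpectra", function(x) standardGeneric("truthSpectra"))

#' @rdname accessors
#' @export
setGeneric("truthUsages", function(x) standardGeneric("truthUsages"))

#' @rdname accessors
#' @export
setGeneric("signatureSets", function(x) standardGeneric("signatureSets"))

#' @rdname accessors
#' @export
setGeneric("metagepAssignments", function(x)
    standardGeneric("metagepAssignments"))

#' @rdname accessors
#' @export
setMethod("consensusSpectra", "ConsensusResult", function(x, type) {
    type <- match.arg(type, c("tpm", "z", "scaled"))
    m <- switch(type, tpm = x@spectraTpm, z = x@spectraZ,
                scaled = x@spectraScaled)
    colnames(m) <- x@geneNames
    m
})

#' @rdname accessors
#' @export
setMethod("consensusSpectra", "MetaGEPSet", function(x, type) {
    type <- match.arg(type, c("tpm", "z"))
    m <- if (type == "tpm") x@meanTpm else x@meanZ
    colnames(m) <- x@geneNames
    m
})

#' @rdname accessors
#' @export
setMethod("consensusUsages", "ConsensusResult", function(x, normalized) {
    u <- x@usages
    if (normalized) {
        rs <- rowSums(u)
        rs[rs == 0] <- 1
        u <- u / rs
    }
    rownames(u) <- x@cellNames
    u
})

#' @rdname accessors
#' @export
setMethod("stabilityScore", "ConsensusResult", function(x) x@stability)

#' @rdname accessors
#' @export
setMethod("reconError", "ConsensusResult", function(x) x@error)

#' @rdname accessors
#' @export
setMethod("truthSpectra", "GroundTruth", function(x) x@spectra)

#' @rdname accessors
#' @export
setMethod("truthUsages", "GroundTruth", function(x) x@usages)

#' @rdname accessors
#' @export
setMethod("signatureSets", "GroundTruth", function(x) x@signatureSets)

#' @rdname accessors
#' @export
setMethod("metagepAssignments", "MetaGEPSet", function(x) x@assignments)

setMethod("show", "TruthConfig", function(object) {
    s <- object@samples
    cat("TruthConfig:", object@nGenes, "genes,", object@nPrograms,
        "programs,", length(unique(s$dataset_id)), "datasets\n")
    cat("  samples:", nrow(s), sprintf("(%d Young / %d Aged)",
        sum(s$cohort == "Young"), sum(s$cohort == "Aged")), "\n")
    cat("  agedBoost:", object@agedBoost, " batchSd:", object@batchSd,
        " seed:", object@seed, "\n")
})

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", ncol(object@spectra), "genes,",
        nrow(object@spectra), "programs (aging =", object@agingProgram,
        "),", nrow(object@usages), "cells\n")
})

setMethod("show", "ConsensusResult", function(object) {
    cat(sprintf(
        "ConsensusResult: sample %s, k = %d, stability = %.3f, error = %.3f\n",
        object@sampleId, object@k, object@stability, object@error))
    cat(sprintf("  %d/%d replicate components kept at distance threshold %g\n",
        sum(object@keptComponentMask), length(object@keptComponentMask),
        object@distThreshold))
})

setMethod("show", "ProgramCatalog", function(object) {
    cat("ProgramCatalog:", nrow(object@info), "programs from",
        length(unique(object@info$sample_id)), "samples /",
        length(unique(object@info$dataset_id)), "datasets,",
        length(object@geneNames), "genes\n")
})

setMethod("show", "MetaGEPSet", function(object) {
    cat("MetaGEPSet:", nrow(object@meanZ), "metaGEPs over",
        length(object@geneNames), "genes\n")
    if (nrow(object@assignments)) {
        tab <- table(object@assignments$metagep)
        for (m in rownames(object@meanZ)) {
            d <- object@assignments[object@assignments$metagep == m, ]
            cat(sprintf("  %s: %d programs, %d samples, %d datasets\n", m,
                nrow(d), length(unique(d$sample_id)),
                length(unique(d$dataset_id))))
        }
    }
})

setMethod("show", "CohortTestResult", function(object) {
    cat("CohortTestResult (samples with >=", object@minCells, "cells):\n")
    print(object@stats, row.names = FALSE)
})

setMethod("show", "TFAssociation", function(object) {
    sel <- object@table$tf[object@table$selected]
    cat("TFAssociation:", nrow(object@table), "TFs across",
        ncol(object@r), "datasets;", length(sel), "selected\n")
    if (length(sel)) cat("  selected:", paste(sel, collapse = ", "), "\n")
})
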