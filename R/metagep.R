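#' @include AllClasses.R cnmf.R
NULL

#' Pool per-sample programs into a catalog
#'
#' Collects the (usage-ratio-filtered) consensus programs of many samples
#' onto one shared gene order. Genes missing from a sample's spectra
#' (dropped by that sample's QC) are filled with 0. Zero-variance Z-score
#' spectra are excluded with a warning.
#'
#' @param results list of \linkS4class{ConsensusResult} (typically the
#'   \code{$programs} element of \code{\link{runCnmfSample}} per sample).
#' @param geneOrder shared gene order (default: union of all spectra gene
#'   names, sorted).
#' @return a \linkS4class{ProgramCatalog}.
#' @export
buildProgramCatalog <- function(results, geneOrder = NULL) {
    results <- Filter(function(r) nrow(r@spectraZ) > 0, results)
    if (!length(results)) stop("no programs to catalog")
    if (is.null(geneOrder))
        geneOrder <- sort(unique(unlist(lapply(results,
                                               function(r) r@geneNames))))
    rows <- list()
    info <- list()
    for (r in results) {
        idx <- match(r@geneNames, geneOrder)
        for (p in seq_len(nrow(r@spectraZ))) {
            z <- numeric(length(geneOrder))
            z[idx] <- r@spectraZ[p, ]
            tpm <- numeric(length(geneOrder))
            tpm[idx] <- r@spectraTpm[p, ]
            if (sd(z) == 0) {
                warning("zero-variance Z spectrum excluded (sample ",
                        r@sampleId, ")")
                next
            }
            rows[[length(rows) + 1L]] <- list(z = z, tpm = tpm)
            info[[length(info) + 1L]] <- data.frame(
                program_id = sprintf("%s_k%d_p%d", r@sampleId, r@k, p),
                sample_id = r@sampleId, dataset_id = r@datasetId,
                k = r@k, stringsAsFactors = FALSE)
        }
    }
    if (!length(rows)) stop("no programs with non-degenerate Z spectra")
    info <- do.call(rbind, info)
    z <- do.call(rbind, lapply(rows, `[[`, "z"))
    tpm <- do.call(rbind, lapply(rows, `[[`, "tpm"))
    rownames(z) <- rownames(tpm) <- info$program_id
    colnames(z) <- colnames(tpm) <- geneOrder
    new("ProgramCatalog", info = info, zSpectra = z, tpmSpectra = tpm,
        geneNames = geneOrder)
}

#' Iteratively cluster program Z-score spectra across samples
#'
#' Agglomerative average-linkage clustering on the Pearson correlation
#' between Z-score spectra: starting from singleton clusters, the pair of
#' clusters with the highest average pairwise member correlation is merged
#' repeatedly until no pair reaches \code{corrThresh}. A cluster is
#' returned when it holds at least two programs and represents at least
#' \code{pctThresh} of the contributing samples. With
#' \code{allowMultiplePerSample = FALSE} only the program best correlated
#' with the cluster's mean spectrum is kept per sample. Merge ties are
#' broken lexicographically by program_id, and programs are sorted before
#' clustering, so runs are deterministic and invariant to input order.
#'
#' Average linkage (rather than a centroid-membership fixed point) is used
#' deliberately: a low threshold such as 0.1 makes centroid-absorption
#' procedures unstable -- a few spuriously correlated programs drag the
#' centroid toward the midpoint of two distinct program families, after
#' which both families join a single runaway cluster. Under average
#' linkage two families merge only if their \emph{average} mutual
#' correlation clears the threshold, which is robust at the same
#' threshold values.
#'
#' @param catalog a \linkS4class{ProgramCatalog}.
#' @param corrThresh correlation threshold for continuing to merge
#'   (default 0.1).
#' @param pctThresh minimum fraction of contributing samples a retained
#'   cluster must span (default 0.1).
#' @param allowMultiplePerSample allow several programs of one sample in a
#'   cluster (default TRUE).
#' @return list of character vectors of program_ids (retained clusters,
#'   largest first).
#' @export
clusterPrograms <- function(catalog, corrThresh = 0.1, pctThresh = 0.1,
                            allowMultiplePerSample = TRUE) {
    Z <- catalog@zSpectra
    if (nrow(Z) < 2) stop("need at least 2 programs")
    if (!all(is.finite(Z))) stop("spectra must be finite")
    info <- catalog@info
    nSamples <- length(unique(info$sample_id))
    ord <- order(rownames(Z))  # lexicographic order fixes all tie-breaks
    Z <- Z[ord, , drop = FALSE]
    info <- info[ord, , drop = FALSE]
    rownames(info) <- info$program_id
    sim <- suppressWarnings(cor(t(Z)))
    sim[is.na(sim)] <- -Inf
    diag(sim) <- -Inf
    members <- as.list(rownames(Z))
    sizes <- rep(1L, nrow(Z))
    active <- rep(TRUE, nrow(Z))
    while (sum(active) > 1) {
        simA <- sim
        simA[!active, ] <- -Inf
        simA[, !active] <- -Inf
        best <- max(simA)
        if (best < corrThresh) break
        hit <- which(simA == best, arr.ind = TRUE)
        i <- min(hit[1, ])
        j <- max(hit[1, ])
        ## Lance-Williams update for average linkage on similarities
        newSim <- (sizes[i] * sim[i, ] + sizes[j] * sim[j, ]) /
            (sizes[i] + sizes[j])
        sim[i, ] <- newSim
        sim[, i] <- newSim
        sim[i, i] <- -Inf
        active[j] <- FALSE
        members[[i]] <- sort(c(members[[i]], members[[j]]))
        sizes[i] <- sizes[i] + sizes[j]
    }
    clusters <- members[active & sizes >= 2L]
    if (!allowMultiplePerSample) {
        clusters <- lapply(clusters, function(m) {
            cen <- colMeans(Z[m, , drop = FALSE])
            r <- suppressWarnings(cor(t(Z[m, , drop = FALSE]), cen))[, 1]
            keep <- vapply(split(m, info[m, "sample_id"]), function(ids)
                ids[which.max(r[ids])], character(1))
            sort(unname(keep))
        })
    }
    clusters <- Filter(function(m)
        length(unique(info[m, "sample_id"])) / nSamples >= pctThresh,
        clusters)
    clusters[order(-lengths(clusters),
                   vapply(clusters, `[`, character(1), 1))]
}

#' Define meta-programs from program clusters
#'
#' Clusters carrying fewer than \code{minPrograms} members or spanning
#' fewer than \code{minDatasets} datasets are dropped. For survivors the
#' mean Z-score spectrum and mean expression-space spectrum are the
#' arithmetic means over members.
#'
#' @param catalog the \linkS4class{ProgramCatalog} the clusters index into.
#' @param clusters output of \code{\link{clusterPrograms}}.
#' @param minPrograms minimum members per metaGEP (default 4).
#' @param minDatasets minimum datasets represented (default 2).
#' @param corrThresh recorded for provenance (default 0.1).
#' @return a \linkS4class{MetaGEPSet} (possibly with zero metaGEPs).
#' @export
defineMetaGEPs <- function(catalog, clusters, minPrograms = 4L,
                           minDatasets = 2L, corrThresh = 0.1) {
    info <- catalog@info
    rownames(info) <- info$program_id
    keep <- Filter(function(m)
        length(m) >= minPrograms &&
        length(unique(info[m, "dataset_id"])) >= minDatasets, clusters)
    G <- length(catalog@geneNames)
    meanZ <- matrix(0, length(keep), G)
    meanTpm <- matrix(0, length(keep), G)
    assignments <- list()
    for (i in seq_along(keep)) {
        m <- keep[[i]]
        meanZ[i, ] <- colMeans(catalog@zSpectra[m, , drop = FALSE])
        meanTpm[i, ] <- colMeans(catalog@tpmSpectra[m, , drop = FALSE])
        assignments[[i]] <- data.frame(
            program_id = m, sample_id = info[m, "sample_id"],
            dataset_id = info[m, "dataset_id"],
            metagep = sprintf("metaGEP%d", i),
            r_to_centroid = as.numeric(suppressWarnings(
                cor(t(catalog@zSpectra[m, , drop = FALSE]), meanZ[i, ]))),
            stringsAsFactors = FALSE)
    }
    assignments <- if (length(assignments)) do.call(rbind, assignments)
        else data.frame(program_id = character(), sample_id = character(),
                        dataset_id = character(), metagep = character(),
                        r_to_centroid = numeric())
    rownames(assignments) <- NULL
    ids <- sprintf("metaGEP%d", seq_along(keep))
    dimnames(meanZ) <- list(ids, catalog@geneNames)
    dimnames(meanTpm) <- list(ids, catalog@geneNames)
    new("MetaGEPSet", assignments = assignments, meanZ = meanZ,
        meanTpm = meanTpm, geneNames = catalog@geneNames,
        params = list(minPrograms = minPrograms, minDatasets = minDatasets,
                      corrThresh = corrThresh))
}

#' The metaGEP x gene expression matrix
#'
#' Rows are the mean expression-space spectra of each metaGEP in the
#' declared gene order; this is the fixed-spectra matrix used for usage
#' projection.
#'
#' @param metageps a \linkS4class{MetaGEPSet}.
#' @param geneOrder requested gene order (default: the set's own order);
#'   must be a permutation or subset of the set's genes.
#' @return metaGEP x gene matrix.
#' @export
metagepExpressionMatrix <- function(metageps, geneOrder = NULL) {
    if (!nrow(metageps@meanTpm)) stop("no metaGEPs")
    if (is.null(geneOrder)) return(metageps@meanTpm)
    idx <- match(geneOrder, metageps@geneNames)
    if (anyNA(idx))
        stop("gene-order mismatch: ", sum(is.na(idx)),
             " requested gene(s) absent from the metaGEP set")
    metageps@meanTpm[, idx, drop = FALSE]
}
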