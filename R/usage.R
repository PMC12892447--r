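#' @include AllClasses.R metagep.R
NULL

#' Project fixed metaGEP spectra onto cells
#'
#' Per cell, the variance-scaled expression vector over \code{geneSubset}
#' is decomposed by nonnegative least squares onto the metaGEP spectra
#' (each spectrum rescaled into the same variance-scaled space by dividing
#' by this dataset's per-gene count standard deviation), and the resulting
#' usages are normalized to fractions. All-zero cells get uniform usage
#' with a warning.
#'
#' @param x a \code{SingleCellExperiment} (counts assay) or genes x cells
#'   count matrix.
#' @param metagepMatrix metaGEP x gene expression matrix
#'   (\code{\link{metagepExpressionMatrix}}).
#' @param geneSubset genes to project on (default: all shared genes).
#' @return cells x metaGEP fraction matrix (rows sum to 1).
#' @export
projectUsages <- function(x, metagepMatrix, geneSubset = NULL) {
    counts <- if (methods::is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "counts") else x
    genes <- intersect(colnames(metagepMatrix), rownames(counts))
    if (!is.null(geneSubset)) genes <- intersect(genes, geneSubset)
    if (length(genes) < 2)
        stop("fewer than 2 shared genes between cells and metaGEP matrix")
    counts <- as.matrix(counts[genes, , drop = FALSE])
    sds <- .rowSdsDense(counts)
    sds[sds == 0] <- 1
    Xs <- t(counts / sds)                       # cells x genes, scaled
    S <- metagepMatrix[, genes, drop = FALSE] /
        rep(sds, each = nrow(metagepMatrix))    # spectra in the same space
    u <- nnlsFit(t(S), Xs)
    zero <- rowSums(u) == 0
    if (any(zero)) {
        warning(sum(zero), " cell(s) with all-zero usage set to uniform")
        u[zero, ] <- 1
    }
    u <- u / rowSums(u)
    dimnames(u) <- list(colnames(counts), rownames(metagepMatrix))
    u
}

#' Assign the predominant metaGEP per cell
#'
#' The argmax-usage program per cell; ties go to the lowest metaGEP index
#' (column order).
#'
#' @param u cells x metaGEP usage matrix (normalized or not).
#' @return factor of metaGEP labels, one per cell, with the usage matrix's
#'   column names as levels.
#' @export
predominantProgram <- function(u) {
    idx <- apply(u, 1L, which.max)  # which.max takes the first tie
    factor(colnames(u)[idx], levels = colnames(u))
}

#' Test cohort differences in predominant-program abundance
#'
#' For every sample with at least \code{minCells} cells, the fraction of
#' cells predominated by each metaGEP is computed (fractions per sample sum
#' to 1 across metaGEPs). Per metaGEP, Young and Aged per-sample fractions
#' are compared by a two-sided Mann-Whitney U test -- exact when both
#' cohorts have at most 12 samples and there are no ties, otherwise the
#' normal approximation with continuity and tie correction -- and p-values
#' are Bonferroni-adjusted over the number of metaGEPs.
#'
#' @param labels per-cell predominant program
#'   (\code{\link{predominantProgram}}), named by barcode or aligned to
#'   \code{sampleMeta}.
#' @param cellSamples per-cell sample id, same length as \code{labels}.
#' @param sampleMeta data.frame with columns sample_id, cohort
#'   ("Young"/"Aged").
#' @param minCells included-sample rule (default 20).
#' @return a \linkS4class{CohortTestResult}.
#' @export
cohortFractionTest <- function(labels, cellSamples, sampleMeta,
                               minCells = 20L) {
    stopifnot(length(labels) == length(cellSamples))
    labels <- as.factor(labels)
    tab <- table(sample_id = cellSamples, metagep = labels)
    nCells <- rowSums(tab)
    keep <- names(nCells)[nCells >= minCells]
    cohorts <- stats::setNames(sampleMeta$cohort, sampleMeta$sample_id)
    keep <- keep[!is.na(cohorts[keep])]
    for (coh in c("Young", "Aged"))
        if (sum(cohorts[keep] == coh) < 2)
            stop("cohort '", coh, "' has fewer than 2 samples with >= ",
                 minCells, " cells")
    fr <- sweep(tab[keep, , drop = FALSE], 1L, nCells[keep], "/")
    fractions <- data.frame(
        sample_id = rep(keep, times = ncol(fr)),
        cohort = rep(unname(cohorts[keep]), times = ncol(fr)),
        metagep = rep(colnames(fr), each = length(keep)),
        fraction = as.vector(fr),
        n_cells = rep(unname(nCells[keep]), times = ncol(fr)),
        stringsAsFactors = FALSE)
    programs <- colnames(fr)
    stats <- lapply(programs, function(m) {
        y <- fr[cohorts[keep] == "Young", m]
        a <- fr[cohorts[keep] == "Aged", m]
        useExact <- length(y) <= 12 && length(a) <= 12 &&
            !anyDuplicated(c(y, a))
        wt <- suppressWarnings(wilcox.test(a, y, exact = useExact,
                                           correct = TRUE))
        p <- wt$p.value
        if (is.na(p)) p <- 1  # all observations tied: no evidence
        data.frame(metagep = m, n_young = length(y), n_aged = length(a),
                   U = unname(wt$statistic), p_raw = p,
                   stringsAsFactors = FALSE)
    })
    stats <- do.call(rbind, stats)
    stats$p_bonf <- pmin(1, stats$p_raw * length(programs))
    new("CohortTestResult", fractions = fractions, stats = stats,
        minCells = as.integer(minCells))
}
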