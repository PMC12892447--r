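#' @include AllClasses.R utils.R
NULL

#' Construct per-sample QC parameters
#'
#' @param minGenesPerCell minimum detected genes per cell (default 50).
#' @param minCellsPerGene minimum expressing cells per kept gene
#'   (default 10).
#' @param madMultiplier total-count window half-width in MAD units
#'   (default 2.5).
#' @param madType \code{"mean"} (default; mean absolute deviation from the
#'   median) or \code{"median"} (median absolute deviation).
#' @param fixedCountWindow optional numeric(2) \code{c(low, high)} that
#'   overrides the MAD window (e.g. \code{c(100, 10000)} for samples with
#'   extreme depth outliers).
#' @return a \linkS4class{QCParams}.
#' @export
qcParams <- function(minGenesPerCell = 50L, minCellsPerGene = 10L,
                     madMultiplier = 2.5, madType = c("mean", "median"),
                     fixedCountWindow = NULL) {
    new("QCParams", minGenesPerCell = as.integer(minGenesPerCell),
        minCellsPerGene = as.integer(minCellsPerGene),
        madMultiplier = as.numeric(madMultiplier),
        madType = match.arg(madType),
        fixedCountWindow = if (is.null(fixedCountWindow)) numeric()
                           else as.numeric(fixedCountWindow))
}

#' Per-sample QC filtering of cells then genes
#'
#' Cells are kept iff they detect at least \code{minGenesPerCell} genes and
#' their total count lies inside the window
#' \code{median +/- madMultiplier * MAD} of this sample's per-cell totals
#' (MAD per \code{madType}; \code{fixedCountWindow} overrides when set).
#' Genes are then kept iff expressed in at least \code{minCellsPerGene} of
#' the remaining cells. The cell filter always runs before the gene filter
#' and never sees gene-filtered state.
#'
#' @param x a \code{SingleCellExperiment} (counts assay, genes x cells).
#' @param params a \linkS4class{QCParams}.
#' @return the filtered \code{SingleCellExperiment}; the QC report (cells/
#'   genes kept and dropped, window used) is in
#'   \code{metadata(x)$qc_report}.
#' @examples
#' truth <- generateTruth(truthConfig(seed = 3))
#' sce <- simulateCounts(truth)$samples[[1]]
#' filtered <- qcFilterSample(sce, qcParams())
#' S4Vectors::metadata(filtered)$qc_report
#' @export
qcFilterSample <- function(x, params = qcParams()) {
    validObject(params)
    counts <- SummarizedExperiment::assay(x, "counts")
    if (ncol(counts) == 0) stop("empty input: no cells")
    totals <- Matrix::colSums(counts)
    detected <- Matrix::colSums(counts > 0)
    if (length(params@fixedCountWindow)) {
        window <- params@fixedCountWindow
    } else {
        med <- median(totals)
        mad <- if (params@madType == "mean") mean(abs(totals - med))
               else median(abs(totals - med))
        window <- c(med - params@madMultiplier * mad,
                    med + params@madMultiplier * mad)
    }
    keepCell <- detected >= params@minGenesPerCell &
        totals >= window[1] & totals <= window[2]
    if (!any(keepCell))
        stop("empty after QC: no cells pass the filters in sample ",
             paste(unique(x$sample_id), collapse = ","))
    sub <- counts[, keepCell, drop = FALSE]
    keepGene <- Matrix::rowSums(sub > 0) >= params@minCellsPerGene
    out <- x[keepGene, keepCell]
    S4Vectors::metadata(out)$qc_report <- list(
        cells_kept = sum(keepCell), cells_dropped = sum(!keepCell),
        genes_kept = sum(keepGene), genes_dropped = sum(!keepGene),
        count_window = window,
        window_source = if (length(params@fixedCountWindow)) "fixed"
                        else paste0("median_", params@madType, "_mad"))
    out
}

## Standardized variance of log-normalized expression: variance z-scored
## within 20 equal-occupancy mean bins. Deterministic, dependency-free
## variable-gene statistic.
.standardizedVariance <- function(counts, nBins = 20L) {
    norm <- logNormalize(counts)
    mu <- Matrix::rowMeans(norm)
    n <- ncol(norm)
    v <- (Matrix::rowSums(norm^2) - n * mu^2) / max(1, n - 1)
    v[v < 0] <- 0
    br <- unique(quantile(mu, probs = seq(0, 1, length.out = nBins + 1)))
    bin <- cut(mu, breaks = br, include.lowest = TRUE)
    z <- numeric(length(v))
    for (b in levels(bin)) {
        i <- which(bin == b)
        s <- sd(v[i])
        z[i] <- if (is.na(s) || s == 0) 0 else (v[i] - mean(v[i])) / s
    }
    stats::setNames(z, rownames(counts))
}

#' Select variable genes shared across datasets
#'
#' Ribosomal-prefix genes are removed first; each dataset is ranked by a
#' standardized-variance statistic on log-normalized counts (variance
#' z-scored within 20 equal-occupancy mean-expression bins); a gene is
#' returned when it falls in the top \code{nTop} of at least
#' \code{minDatasets} datasets. Ordering is deterministic: descending count
#' of supporting datasets, ties by gene name.
#'
#' @param datasets named list with one genes x cells count matrix (or
#'   \code{SingleCellExperiment}) per dataset; genes must share one
#'   namespace.
#' @param nTop per-dataset variable-gene count (default 3000).
#' @param minDatasets minimum datasets a gene must be variable in
#'   (default 4).
#' @param riboPrefixes prefixes removed before ranking
#'   (default \code{c("RPS", "RPL")}).
#' @return character vector of selected genes.
#' @export
selectSharedVariableGenes <- function(datasets, nTop = 3000L,
                                      minDatasets = 4L,
                                      riboPrefixes = c("RPS", "RPL")) {
    if (!length(datasets)) stop("need at least one dataset")
    if (minDatasets > length(datasets))
        stop("minDatasets (", minDatasets, ") exceeds the number of ",
             "datasets (", length(datasets), ")")
    mats <- lapply(datasets, function(d)
        if (methods::is(d, "SummarizedExperiment"))
            SummarizedExperiment::assay(d, "counts") else d)
    hits <- list()
    for (m in mats) {
        genes <- rownames(m)
        ribo <- Reduce(`|`, lapply(riboPrefixes, startsWith, x = genes))
        m <- m[!ribo, , drop = FALSE]
        z <- .standardizedVariance(m)
        ord <- order(-z, names(z))
        hits[[length(hits) + 1L]] <- names(z)[ord][seq_len(min(nTop,
                                                               length(z)))]
    }
    counts <- table(unlist(hits))
    sel <- counts[counts >= minDatasets]
    if (!length(sel)) return(character())
    names(sel)[order(-as.integer(sel), names(sel))]
}

#' Pseudobulk samples into a gene x sample count matrix
#'
#' Entry (g, s) is the sum of counts of gene g over the cells of sample s;
#' column sums equal the per-sample totals.
#'
#' @param samples list of \code{SingleCellExperiment}s (or genes x cells
#'   matrices) sharing one gene namespace; names become column names when
#'   the objects carry no sample_id.
#' @return a dense gene x sample matrix.
#' @export
pseudobulkCounts <- function(samples) {
    mats <- lapply(samples, function(s)
        if (methods::is(s, "SummarizedExperiment"))
            SummarizedExperiment::assay(s, "counts") else s)
    genes <- rownames(mats[[1]])
    for (m in mats)
        if (!identical(rownames(m), genes))
            stop("samples must share one gene namespace and order")
    out <- vapply(mats, function(m) as.numeric(Matrix::rowSums(m)),
                  numeric(length(genes)))
    out <- matrix(out, nrow = length(genes),
                  dimnames = list(genes, names(samples)))
    ids <- vapply(seq_along(samples), function(i) {
        s <- samples[[i]]
        if (methods::is(s, "SummarizedExperiment") &&
            "sample_id" %in% names(SummarizedExperiment::colData(s)) &&
            ncol(s) > 0)
            as.character(s$sample_id[1])
        else if (!is.null(names(samples))) names(samples)[i]
        else sprintf("sample%d", i)
    }, character(1))
    colnames(out) <- ids
    out
}
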