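#' @include AllClasses.R utils.R
NULL

#' Read a 10x-style Matrix-Market triple
#'
#' Reads \code{matrix.mtx}, \code{features.tsv} and \code{barcodes.tsv}
#' from a directory into a \link[SingleCellExperiment]{SingleCellExperiment}
#' with a sparse integer \code{counts} assay (genes x cells). Dimensions
#' are checked against the feature/barcode files, entries must be
#' nonnegative integers, and duplicate gene names or barcodes are an error
#' naming the offending file.
#'
#' @param path directory holding the triple.
#' @param sampleId,datasetId provenance strings stored in \code{colData}.
#' @return a \code{SingleCellExperiment}.
#' @seealso \code{\link{writeMatrixMarketTriple}}
#' @export
readMatrixMarketTriple <- function(path, sampleId = basename(path),
                                   datasetId = NA_character_) {
    mtx <- file.path(path, "matrix.mtx")
    ftsv <- file.path(path, "features.tsv")
    btsv <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, ftsv, btsv))
        if (!file.exists(f)) stop("missing file: ", f)
    m <- Matrix::readMM(mtx)
    genes <- read.delim(ftsv, header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    cells <- read.delim(btsv, header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(genes))
        stop("format error in ", ftsv, ": matrix declares ", nrow(m),
             " genes but features.tsv has ", length(genes))
    if (ncol(m) != length(cells))
        stop("format error in ", btsv, ": matrix declares ", ncol(m),
             " cells but barcodes.tsv has ", length(cells))
    vals <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
    if (any(vals < 0) || any(vals != round(vals)))
        stop("format error in ", mtx, ": entries must be nonnegative integers")
    if (anyDuplicated(genes))
        stop("format error in ", ftsv, ": duplicate gene names")
    if (anyDuplicated(cells))
        stop("format error in ", btsv, ": duplicate barcodes")
    m <- methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")
    dimnames(m) <- list(genes, cells)
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m),
        colData = S4Vectors::DataFrame(
            sample_id = rep(sampleId, length(cells)),
            dataset_id = rep(datasetId, length(cells)),
            row.names = cells))
}

#' Write a 10x-style Matrix-Market triple
#'
#' Inverse of \code{\link{readMatrixMarketTriple}}: the round trip is
#' lossless for integer count matrices.
#'
#' @param x a \code{SingleCellExperiment} (or genes x cells matrix).
#' @param path output directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
writeMatrixMarketTriple <- function(x, path) {
    counts <- if (methods::is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "counts") else x
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(counts), file.path(path, "features.tsv"))
    writeLines(colnames(counts), file.path(path, "barcodes.tsv"))
    invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (tab-separated: name, description, genes...).
#' @return named list of character vectors.
#' @export
readGMT <- function(path) fgsea::gmtPathways(path)

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description description field (recycled; default the set name).
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(sets, path, description = names(sets)) {
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], description[i], sets[[i]]),
              collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Write a complete synthetic fixture to disk
#'
#' Emits one Matrix-Market triple per sample, a sample metadata TSV
#' (sample_id, dataset, cohort, age, sex, n_cells), GMT files of the
#' planted program signatures, per-dataset TF-activity TSVs (rows TFs,
#' columns cell barcodes), and a YAML record of the full configuration
#' including the seed.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param dir output directory.
#' @param sim optional precomputed result of \code{\link{simulateCounts}}.
#' @param tfActivities optional result of \code{\link{simulateTFActivities}};
#'   skipped when \code{NULL}.
#' @return \code{dir}, invisibly.
#' @export
writeTruthFixture <- function(truth, dir, sim = simulateCounts(truth),
                              tfActivities = NULL) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(sim$samples))
        writeMatrixMarketTriple(sim$samples[[sid]], file.path(dir, sid))
    cfg <- truth@config
    meta <- cfg@samples
    meta <- data.frame(sample_id = meta$sample_id, dataset = meta$dataset_id,
                       cohort = meta$cohort, age = meta$age, sex = meta$sex,
                       n_cells = meta$n_cells)
    write.table(meta, file.path(dir, "sample_metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeGMT(truth@signatureSets, file.path(dir, "planted_signatures.gmt"))
    if (!is.null(tfActivities))
        for (ds in names(tfActivities))
            write.table(tfActivities[[ds]],
                        file.path(dir, paste0("tf_activity_", ds, ".tsv")),
                        sep = "\t", quote = FALSE, col.names = NA)
    yaml::write_yaml(list(
        nGenes = cfg@nGenes, nPrograms = cfg@nPrograms,
        nAnchors = cfg@nAnchors, agedBoost = cfg@agedBoost,
        batchSd = cfg@batchSd, libsizeMu = cfg@libsizeMu,
        libsizeSd = cfg@libsizeSd,
        nbDispersion = if (length(cfg@nbDispersion)) cfg@nbDispersion
                       else "poisson",
        seed = cfg@seed,
        samples = lapply(seq_len(nrow(cfg@samples)), function(i)
            as.list(cfg@samples[i, c("sample_id", "dataset_id", "cohort",
                                     "n_cells")]))),
        file.path(dir, "truth_config.yaml"))
    invisible(dir)
}
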