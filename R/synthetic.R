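#' @include AllClasses.R utils.R
NULL

## Default multi-dataset sample layout: 44 samples (27 Young / 17 Aged)
## over 3 datasets; 22 samples at 110 cells (the discovery-eligible set
## under the >= 100-cell rule, 14 Young / 8 Aged) and 22 at 45 cells.
.defaultSampleTable <- function() {
    mk <- function(ds, cohort, n, cells, offset) {
        data.frame(
            sample_id = sprintf("%s_%s%02d", ds, substr(cohort, 1, 1),
                                offset + seq_len(n)),
            dataset_id = ds, cohort = cohort, n_cells = cells,
            stringsAsFactors = FALSE)
    }
    big <- rbind(
        mk("DS1", "Young", 5, 110, 0), mk("DS1", "Aged", 3, 110, 0),
        mk("DS2", "Young", 5, 110, 0), mk("DS2", "Aged", 3, 110, 0),
        mk("DS3", "Young", 4, 110, 0), mk("DS3", "Aged", 2, 110, 0))
    small <- rbind(
        mk("DS1", "Young", 4, 45, 5), mk("DS1", "Aged", 3, 45, 3),
        mk("DS2", "Young", 4, 45, 5), mk("DS2", "Aged", 3, 45, 3),
        mk("DS3", "Young", 5, 45, 4), mk("DS3", "Aged", 3, 45, 2))
    rbind(big, small)
}

#' Construct a synthetic study configuration
#'
#' Defaults emulate a multi-study single-cell HSC aging design: 3 datasets,
#' 4 planted programs (an aging program plus GMP/MEP/CLP-like lineage
#' programs), 27 Young and 17 Aged samples of which 22 have at least 100
#' cells (14 Young / 8 Aged, the discovery-eligible set), 500 genes with 25
#' disjoint anchor genes per program and 40 ribosomal-named decoy genes,
#' lognormal library sizes, dataset-level multiplicative batch factors, and
#' a 3-fold boost of the aging program's usage concentration in Aged
#' samples.
#'
#' @param nGenes gene-universe size (default 500).
#' @param nPrograms number of planted programs (default 4; program 1 is the
#'   aging program).
#' @param nAnchors anchor genes per program (default 25, disjoint across
#'   programs).
#' @param samples sample layout data.frame (sample_id, dataset_id, cohort,
#'   n_cells[, age, sex]); default \code{.defaultSampleTable()}.
#' @param agedBoost multiplier (>= 1) on the aging program's Dirichlet
#'   concentration in Aged samples (default 3).
#' @param batchSd lognormal sigma of dataset-level gene multipliers
#'   (default 0.15).
#' @param libsizeMu,libsizeSd lognormal meanlog/sdlog of per-cell depth
#'   (defaults log(1500) and 0.4).
#' @param nbDispersion optional NB dispersion (1/size); \code{NULL} for
#'   Poisson counts.
#' @param seed integer RNG seed.
#' @return a \linkS4class{TruthConfig}.
#' @examples
#' cfg <- truthConfig(seed = 1)
#' cfg
#' @export
truthConfig <- function(nGenes = 500L, nPrograms = 4L, nAnchors = 25L,
                        samples = .defaultSampleTable(), agedBoost = 3,
                        batchSd = 0.15, libsizeMu = log(1500),
                        libsizeSd = 0.4, nbDispersion = NULL, seed = 1L) {
    if (!"age" %in% names(samples))
        samples$age <- ifelse(samples$cohort == "Aged", 70L, 30L)
    if (!"sex" %in% names(samples))
        samples$sex <- rep_len(c("F", "M"), nrow(samples))
    new("TruthConfig", nGenes = as.integer(nGenes),
        nPrograms = as.integer(nPrograms), nAnchors = as.integer(nAnchors),
        samples = samples, agedBoost = as.numeric(agedBoost),
        batchSd = as.numeric(batchSd), libsizeMu = as.numeric(libsizeMu),
        libsizeSd = as.numeric(libsizeSd),
        nbDispersion = if (is.null(nbDispersion)) numeric()
                       else as.numeric(nbDispersion),
        seed = as.integer(seed))
}

.programLabels <- function(n) {
    base <- c("aging", "GMP", "MEP", "CLP")
    if (n <= 4L) base[seq_len(n)]
    else c(base, sprintf("P%d", seq_len(n - 4L) + 4L))
}

#' Generate the ground truth of a synthetic study
#'
#' Program spectra are sparse Dirichlet-like vectors: every program gets a
#' disjoint block of anchor genes with elevated Gamma mass (shape 5) over a
#' low background (shape 0.05), plus a shared block of highly expressed
#' ribosomal-named decoy genes (RPS/RPL prefixes) present in every program,
#' and rows are normalized to sum 1. Per-cell usages are Dirichlet with
#' base concentration 0.6 for the aging program and 0.8 for the others; in
#' Aged samples the aging concentration is multiplied by
#' \code{config@agedBoost}. Deterministic under \code{config@seed}.
#'
#' @param config a \linkS4class{TruthConfig}.
#' @return a \linkS4class{GroundTruth}.
#' @examples
#' truth <- generateTruth(truthConfig(seed = 7))
#' truth
#' @export
generateTruth <- function(config) {
    validObject(config)
    set.seed(config@seed)
    P <- config@nPrograms
    G <- config@nGenes
    nA <- config@nAnchors
    nRibo <- min(40L, G - P * nA)
    geneNames <- sprintf("GENE%04d", seq_len(G))
    riboIdx <- if (nRibo > 0) (P * nA + 1L):(P * nA + nRibo) else integer()
    if (nRibo > 0)
        geneNames[riboIdx] <- c(sprintf("RPS%d", seq_len(ceiling(nRibo / 2))),
                                sprintf("RPL%d", seq_len(floor(nRibo / 2))))
    labels <- .programLabels(P)

    spectra <- matrix(rgamma(P * G, shape = 0.05), P, G)
    anchors <- vector("list", P)
    for (p in seq_len(P)) {
        idx <- ((p - 1L) * nA + 1L):(p * nA)
        spectra[p, idx] <- rgamma(nA, shape = 5)
        anchors[[p]] <- idx
    }
    if (nRibo > 0)  # housekeeping-like decoys: high in every program
        spectra[, riboIdx] <- matrix(rgamma(P * nRibo, shape = 3, rate = 2),
                                     P, nRibo)
    spectra <- spectra / rowSums(spectra)
    dimnames(spectra) <- list(labels, geneNames)

    samples <- config@samples
    alphaBase <- c(0.6, rep(0.8, P - 1L))
    cellMeta <- data.frame(
        barcode = character(), sample_id = character(),
        dataset_id = character(), cohort = character(),
        stringsAsFactors = FALSE)
    usages <- matrix(0, 0, P)
    for (i in seq_len(nrow(samples))) {
        n <- samples$n_cells[i]
        alpha <- alphaBase
        if (samples$cohort[i] == "Aged") alpha[1] <- alpha[1] * config@agedBoost
        u <- matrix(rgamma(n * P, shape = rep(alpha, each = n)), n, P)
        zero <- rowSums(u) == 0
        if (any(zero)) u[zero, ] <- 1 / P
        u <- u / rowSums(u)
        usages <- rbind(usages, u)
        cellMeta <- rbind(cellMeta, data.frame(
            barcode = sprintf("%s_cell%04d", samples$sample_id[i], seq_len(n)),
            sample_id = samples$sample_id[i],
            dataset_id = samples$dataset_id[i],
            cohort = samples$cohort[i], stringsAsFactors = FALSE))
    }
    colnames(usages) <- labels
    rownames(usages) <- cellMeta$barcode

    sigSets <- lapply(seq_len(P), function(p) {
        idx <- anchors[[p]]
        geneNames[idx[order(spectra[p, idx], decreasing = TRUE)]]
    })
    names(sigSets) <- paste0("planted_", labels)

    new("GroundTruth", spectra = spectra, usages = usages,
        cellMeta = cellMeta, programLabels = labels, agingProgram = "aging",
        signatureSets = sigSets,
        decoyRibosomalGenes = geneNames[riboIdx], config = config)
}

#' Simulate per-sample count matrices from a ground truth
#'
#' The expected expression of cell j is
#' \code{libsize_j * (usage_j \%*\% spectra) * batchFactor[dataset, ]}, with
#' lognormal library sizes, lognormal dataset-level gene multipliers
#' (sigma \code{config@batchSd}), and Poisson counts (negative binomial
#' when \code{config@nbDispersion} is set). Deterministic under
#' \code{config@seed}.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param config the matching \linkS4class{TruthConfig} (defaults to the
#'   one stored in \code{truth}).
#' @return a list with elements \code{samples} (named list of
#'   \link[SingleCellExperiment]{SingleCellExperiment} objects, one per
#'   sample, sparse counts, colData columns sample_id/dataset_id/cohort/
#'   libsize), \code{batchFactors} (dataset x gene multipliers) and
#'   \code{libsizes} (per cell, named by barcode).
#' @examples
#' truth <- generateTruth(truthConfig(seed = 7))
#' sim <- simulateCounts(truth)
#' sim$samples[[1]]
#' @export
simulateCounts <- function(truth, config = truth@config) {
    validObject(truth)
    set.seed(.childSeed(config@seed, 1L))
    G <- config@nGenes
    datasets <- unique(config@samples$dataset_id)
    batch <- matrix(exp(rnorm(length(datasets) * G, 0, config@batchSd)),
                    length(datasets), G,
                    dimnames = list(datasets, colnames(truth@spectra)))
    nCells <- nrow(truth@usages)
    libsizes <- stats::setNames(
        exp(rnorm(nCells, config@libsizeMu, config@libsizeSd)),
        rownames(truth@usages))
    meanExpr <- truth@usages %*% truth@spectra  # cells x genes, rows sum 1
    out <- vector("list", nrow(config@samples))
    names(out) <- config@samples$sample_id
    for (i in seq_len(nrow(config@samples))) {
        sid <- config@samples$sample_id[i]
        cells <- which(truth@cellMeta$sample_id == sid)
        ds <- config@samples$dataset_id[i]
        mu <- meanExpr[cells, , drop = FALSE] *
            rep(batch[ds, ], each = length(cells)) * libsizes[cells]
        cnt <- if (length(config@nbDispersion))
            rnbinom(length(mu), mu = as.vector(mu),
                    size = 1 / config@nbDispersion)
        else rpois(length(mu), as.vector(mu))
        counts <- Matrix::Matrix(
            matrix(cnt, nrow = G, ncol = length(cells), byrow = TRUE,
                   dimnames = list(colnames(truth@spectra),
                                   truth@cellMeta$barcode[cells])),
            sparse = TRUE)
        cd <- S4Vectors::DataFrame(
            sample_id = sid, dataset_id = ds,
            cohort = config@samples$cohort[i],
            libsize = libsizes[cells],
            row.names = truth@cellMeta$barcode[cells])
        sce <- SingleCellExperiment::SingleCellExperiment(
            assays = list(counts = counts), colData = cd)
        S4Vectors::metadata(sce)$batch_factors <- batch[ds, ]
        out[[i]] <- sce
    }
    list(samples = out, batchFactors = batch, libsizes = libsizes)
}

#' Simulate per-dataset TF-activity matrices
#'
#' Emulates regulon-activity (AUC-like) matrices: a TF coupled to a planted
#' program has activity \code{0.15 + 0.7 * usage + N(0, noiseSd)} clipped to
#' [0, 1]; uncoupled TFs are pure noise around 0.3. Each dataset carries
#' \code{nShared} TFs common to all datasets plus \code{nExtra}
#' dataset-specific TFs, mirroring a downstream all-datasets intersection
#' step (108 shared TFs by default).
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param nShared TFs present in every dataset (default 108).
#' @param nExtra additional dataset-specific TFs per dataset (default 5).
#' @param coupled named character vector mapping TF name -> program label;
#'   the default couples six AP-1/quiescence-style TFs to the aging program
#'   and one TF to each lineage program.
#' @param noiseSd Gaussian noise sd (>= 0; default 0.1).
#' @param seed integer seed (default: derived from the truth's config).
#' @return named list (per dataset) of TF x cell activity matrices.
#' @examples
#' truth <- generateTruth(truthConfig(seed = 7))
#' act <- simulateTFActivities(truth, noiseSd = 0.05)
#' dim(act[[1]])
#' @export
simulateTFActivities <- function(truth, nShared = 108L, nExtra = 5L,
                                 coupled = NULL, noiseSd = 0.1,
                                 seed = NULL) {
    if (noiseSd < 0) stop("noiseSd must be >= 0")
    if (is.null(seed)) seed <- .childSeed(truth@config@seed, 2L)
    if (is.null(coupled)) {
        agingTFs <- c("JUN", "JUNB", "FOSB", "FOS", "EGR1", "KLF4")
        coupled <- stats::setNames(rep(truth@agingProgram, length(agingTFs)),
                                   agingTFs)
        lineage <- setdiff(truth@programLabels, truth@agingProgram)
        lineageTFs <- c("SPI1", "GATA1", "EBF1", "TCF7", "CEBPA")
        for (i in seq_along(lineage))
            if (i <= length(lineageTFs))
                coupled[lineageTFs[i]] <- lineage[i]
    }
    if (!all(coupled %in% truth@programLabels))
        stop("coupled TFs reference unknown programs: ",
             paste(setdiff(coupled, truth@programLabels), collapse = ", "))
    set.seed(seed)
    nFree <- max(0L, nShared - length(coupled))
    tfNames <- c(names(coupled), sprintf("TF%03d", seq_len(nFree)))
    datasets <- unique(truth@cellMeta$dataset_id)
    out <- vector("list", length(datasets))
    names(out) <- datasets
    for (d in seq_along(datasets)) {
        cells <- which(truth@cellMeta$dataset_id == datasets[d])
        allTfs <- c(tfNames,
                    if (nExtra > 0) sprintf("%s_TF%02d", datasets[d],
                                            seq_len(nExtra)))
        act <- matrix(NA_real_, length(allTfs), length(cells),
                      dimnames = list(allTfs,
                                      truth@cellMeta$barcode[cells]))
        for (tf in allTfs) {
            base <- if (tf %in% names(coupled))
                0.15 + 0.7 * truth@usages[cells, coupled[[tf]]]
            else rep(0.3, length(cells))
            act[tf, ] <- pmin(1, pmax(0, base + rnorm(length(cells), 0,
                                                      noiseSd)))
        }
        out[[d]] <- act
    }
    out
}
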