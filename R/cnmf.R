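#' @include AllClasses.R utils.R qc.R
NULL

#' Prepare the variance-scaled NMF input for one sample
#'
#' Counts are subset to the shared variable-gene list and each gene is
#' scaled to unit variance without centering, preserving nonnegativity
#' (the standard input space for consensus NMF). Zero-variance genes are
#' dropped with a warning. The log-normalized matrix on the same genes is
#' kept for the Z-score spectra regression.
#'
#' @param x a \code{SingleCellExperiment} (counts assay, genes x cells),
#'   typically after \code{\link{qcFilterSample}}.
#' @param genes the shared variable-gene list.
#' @return a \linkS4class{CnmfInput} (cells x genes orientation).
#' @export
prepareCnmfInput <- function(x, genes) {
    counts <- SummarizedExperiment::assay(x, "counts")
    genes <- intersect(genes, rownames(counts))
    if (length(genes) < 2) stop("fewer than 2 usable genes in sample ",
                                paste(unique(x$sample_id), collapse = ","))
    counts <- counts[genes, , drop = FALSE]
    sds <- .colSds(Matrix::t(counts))
    if (any(sds == 0)) {
        warning(sum(sds == 0), " zero-variance gene(s) dropped")
        counts <- counts[sds > 0, , drop = FALSE]
        sds <- sds[sds > 0]
        if (nrow(counts) < 2) stop("fewer than 2 usable genes after ",
                                   "dropping zero-variance genes")
    }
    X <- t(as.matrix(counts)) / rep(sds, each = ncol(counts))
    logNorm <- t(as.matrix(logNormalize(counts)))
    new("CnmfInput", X = X, geneSd = stats::setNames(sds, rownames(counts)),
        logNorm = logNorm,
        sampleId = as.character(x$sample_id[1] %||% NA_character_),
        datasetId = as.character(x$dataset_id[1] %||% NA_character_))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

## Multiplicative-update NMF with Frobenius objective. Relative-error
## change is checked every 10 iterations against tol; max 400 iterations.
## The objective is non-increasing under these updates.
.muNMF <- function(X, k, seed, tol = 1e-4, maxIter = 400L) {
    set.seed(seed)
    n <- nrow(X); G <- ncol(X)
    amp <- sqrt(mean(X) / k)
    W <- matrix(runif(n * k, 0, amp), n, k)
    H <- matrix(runif(k * G, 0, amp), k, G)
    eps <- 1e-12
    nX <- sum(X^2)
    prev <- Inf
    err <- NA_real_
    for (it in seq_len(maxIter)) {
        H <- H * crossprod(W, X) / (crossprod(W) %*% H + eps)
        W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
        if (it %% 10L == 0L || it == maxIter) {
            XHt <- X %*% t(H)
            err <- sqrt(max(0, nX - 2 * sum(W * XHt) +
                            sum(crossprod(W) * tcrossprod(H)))) / sqrt(nX)
            if (is.finite(prev) && abs(prev - err) < tol * max(prev, eps))
                break
            prev <- err
        }
    }
    list(W = W, H = H, error = err, iterations = it)
}

#' Run replicated NMF factorizations for one sample and one k
#'
#' Each replicate solves \code{min ||X - W H||_F} with \code{W, H >= 0} by
#' multiplicative updates from a distinct seeded random initialization
#' (tolerance 1e-4 on the relative-error change, at most 400 iterations).
#' Component spectra are L2-normalized for the consensus step.
#'
#' @param X cells x genes nonnegative matrix, or a
#'   \linkS4class{CnmfInput}.
#' @param k number of programs (2 <= k < min(dim(X)); k = 1 is allowed for
#'   degenerate checks).
#' @param nReplicates number of random restarts (500 in the full-scale
#'   analysis; 100 is the desk-scale default).
#' @param baseSeed integer; replicate r uses a seed derived from
#'   \code{baseSeed} and r, so identical \code{baseSeed} gives identical
#'   results.
#' @return a \linkS4class{FactorizationRun}.
#' @export
runNMFReplicates <- function(X, k, nReplicates = 100L, baseSeed = 1L) {
    if (methods::is(X, "CnmfInput")) X <- X@X
    if (!all(is.finite(X))) stop("input contains non-finite values")
    if (any(X < 0)) stop("input must be nonnegative")
    k <- as.integer(k)
    if (k < 1L || k > min(dim(X)))
        stop("k must satisfy 1 <= k <= min(dim(X))")
    seeds <- vapply(seq_len(nReplicates), function(r)
        .childSeed(baseSeed, k, r), integer(1))
    spectra <- matrix(0, nReplicates * k, ncol(X))
    objective <- numeric(nReplicates)
    for (r in seq_len(nReplicates)) {
        fit <- .muNMF(X, k, seeds[r])
        H <- fit$H
        l2 <- sqrt(rowSums(H^2))
        l2[l2 == 0] <- 1
        spectra[((r - 1L) * k + 1L):(r * k), ] <- H / l2
        objective[r] <- fit$error
    }
    colnames(spectra) <- colnames(X)
    new("FactorizationRun", k = k, spectra = spectra,
        objective = objective, replicateSeeds = seeds)
}

## OLS of per-gene z-scored log-normalized expression onto row-normalized
## usages; the coefficient matrix (k x G) is the Z-score spectrum.
.zscoreSpectra <- function(logNorm, usages) {
    Z <- scale(logNorm)
    Z[, attr(Z, "scaled:scale") == 0] <- 0
    Z[is.na(Z)] <- 0
    rs <- rowSums(usages)
    rs[rs == 0] <- 1
    U <- usages / rs
    UtU <- crossprod(U)
    B <- tryCatch(solve(UtU, crossprod(U, Z)),
                  error = function(e)
                      solve(UtU + diag(1e-8, ncol(U)), crossprod(U, Z)))
    B
}

#' Consensus over replicated factorizations
#'
#' Replicate components are density-filtered: a component is kept when its
#' mean Euclidean distance to its K nearest neighbor components
#' (K = floor(0.3 * nReplicates)) on L2-normalized spectra is at most
#' \code{distThreshold}. Survivors are clustered into k groups by seeded
#' k-means; the consensus spectrum of each group is the component-wise
#' median, re-expressed in normalized-expression units. Usages are refit by
#' nonnegative least squares of X onto the consensus spectra; stability is
#' the mean silhouette width of the component clustering and error the
#' relative Frobenius reconstruction error of the refit.
#'
#' @param run a \linkS4class{FactorizationRun}.
#' @param input the matching \linkS4class{CnmfInput} (or the cells x genes
#'   matrix X used for the run).
#' @param distThreshold density-filter threshold; 0.1 reproduces the most
#'   stable clustering in the motivating analysis, with 0.05 and 0.15 the
#'   standard alternatives to assess.
#' @param seed seed for the k-means step.
#' @return a \linkS4class{ConsensusResult}.
#' @export
consensusNMF <- function(run, input, distThreshold = 0.1, seed = 1L) {
    validObject(run)
    if (methods::is(input, "CnmfInput")) {
        X <- input@X
        geneSd <- input@geneSd
        logNorm <- input@logNorm
        sampleId <- input@sampleId
        datasetId <- input@datasetId
    } else {
        X <- input
        geneSd <- rep(1, ncol(X))
        logNorm <- NULL
        sampleId <- NA_character_
        datasetId <- NA_character_
    }
    S <- run@spectra
    nRep <- length(run@replicateSeeds)
    k <- run@k
    ## mean distance to K nearest neighbors on L2-normalized rows
    K <- max(1L, min(nrow(S) - 1L, as.integer(floor(0.3 * nRep))))
    cp <- tcrossprod(S)
    d2 <- outer(diag(cp), diag(cp), "+") - 2 * cp
    d2[d2 < 0] <- 0
    d <- sqrt(d2)
    diag(d) <- Inf
    meanNN <- apply(d, 1L, function(r) mean(sort.int(r,
        partial = K)[seq_len(K)]))
    kept <- meanNN <= distThreshold
    if (!any(kept))
        stop("all replicate components removed by the density filter; ",
             "consider a larger distThreshold")
    Sk <- S[kept, , drop = FALSE]
    ## lexicographic row sort makes the k-means step (and hence the whole
    ## consensus) invariant to replicate order
    Sk <- Sk[do.call(order, as.data.frame(Sk)), , drop = FALSE]
    set.seed(.childSeed(seed, 97L))
    uniq <- unique(Sk)
    if (nrow(uniq) <= k) {  # fewer distinct components than clusters
        cl <- match(apply(Sk, 1L, paste, collapse = "\r"),
                    apply(uniq, 1L, paste, collapse = "\r"))
    } else {
        km <- kmeans(Sk, centers = k, nstart = 5, iter.max = 50)
        cl <- km$cluster
    }
    nCl <- length(unique(cl))
    consScaled <- matrix(0, nCl, ncol(S))
    for (g in seq_len(nCl))
        consScaled[g, ] <- apply(Sk[cl == g, , drop = FALSE], 2L, median)
    ordCons <- do.call(order, as.data.frame(consScaled))
    consScaled <- consScaled[ordCons, , drop = FALSE]
    cl <- match(cl, ordCons)
    stability <- if (nCl > 1 && nrow(Sk) > nCl) {
        sil <- cluster::silhouette(cl, dist(Sk))
        mean(sil[, "sil_width"])
    } else 1
    ## usages refit in the variance-scaled space
    usages <- nnlsFit(t(consScaled), X)
    recon <- usages %*% consScaled
    err <- sqrt(sum((X - recon)^2)) / sqrt(sum(X^2))
    ## expression-space spectra: undo the gene variance scaling, normalize
    ## rows to counts-per-10k units
    tpm <- consScaled * rep(geneSd, each = nCl)
    rs <- rowSums(tpm)
    rs[rs == 0] <- 1
    tpm <- tpm * (1e4 / rs)
    zspec <- if (!is.null(logNorm)) .zscoreSpectra(logNorm, usages)
             else consScaled
    progNames <- sprintf("GEP%d", seq_len(nCl))
    dimnames(consScaled) <- list(progNames, colnames(X))
    dimnames(tpm) <- list(progNames, colnames(X))
    dimnames(zspec) <- list(progNames, colnames(X))
    dimnames(usages) <- list(rownames(X), progNames)
    new("ConsensusResult", k = as.integer(nCl),
        distThreshold = distThreshold, keptComponentMask = kept,
        spectraScaled = consScaled, spectraTpm = tpm, spectraZ = zspec,
        usages = usages, stability = stability, error = err,
        geneNames = colnames(X) %||% character(),
        cellNames = rownames(X) %||% sprintf("cell%d", seq_len(nrow(X))),
        sampleId = sampleId, datasetId = datasetId)
}

#' Select k from consensus diagnostics
#'
#' Automatic stand-in for visual inspection of the stability-vs-error
#' plot: among k whose reconstruction error is within 5\% of the minimum
#' (error <= 1.05 * min error), pick the k with maximal stability; ties go
#' to the smallest k. The full diagnostics table is returned so a caller
#' can override.
#'
#' @param results named list of \linkS4class{ConsensusResult}, one per k.
#' @return list with \code{k} (chosen) and \code{diagnostics} (data.frame:
#'   k, stability, error, n_filtered).
#' @export
selectK <- function(results) {
    if (!length(results)) stop("no consensus results supplied")
    diag <- data.frame(
        k = vapply(results, function(r) r@k, integer(1)),
        stability = vapply(results, function(r) r@stability, numeric(1)),
        error = vapply(results, function(r) r@error, numeric(1)),
        n_filtered = vapply(results, function(r)
            sum(!r@keptComponentMask), integer(1)))
    diag <- diag[order(diag$k), , drop = FALSE]
    rownames(diag) <- NULL
    eligible <- diag$error <= 1.05 * min(diag$error)
    cand <- diag[eligible, , drop = FALSE]
    best <- cand$k[order(-cand$stability, cand$k)][1]
    list(k = best, diagnostics = diag)
}

#' Exclude single-cell-driven programs by the usage quantile ratio
#'
#' For each program the ratio between the 100\% and 75\% usage quantiles is
#' computed; programs with ratio > \code{maxRatio} are removed from the
#' spectra and usages. A 75\% quantile of 0 yields ratio +Inf (always
#' excluded), matching the rule's intent of removing programs driven by a
#' single cell.
#'
#' @param cr a \linkS4class{ConsensusResult}.
#' @param maxRatio exclusion threshold (default 10).
#' @return list with \code{result} (filtered \code{ConsensusResult}; may
#'   have zero programs) and \code{qc} (data.frame: program, ratio,
#'   excluded).
#' @export
filterSingleCellDriven <- function(cr, maxRatio = 10) {
    u <- cr@usages
    ratio <- apply(u, 2L, function(col) {
        q <- quantile(col, c(0.75, 1), names = FALSE)
        if (q[1] <= 0) Inf else q[2] / q[1]
    })
    excluded <- ratio > maxRatio
    qc <- data.frame(program = colnames(u), ratio = ratio,
                     excluded = excluded, row.names = NULL)
    keep <- which(!excluded)
    out <- cr
    out@spectraScaled <- cr@spectraScaled[keep, , drop = FALSE]
    out@spectraTpm <- cr@spectraTpm[keep, , drop = FALSE]
    out@spectraZ <- cr@spectraZ[keep, , drop = FALSE]
    out@usages <- cr@usages[, keep, drop = FALSE]
    list(result = out, qc = qc)
}

#' Consensus NMF over a k grid for one sample
#'
#' Convenience wrapper: runs \code{\link{runNMFReplicates}} and
#' \code{\link{consensusNMF}} for every k in \code{kRange}, applies
#' \code{\link{selectK}} and the single-cell-driven program filter to the
#' chosen k.
#'
#' @param input a \linkS4class{CnmfInput}.
#' @param kRange integer vector of k values (default 3:10).
#' @param nReplicates random restarts per k (default 100).
#' @param distThreshold density-filter threshold (default 0.1).
#' @param maxUsageRatio q100/q75 exclusion threshold (default 10).
#' @param seed integer base seed.
#' @return list: \code{byK} (named list of \code{ConsensusResult}),
#'   \code{k} (selected), \code{diagnostics}, \code{programs} (filtered
#'   \code{ConsensusResult} at the selected k), \code{programQC}.
#' @export
runCnmfSample <- function(input, kRange = 3:10, nReplicates = 100L,
                          distThreshold = 0.1, maxUsageRatio = 10,
                          seed = 1L) {
    byK <- list()
    for (k in kRange) {
        run <- runNMFReplicates(input, k, nReplicates,
                                baseSeed = .childSeed(seed, k))
        byK[[as.character(k)]] <- consensusNMF(run, input, distThreshold,
                                               seed = .childSeed(seed, k, 7L))
    }
    sel <- selectK(byK)
    filt <- filterSingleCellDriven(byK[[as.character(sel$k)]],
                                   maxRatio = maxUsageRatio)
    list(byK = byK, k = sel$k, diagnostics = sel$diagnostics,
         programs = filt$result, programQC = filt$qc)
}
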