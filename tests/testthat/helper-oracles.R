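# Independent oracles used to freeze expected values. Each is a direct,
# unoptimized implementation that never shares code with the package paths
# it checks.

# Brute-force weighted (exponent 1) GSEA running sum: walk the ranked list
# gene by gene and record the signed extremum.
bruteGseaES <- function(ranking, set) {
    ord <- order(ranking, decreasing = TRUE)
    genes <- names(ranking)[ord]
    w <- abs(ranking)[ord]
    hit <- genes %in% set
    denomHit <- sum(w[hit])
    denomMiss <- length(genes) - sum(hit)
    run <- 0
    best <- 0
    for (i in seq_along(genes)) {
        run <- if (hit[i]) {
            if (denomHit == 0) run else run + w[i] / denomHit
        } else run - 1 / denomMiss
        if (abs(run) > abs(best)) best <- run
    }
    unname(best)
}

# Two-sided Fisher p by enumerating every 2x2 table with the observed
# margins, using explicit binomial coefficients (lchoose), and summing the
# probabilities of tables at most as likely as the observed one.
enumFisherP <- function(a, b, c, d) {
    rowA <- a + c
    colA <- a + b
    n <- a + b + c + d
    support <- max(0, rowA + colA - n):min(rowA, colA)
    logp <- vapply(support, function(x)
        lchoose(colA, x) + lchoose(n - colA, rowA - x) - lchoose(n, rowA),
        numeric(1))
    p <- exp(logp - max(logp))
    p <- p / sum(p)
    obs <- p[match(a, support)]
    sum(p[p <= obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
enumWilcoxP <- function(x, y) {
    pooled <- c(x, y)
    n1 <- length(x)
    idx <- utils::combn(length(pooled), n1)
    uStat <- function(g1, g2)
        sum(vapply(g1, function(v) sum(v > g2) + 0.5 * sum(v == g2),
                   numeric(1)))
    obs <- uStat(x, y)
    mid <- n1 * length(y) / 2
    us <- apply(idx, 2, function(i) uStat(pooled[i], pooled[-i]))
    mean(abs(us - mid) >= abs(obs - mid) - 1e-9)
}

# Exhaustive grid search NNLS for two coefficients.
gridNNLS2 <- function(A, b, step = 0.01, upper = 1.5) {
    grid <- seq(0, upper, by = step)
    best <- c(0, 0)
    bestSse <- sum(b^2)
    for (u1 in grid) for (u2 in grid) {
        r <- b - A[, 1] * u1 - A[, 2] * u2
        sse <- sum(r^2)
        if (sse < bestSse) {
            bestSse <- sse
            best <- c(u1, u2)
        }
    }
    best
}

# Small, fast synthetic design used by unit tests (2 datasets, 6 samples).
tinyConfig <- function(seed = 1L, nCells = 60L, agedBoost = 3, ...) {
    samples <- data.frame(
        sample_id = sprintf("S%d", 1:6),
        dataset_id = rep(c("DA", "DB"), each = 3),
        cohort = rep(c("Young", "Young", "Aged"), 2),
        n_cells = nCells, stringsAsFactors = FALSE)
    truthConfig(nGenes = 200L, nPrograms = 3L, nAnchors = 20L,
                samples = samples, agedBoost = agedBoost, seed = seed, ...)
}

# Construct a ConsensusResult directly from given spectra (for tests of
# downstream stages that need controlled inputs).
fakeConsensus <- function(zSpectra, tpmSpectra = abs(zSpectra),
                          usages = NULL, sampleId = "S", datasetId = "D") {
    k <- nrow(zSpectra)
    genes <- colnames(zSpectra)
    if (is.null(usages)) usages <- matrix(1 / k, 4, k)
    new("ConsensusResult", k = as.integer(k), distThreshold = 0.1,
        keptComponentMask = rep(TRUE, k),
        spectraScaled = tpmSpectra, spectraTpm = tpmSpectra,
        spectraZ = zSpectra, usages = usages, stability = 1, error = 0,
        geneNames = genes, cellNames = sprintf("c%d", seq_len(nrow(usages))),
        sampleId = sampleId, datasetId = datasetId)
}
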