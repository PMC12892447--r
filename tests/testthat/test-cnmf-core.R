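sceFromCounts <- function(counts, sampleId = "S1", datasetId = "D1") {
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
        colData = S4Vectors::DataFrame(
            sample_id = rep(sampleId, ncol(counts)),
            dataset_id = rep(datasetId, ncol(counts)),
            row.names = colnames(counts)))
}

plantedInput <- function(seed = 1, n = 80, G = 60, P = 3, lib = 600) {
    set.seed(seed)
    S <- matrix(rgamma(P * G, 0.05), P, G)
    for (p in seq_len(P)) S[p, ((p - 1) * 15 + 1):(p * 15)] <- rgamma(15, 5)
    S <- S / rowSums(S)
    U <- matrix(rgamma(n * P, 0.5), n, P)
    U <- U / rowSums(U)
    counts <- matrix(rpois(n * G, lib * (U %*% S)), G, n, byrow = TRUE,
                     dimnames = list(sprintf("g%02d", 1:G),
                                     sprintf("c%02d", 1:n)))
    list(sce = sceFromCounts(counts), spectra = S, usages = U)
}

# planted counts can leave a few all-zero background genes; their
# documented drop-with-warning is tested separately
quietInput <- function(sce) suppressWarnings(prepareCnmfInput(sce, rownames(sce)))

test_that("NMF input preparation scales genes to unit variance reversibly", {
    p <- plantedInput(1)
    counts <- as.matrix(SummarizedExperiment::assay(p$sce, "counts"))
    counts["g01", ] <- 7  # constant gene
    expect_warning(
        inp <- prepareCnmfInput(sceFromCounts(counts), rownames(counts)),
        "zero-variance")
    expect_false("g01" %in% colnames(inp@X))
    expect_true(all(abs(apply(inp@X, 2, sd) - 1) < 1e-9))
    back <- inp@X * rep(inp@geneSd, each = nrow(inp@X))
    expect_equal(back, t(counts[colnames(inp@X), ]),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_error(prepareCnmfInput(p$sce, c("g02")), "fewer than 2")
})

test_that("a rank-1 matrix is recovered exactly at k = 1", {
    set.seed(2)
    u <- runif(30, 1, 3)
    s <- runif(20)
    X <- outer(u, s)
    run <- runNMFReplicates(X, k = 1, nReplicates = 3, baseSeed = 9)
    expect_lt(min(run@objective), 1e-6)
    spec <- run@spectra[1, ]
    expect_gt(abs(cor(spec, s)), 1 - 1e-6)
})

test_that("replicated factorization is deterministic in the base seed", {
    p <- plantedInput(3)
    inp <- quietInput(p$sce)
    r1 <- runNMFReplicates(inp, k = 3, nReplicates = 5, baseSeed = 11)
    r2 <- runNMFReplicates(inp, k = 3, nReplicates = 5, baseSeed = 11)
    expect_identical(r1@spectra, r2@spectra)
    expect_identical(r1@objective, r2@objective)
    expect_error(runNMFReplicates(matrix(c(1, NA, 2, 3), 2), 1),
                 "non-finite")
})

test_that("consensus recovers planted programs and matches the NNLS refit contract", {
    p <- plantedInput(5, n = 100, G = 60, P = 3)
    inp <- quietInput(p$sce)
    run <- runNMFReplicates(inp, k = 3, nReplicates = 30, baseSeed = 4)
    cr <- consensusNMF(run, inp, distThreshold = 0.1)
    # greedy matching of consensus expression spectra to planted spectra
    cc <- cor(t(consensusSpectra(cr, "tpm")),
              t(p$spectra[, match(cr@geneNames, rownames(p$sce))]))
    matched <- numeric(3)
    avail <- 1:3
    for (i in 1:3) {
        j <- avail[which.max(cc[i, avail])]
        matched[i] <- cc[i, j]
        avail <- setdiff(avail, j)
    }
    expect_true(all(matched > 0.9))
    u <- consensusUsages(cr, normalized = TRUE)
    expect_true(all(cr@usages >= 0))
    expect_true(all(abs(rowSums(u) - 1) < 1e-9))
})

test_that("identical replicate components give stability 1 and no filtering", {
    set.seed(6)
    base <- matrix(runif(3 * 20), 3, 20)
    base <- base / sqrt(rowSums(base^2))
    spectra <- base[rep(1:3, times = 10), ]
    run <- new("FactorizationRun", k = 3L, spectra = spectra,
               objective = rep(0.1, 10), replicateSeeds = 1:10)
    X <- matrix(runif(8 * 20), 8, 20)
    cr <- consensusNMF(run, X, distThreshold = 0.1)
    expect_equal(cr@stability, 1)
    expect_true(all(cr@keptComponentMask))
    # spectra should be the three planted rows (any order)
    expect_equal(unname(sort(rowSums(cr@spectraScaled))),
                 unname(sort(rowSums(base))), tolerance = 1e-12)
})

test_that("noise components are removed by the density filter", {
    set.seed(7)
    base <- matrix(runif(2 * 30), 2, 30)
    base <- base / sqrt(rowSums(base^2))
    reps <- 40
    spectra <- base[rep(1:2, times = reps), ] +
        matrix(rnorm(2 * reps * 30, 0, 0.002), 2 * reps, 30)
    spectra <- abs(spectra)
    noiseIdx <- sample(nrow(spectra), 4)  # 5% planted junk components
    spectra[noiseIdx, ] <- matrix(runif(4 * 30), 4, 30)
    spectra <- spectra / sqrt(rowSums(spectra^2))
    run <- new("FactorizationRun", k = 2L, spectra = spectra,
               objective = rep(0.1, reps), replicateSeeds = seq_len(reps))
    X <- matrix(runif(10 * 30), 10, 30)
    cr <- consensusNMF(run, X, distThreshold = 0.1)
    expect_true(all(!cr@keptComponentMask[noiseIdx]))
    expect_true(all(cr@keptComponentMask[-noiseIdx]))
    expect_error(consensusNMF(run, X, distThreshold = 1e-9),
                 "larger distThreshold")
})

test_that("consensus is invariant to replicate order", {
    p <- plantedInput(8, n = 60, G = 50, P = 2)
    inp <- quietInput(p$sce)
    run <- runNMFReplicates(inp, k = 2, nReplicates = 12, baseSeed = 3)
    cr1 <- consensusNMF(run, inp, distThreshold = 0.15)
    perm <- sample(12)
    rows <- as.vector(t(outer((perm - 1) * 2, 1:2, "+")))
    run2 <- new("FactorizationRun", k = 2L, spectra = run@spectra[rows, ],
                objective = run@objective[perm],
                replicateSeeds = run@replicateSeeds[perm])
    cr2 <- consensusNMF(run2, inp, distThreshold = 0.15)
    expect_equal(cr1@spectraScaled, cr2@spectraScaled, tolerance = 1e-12)
    expect_equal(cr1@usages, cr2@usages, tolerance = 1e-10)
})

test_that("k selection follows the stability/error rule and errors on empty input", {
    mk <- function(k, stab, err) {
        new("ConsensusResult", k = as.integer(k), distThreshold = 0.1,
            keptComponentMask = TRUE, spectraScaled = matrix(1, k, 2),
            spectraTpm = matrix(1, k, 2), spectraZ = matrix(0, k, 2),
            usages = matrix(1, 2, k), stability = stab, error = err,
            geneNames = c("a", "b"), cellNames = c("x", "y"),
            sampleId = "S", datasetId = "D")
    }
    res <- list(`3` = mk(3, 0.8, 0.50), `4` = mk(4, 0.95, 0.49),
                `5` = mk(5, 0.99, 0.60))  # k=5 excluded: error too high
    sel <- selectK(res)
    expect_equal(sel$k, 4)
    expect_equal(nrow(sel$diagnostics), 3)
    single <- selectK(res[2])
    expect_equal(single$k, 4)
    expect_error(selectK(list()), "no consensus")
})

test_that("reconstruction error does not increase with k on a fixed sample", {
    p <- plantedInput(10, n = 70, G = 60, P = 3)
    inp <- quietInput(p$sce)
    errs <- vapply(2:5, function(k) {
        run <- runNMFReplicates(inp, k, nReplicates = 15, baseSeed = 21)
        consensusNMF(run, inp)@error
    }, numeric(1))
    expect_true(all(diff(errs) <= 1e-6))
})

test_that("the q100/q75 usage-ratio filter excludes single-cell-driven programs", {
    # direct quantile oracle: q75 of {0.1 x99, 5 x1} is 0.1 -> ratio 50
    u <- cbind(flat = rep(0.5, 100),
               spiky = c(rep(0.1, 99), 5),
               lone = c(rep(0, 99), 1))
    expect_equal(unname(quantile(u[, "spiky"], 0.75)), 0.1)
    cr <- new("ConsensusResult", k = 3L, distThreshold = 0.1,
              keptComponentMask = rep(TRUE, 3),
              spectraScaled = matrix(1, 3, 4), spectraTpm = matrix(1, 3, 4),
              spectraZ = matrix(0, 3, 4), usages = u,
              stability = 1, error = 0.1, geneNames = letters[1:4],
              cellNames = sprintf("c%d", 1:100),
              sampleId = "S", datasetId = "D")
    out <- filterSingleCellDriven(cr, maxRatio = 10)
    expect_equal(out$qc$ratio, c(1, 50, Inf))
    expect_equal(out$qc$excluded, c(FALSE, TRUE, TRUE))
    expect_equal(colnames(out$result@usages), "flat")
})

test_that("NNLS matches grid search and an independent solver", {
    set.seed(12)
    A <- matrix(runif(6 * 2), 6, 2)  # 6 genes, 2 programs
    for (j in 1:8) {
        b <- A %*% runif(2, 0, 1.2) + rnorm(6, 0, 0.05)
        x <- nnlsFit(A, as.numeric(b))
        g <- gridNNLS2(A, as.numeric(b), step = 0.01, upper = 1.5)
        expect_true(all(abs(x - g) <= 0.02))
    }
    skip_if_not_installed("pracma")
    for (j in 1:5) {
        A5 <- matrix(runif(20 * 5, 0, 2), 20, 5)
        b5 <- runif(20, -0.2, 2)
        expect_equal(as.numeric(nnlsFit(A5, b5)),
                     as.numeric(pracma::lsqnonneg(A5, b5)$x),
                     tolerance = 1e-8)
    }
})

test_that("the selection rule recovers the planted program count across seeds", {
    # near-constant sequencing depth: otherwise depth variation is itself
    # a reproducibly stable extra factor and the true rank exceeds the
    # planted program count
    pick <- function(seed) {
        samples <- data.frame(sample_id = "S1", dataset_id = "DA",
                              cohort = "Young", n_cells = 110L)
        cfg <- truthConfig(nGenes = 200L, nPrograms = 4L, nAnchors = 25L,
                           samples = samples, libsizeSd = 0.05,
                           libsizeMu = log(1200), seed = seed)
        sim <- simulateCounts(generateTruth(cfg))
        sce <- qcFilterSample(sim$samples[[1]])
        vg <- selectSharedVariableGenes(
            list(DA = SummarizedExperiment::assay(sce, "counts")),
            nTop = 150, minDatasets = 1)
        inp <- suppressWarnings(prepareCnmfInput(sce, vg))
        runCnmfSample(inp, kRange = 3:6, nReplicates = 50, seed = seed)$k
    }
    ks <- vapply(1:20, pick, numeric(1))
    expect_gte(mean(ks == 4), 0.8)
})
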