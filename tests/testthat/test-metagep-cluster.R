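# Build a catalog of planted programs duplicated across samples/datasets
# with Gaussian spectrum noise.
plantedCatalog <- function(nPrograms = 4, nSamples = 6, G = 120,
                           noise = 0.1, seed = 1,
                           datasets = rep(c("D1", "D2"), length.out = nSamples)) {
    set.seed(seed)
    # orthogonalized base spectra: cross-family correlations stay near 0,
    # which a threshold as low as 0.1 requires
    base <- t(qr.Q(qr(matrix(rnorm(G * nPrograms), G, nPrograms)))) *
        sqrt(G)
    results <- lapply(seq_len(nSamples), function(s) {
        z <- base + matrix(rnorm(nPrograms * G, 0, noise), nPrograms, G)
        dimnames(z) <- list(sprintf("p%d", seq_len(nPrograms)),
                            sprintf("g%03d", seq_len(G)))
        fakeConsensus(z, sampleId = sprintf("S%02d", s),
                      datasetId = datasets[s])
    })
    list(catalog = buildProgramCatalog(results), base = base)
}

test_that("identical spectra cluster together and orthogonal spectra do not", {
    z <- matrix(rnorm(2 * 50), 2, 50)
    z <- rbind(z, z[1, ])  # program 3 duplicates program 1
    dimnames(z) <- list(c("a", "b", "dup"), sprintf("g%02d", 1:50))
    cat2 <- buildProgramCatalog(list(
        fakeConsensus(z[c(1, 3), ], sampleId = "S1", datasetId = "D1"),
        fakeConsensus(z[2, , drop = FALSE], sampleId = "S2",
                      datasetId = "D2")))
    cl <- clusterPrograms(cat2, corrThresh = 0.5)
    expect_length(cl, 1)
    expect_length(cl[[1]], 2)  # the two copies, not the unrelated program
    # exactly orthogonal spectra: no pair above threshold, no clusters
    zo <- diag(4)[, rep(1:4, each = 10)] * rep(c(1, -1), 20)[1:40]
    zo <- matrix(0, 4, 40)
    for (i in 1:4) zo[i, ((i - 1) * 10 + 1):(i * 10)] <- rnorm(10)
    zo <- zo - rowMeans(zo)  # centered, disjoint support: r near 0
    dimnames(zo) <- list(sprintf("p%d", 1:4), sprintf("g%02d", 1:40))
    cato <- buildProgramCatalog(lapply(1:4, function(i)
        fakeConsensus(zo[i, , drop = FALSE], sampleId = sprintf("S%d", i),
                      datasetId = "D1")))
    expect_length(clusterPrograms(cato, corrThresh = 0.6), 0)
})

test_that("planted program copies are recovered as exactly one cluster each", {
    pc <- plantedCatalog(nPrograms = 4, nSamples = 6, noise = 0.1, seed = 3)
    cl <- clusterPrograms(pc$catalog, corrThresh = 0.1, pctThresh = 0.1)
    expect_length(cl, 4)
    expect_true(all(lengths(cl) == 6))
    # each cluster collects all copies of one planted program
    for (m in cl) {
        progs <- sub(".*_k[0-9]+_p", "", m)
        expect_length(unique(progs), 1)
    }
})

test_that("cluster output is invariant to program input order", {
    pc <- plantedCatalog(nPrograms = 3, nSamples = 5, noise = 0.15, seed = 5)
    cl1 <- clusterPrograms(pc$catalog, corrThresh = 0.1)
    perm <- sample(nrow(pc$catalog@info))
    cat2 <- new("ProgramCatalog", info = pc$catalog@info[perm, ],
                zSpectra = pc$catalog@zSpectra[perm, ],
                tpmSpectra = pc$catalog@tpmSpectra[perm, ],
                geneNames = pc$catalog@geneNames)
    cl2 <- clusterPrograms(cat2, corrThresh = 0.1)
    expect_equal(lapply(cl1, sort), lapply(cl2, sort))
})

test_that("raising the correlation threshold never grows a cluster", {
    pc <- plantedCatalog(nPrograms = 3, nSamples = 6, noise = 0.4, seed = 7)
    sizes <- vapply(c(0.1, 0.4, 0.7, 0.9), function(th) {
        cl <- clusterPrograms(pc$catalog, corrThresh = th)
        if (length(cl)) max(lengths(cl)) else 0L
    }, integer(1))
    expect_true(all(diff(sizes) <= 0))
})

test_that("metaGEP membership rules reject small or single-dataset clusters", {
    # 4 programs / 1 dataset: size rule passes, dataset rule fails
    pc1 <- plantedCatalog(nPrograms = 1, nSamples = 4, noise = 0.05,
                          seed = 11, datasets = rep("D1", 4))
    cl1 <- clusterPrograms(pc1$catalog, corrThresh = 0.1)
    expect_length(cl1, 1)
    mg1 <- defineMetaGEPs(pc1$catalog, cl1, minPrograms = 4, minDatasets = 2)
    expect_equal(nrow(mg1@meanZ), 0)
    # 3 programs / 3 datasets: dataset rule passes, size rule fails
    pc2 <- plantedCatalog(nPrograms = 1, nSamples = 3, noise = 0.05,
                          seed = 12, datasets = c("D1", "D2", "D3"))
    cl2 <- clusterPrograms(pc2$catalog, corrThresh = 0.1)
    mg2 <- defineMetaGEPs(pc2$catalog, cl2, minPrograms = 4, minDatasets = 2)
    expect_equal(nrow(mg2@meanZ), 0)
})

test_that("metaGEP spectra are member means and members satisfy the invariants", {
    pc <- plantedCatalog(nPrograms = 4, nSamples = 6, noise = 0.1, seed = 9)
    cl <- clusterPrograms(pc$catalog, corrThresh = 0.1)
    mg <- defineMetaGEPs(pc$catalog, cl, minPrograms = 4, minDatasets = 2)
    expect_equal(nrow(mg@meanZ), 4)
    asn <- metagepAssignments(mg)
    expect_true(all(asn$r_to_centroid >= 0.1))
    # mean spectra equal hand-computed member means
    m1 <- asn$program_id[asn$metagep == "metaGEP1"]
    expect_equal(mg@meanZ["metaGEP1", ],
                 colMeans(pc$catalog@zSpectra[m1, ]), tolerance = 1e-12)
    expect_equal(mg@meanTpm["metaGEP1", ],
                 colMeans(pc$catalog@tpmSpectra[m1, ]), tolerance = 1e-12)
    # every metaGEP satisfies the membership rules
    for (m in rownames(mg@meanZ)) {
        d <- asn[asn$metagep == m, ]
        expect_gte(nrow(d), 4)
        expect_gte(length(unique(d$dataset_id)), 2)
    }
})

test_that("the expression matrix respects gene order and single/mean members", {
    z <- matrix(rnorm(2 * 30), 2, 30,
                dimnames = list(c("p1", "p2"), sprintf("g%02d", 1:30)))
    cat1 <- buildProgramCatalog(lapply(1:4, function(i)
        fakeConsensus(z + rnorm(60, 0, 0.01),
                      sampleId = sprintf("S%d", i),
                      datasetId = c("D1", "D2")[1 + i %% 2])))
    cl <- clusterPrograms(cat1, corrThresh = 0.5)
    mg <- defineMetaGEPs(cat1, cl, minPrograms = 4, minDatasets = 2)
    em <- metagepExpressionMatrix(mg)
    expect_equal(dim(em), c(nrow(mg@meanZ), 30L))
    rev <- metagepExpressionMatrix(mg, rev(mg@geneNames))
    expect_equal(rev[, 1], em[, 30])
    expect_error(metagepExpressionMatrix(mg, c("nope", mg@geneNames)),
                 "gene-order mismatch")
    # a two-member cluster averages elementwise; one member passes through
    two <- buildProgramCatalog(list(
        fakeConsensus(z[1, , drop = FALSE], sampleId = "A", datasetId = "D1"),
        fakeConsensus(z[1, , drop = FALSE] + 0.02, sampleId = "B",
                      datasetId = "D2")))
    clTwo <- clusterPrograms(two, corrThresh = 0.5)
    mgTwo <- defineMetaGEPs(two, clTwo, minPrograms = 2, minDatasets = 2)
    expect_equal(unname(mgTwo@meanTpm[1, ]),
                 unname(colMeans(two@tpmSpectra)), tolerance = 1e-12)
})

test_that("zero-variance spectra are excluded from the catalog with a warning", {
    z <- rbind(flat = rep(0, 20), ok = rnorm(20))
    colnames(z) <- sprintf("g%02d", 1:20)
    expect_warning(
        cat1 <- buildProgramCatalog(list(
            fakeConsensus(z, sampleId = "S1", datasetId = "D1"))),
        "zero-variance")
    expect_equal(nrow(cat1@info), 1)
})
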