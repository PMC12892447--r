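test_that("the enrichment score matches a brute-force running sum", {
    # forced maximum: the set is the single top-ranked gene
    rk <- stats::setNames(seq(5, 0.5, length.out = 10),
                          sprintf("g%02d", 1:10))
    res <- prerankedGSEA(rk, "g01", nPerm = 200, seed = 1)
    expect_equal(res$ES, 1)
    # random 10-gene rankings vs the independent oracle
    set.seed(2)
    for (i in 1:12) {
        rk <- stats::setNames(rnorm(10), sprintf("g%02d", 1:10))
        set <- sample(names(rk), 3)
        mine <- prerankedGSEA(rk, set, nPerm = 100, seed = i)
        expect_equal(mine$ES, bruteGseaES(rk, set), tolerance = 1e-12)
        expect_true(mine$ES >= -1 && mine$ES <= 1)
        expect_true(mine$p > 0 && mine$p <= 1)
        expect_equal(sign(mine$NES), sign(mine$ES))
    }
    expect_error(prerankedGSEA(rk, "absent"), "no gene of the set")
    expect_error(prerankedGSEA(c(a = 1, b = NA), "a"), "NA")
})

test_that("enrichment scores agree with fgsea on a larger ranking", {
    set.seed(5)
    rk <- sort(stats::setNames(rnorm(60), sprintf("g%02d", 1:60)),
               decreasing = TRUE)
    sets <- list(s1 = sprintf("g%02d", c(1, 3, 5, 8, 13)),
                 s2 = sprintf("g%02d", c(48, 50, 55, 58)),
                 s3 = sample(names(rk), 10))
    mine <- gseaBatch(rk, sets, nPerm = 100, seed = 3)
    ref <- suppressWarnings(fgsea::fgsea(sets, rk, nperm = 1000))
    expect_equal(mine$ES[match(ref$pathway, mine$set)], ref$ES,
                 tolerance = 1e-6)
})

test_that("DE signatures honor thresholds, direction and ordering", {
    de <- data.frame(gene = c("a", "b", "c", "d", "e"),
                     logFC = c(2.5, 1.2, 0.8, -2.4, -3.1),
                     p_adj = c(1e-4, 0.01, 1e-6, 1e-7, 0.2))
    up <- signatureFromDE(de, lfcMin = 1, pMax = 0.05, direction = "up")
    expect_equal(up, c("a", "b"))
    down <- signatureFromDE(de, lfcMin = 2, pMax = 1e-5,
                            direction = "down")
    expect_equal(down, "d")  # e fails the p threshold
    expect_error(signatureFromDE(de[0, ]), "empty DE table")
    expect_error(signatureFromDE(data.frame(gene = "a")), "columns")
})

test_that("lineage signatures drop genes shared between lineages", {
    mkDe <- function(genes) data.frame(
        gene = genes, logFC = seq(3, 2, length.out = length(genes)),
        p_adj = rep(1e-12, length(genes)))
    de <- list(MEP = mkDe(c("m1", "m2", "shared")),
               GMP = mkDe(c("g1", "shared", "g2")),
               CLP = mkDe(c("c1", "c2", "c3")))
    sig <- lineageSignatures(de, topN = 50)
    expect_equal(sig$MEP, c("m1", "m2"))
    expect_equal(sort(sig$GMP), c("g1", "g2"))
    expect_equal(sig$CLP, c("c1", "c2", "c3"))
    # all-distinct sets pass through unchanged
    de2 <- list(A = mkDe(c("x1", "x2")), B = mkDe(c("y1", "y2")))
    expect_equal(lineageSignatures(de2, topN = 50),
                 list(A = c("x1", "x2"), B = c("y1", "y2")))
})

test_that("expression-matched random sets reproduce the signature's bin histogram", {
    set.seed(9)
    meanExpr <- stats::setNames(c(rgamma(980, 2, 2), runif(20, 2, 4)),
                                sprintf("g%03d", 1:1000))
    # draw the signature from the dense part of the expression range so
    # every occupied bin has enough non-signature candidates
    dense <- names(meanExpr)[meanExpr < quantile(meanExpr, 0.85)]
    signature <- sample(dense, 68)
    sets <- expressionMatchedRandomSets(meanExpr, signature, nSets = 20,
                                        nBins = 50, seed = 4)
    expect_length(sets, 20)
    rng <- range(meanExpr)
    breaks <- seq(rng[1], rng[2], length.out = 51)
    binOf <- function(g) findInterval(meanExpr[g], breaks,
                                      rightmost.closed = TRUE,
                                      all.inside = TRUE)
    hSig <- tabulate(binOf(signature), 50)
    for (s in sets) {
        expect_length(s, 68)
        expect_equal(tabulate(binOf(s), 50), hSig)
    }
    # matched means: every random set within one bin width of the signature
    binW <- diff(breaks)[1]
    mr <- vapply(sets, function(s) mean(meanExpr[s]), numeric(1))
    expect_true(all(abs(mr - mean(meanExpr[signature])) <= binW))
    # a bin without non-signature alternatives falls back to the
    # signature's own genes, keeping the histogram exact
    tiny <- stats::setNames(c(0.1, 0.2, 0.3, 5), letters[1:4])
    fb <- expressionMatchedRandomSets(tiny, c("d"), nSets = 1,
                                      nBins = 5, seed = 1)
    expect_equal(fb[[1]], "d")
})

test_that("recovery rates hit planted programs and stay at chance for null sets", {
    set.seed(6)
    G <- 200
    genes <- sprintf("g%03d", 1:G)
    mkRun <- function() {
        z <- matrix(rnorm(3 * G, 0, 0.3), 3, G,
                    dimnames = list(NULL, genes))
        z[1, 1:20] <- rnorm(20, 4, 0.3)   # planted top-Z block, program 1
        z[2, 21:40] <- rnorm(20, 4, 0.3)
        fakeConsensus(z, sampleId = "S1", datasetId = "D1")
    }
    runs <- list(S1 = list(mkRun(), mkRun(), mkRun()))
    sets <- c(list(planted1 = genes[1:20], planted2 = genes[21:40],
                   union12 = genes[1:40]),
              lapply(stats::setNames(nm = sprintf("rand%02d", 1:8)),
                     function(nm) sample(genes[41:200], 20)))
    rr <- recoveryRate(runs, sets, alpha = 0.05, nPerm = 4000, seed = 2)
    expect_equal(unname(rr["S1", "planted1"]), 1)
    expect_equal(unname(rr["S1", "planted2"]), 1)
    expect_equal(unname(rr["S1", "union12"]), 1)
    expect_lt(mean(rr["S1", sprintf("rand%02d", 1:8)]), 0.1)
})

test_that("module scores are centered under the null and detect planted shifts", {
    set.seed(7)
    G <- 300
    expr <- matrix(rnorm(G * 100, 2, 1), G, 100,
                   dimnames = list(sprintf("g%03d", 1:G),
                                   sprintf("c%d", 1:100)))
    nullSet <- sample(rownames(expr), 30)
    sc <- moduleScore(expr, nullSet, seed = 3)
    expect_lt(abs(mean(sc)), 0.1)
    # +1 shift in half the cells
    shifted <- expr
    shifted[nullSet, 1:50] <- shifted[nullSet, 1:50] + 1
    sc2 <- moduleScore(shifted, nullSet, seed = 3)
    expect_lt(wilcox.test(sc2[1:50], sc2[51:100],
                          alternative = "greater")$p.value, 0.01)
    expect_error(moduleScore(expr, "absent"), "no set gene")
})

test_that("Fisher overlap reproduces enumeration and symmetric tables", {
    sym <- fisherOverlap(1, 1, 1, 1)
    expect_equal(sym$odds_ratio, 1, tolerance = 1e-9)
    expect_equal(sym$p, 1)
    # spec toy table against the enumeration oracle
    t1 <- fisherOverlap(3, 2, 1, 4)
    expect_equal(t1$p, enumFisherP(3, 2, 1, 4), tolerance = 1e-9)
    # random small tables (total <= 30)
    set.seed(8)
    for (i in 1:10) {
        v <- as.vector(stats::rmultinom(1, sample(8:30, 1), rep(1, 4)))
        ft <- fisherOverlap(v[1], v[2], v[3], v[4])
        expect_equal(ft$p, enumFisherP(v[1], v[2], v[3], v[4]),
                     tolerance = 1e-9)
    }
    expect_error(fisherOverlap(-1, 2, 3, 4), "nonnegative")
})

test_that("hypergeometric ORA matches the one-sided Fisher identity", {
    bg <- sprintf("g%03d", 1:200)
    set <- bg[1:20]
    pws <- list(self = set, disjoint = bg[101:130],
                partial = bg[c(5:10, 150:160)])
    res <- oraHypergeometric(set, pws, bg)
    expect_equal(res$overlap[res$pathway == "self"], 20)
    expect_equal(res$p[res$pathway == "disjoint"], 1)
    for (nm in names(pws)) {
        pw <- pws[[nm]]
        a <- length(intersect(set, pw))
        b <- length(setdiff(pw, set))
        c <- length(setdiff(set, pw))
        d <- 200 - a - b - c
        fp <- fisher.test(matrix(c(a, c, b, d), 2),
                          alternative = "greater")$p.value
        expect_equal(res$p[res$pathway == nm], fp, tolerance = 1e-12)
    }
    expect_error(oraHypergeometric(c(set, "zz"), pws, bg), "subset")
})

test_that("significance stars follow the 0.05/0.01/0.001 convention", {
    expect_equal(significanceStars(c(0.2, 0.04, 0.009, 0.0009, NA)),
                 c("", "*", "**", "***", ""))
})
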