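#' @include AllClasses.R utils.R
NULL

## Classic weighted (exponent 1) running-sum enrichment score.
## w: |score| in descending-score order; pos: sorted hit positions.
.gseaESCore <- function(w, pos) {
    N <- length(w)
    m <- length(pos)
    if (m == N) return(1)
    hitW <- w[pos]
    tot <- sum(hitW)
    miss <- (pos - seq_len(m)) / (N - m)
    if (tot == 0) {  # degenerate: all hit scores zero; only misses move
        return(-max(miss))
    }
    cumW <- cumsum(hitW)
    after <- cumW / tot - miss
    before <- (cumW - hitW) / tot - miss
    hi <- max(after)
    lo <- min(before)
    if (hi > -lo) hi else lo
}

## Permutation null of the enrichment score for random same-size gene sets
## on a fixed ranking. Vectorized across permutations: cumulative sums via
## one triangular matrix product.
.gseaNullES <- function(w, m, nPerm, seed) {
    N <- length(w)
    if (m >= N) return(rep(1, nPerm))
    set.seed(seed)
    P <- vapply(seq_len(nPerm),
                function(i) sort.int(sample.int(N, m)), numeric(m))
    P <- if (m == 1L) matrix(P, ncol = 1L) else t(P)
    W <- matrix(w[P], nPerm, m)
    U <- upper.tri(matrix(0, m, m), diag = TRUE) * 1
    cumW <- W %*% U
    tot <- cumW[, m]
    zero <- tot == 0
    tot[zero] <- 1
    miss <- (P - rep(seq_len(m), each = nPerm)) / (N - m)
    after <- cumW / tot - miss
    before <- (cumW - W) / tot - miss
    hi <- do.call(pmax, as.data.frame(after))
    lo <- do.call(pmin, as.data.frame(before))
    es <- ifelse(hi > -lo, hi, lo)
    es[zero] <- -do.call(pmax, as.data.frame(miss))[zero]
    es
}

.gseaOne <- function(scores, ordIdx, w, setIdx, nulls) {
    pos <- sort.int(match(setIdx, ordIdx))
    es <- .gseaESCore(w, pos)
    same <- if (es >= 0) nulls[nulls > 0] else nulls[nulls < 0]
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    c(ES = es, NES = nes, p = p)
}

#' Preranked GSEA with a random gene-set permutation null
#'
#' Classic weighted running-sum enrichment score (weight exponent 1: a hit
#' increments proportionally to |score| / sum over set |score|, a miss
#' decrements 1/(N - set size)); ES is the signed extremum of the running
#' sum. The null is \code{nPerm} random same-size gene sets drawn from the
#' ranking; p = (1 + #same-sign null |ES| >= |ES|) / (1 + #same-sign
#' nulls), and NES = ES / mean(|same-sign null ES|).
#'
#' @param ranking named numeric vector of per-gene scores (no NA).
#' @param set character vector of genes (at least one must be in the
#'   ranking).
#' @param nPerm number of null sets (default 1000).
#' @param seed RNG seed.
#' @return one-row data.frame: set_size, ES, NES, p.
#' @seealso \code{\link{gseaBatch}} for many sets with BH adjustment.
#' @export
prerankedGSEA <- function(ranking, set, nPerm = 1000L, seed = 1L) {
    if (anyNA(ranking)) stop("ranking contains NA")
    setIdx <- which(names(ranking) %in% set)
    if (!length(setIdx)) stop("no gene of the set occurs in the ranking")
    ordIdx <- order(ranking, decreasing = TRUE)
    w <- abs(ranking)[ordIdx]
    nulls <- .gseaNullES(w, length(setIdx), nPerm, seed)
    res <- .gseaOne(ranking, ordIdx, w, setIdx, nulls)
    data.frame(set_size = length(setIdx), ES = res["ES"], NES = res["NES"],
               p = res["p"], row.names = NULL)
}

#' Preranked GSEA for a batch of gene sets
#'
#' As \code{\link{prerankedGSEA}}, sharing one permutation null per unique
#' effective set size (the null depends only on the ranking and the set
#' size), with Benjamini-Hochberg adjustment across the batch.
#'
#' @param ranking named numeric vector of per-gene scores.
#' @param sets named list of gene sets; sets without any gene in the
#'   ranking are dropped with a warning.
#' @param nPerm number of null sets per unique size (default 1000).
#' @param seed RNG seed.
#' @return data.frame: set, set_size, ES, NES, p, p_adj (BH).
#' @export
gseaBatch <- function(ranking, sets, nPerm = 1000L, seed = 1L) {
    if (anyNA(ranking)) stop("ranking contains NA")
    ordIdx <- order(ranking, decreasing = TRUE)
    w <- abs(ranking)[ordIdx]
    idxList <- lapply(sets, function(s) which(names(ranking) %in% s))
    empty <- lengths(idxList) == 0
    if (any(empty)) {
        warning(sum(empty), " set(s) without genes in the ranking dropped")
        idxList <- idxList[!empty]
    }
    if (!length(idxList)) stop("no set overlaps the ranking")
    sizes <- lengths(idxList)
    nullBySize <- lapply(stats::setNames(nm = unique(sizes)), function(m)
        .gseaNullES(w, as.integer(m), nPerm, .childSeed(seed, as.integer(m))))
    rows <- lapply(names(idxList), function(nm) {
        res <- .gseaOne(ranking, ordIdx, w, idxList[[nm]],
                        nullBySize[[as.character(sizes[[nm]])]])
        data.frame(set = nm, set_size = sizes[[nm]], ES = res["ES"],
                   NES = res["NES"], p = res["p"], row.names = NULL)
    })
    out <- do.call(rbind, rows)
    out$p_adj <- p.adjust(out$p, method = "BH")
    out
}

#' Significance stars for adjusted p-values
#'
#' The annotation convention used on meta-program enrichment heatmaps:
#' \code{***} for p < 0.001, \code{**} for p < 0.01, \code{*} for
#' p < 0.05, empty otherwise.
#'
#' @param p numeric vector of (adjusted) p-values.
#' @return character vector of star annotations.
#' @export
significanceStars <- function(p) {
    vapply(p, function(x) {
        if (is.na(x)) ""
        else if (x < 0.001) "***"
        else if (x < 0.01) "**"
        else if (x < 0.05) "*"
        else ""
    }, character(1))
}

#' Build a gene signature from a differential-expression table
#'
#' Genes passing both the log-fold-change and adjusted-p thresholds in the
#' stated direction, ordered by descending |logFC|. With
#' \code{direction = "up"} the rule is logFC > lfcMin and p_adj < pMax
#' (e.g. the aging signature: logFC > 1, p.adj < 0.05); with
#' \code{"down"}, logFC < -lfcMin (e.g. a quiescence signature:
#' logFC < -2, FDR < 1e-5).
#'
#' @param de data.frame with columns \code{gene}, \code{logFC},
#'   \code{p_adj}.
#' @param lfcMin absolute logFC threshold.
#' @param pMax adjusted-p threshold.
#' @param direction \code{"up"} or \code{"down"}.
#' @return character vector of genes (descending |logFC|).
#' @export
signatureFromDE <- function(de, lfcMin = 1, pMax = 0.05,
                            direction = c("up", "down")) {
    direction <- match.arg(direction)
    need <- c("gene", "logFC", "p_adj")
    if (!all(need %in% names(de)))
        stop("DE table must have columns: ", paste(need, collapse = ", "))
    if (!nrow(de)) stop("empty DE table")
    pass <- de$p_adj < pMax &
        (if (direction == "up") de$logFC > lfcMin else de$logFC < -lfcMin)
    pass[is.na(pass)] <- FALSE
    hit <- de[pass, , drop = FALSE]
    hit$gene[order(-abs(hit$logFC))]
}

#' Disjoint lineage signatures from per-lineage DE tables
#'
#' Per lineage: filter to p_adj < \code{pMax} and logFC > \code{lfcMin},
#' rank by descending logFC, take the top \code{topN}; then remove every
#' gene occurring in two or more of the resulting sets from all of them.
#'
#' @param deList named list of DE tables (gene, logFC, p_adj).
#' @param topN genes per lineage before the overlap exclusion (default 50).
#' @param pMax adjusted-p threshold (default 1e-10).
#' @param lfcMin logFC threshold (default 1).
#' @return named list of disjoint gene vectors.
#' @export
lineageSignatures <- function(deList, topN = 50L, pMax = 1e-10,
                              lfcMin = 1) {
    sets <- lapply(deList, function(de) {
        pass <- de$p_adj < pMax & de$logFC > lfcMin
        pass[is.na(pass)] <- FALSE
        hit <- de[pass, , drop = FALSE]
        head(hit$gene[order(-hit$logFC)], topN)
    })
    shared <- unique(unlist(sets)[duplicated(unlist(sets))])
    lapply(sets, setdiff, y = shared)
}

#' Expression-matched random gene sets
#'
#' Genes are split into \code{nBins} equal-width (equidistant) bins over
#' the range of mean expression. Each random set draws, per bin, exactly
#' as many genes as the signature has in that bin (without replacement,
#' excluding the signature's own genes whenever enough alternatives
#' exist), so every random set reproduces the signature's per-bin
#' histogram and size. A bin with too few candidates falls back to the
#' nearest bins with a warning.
#'
#' @param meanExpr named numeric of per-gene mean (log-normalized)
#'   expression over all genes in the universe.
#' @param signature character vector of genes, all present in
#'   \code{meanExpr}.
#' @param nSets number of random sets (default 20).
#' @param nBins number of equal-width bins (default 50).
#' @param seed RNG seed.
#' @return named list of \code{nSets} gene vectors.
#' @export
expressionMatchedRandomSets <- function(meanExpr, signature, nSets = 20L,
                                        nBins = 50L, seed = 1L) {
    if (!all(signature %in% names(meanExpr)))
        stop("signature genes missing from meanExpr: ",
             paste(head(setdiff(signature, names(meanExpr))), collapse = ", "))
    rng <- range(meanExpr)
    breaks <- seq(rng[1], rng[2], length.out = nBins + 1)
    bin <- findInterval(meanExpr, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    names(bin) <- names(meanExpr)
    sigBin <- bin[signature]
    need <- table(sigBin)
    set.seed(seed)
    out <- vector("list", nSets)
    for (s in seq_len(nSets)) {
        picked <- character()
        for (b in names(need)) {
            bi <- as.integer(b)
            n <- need[[b]]
            pool <- names(bin)[bin == bi & !(names(bin) %in% signature)]
            if (length(pool) < n)  # signature genes allowed when no
                pool <- names(bin)[bin == bi]  # alternatives exist
            if (length(pool) < n) {
                ## the whole bin is short: spill into nearest bins
                off <- 1L
                while (length(pool) < n && off < nBins) {
                    pool <- c(pool, names(bin)[bin %in% c(bi - off, bi + off)])
                    off <- off + 1L
                }
                warning("bin ", b, " short of candidates; fell back to ",
                        "nearest bins")
            }
            picked <- c(picked, sample(pool, n))
        }
        out[[s]] <- unname(picked)
    }
    names(out) <- sprintf("random_%02d", seq_len(nSets))
    out
}

#' Gene-set recovery rates over consensus NMF runs
#'
#' A run (one consensus factorization of a sample, e.g. at one k)
#' "recovers" a gene set when any of its programs shows a significantly
#' positively enriched preranked GSEA result on the program's Z-score
#' ranking after Bonferroni correction across (sets tested x programs in
#' the run). The recovery rate of a set in a sample is the fraction of
#' that sample's runs that recover it. Combination signatures are
#' supported by passing union sets.
#'
#' @param runs named list (per sample) of lists of
#'   \linkS4class{ConsensusResult} (the sample's cNMF runs).
#' @param geneSets named list of gene sets.
#' @param alpha significance level after Bonferroni (default 0.05).
#' @param nPerm permutations per null (default 10000; the Bonferroni
#'   threshold must be reachable: the smallest attainable p is about
#'   2/nPerm).
#' @param seed RNG seed.
#' @return sample x set matrix of recovery fractions.
#' @export
recoveryRate <- function(runs, geneSets, alpha = 0.05, nPerm = 10000L,
                         seed = 1L) {
    samples <- names(runs)
    out <- matrix(0, length(samples), length(geneSets),
                  dimnames = list(samples, names(geneSets)))
    for (s in seq_along(runs)) {
        rec <- matrix(FALSE, length(runs[[s]]), length(geneSets))
        for (t in seq_along(runs[[s]])) {
            cr <- runs[[s]][[t]]
            Z <- cr@spectraZ
            nTests <- length(geneSets) * nrow(Z)
            for (p in seq_len(nrow(Z))) {
                ranking <- stats::setNames(Z[p, ], cr@geneNames)
                res <- gseaBatch(ranking, geneSets, nPerm = nPerm,
                                 seed = .childSeed(seed, s, t, p))
                hit <- res$ES > 0 & res$p * nTests < alpha
                rec[t, match(res$set, names(geneSets))] <-
                    rec[t, match(res$set, names(geneSets))] | hit
            }
        }
        out[s, ] <- colMeans(rec)
    }
    out
}

#' Module score of a gene set per cell
#'
#' Mean normalized expression of the set genes minus the mean expression
#' of a control set drawn once per call: genes are placed into
#' \code{nBins} equal-occupancy average-expression bins and
#' \code{ctrlPerGene} control genes are sampled from the bin of each set
#' gene.
#'
#' @param normExpr genes x cells normalized-expression matrix.
#' @param set gene set (at least one gene present).
#' @param nBins equal-occupancy bins (default 25).
#' @param ctrlPerGene control genes sampled per set gene (default 100).
#' @param seed RNG seed.
#' @return numeric per-cell score, named by cell.
#' @export
moduleScore <- function(normExpr, set, nBins = 25L, ctrlPerGene = 100L,
                        seed = 1L) {
    set <- intersect(set, rownames(normExpr))
    if (!length(set)) stop("no set gene present in the expression matrix")
    avg <- Matrix::rowMeans(normExpr)
    bin <- cut(rank(avg, ties.method = "first"), breaks = nBins,
               labels = FALSE)
    names(bin) <- rownames(normExpr)
    set.seed(seed)
    ctrl <- unlist(lapply(set, function(g) {
        pool <- names(bin)[bin == bin[[g]]]
        sample(pool, min(ctrlPerGene, length(pool)))
    }))
    setMean <- Matrix::colMeans(normExpr[set, , drop = FALSE])
    ctrlMean <- Matrix::colMeans(normExpr[ctrl, , drop = FALSE])
    stats::setNames(as.numeric(setMean - ctrlMean), colnames(normExpr))
}

#' Fisher's exact test on a 2x2 overlap table
#'
#' Two-sided p by summing hypergeometric probabilities at most as likely
#' as the observed table, and the conditional maximum-likelihood odds
#' ratio (both via \code{stats::fisher.test}), alongside the cross-product
#' (sample) odds-ratio estimate.
#'
#' @param a genes in both sets; @param b in set B only; @param c in set A
#'   only; @param d in neither (background remainder). All nonnegative
#'   integers; a+b+c+d is the background size.
#' @return list: odds_ratio (conditional MLE), odds_ratio_sample
#'   (cross-product), p (two-sided), table (the 2x2 matrix).
#' @examples
#' # mouse/human aging-signature ortholog overlap:
#' fisherOverlap(7, 119, 111, 11409)
#' @export
fisherOverlap <- function(a, b, c, d) {
    v <- c(a, b, c, d)
    if (any(v < 0) || any(v != round(v)))
        stop("table entries must be nonnegative integers")
    tab <- matrix(c(a, c, b, d), 2, 2,
                  dimnames = list(inA = c("yes", "no"),
                                  inB = c("yes", "no")))
    ft <- fisher.test(tab)
    list(odds_ratio = unname(ft$estimate),
         odds_ratio_sample = if (b * c == 0) Inf else (a * d) / (b * c),
         p = ft$p.value, table = tab)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p of the overlap between a query set and each
#' pathway over a fixed background, BH-adjusted across pathways. A
#' disjoint overlap yields p = 1 under the upper-tail convention
#' P(X >= overlap).
#'
#' @param set query gene set (must be a subset of \code{background}).
#' @param pathways named list of pathways (intersected with the
#'   background).
#' @param background background gene universe.
#' @return data.frame: pathway, overlap, pathway_size, p, p_adj.
#' @export
oraHypergeometric <- function(set, pathways, background) {
    if (!all(set %in% background))
        stop("query set is not a subset of the background")
    if (!is.list(pathways)) pathways <- list(pathway = pathways)
    rows <- lapply(names(pathways), function(nm) {
        pw <- intersect(pathways[[nm]], background)
        ov <- length(intersect(set, pw))
        p <- phyper(ov - 1, length(pw), length(background) - length(pw),
                    length(set), lower.tail = FALSE)
        data.frame(pathway = nm, overlap = ov, pathway_size = length(pw),
                   p = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_adj <- p.adjust(out$p, method = "BH")
    out
}
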