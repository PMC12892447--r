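#' @include AllClasses.R utils.R
NULL

#' Intersect TF sets across datasets
#'
#' @param matrices named list of TF x cell activity matrices (one per
#'   dataset).
#' @return sorted character vector of TFs present in every dataset.
#' @export
intersectTFs <- function(matrices) {
    if (!length(matrices)) stop("need at least one dataset")
    common <- Reduce(intersect, lapply(matrices, rownames))
    if (!length(common)) stop("no TF is present in all datasets")
    sort(common)
}

#' Associate TF activities with a cohort or usage target
#'
#' Within each dataset, the Pearson correlation between every TF's
#' activity and the target is computed (point-biserial when the target is
#' a 0/1 cohort encoding, which is the same formula); TFs are ranked
#' within each dataset by descending correlation (rank 1 = largest, ties
#' averaged; set \code{absRank = TRUE} to rank by |r|). Ranks and
#' correlations are averaged across datasets and a TF is selected when
#' mean rank <= \code{rankMax} and mean correlation >= \code{rMin}.
#' Zero-variance activities yield an undefined correlation, which is
#' recorded as missing, excluded from the means, and warned about.
#'
#' @param matrices named list of TF x cell activity matrices; only TFs
#'   present in all datasets (\code{\link{intersectTFs}}) are used.
#' @param target named numeric vector over cells: binary cohort (0/1,
#'   1 = Aged) or a real per-cell metaGEP usage; matched to each dataset's
#'   cell barcodes by name.
#' @param rankMax mean-rank selection threshold (default 10).
#' @param rMin mean-correlation selection threshold (default 0.15).
#' @param absRank rank by |r| instead of signed r (default FALSE).
#' @return a \linkS4class{TFAssociation}.
#' @export
associateTFs <- function(matrices, target, rankMax = 10, rMin = 0.15,
                         absRank = FALSE) {
    tfs <- intersectTFs(matrices)
    nd <- length(matrices)
    r <- matrix(NA_real_, length(tfs), nd,
                dimnames = list(tfs, names(matrices)))
    for (d in seq_len(nd)) {
        act <- matrices[[d]][tfs, , drop = FALSE]
        cells <- intersect(colnames(act), names(target))
        if (length(cells) < 3)
            stop("fewer than 3 cells with a target value in dataset ",
                 names(matrices)[d])
        act <- act[, cells, drop = FALSE]
        y <- target[cells]
        if (sd(y) == 0) stop("target is constant in dataset ",
                             names(matrices)[d])
        sds <- .rowSdsDense(act)
        if (any(sds == 0))
            warning(sum(sds == 0), " zero-variance TF activity value(s) in ",
                    "dataset ", names(matrices)[d],
                    " recorded as missing")
        rd <- suppressWarnings(as.numeric(cor(t(act), y)))
        rd[sds == 0] <- NA_real_
        r[, d] <- rd
    }
    key <- if (absRank) abs(r) else r
    ranks <- apply(key, 2L, function(col) {
        out <- rep(NA_real_, length(col))
        ok <- !is.na(col)
        out[ok] <- rank(-col[ok], ties.method = "average")
        out
    })
    dimnames(ranks) <- dimnames(r)
    meanRank <- rowMeans(ranks, na.rm = TRUE)
    meanR <- rowMeans(r, na.rm = TRUE)
    tab <- data.frame(tf = tfs, mean_rank = meanRank, mean_r = meanR,
                      selected = meanRank <= rankMax & meanR >= rMin,
                      row.names = NULL, stringsAsFactors = FALSE)
    tab$selected[is.na(tab$selected)] <- FALSE
    new("TFAssociation", r = r, ranks = ranks, table = tab,
        params = list(rankMax = rankMax, rMin = rMin, absRank = absRank))
}

#' Z-score and percentile-clip values for export
#'
#' Z-scores the values and winsorizes them at the given percentiles (the
#' convention used when visualizing per-cell TF activities, avoiding color
#' scales distorted by outliers). Constant input yields all zeros.
#'
#' @param values numeric vector (length >= 2).
#' @param loPct,hiPct clipping percentiles (defaults 0.1 and 99.9).
#' @return clipped z-scores, same length and names.
#' @export
zscoreClip <- function(values, loPct = 0.1, hiPct = 99.9) {
    if (length(values) < 2) stop("need at least 2 values")
    s <- sd(values)
    if (s == 0) return(stats::setNames(rep(0, length(values)),
                                       names(values)))
    z <- (values - mean(values)) / s
    q <- quantile(z, c(loPct, hiPct) / 100, names = FALSE)
    pmin(pmax(z, q[1]), q[2])
}
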