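#' @include AllClasses.R
NULL

## Lawson-Hanson active-set NNLS on the normal equations. k is small
## (number of programs), so subset solves are cheap; the normal-equation
## form lets many right-hand sides share one crossprod.
.nnlsCore <- function(AtA, Atb, tol = 1e-10) {
    k <- length(Atb)
    x <- numeric(k)
    passive <- logical(k)
    w <- Atb
    scale <- max(abs(Atb), 1)
    for (outer in seq_len(30L * k)) {
        cand <- which(!passive & w > tol * scale)
        if (!length(cand)) break
        passive[cand[which.max(w[cand])]] <- TRUE
        repeat {
            s <- numeric(k)
            sub <- tryCatch(
                solve(AtA[passive, passive, drop = FALSE], Atb[passive]),
                error = function(e)
                    solve(AtA[passive, passive, drop = FALSE] +
                          diag(1e-12, sum(passive)), Atb[passive]))
            s[passive] <- sub
            if (all(s[passive] > 0)) { x <- s; break }
            drop <- passive & (s <= 0)
            alpha <- min(x[drop] / (x[drop] - s[drop]))
            x <- x + alpha * (s - x)
            passive <- passive & (x > tol)
            x[!passive] <- 0
        }
        w <- Atb - drop(AtA %*% x)
    }
    x
}

#' Nonnegative least squares fit of one or many observations
#'
#' Solves \code{min ||b - A x||} subject to \code{x >= 0} by the
#' Lawson-Hanson active-set method on the normal equations. When \code{B}
#' is a matrix, each row is solved against the same design (the cross
#' products are computed once), which is the per-cell usage-projection
#' workhorse.
#'
#' @param A design matrix (observations in rows, one column per
#'   coefficient), e.g. \code{t(spectra)} with genes in rows.
#' @param B numeric vector (one problem) or matrix with one problem per
#'   row of length \code{nrow(A)}.
#' @return a coefficient vector, or a matrix with one coefficient row per
#'   row of \code{B}.
#' @export
nnlsFit <- function(A, B) {
    A <- as.matrix(A)
    AtA <- crossprod(A)
    if (is.matrix(B)) {
        stopifnot(ncol(B) == nrow(A))
        AtB <- B %*% A  # row i holds t(A) %*% B[i, ]
        out <- matrix(0, nrow(B), ncol(A),
                      dimnames = list(rownames(B), colnames(A)))
        for (i in seq_len(nrow(B)))
            out[i, ] <- .nnlsCore(AtA, AtB[i, ])
        out
    } else {
        stopifnot(length(B) == nrow(A))
        stats::setNames(.nnlsCore(AtA, drop(crossprod(A, B))), colnames(A))
    }
}

#' Log-normalize counts (counts per 10,000, then log1p)
#'
#' The package-wide convention for "normalized expression": each cell is
#' scaled to \code{scaleFactor} total counts and log1p-transformed.
#'
#' @param counts genes x cells matrix (dense or sparse).
#' @param scaleFactor target per-cell total (default 1e4).
#' @return a matrix of the same shape and class family.
#' @export
logNormalize <- function(counts, scaleFactor = 1e4) {
    tot <- Matrix::colSums(counts)
    tot[tot == 0] <- 1
    if (inherits(counts, "sparseMatrix")) {
        norm <- counts %*% Matrix::Diagonal(x = scaleFactor / tot)
        norm@x <- log1p(norm@x)
        dimnames(norm) <- dimnames(counts)
        norm
    } else {
        log1p(sweep(counts, 2, scaleFactor / tot, "*"))
    }
}

## Derive a bounded child seed from a base seed and one or more indices.
## Keeps every seed in [0, 2^31): R set.seed() requires a 32-bit integer.
.childSeed <- function(seed, ...) {
    idx <- c(...)
    v <- as.numeric(seed) %% 2147483647
    for (i in idx) v <- (v * 1103515245 + 12345 + i) %% 2147483647
    as.integer(v)
}

## Column-wise standard deviations of a dense or sparse matrix without
## densifying (denominator n - 1).
.colSds <- function(m) {
    n <- nrow(m)
    if (n < 2) return(rep(0, ncol(m)))
    mu <- Matrix::colSums(m) / n
    sq <- Matrix::colSums(m^2)
    v <- (sq - n * mu^2) / (n - 1)
    v[v < 0] <- 0
    sqrt(v)
}

.rowSdsDense <- function(m) {
    n <- ncol(m)
    if (n < 2) return(rep(0, nrow(m)))
    mu <- rowMeans(m)
    v <- (rowSums(m^2) - n * mu^2) / (n - 1)
    v[v < 0] <- 0
    sqrt(v)
}
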