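## Probe-level -> gene-level processing: RMA-style background correction,
## quantile normalization and median-polish summarization, plus MAS5-style
## scaling factors and Present/Absent detection calls for array QC.

#' @useDynLib arrayConcord, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.densityMode <- function(x) {
    ## cap the evaluation grid below the extreme right tail: intensity
    ## distributions are heavy-tailed and a stray maximum would stretch the
    ## grid (and the bandwidth) so far that the mode location becomes
    ## unstable; the background mode always sits in the bulk
    hi <- stats::quantile(x, 0.995, names = FALSE)
    d <- stats::density(x, kernel = "epanechnikov", n = 16384L,
                        from = min(x), to = hi)
    d$x[which.max(d$y)]
}

.bgParameters <- function(x) {
    ## Mode-based ad hoc estimators of the normal (background) + exponential
    ## (signal) convolution: background mean = (refined) mode of the
    ## intensity distribution, background SD from the spread below the mode,
    ## signal rate from the mode of the exceedances.
    mu <- .densityMode(x)
    lo <- x[x < mu]
    if (length(lo) >= 2L) mu <- .densityMode(lo)
    lo <- x[x < mu] - mu
    sigma <- if (length(lo) >= 2L)
        sqrt(sum(lo^2) / (length(lo) - 1)) * sqrt(2) else stats::sd(x)
    hi <- x[x > mu] - mu
    alpha <- if (length(hi) >= 2L) 1 / max(.densityMode(hi), .Machine$double.eps)
             else 1 / max(mean(x), .Machine$double.eps)
    list(mu = mu, sigma = max(sigma, .Machine$double.eps), alpha = alpha)
}

.bgAdjustColumn <- function(x) {
    if (length(x) < 10L)
        stop("background correction needs at least 10 probes per array")
    if (stats::sd(x) == 0) return(x)   # degenerate: nothing to deconvolve
    p <- .bgParameters(x)
    a <- x - p$mu - p$sigma^2 * p$alpha
    z <- a / p$sigma
    ## E[signal | observed]: positive and increasing in x. Far in the left
    ## tail the Mills-ratio term cancels a to machine zero, so floor at a
    ## tiny positive intensity to keep downstream log2 finite.
    out <- a + p$sigma * exp(stats::dnorm(z, log = TRUE) -
                             stats::pnorm(z, log.p = TRUE))
    pmax(out, 2^-20)
}

#' RMA-style background correction
#'
#' Per array, fits the normal-plus-exponential convolution model with the
#' published mode-based ad hoc estimators and replaces each observed
#' intensity by the expected true signal given the observation. The
#' transformation is strictly positive and order-preserving within each
#' array.
#'
#' @param x numeric vector (one array) or matrix (arrays in columns) of
#'   strictly positive linear-scale intensities.
#' @return corrected vector or matrix of the same shape.
#' @export
rmaBackgroundCorrect <- function(x) {
    if (any(x <= 0)) stop("intensities must be strictly positive")
    if (is.matrix(x)) {
        out <- vapply(seq_len(ncol(x)), function(j) .bgAdjustColumn(x[, j]),
                      numeric(nrow(x)))
        dimnames(out) <- dimnames(x)
        out
    } else .bgAdjustColumn(x)
}

#' Quantile normalization
#'
#' Forces every column to share the across-column mean of sorted values while
#' preserving within-column ranks. Ties receive the average of the reference
#' values at their tied ranks.
#'
#' @param x numeric matrix with no missing values, arrays in columns.
#' @return normalized matrix of the same shape.
#' @export
quantileNormalize <- function(x) {
    stopifnot(is.matrix(x), !anyNA(x))
    if (ncol(x) == 1L) {
        warning("single-column matrix: quantile normalization is the identity")
        return(x)
    }
    ref <- rowMeans(apply(x, 2L, sort))
    out <- apply(x, 2L, function(col) {
        r <- rank(col, ties.method = "average")
        (ref[floor(r)] + ref[ceiling(r)]) / 2
    })
    dimnames(out) <- dimnames(x)
    out
}

.probesetBlocks <- function(probesetIds) {
    sets <- unique(probesetIds)
    ord <- order(match(probesetIds, sets))
    len <- as.integer(table(factor(probesetIds, levels = sets)))
    list(sets = sets, ord = ord,
         start = c(0L, cumsum(len)[-length(len)]), len = len)
}

#' Median-polish summarization
#'
#' Per probeset, fits log2(PM) ~ probe effect + array effect by Tukey median
#' polish (alternating row/column sweeps; even-count medians take the lower
#' middle value for determinism; convergence when the total absolute residual
#' changes by less than \code{tol} relative, capped at \code{maxIter}
#' iterations) and reports overall + array effects as the probeset's log2
#' expression. Probesets with a single probe pass through unchanged.
#'
#' @param probes a \linkS4class{ProbeMatrix} (supplies the probe -> probeset
#'   map and array annotation).
#' @param pm processed perfect-match matrix on the linear scale (defaults to
#'   the raw \code{pmMatrix(probes)}); log2 is taken internally.
#' @param tol,maxIter convergence tolerance and iteration cap.
#' @return An \linkS4class{ExpressionMatrix} with one row per probeset, in
#'   first-occurrence order.
#' @export
medianPolishSummarize <- function(probes, pm = pmMatrix(probes), tol = 0.01,
                                  maxIter = 10L) {
    ps <- probesets(probes)
    bl <- .probesetBlocks(ps)
    lx <- log2(pm[bl$ord, , drop = FALSE])
    vals <- .medianPolishBlocks(lx, bl$start, bl$len, tol, as.integer(maxIter))
    dimnames(vals) <- list(bl$sets, colnames(pm))
    ExpressionMatrix(vals, group = arrayGroups(probes),
                     replicate = arrayReplicates(probes))
}

#' Full RMA-style summarization
#'
#' Background correction, quantile normalization across the supplied arrays,
#' then log2 median-polish summarization. Following standard practice the
#' procedure is applied to one experiment group at a time, so pass each
#' platform's arrays separately.
#'
#' @param probes a \linkS4class{ProbeMatrix}.
#' @param background,normalize logical switches for the first two stages.
#' @param tol,maxIter forwarded to \code{\link{medianPolishSummarize}}.
#' @return An \linkS4class{ExpressionMatrix} of log2 expression values.
#' @export
rmaSummarize <- function(probes, background = TRUE, normalize = TRUE,
                         tol = 0.01, maxIter = 10L) {
    pm <- pmMatrix(probes)
    if (background) pm <- rmaBackgroundCorrect(pm)
    if (normalize) pm <- quantileNormalize(pm)
    medianPolishSummarize(probes, pm = pm, tol = tol, maxIter = maxIter)
}

#' MAS5-style scaling factor
#'
#' Ratio of the target intensity to the two-sided trimmed mean of an array's
#' linear-scale signal values. Values far above 1 indicate weak hybridization
#' signal; the factor is reported, not enforced.
#'
#' @param values strictly positive signal vector for one array.
#' @param target trimmed-mean target (Affymetrix convention: 500).
#' @param trim fraction trimmed from each tail (vendor convention: 0.02).
#' @return the scaling factor, a positive scalar.
#' @export
mas5ScalingFactor <- function(values, target = 500, trim = 0.02) {
    if (any(values <= 0)) stop("signal values must be strictly positive")
    n <- length(values)
    k <- floor(n * trim)
    if (k < 1L)
        stop(sprintf("need more than %d values so the %.3g trim removes at least one value per tail",
                     ceiling(1 / trim), trim))
    s <- sort(values)
    target / mean(s[(k + 1L):(n - k)])
}

.signedRankGreater <- function(d) {
    ## One-sided exact signed-rank p-value for median(d) > 0; normal
    ## approximation with continuity and tie correction when exact theory
    ## does not apply (zeros or tied magnitudes).
    n <- length(d)
    ad <- abs(d)
    if (all(d == 0)) return(1)
    if (any(d == 0) || anyDuplicated(ad)) {
        keep <- d != 0
        d <- d[keep]; ad <- ad[keep]; n <- length(d)
        r <- rank(ad)
        W <- sum(r[d > 0])
        mu <- n * (n + 1) / 4
        ties <- table(r)
        sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
            sum(ties^3 - ties) / 48
        return(stats::pnorm((W - mu - 0.5) / sqrt(sig2), lower.tail = FALSE))
    }
    W <- sum(rank(ad)[d > 0])
    stats::psignrank(W - 1, n, lower.tail = FALSE)
}

.colRanksNoTies <- function(m) {
    ## ranks within each column of a small-row matrix, assuming no ties
    r <- matrix(1L, nrow(m), ncol(m))
    for (i in seq_len(nrow(m)))
        r[i, ] <- 1L + .colSums(m < rep(m[i, ], each = nrow(m)),
                                nrow(m), ncol(m))
    r
}

#' MAS5-style Present/Marginal/Absent detection calls
#'
#' Per probeset and array, computes discrimination scores
#' R = (PM - MM) / (PM + MM) and performs a one-sided Wilcoxon signed-rank
#' test of median(R) > tau. p < alpha1 gives a Present call, p < alpha2
#' Marginal, otherwise Absent. Probesets with fewer than 3 probes are called
#' but flagged low-confidence.
#'
#' @param probes a \linkS4class{ProbeMatrix} carrying mismatch intensities.
#' @param tau discrimination threshold (vendor default 0.015).
#' @param alpha1,alpha2 Present/Marginal p-value cutoffs (vendor defaults
#'   0.04 and 0.06).
#' @return list with \code{calls} (probeset x array character matrix of
#'   "P"/"M"/"A"), \code{pValue} (same shape), \code{percentPresent} (named
#'   per-array vector, in percent) and \code{lowConfidence} (per-probeset
#'   logical).
#' @export
detectionCalls <- function(probes, tau = 0.015, alpha1 = 0.04,
                           alpha2 = 0.06) {
    mm <- mmMatrix(probes)
    if (is.null(mm)) stop("detection calls require mismatch intensities")
    stopifnot(alpha1 < alpha2)
    pm <- pmMatrix(probes)
    d <- (pm - mm) / (pm + mm) - tau
    bl <- .probesetBlocks(probesets(probes))
    d <- d[bl$ord, , drop = FALSE]
    nArr <- ncol(pm)
    pmat <- matrix(NA_real_, length(bl$sets), nArr,
                   dimnames = list(bl$sets, colnames(pm)))
    for (n in unique(bl$len)) {
        rows <- which(bl$len == n)
        ## columns of `sub`: one per (probeset of size n, array)
        sub <- matrix(0, n, length(rows) * nArr)
        for (k in seq_along(rows)) {
            idx <- bl$start[rows[k]] + seq_len(n)
            sub[, (k - 1L) * nArr + seq_len(nArr)] <- d[idx, ]
        }
        irregular <- apply(sub, 2L, function(col)
            any(col == 0) || anyDuplicated(abs(col)) > 0L)
        p <- numeric(ncol(sub))
        if (any(!irregular)) {
            cols <- which(!irregular)
            rk <- .colRanksNoTies(abs(sub[, cols, drop = FALSE]))
            W <- .colSums(rk * (sub[, cols, drop = FALSE] > 0), n,
                          length(cols))
            p[cols] <- stats::psignrank(W - 1, n, lower.tail = FALSE)
        }
        for (j in which(irregular)) p[j] <- .signedRankGreater(sub[, j])
        pmat[rows, ] <- matrix(p, length(rows), nArr, byrow = TRUE)
    }
    calls <- matrix("A", nrow(pmat), ncol(pmat), dimnames = dimnames(pmat))
    calls[pmat < alpha2] <- "M"
    calls[pmat < alpha1] <- "P"
    list(calls = calls, pValue = pmat,
         percentPresent = 100 * colMeans(calls == "P"),
         lowConfidence = stats::setNames(bl$len < 3L, bl$sets))
}

#' Per-array quality summaries
#'
#' One row per array: MAS5-style scaling factor of the linear-scale
#' summarized signal, Present-call percentage (when mismatch probes exist),
#' and mean/SD of the log2 expression values.
#'
#' @param probes a \linkS4class{ProbeMatrix} (raw, for detection calls).
#' @param expr the matching \linkS4class{ExpressionMatrix} of log2 values.
#' @param target,trim forwarded to \code{\link{mas5ScalingFactor}}.
#' @param tau,alpha1,alpha2 forwarded to \code{\link{detectionCalls}}.
#' @return data.frame with columns array_id, scaling_factor, percent_present,
#'   mean_log2, sd_log2.
#' @export
arrayQC <- function(probes, expr, target = 500, trim = 0.02, tau = 0.015,
                    alpha1 = 0.04, alpha2 = 0.06) {
    vals <- exprsMatrix(expr)
    sf <- apply(2^vals, 2L, mas5ScalingFactor, target = target, trim = trim)
    pp <- if (!is.null(mmMatrix(probes)))
        detectionCalls(probes, tau = tau, alpha1 = alpha1,
                       alpha2 = alpha2)$percentPresent[colnames(vals)]
    else rep(NA_real_, ncol(vals))
    data.frame(array_id = colnames(vals), scaling_factor = sf,
               percent_present = as.numeric(pp),
               mean_log2 = colMeans(vals),
               sd_log2 = apply(vals, 2L, stats::sd),
               row.names = NULL, stringsAsFactors = FALSE)
}
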