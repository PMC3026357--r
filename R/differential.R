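## Per-gene two-group statistics and fold-change-ranked DEG selection.
##
## Selection follows the MAQC rule: filter on a non-stringent p-value cutoff
## (no multiple-testing correction), then rank the survivors by log2 fold
## change and take the top L genes from each regulation direction.

#' Per-gene Welch t-test between two array groups
#'
#' For each gene, t = (mean_B - mean_A) / sqrt(s_A^2/n_A + s_B^2/n_B) with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. The log2
#' fold change is the difference of log2 means (B over A). p-values are used
#' directly for filtering, without multiple-testing correction.
#'
#' Degenerate genes where both groups have zero variance get t = 0, p = 1
#' when the means are equal; when the means differ the p-value is reported as
#' the limit 0 and the gene id is recorded in the result's \code{flagged}
#' slot.
#'
#' @param expr an \linkS4class{ExpressionMatrix} of log2 intensities.
#' @param groupA,groupB array ids of the two groups; default: arrays labelled
#'   A and B in \code{arrayGroups(expr)}. Groups must be disjoint with at
#'   least 2 arrays each.
#' @return A \linkS4class{DifferentialResult}.
#' @export
welchTTest <- function(expr, groupA = NULL, groupB = NULL) {
    g <- arrayGroups(expr)
    if (is.null(groupA)) groupA <- names(g)[g == "A"]
    if (is.null(groupB)) groupB <- names(g)[g == "B"]
    if (length(groupA) < 2L || length(groupB) < 2L)
        stop("each group needs at least 2 arrays")
    if (length(intersect(groupA, groupB)))
        stop("groups must be disjoint")
    vals <- exprsMatrix(expr)
    xa <- vals[, groupA, drop = FALSE]
    xb <- vals[, groupB, drop = FALSE]
    na <- ncol(xa); nb <- ncol(xb)
    ma <- rowMeans(xa); mb <- rowMeans(xb)
    va <- rowSums((xa - ma)^2) / (na - 1)
    vb <- rowSums((xb - mb)^2) / (nb - 1)
    se2 <- va / na + vb / nb
    fc <- mb - ma
    t <- fc / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)

    degenerate <- se2 == 0
    flagged <- character()
    if (any(degenerate)) {
        null0 <- degenerate & fc == 0
        t[null0] <- 0; p[null0] <- 1; df[null0] <- Inf
        bad <- degenerate & fc != 0
        t[bad] <- sign(fc[bad]) * Inf; p[bad] <- 0; df[bad] <- Inf
        flagged <- rownames(vals)[bad]
    }
    new("DifferentialResult", geneIds = rownames(vals), log2fc = unname(fc),
        tStat = unname(t), pValue = unname(p), df = unname(df),
        groupSizes = c(na, nb), flagged = flagged)
}

.rankedDirection <- function(result, direction, pCutoff) {
    keep <- result@pValue < pCutoff &
        (if (direction == "up") result@log2fc > 0 else result@log2fc < 0)
    ids <- result@geneIds[keep]
    fc <- result@log2fc[keep]
    p <- result@pValue[keep]
    ## rank by |FC|, ties by smaller p, then lexicographic gene id
    ids[order(-abs(fc), p, ids)]
}

#' Select equal-size up/down DEG lists by fold-change ranking
#'
#' Genes with p below \code{pCutoff} are split by the sign of their log2 fold
#' change and ranked by fold-change magnitude within each direction (ties
#' broken by smaller p-value, then gene id, for determinism). The top
#' \code{L} genes per direction form the list; genes with a log2 fold change
#' of exactly 0 belong to neither direction.
#'
#' @param result a \linkS4class{DifferentialResult}.
#' @param L genes per direction.
#' @param pCutoff p-value filter (default 0.05).
#' @return A \linkS4class{DEGList}.
#' @export
selectDEGs <- function(result, L, pCutoff = 0.05) {
    L <- as.integer(L)
    stopifnot(L >= 1L)
    up <- .rankedDirection(result, "up", pCutoff)
    down <- .rankedDirection(result, "down", pCutoff)
    for (dir in c("up", "down")) {
        avail <- if (dir == "up") length(up) else length(down)
        if (avail < L)
            stop(sprintf(
                "L=%d exceeds the %d available %s-regulated genes (max feasible L is %d)",
                L, avail, dir, avail), call. = FALSE)
    }
    new("DEGList", pCutoff = pCutoff, L = L, up = up[seq_len(L)],
        down = down[seq_len(L)])
}

#' Largest list size shared by two experiments
#'
#' The maximum L at which equal-size up/down lists can be built in both
#' experiments: the minimum over experiments of the smaller direction count
#' after p-filtering.
#'
#' @param a,b \linkS4class{DifferentialResult} objects on the same gene
#'   universe.
#' @param pCutoff p-value filter.
#' @return positive integer.
#' @export
maxSharedL <- function(a, b, pCutoff = 0.05) {
    counts <- vapply(list(a, b), function(r)
        c(length(.rankedDirection(r, "up", pCutoff)),
          length(.rankedDirection(r, "down", pCutoff))), numeric(2))
    if (any(counts == 0L)) {
        who <- which(counts == 0L, arr.ind = TRUE)[1L, ]
        stop(sprintf("no %s-regulated genes pass p < %g in experiment %s",
                     c("up", "down")[who[1L]], pCutoff,
                     c("a", "b")[who[2L]]), call. = FALSE)
    }
    as.integer(min(counts))
}
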