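## Cross-experiment agreement statistics: POG, POG-vs-2L curves, reference
## confidence band, three-scenario directional agreement, fold-change
## scatter classification, compression slope and replicate-correlation
## summaries.

#' Overlap counts between two DEG lists
#'
#' @param a,b \linkS4class{DEGList} objects with equal L.
#' @return An \linkS4class{OverlapCounts} (commonly down-regulated DD,
#'   commonly up-regulated UU).
#' @export
overlapCounts <- function(a, b) {
    if (a@L != b@L) stop("DEG lists must have equal L")
    new("OverlapCounts", DD = length(intersect(a@down, b@down)),
        UU = length(intersect(a@up, b@up)), L = a@L)
}

#' Percentage of overlapping genes (POG)
#'
#' POG = 100 (DD + UU) / (2L), where DD and UU count the genes commonly
#' down- and up-regulated in the two equal-size, direction-split DEG lists.
#' Symmetric in its arguments.
#'
#' @param a,b \linkS4class{DEGList} objects with equal L.
#' @return POG in percent.
#' @export
pog <- function(a, b) {
    oc <- overlapCounts(a, b)
    100 * (oc@DD + oc@UU) / (2 * oc@L)
}

.cumOverlap <- function(rankedA, rankedB, Lmax) {
    ## For each L in 1..Lmax, the number of genes in both top-L lists.
    ## A shared gene enters the overlap at L = max(rank in a, rank in b).
    common <- intersect(rankedA[seq_len(Lmax)], rankedB[seq_len(Lmax)])
    if (!length(common)) return(integer(Lmax))
    entry <- pmax(match(common, rankedA), match(common, rankedB))
    cumsum(tabulate(entry, nbins = Lmax))
}

#' POG as a function of list size
#'
#' Builds equal-size up/down DEG lists in both experiments for every
#' L = 1..\code{maxSharedL} (step one) and records the POG; the x-coordinate
#' is the total number of selected genes, 2L.
#'
#' @param a,b \linkS4class{DifferentialResult} objects on the same gene
#'   universe.
#' @param pCutoff p-value filter applied before ranking.
#' @param label curve label.
#' @return A \linkS4class{POGCurve}.
#' @export
pogCurve <- function(a, b, pCutoff = 0.05, label = "a vs b") {
    Lmax <- maxSharedL(a, b, pCutoff)
    upA <- .rankedDirection(a, "up", pCutoff)
    upB <- .rankedDirection(b, "up", pCutoff)
    downA <- .rankedDirection(a, "down", pCutoff)
    downB <- .rankedDirection(b, "down", pCutoff)
    L <- seq_len(Lmax)
    overlap <- .cumOverlap(upA, upB, Lmax) + .cumOverlap(downA, downB, Lmax)
    new("POGCurve", twoL = 2L * L, pog = 100 * overlap / (2 * L),
        label = label)
}

#' Mean POG reference line with confidence band
#'
#' Pointwise mean of two or more POG curves on their shared 2L support
#' (curves are truncated to the common grid), with a pointwise t-interval:
#' mean +/- t_{(1+level)/2, n-1} * sd / sqrt(n).
#'
#' @param curves list of \linkS4class{POGCurve} objects (>= 2).
#' @param level confidence level (default 0.95).
#' @return A \linkS4class{ReferenceBand}.
#' @export
referenceBand <- function(curves, level = 0.95) {
    n <- length(curves)
    if (n < 2L) stop("a reference band needs at least 2 curves")
    maxTwoL <- min(vapply(curves, function(cv) max(cv@twoL), numeric(1)))
    grid <- seq.int(2L, maxTwoL, by = 2L)
    mat <- vapply(curves, function(cv) cv@pog[match(grid, cv@twoL)],
                  numeric(length(grid)))
    m <- rowMeans(mat)
    sd <- apply(mat, 1L, stats::sd)
    half <- stats::qt((1 + level) / 2, df = n - 1) * sd / sqrt(n)
    new("ReferenceBand", twoL = as.integer(grid), meanPog = m,
        ciLower = m - half, ciUpper = m + half, nComparisons = as.integer(n),
        level = level)
}

.scenarioGenes <- function(a, b, scenario, pCutoff) {
    stopifnot(identical(a@geneIds, b@geneIds))
    switch(scenario,
           all = rep(TRUE, length(a@geneIds)),
           either = a@pValue < pCutoff | b@pValue < pCutoff,
           both = a@pValue < pCutoff & b@pValue < pCutoff,
           stop("scenario must be one of 'all', 'either', 'both'"))
}

#' Directional agreement between two experiments
#'
#' Restricts the common gene universe to one of three scenarios -- all genes,
#' genes significant (p < cutoff) in either experiment, or in both -- and
#' counts genes whose log2 fold changes agree in sign. Genes with a fold
#' change of exactly 0 in either experiment cannot be classified and are
#' excluded (their count is reported).
#'
#' @param a,b \linkS4class{DifferentialResult} objects on the same gene
#'   universe (same gene order).
#' @param scenario \code{"all"}, \code{"either"} or \code{"both"}.
#' @param pCutoff p-value cutoff defining significance.
#' @return A \linkS4class{ScenarioAgreement}.
#' @export
directionalAgreement <- function(a, b, scenario = c("all", "either", "both"),
                                 pCutoff = 0.05) {
    scenario <- match.arg(scenario)
    sel <- .scenarioGenes(a, b, scenario, pCutoff)
    if (!any(sel)) stop(sprintf("scenario '%s' selects no genes", scenario))
    fa <- a@log2fc[sel]; fb <- b@log2fc[sel]
    zero <- fa == 0 | fb == 0
    conc <- sum(sign(fa[!zero]) == sign(fb[!zero]))
    nGenes <- sum(!zero)
    new("ScenarioAgreement", scenario = scenario, nGenes = as.integer(nGenes),
        nConcordant = as.integer(conc),
        nDiscordant = as.integer(nGenes - conc),
        percent = 100 * conc / nGenes, nZeroExcluded = as.integer(sum(zero)))
}

#' Per-gene fold-change scatter classification
#'
#' The table behind a fold-change concordance scatterplot: one row per
#' classified gene in the scenario, with both log2 fold changes and the class
#' \code{up-up}, \code{down-down} or \code{discordant}.
#'
#' @inheritParams directionalAgreement
#' @return data.frame with columns gene_id, log2fc_a, log2fc_b, class.
#' @export
fcScatterTable <- function(a, b, scenario = c("all", "either", "both"),
                           pCutoff = 0.05) {
    scenario <- match.arg(scenario)
    sel <- .scenarioGenes(a, b, scenario, pCutoff)
    if (!any(sel)) stop(sprintf("scenario '%s' selects no genes", scenario))
    ids <- a@geneIds[sel]; fa <- a@log2fc[sel]; fb <- b@log2fc[sel]
    keep <- fa != 0 & fb != 0
    cls <- ifelse(fa[keep] > 0 & fb[keep] > 0, "up-up",
                  ifelse(fa[keep] < 0 & fb[keep] < 0, "down-down",
                         "discordant"))
    data.frame(gene_id = ids[keep], log2fc_a = fa[keep], log2fc_b = fb[keep],
               class = cls, stringsAsFactors = FALSE)
}

#' Fold-change compression slope
#'
#' Least-squares slope through the origin of the log2 fold changes of
#' experiment \code{a} regressed on those of experiment \code{b}. A slope
#' below 1 indicates fold-change compression of \code{a} relative to
#' \code{b}.
#'
#' @param a,b \linkS4class{DifferentialResult} objects on the same gene
#'   universe.
#' @return the slope, a scalar.
#' @export
compressionSlope <- function(a, b) {
    stopifnot(identical(a@geneIds, b@geneIds))
    if (all(b@log2fc == 0))
        stop("all fold changes in 'b' are zero; slope undefined")
    sum(a@log2fc * b@log2fc) / sum(b@log2fc^2)
}

#' Averaged between-replicate correlation
#'
#' Mean of all pairwise Pearson correlations of log2 intensities among one
#' sample's replicate arrays.
#'
#' @param expr an \linkS4class{ExpressionMatrix}.
#' @param sample \code{"A"} or \code{"B"}.
#' @return mean pairwise correlation, a scalar.
#' @export
replicateCorrelationSummary <- function(expr, sample = c("A", "B")) {
    sample <- match.arg(sample)
    g <- arrayGroups(expr)
    cols <- names(g)[g == sample]
    if (length(cols) < 2L)
        stop(sprintf("sample %s has fewer than 2 replicates", sample))
    vals <- exprsMatrix(expr)[, cols, drop = FALSE]
    if (any(apply(vals, 2L, stats::sd) == 0))
        stop("constant replicate column: correlation undefined")
    cm <- stats::cor(vals)
    mean(cm[upper.tri(cm)])
}
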