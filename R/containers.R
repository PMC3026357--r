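## Constructors, accessors and show methods for the core containers.

#' Construct a ProbeMatrix
#'
#' @param pm numeric matrix of strictly positive perfect-match intensities,
#'   probes in rows (rownames = probe ids), arrays in columns (colnames =
#'   array ids).
#' @param probeset character vector assigning each probe (row) to one
#'   probeset/gene id.
#' @param group character vector, one of \code{"A"}/\code{"B"} per array.
#' @param replicate integer replicate index per array.
#' @param mm optional mismatch intensity matrix, same shape as \code{pm}.
#'
#' @return A \linkS4class{ProbeMatrix}.
#' @export
ProbeMatrix <- function(pm, probeset, group, replicate, mm = NULL) {
    assays <- list(pm = pm)
    if (!is.null(mm)) assays$mm <- mm
    se <- SummarizedExperiment(
        assays = assays,
        rowData = DataFrame(probeset = as.character(probeset)),
        colData = DataFrame(group = as.character(group),
                            replicate = as.integer(replicate),
                            row.names = colnames(pm)))
    new("ProbeMatrix", se)
}

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix of log2 intensities, genes in rows (rownames =
#'   gene ids), arrays in columns (colnames = array ids).
#' @param group,replicate per-array sample group (\code{"A"}/\code{"B"}) and
#'   replicate index.
#'
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
ExpressionMatrix <- function(values, group, replicate) {
    se <- SummarizedExperiment(
        assays = list(exprs = values),
        colData = DataFrame(group = as.character(group),
                            replicate = as.integer(replicate),
                            row.names = colnames(values)))
    new("ExpressionMatrix", se)
}

#' @describeIn ProbeMatrix perfect-match intensity matrix.
#' @param x a container object.
#' @export
pmMatrix <- function(x) assay(x, "pm")

#' @describeIn ProbeMatrix mismatch intensity matrix, or \code{NULL} when the
#'   platform carries no mismatch probes.
#' @export
mmMatrix <- function(x) if ("mm" %in% assayNames(x)) assay(x, "mm") else NULL

#' @describeIn ProbeMatrix probe -> probeset assignment (parallel to rows).
#' @export
probesets <- function(x) as.character(rowData(x)$probeset)

#' Per-array sample annotation
#'
#' @param x a \linkS4class{ProbeMatrix} or \linkS4class{ExpressionMatrix}.
#' @return \code{arrayGroups}: named character vector of sample groups;
#'   \code{arrayReplicates}: named integer vector of replicate indices.
#' @export
arrayGroups <- function(x) {
    stats::setNames(as.character(colData(x)$group), colnames(x))
}

#' @rdname arrayGroups
#' @export
arrayReplicates <- function(x) {
    stats::setNames(as.integer(colData(x)$replicate), colnames(x))
}

#' @describeIn ExpressionMatrix log2 expression matrix.
#' @param x an ExpressionMatrix.
#' @export
exprsMatrix <- function(x) assay(x, "exprs")

## ----- DifferentialResult ---------------------------------------------------

#' @describeIn welchTTest coerce results to a data.frame with columns
#'   gene_id, log2fc, t, p, df.
#' @param x a DifferentialResult.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "DifferentialResult", function(x, ...) {
    data.frame(gene_id = x@geneIds, log2fc = x@log2fc, t = x@tStat,
               p = x@pValue, df = x@df, stringsAsFactors = FALSE)
})

#' @describeIn welchTTest gene identifiers of a result.
#' @export
geneIds <- function(x) x@geneIds

#' @describeIn welchTTest per-gene log2 fold changes (B over A).
#' @export
log2FoldChanges <- function(x) stats::setNames(x@log2fc, x@geneIds)

#' @describeIn welchTTest per-gene two-sided Welch p-values.
#' @export
pValues <- function(x) stats::setNames(x@pValue, x@geneIds)

setMethod("show", "DifferentialResult", function(object) {
    cat(sprintf("DifferentialResult: %d genes, groups n_A=%d n_B=%d\n",
                length(object@geneIds), object@groupSizes[1L],
                object@groupSizes[2L]))
    cat(sprintf("  p < 0.05: %d genes; |log2FC| range [%.3g, %.3g]\n",
                sum(object@pValue < 0.05), min(abs(object@log2fc)),
                max(abs(object@log2fc))))
    if (length(object@flagged))
        cat(sprintf("  %d gene(s) flagged: zero variance with unequal means\n",
                    length(object@flagged)))
})

## ----- DEGList ---------------------------------------------------------------

#' @describeIn selectDEGs up-regulated gene list (descending log2 FC).
#' @param x a DEGList.
#' @export
upGenes <- function(x) x@up

#' @describeIn selectDEGs down-regulated gene list (ascending log2 FC).
#' @export
downGenes <- function(x) x@down

setMethod("show", "DEGList", function(object) {
    cat(sprintf("DEGList: L=%d per direction (p < %g)\n", object@L,
                object@pCutoff))
    cat("  up:  ", paste(utils::head(object@up, 5L), collapse = ", "),
        if (object@L > 5L) ", ..." else "", "\n", sep = "")
    cat("  down:", paste(utils::head(object@down, 5L), collapse = ", "),
        if (object@L > 5L) ", ..." else "", "\n", sep = "")
})

setMethod("show", "POGCurve", function(object) {
    cat(sprintf("POGCurve '%s': %d points, 2L in [%d, %d]\n", object@label,
                length(object@twoL), min(object@twoL), max(object@twoL)))
    cat(sprintf("  POG range [%.1f, %.1f], final %.1f%%\n", min(object@pog),
                max(object@pog), object@pog[length(object@pog)]))
})

setMethod("show", "ReferenceBand", function(object) {
    cat(sprintf("ReferenceBand: %d curves, %d%% CI, 2L in [%d, %d]\n",
                object@nComparisons, round(100 * object@level),
                min(object@twoL), max(object@twoL)))
})

setMethod("show", "ScenarioAgreement", function(object) {
    cat(sprintf("Directional agreement [%s]: %.2f%% (%d of %d genes)\n",
                object@scenario, object@percent, object@nConcordant,
                object@nGenes))
    if (object@nZeroExcluded > 0L)
        cat(sprintf("  (%d genes with log2FC == 0 excluded)\n",
                    object@nZeroExcluded))
})

setMethod("show", "MappingTable", function(object) {
    cat(sprintf("MappingTable: %d genes x %d platforms (%s)\n",
                length(object@geneIds), length(object@platforms),
                paste(object@platforms, collapse = ", ")))
    unmapped <- colSums(is.na(object@probes))
    if (any(unmapped > 0))
        cat("  unmapped genes per platform: ",
            paste(sprintf("%s=%d", object@platforms, unmapped),
                  collapse = ", "), "\n", sep = "")
})

#' @describeIn readMappingTable platform names of a mapping table.
#' @export
platforms <- function(x) x@platforms

#' @describeIn readMappingTable gene ids of a mapping table (row order).
#' @export
mappedGenes <- function(x) x@geneIds

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:\n")
    cat(sprintf("  %d genes x %d probes, %d replicates/sample, piDE=%.2f\n",
                object@nGenes, object@probesPerGene, object@nReplicates,
                object@piDE))
    cat(sprintf("  effect=%.2f log2, sigmaRep=%.3f, baseline N(%.2f, %.2f)\n",
                object@effectSizeLog2, object@sigmaRep,
                object@baselineMeanLog2, object@baselineSdLog2))
    cat(sprintf(
        "  degraded: compression=%.2f, shift=%.2f, spreadShrink=%.2f, background %g (x%g)\n",
        object@compression, object@intensityShiftLog2, object@spreadShrink,
        object@backgroundLevel, object@backgroundInflation))
    cat(sprintf("  seed=%d\n", object@seed))
})

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth: %d genes, %d DE (%d up, %d down)\n",
                length(object@geneIds), sum(object@isDE),
                sum(object@direction == "up"),
                sum(object@direction == "down")))
})

#' @describeIn simulateExperimentPair per-gene true log2 fold changes of a
#'   GroundTruth, as a named vector.
#' @export
trueLog2fc <- function(x) stats::setNames(x@trueLog2fc, x@geneIds)

#' @describeIn simulateExperimentPair logical DE indicator of a GroundTruth.
#' @export
isDE <- function(x) stats::setNames(x@isDE, x@geneIds)

#' @describeIn simulateExperimentPair per-gene regulation direction
#'   ("up"/"down"/"null") of a GroundTruth.
#' @export
deDirection <- function(x) stats::setNames(x@direction, x@geneIds)
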