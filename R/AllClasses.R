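#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
NULL

## ---------------------------------------------------------------------------
## Core containers (extend SummarizedExperiment)
## ---------------------------------------------------------------------------

#' ProbeMatrix: probe-level intensity container
#'
#' A \linkS4class{SummarizedExperiment} holding linear-scale perfect-match
#' (\code{pm}) probe intensities, optionally mismatch (\code{mm}) intensities
#' of the same shape, the probe-to-probeset assignment in
#' \code{rowData(x)$probeset}, and per-array sample annotation
#' (\code{colData(x)$group} in \code{A}/\code{B}, \code{colData(x)$replicate}).
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; assays must contain
#'   \code{"pm"} (strictly positive) and may contain \code{"mm"}.
#' @aliases ProbeMatrix-class
#' @exportClass ProbeMatrix
setClass("ProbeMatrix", contains = "SummarizedExperiment")

.validProbeMatrix <- function(object) {
    msg <- NULL
    if (!"pm" %in% assayNames(object))
        msg <- c(msg, "assay 'pm' is required")
    else {
        pm <- assay(object, "pm")
        if (!is.numeric(pm) || anyNA(pm) || any(pm <= 0))
            msg <- c(msg, "'pm' intensities must be strictly positive and non-missing")
    }
    if ("mm" %in% assayNames(object)) {
        mm <- assay(object, "mm")
        if (!is.numeric(mm) || anyNA(mm) || any(mm <= 0))
            msg <- c(msg, "'mm' intensities must be strictly positive and non-missing")
    }
    if (is.null(rowData(object)$probeset))
        msg <- c(msg, "rowData()$probeset (probe -> probeset map) is required")
    msg <- c(msg, .validArrayAnnotation(object))
    if (is.null(msg)) TRUE else msg
}
setValidity("ProbeMatrix", .validProbeMatrix)

.validArrayAnnotation <- function(object) {
    msg <- NULL
    cd <- colData(object)
    if (is.null(cd$group) || !all(cd$group %in% c("A", "B")))
        msg <- c(msg, "colData()$group must be 'A' or 'B' for every array")
    if (is.null(cd$replicate) || anyNA(cd$replicate) || any(cd$replicate < 1))
        msg <- c(msg, "colData()$replicate must be a positive integer for every array")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "array ids (colnames) must be present and unique")
    msg
}

#' ExpressionMatrix: gene-level log2 expression container
#'
#' A \linkS4class{SummarizedExperiment} with a single \code{"exprs"} assay of
#' log2-scale intensities, unique gene ids as rownames, and the same
#' \code{group}/\code{replicate} array annotation as
#' \linkS4class{ProbeMatrix}.
#'
#' @aliases ExpressionMatrix-class
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
    msg <- NULL
    if (!"exprs" %in% assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        v <- assay(object, "exprs")
        if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
            msg <- c(msg, "'exprs' values must be finite and non-missing")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids (rownames) must be present and unique")
    msg <- c(msg, .validArrayAnnotation(object))
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## Mapping table
## ---------------------------------------------------------------------------

#' One-probe-to-one-gene cross-platform mapping table
#'
#' Each row maps a unique gene id to at most one probe/probeset id per
#' platform. Empty probe cells are stored as \code{NA} and mark the gene as
#' unmapped on that platform.
#'
#' @slot geneIds character vector of unique gene identifiers.
#' @slot probes character matrix, genes x platforms; \code{NA} = unmapped.
#' @slot platforms character vector of platform names (matrix colnames).
#' @aliases MappingTable-class
#' @exportClass MappingTable
setClass("MappingTable",
    representation(geneIds = "character", probes = "matrix",
                   platforms = "character"))

setValidity("MappingTable", function(object) {
    msg <- NULL
    if (anyDuplicated(object@geneIds))
        msg <- c(msg, "gene ids must be unique")
    if (nrow(object@probes) != length(object@geneIds))
        msg <- c(msg, "probe matrix rows must match geneIds")
    if (!identical(colnames(object@probes), object@platforms))
        msg <- c(msg, "probe matrix columns must match platforms")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## Differential expression results
## ---------------------------------------------------------------------------

#' Per-gene two-group Welch test results
#'
#' Log2 fold changes are sample B over sample A (difference of log2 means).
#' \code{flagged} lists genes where both groups had zero variance but unequal
#' means (p reported as 0).
#'
#' @slot geneIds,log2fc,tStat,pValue,df parallel per-gene vectors.
#' @slot groupSizes integer(2): replicates in groups A and B.
#' @slot flagged character: gene ids with degenerate zero-variance tests.
#' @aliases DifferentialResult-class
#' @exportClass DifferentialResult
setClass("DifferentialResult",
    representation(geneIds = "character", log2fc = "numeric",
                   tStat = "numeric", pValue = "numeric", df = "numeric",
                   groupSizes = "integer", flagged = "character"))

setValidity("DifferentialResult", function(object) {
    n <- length(object@geneIds)
    msg <- NULL
    if (anyDuplicated(object@geneIds))
        msg <- c(msg, "gene ids must be unique")
    for (s in c("log2fc", "tStat", "pValue", "df"))
        if (length(slot(object, s)) != n)
            msg <- c(msg, sprintf("'%s' must have one value per gene", s))
    if (any(!is.finite(object@log2fc)))
        msg <- c(msg, "log2 fold changes must be finite")
    if (any(object@pValue < 0 | object@pValue > 1))
        msg <- c(msg, "p-values must lie in [0, 1]")
    if (length(object@groupSizes) != 2L)
        msg <- c(msg, "groupSizes must be length 2 (n_A, n_B)")
    if (is.null(msg)) TRUE else msg
})

#' Equal-size up/down differentially expressed gene lists
#'
#' Holds the top \code{L} up-regulated genes (descending log2 fold change) and
#' top \code{L} down-regulated genes (ascending log2 fold change) among genes
#' passing the p-value cutoff.
#'
#' @slot pCutoff p-value filter applied before ranking.
#' @slot L genes selected per direction.
#' @slot up,down ordered gene id vectors, each of length \code{L}, disjoint.
#' @aliases DEGList-class
#' @exportClass DEGList
setClass("DEGList",
    representation(pCutoff = "numeric", L = "integer",
                   up = "character", down = "character"))

setValidity("DEGList", function(object) {
    msg <- NULL
    if (length(object@up) != object@L || length(object@down) != object@L)
        msg <- c(msg, "up and down lists must each contain exactly L genes")
    if (length(intersect(object@up, object@down)) > 0L)
        msg <- c(msg, "up and down lists must be disjoint")
    if (anyDuplicated(object@up) || anyDuplicated(object@down))
        msg <- c(msg, "gene lists must not contain duplicates")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## Concordance results
## ---------------------------------------------------------------------------

#' Overlap counts between two direction-split gene lists
#'
#' @slot DD commonly down-regulated genes; \code{UU} commonly up-regulated;
#'   \code{L} list size per direction.
#' @aliases OverlapCounts-class
#' @exportClass OverlapCounts
setClass("OverlapCounts",
    representation(DD = "integer", UU = "integer", L = "integer"))

setValidity("OverlapCounts", function(object) {
    if (object@DD > object@L || object@UU > object@L)
        "DD and UU cannot exceed L" else TRUE
})

#' POG as a function of the number of selected genes
#'
#' @slot twoL number of genes selected (2L), strictly increasing by 2.
#' @slot pog POG percentages in [0, 100], parallel to \code{twoL}.
#' @slot label comparison name.
#' @aliases POGCurve-class
#' @exportClass POGCurve
setClass("POGCurve",
    representation(twoL = "integer", pog = "numeric", label = "character"))

setValidity("POGCurve", function(object) {
    msg <- NULL
    if (length(object@twoL) != length(object@pog))
        msg <- c(msg, "twoL and pog must have equal length")
    if (length(object@twoL) > 1L && any(diff(object@twoL) != 2L))
        msg <- c(msg, "twoL must increase in steps of 2")
    if (any(object@pog < 0 | object@pog > 100))
        msg <- c(msg, "pog must lie in [0, 100]")
    if (is.null(msg)) TRUE else msg
})

#' Pointwise mean POG reference line with confidence band
#'
#' @slot twoL shared grid; \code{meanPog} pointwise mean across curves;
#'   \code{ciLower}/\code{ciUpper} t-interval limits; \code{nComparisons}
#'   number of curves; \code{level} confidence level.
#' @aliases ReferenceBand-class
#' @exportClass ReferenceBand
setClass("ReferenceBand",
    representation(twoL = "integer", meanPog = "numeric", ciLower = "numeric",
                   ciUpper = "numeric", nComparisons = "integer",
                   level = "numeric"))

setValidity("ReferenceBand", function(object) {
    msg <- NULL
    n <- length(object@twoL)
    if (length(object@meanPog) != n || length(object@ciLower) != n ||
        length(object@ciUpper) != n)
        msg <- c(msg, "band components must share the twoL grid")
    if (any(object@ciLower > object@meanPog | object@meanPog > object@ciUpper))
        msg <- c(msg, "ciLower <= meanPog <= ciUpper must hold pointwise")
    if (is.null(msg)) TRUE else msg
})

#' Directional agreement under a gene-selection scenario
#'
#' @slot scenario one of \code{"all"}, \code{"either"}, \code{"both"}.
#' @slot nGenes genes classified; \code{nConcordant}/\code{nDiscordant}
#'   partition them; \code{percent} = 100 * concordant / classified.
#' @slot nZeroExcluded genes dropped because log2 fold change was exactly 0
#'   in one of the experiments.
#' @aliases ScenarioAgreement-class
#' @exportClass ScenarioAgreement
setClass("ScenarioAgreement",
    representation(scenario = "character", nGenes = "integer",
                   nConcordant = "integer", nDiscordant = "integer",
                   percent = "numeric", nZeroExcluded = "integer"))

setValidity("ScenarioAgreement", function(object) {
    msg <- NULL
    if (object@nConcordant + object@nDiscordant != object@nGenes)
        msg <- c(msg, "concordant + discordant must equal nGenes")
    if (object@nGenes > 0L &&
        abs(object@percent - 100 * object@nConcordant / object@nGenes) > 1e-8)
        msg <- c(msg, "percent inconsistent with counts")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## Simulation
## ---------------------------------------------------------------------------

#' Configuration of the paired-platform probe-level simulator
#'
#' See \code{\link{SimulationConfig}} for field semantics and defaults.
#'
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(nGenes = "integer", probesPerGene = "integer",
                   nReplicates = "integer", piDE = "numeric",
                   effectSizeLog2 = "numeric", sigmaRep = "numeric",
                   baselineMeanLog2 = "numeric", baselineSdLog2 = "numeric",
                   compression = "numeric", intensityShiftLog2 = "numeric",
                   spreadShrink = "numeric", backgroundLevel = "numeric",
                   backgroundInflation = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- NULL
    chk <- function(ok, what) if (!ok) msg <<- c(msg, what)
    chk(object@nGenes >= 1L, "nGenes must be a positive integer")
    chk(object@probesPerGene >= 1L, "probesPerGene must be a positive integer")
    chk(object@nReplicates >= 1L, "nReplicates must be a positive integer")
    chk(object@piDE >= 0 && object@piDE <= 1, "piDE must lie in [0, 1]")
    chk(object@effectSizeLog2 > 0, "effectSizeLog2 must be positive")
    chk(object@sigmaRep >= 0, "sigmaRep must be nonnegative")
    chk(object@baselineSdLog2 > 0, "baselineSdLog2 must be positive")
    chk(object@compression > 0 && object@compression <= 1,
        "compression must lie in (0, 1]")
    chk(object@intensityShiftLog2 <= 0, "intensityShiftLog2 must be <= 0")
    chk(object@spreadShrink > 0 && object@spreadShrink <= 1,
        "spreadShrink must lie in (0, 1]")
    chk(object@backgroundLevel >= 0, "backgroundLevel must be nonnegative")
    chk(object@backgroundInflation >= 1,
        "backgroundInflation must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' Ground truth of a simulated experiment pair
#'
#' @slot geneIds gene identifiers; \code{trueLog2fc} per-gene true log2 fold
#'   change (B vs A); \code{isDE} whether the gene is differentially
#'   expressed; \code{direction} \code{"up"}, \code{"down"} or \code{"null"}.
#' @aliases GroundTruth-class
#' @exportClass GroundTruth
setClass("GroundTruth",
    representation(geneIds = "character", trueLog2fc = "numeric",
                   isDE = "logical", direction = "character"))

setValidity("GroundTruth", function(object) {
    msg <- NULL
    if (!all(object@isDE == (object@trueLog2fc != 0)))
        msg <- c(msg, "isDE must be true exactly when trueLog2fc != 0")
    expect <- ifelse(object@trueLog2fc > 0, "up",
                     ifelse(object@trueLog2fc < 0, "down", "null"))
    if (!all(object@direction == expect))
        msg <- c(msg, "direction must be consistent with the sign of trueLog2fc")
    if (is.null(msg)) TRUE else msg
})
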