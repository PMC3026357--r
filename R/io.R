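## Text I/O: expression/probe matrices, mapping tables, group assignments.
##
## Dialect: TSV, UTF-8, mandatory header row, no quoting, '#' comment lines
## reserved for provenance headers. Missing values are not supported in
## expression matrices; a blank or non-numeric cell is a hard error.

.readTSV <- function(path) {
    utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                      header = TRUE, check.names = FALSE,
                      colClasses = "character", stringsAsFactors = FALSE)
}

.writeTSV <- function(df, path, comments = character()) {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    if (length(comments))
        writeLines(paste0("# ", comments), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = TRUE)
}

.parseNumericCells <- function(raw, geneIds, arrayIds, path) {
    vals <- suppressWarnings(
        vapply(seq_along(arrayIds),
               function(j) as.numeric(raw[[j]]), numeric(length(geneIds))))
    vals <- matrix(vals, nrow = length(geneIds),
                   dimnames = list(geneIds, arrayIds))
    bad <- which(is.na(vals), arr.ind = TRUE)
    if (nrow(bad) > 0L)
        stop(sprintf("non-numeric value in '%s' at gene '%s', array '%s'",
                     path, geneIds[bad[1L, 1L]], arrayIds[bad[1L, 2L]]),
             call. = FALSE)
    vals
}

.applyGroupMap <- function(arrayIds, groupMap) {
    missing <- setdiff(arrayIds, names(groupMap))
    if (length(missing))
        stop("array id(s) missing from group map: ",
             paste(missing, collapse = ", "), call. = FALSE)
    gm <- groupMap[arrayIds]
    list(group = vapply(gm, function(g) as.character(g$group), character(1)),
         replicate = vapply(gm, function(g) as.integer(g$replicate),
                            integer(1)))
}

#' Read a gene-level expression matrix from TSV
#'
#' The file must have a header row of array ids; the first column holds
#' gene/probeset ids; remaining cells are log2 intensities. Lines starting
#' with \code{#} are ignored.
#'
#' @param path TSV file path.
#' @param groupMap named list mapping each array id to
#'   \code{list(group = "A"|"B", replicate = k)}; see
#'   \code{\link{readGroupMap}}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
readExpressionMatrix <- function(path, groupMap) {
    df <- .readTSV(path)
    if (ncol(df) < 2L) stop("expression TSV needs a gene-id column plus at least one array column")
    geneIds <- df[[1L]]
    dup <- geneIds[duplicated(geneIds)]
    if (length(dup))
        stop(sprintf("duplicate gene id '%s' in '%s'", dup[1L], path),
             call. = FALSE)
    arrayIds <- colnames(df)[-1L]
    vals <- .parseNumericCells(df[-1L], geneIds, arrayIds, path)
    ann <- .applyGroupMap(arrayIds, groupMap)
    ExpressionMatrix(vals, group = ann$group, replicate = ann$replicate)
}

#' Write a gene-level expression matrix to TSV
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param path output file path.
#' @param comments optional character vector written as leading \code{#}
#'   provenance lines.
#' @export
writeExpressionMatrix <- function(x, path, comments = character()) {
    vals <- exprsMatrix(x)
    df <- data.frame(gene_id = rownames(vals),
                     format(vals, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    .writeTSV(df, path, comments)
    invisible(path)
}

#' Read/write probe-level intensity matrices
#'
#' Probe TSVs have columns \code{probe_id}, \code{probeset_id}, then one
#' column per array with linear-scale intensities. The optional mismatch file
#' must have identical probe rows and array columns.
#'
#' @param pmPath,mmPath paths to the perfect-match and (optional) mismatch
#'   TSV files.
#' @param groupMap as in \code{\link{readExpressionMatrix}}.
#' @return A \linkS4class{ProbeMatrix}.
#' @export
readProbeMatrix <- function(pmPath, groupMap, mmPath = NULL) {
    df <- .readTSV(pmPath)
    if (ncol(df) < 3L)
        stop("probe TSV needs probe_id, probeset_id and at least one array column")
    probeIds <- df[[1L]]
    if (anyDuplicated(probeIds))
        stop(sprintf("duplicate probe id '%s' in '%s'",
                     probeIds[duplicated(probeIds)][1L], pmPath), call. = FALSE)
    arrayIds <- colnames(df)[-(1:2)]
    pm <- .parseNumericCells(df[-(1:2)], probeIds, arrayIds, pmPath)
    mm <- NULL
    if (!is.null(mmPath)) {
        mdf <- .readTSV(mmPath)
        if (!identical(mdf[[1L]], probeIds) ||
            !identical(colnames(mdf)[-(1:2)], arrayIds))
            stop("mismatch file does not align with the perfect-match file")
        mm <- .parseNumericCells(mdf[-(1:2)], probeIds, arrayIds, mmPath)
    }
    ann <- .applyGroupMap(arrayIds, groupMap)
    ProbeMatrix(pm, probeset = df[[2L]], group = ann$group,
                replicate = ann$replicate, mm = mm)
}

#' @rdname readProbeMatrix
#' @param x a \linkS4class{ProbeMatrix}.
#' @param path output path for the perfect-match TSV.
#' @param comments provenance comment lines.
#' @export
writeProbeMatrix <- function(x, path, mmPath = NULL, comments = character()) {
    pm <- pmMatrix(x)
    base <- data.frame(probe_id = rownames(pm), probeset_id = probesets(x),
                       stringsAsFactors = FALSE)
    .writeTSV(cbind(base, format(pm, digits = 15, trim = TRUE,
                                 scientific = FALSE)), path, comments)
    mm <- mmMatrix(x)
    if (!is.null(mm) && !is.null(mmPath))
        .writeTSV(cbind(base, format(mm, digits = 15, trim = TRUE,
                                     scientific = FALSE)), mmPath, comments)
    invisible(path)
}

#' Read a sample-group assignment file
#'
#' YAML or JSON mapping each array id to its sample group and replicate
#' index, e.g. \code{A1: {group: A, replicate: 1}}.
#'
#' @param path file path (\code{.yaml}/\code{.yml} or \code{.json}).
#' @return named list of \code{list(group, replicate)} entries.
#' @export
readGroupMap <- function(path) {
    gm <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = FALSE)
    else yaml::read_yaml(path)
    if (!length(gm) || is.null(names(gm)))
        stop("group map must name at least one array id")
    bad <- names(gm)[!vapply(gm, function(g)
        !is.null(g$group) && g$group %in% c("A", "B") &&
        !is.null(g$replicate) && g$replicate >= 1, logical(1))]
    if (length(bad))
        stop("invalid group map entries for: ", paste(bad, collapse = ", "))
    gm
}

#' Read a one-probe-to-one-gene cross-platform mapping table
#'
#' TSV with a gene-id column (first) and one probe-id column per platform,
#' mirroring the MAQC cross-platform mapping file layout. Empty probe cells
#' are retained but mark the gene as unmapped on that platform.
#'
#' @param path TSV file path.
#' @return A \linkS4class{MappingTable}.
#' @export
readMappingTable <- function(path) {
    df <- .readTSV(path)
    if (nrow(df) == 0L) stop("mapping table has zero data rows")
    if (ncol(df) < 2L) stop("mapping table needs a gene-id column plus at least one platform column")
    geneIds <- df[[1L]]
    dup <- geneIds[duplicated(geneIds)]
    if (length(dup))
        stop(sprintf("duplicate gene id '%s' in mapping table", dup[1L]),
             call. = FALSE)
    probes <- as.matrix(df[-1L])
    probes[!nzchar(trimws(probes)) | is.na(probes)] <- NA_character_
    rownames(probes) <- geneIds
    new("MappingTable", geneIds = geneIds, probes = probes,
        platforms = colnames(probes))
}

#' Align experiments onto their common mapped gene universe
#'
#' Restricts each experiment to the genes that are (i) mapped on every input
#' platform in the mapping table and (ii) present (by probe id or gene id) in
#' every matrix, translating probe ids to gene ids. All returned matrices
#' share an identical gene order, which follows the mapping-table row order so
#' downstream paired-vector operations are positionally aligned.
#'
#' @param experiments named list of \linkS4class{ExpressionMatrix} objects,
#'   names = platform names appearing in \code{mapping}.
#' @param mapping a \linkS4class{MappingTable}.
#' @return list of \linkS4class{ExpressionMatrix} objects, one per input,
#'   rows renamed to gene ids and identically ordered.
#' @export
intersectCommonGenes <- function(experiments, mapping) {
    stopifnot(is.list(experiments), length(experiments) >= 1L)
    plats <- names(experiments)
    if (is.null(plats) || !all(nzchar(plats)))
        stop("'experiments' must be a named list keyed by platform")
    unknown <- setdiff(plats, mapping@platforms)
    if (length(unknown))
        stop("platform(s) not in mapping table: ",
             paste(unknown, collapse = ", "))
    keep <- rep(TRUE, length(mapping@geneIds))
    for (p in plats) {
        probes <- mapping@probes[, p]
        keep <- keep & !is.na(probes) &
            probes %in% rownames(experiments[[p]])
    }
    genes <- mapping@geneIds[keep]          # mapping-table row order
    if (length(genes) == 0L)
        stop("empty gene intersection across the supplied experiments")
    lapply(stats::setNames(plats, plats), function(p) {
        x <- experiments[[p]]
        vals <- exprsMatrix(x)[mapping@probes[keep, p], , drop = FALSE]
        rownames(vals) <- genes
        ExpressionMatrix(vals, group = arrayGroups(x),
                         replicate = arrayReplicates(x))
    })
}
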