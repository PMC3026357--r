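# Shared fixtures: all built in code at test time.

# Minimal DifferentialResult from a fold-change vector (p defaults well below
# any cutoff so filtering keeps everything unless overridden).
makeResult <- function(fc, p = rep(1e-4, length(fc)),
                       ids = sprintf("g%04d", seq_along(fc))) {
    new("DifferentialResult", geneIds = ids, log2fc = as.numeric(fc),
        tStat = as.numeric(fc), pValue = as.numeric(p),
        df = rep(4, length(fc)), groupSizes = c(3L, 3L),
        flagged = character())
}

makeExprMatrix <- function(vals, group = NULL, replicate = NULL) {
    if (is.null(group)) group <- rep(c("A", "B"), each = ncol(vals) / 2)
    if (is.null(replicate))
        replicate <- stats::ave(seq_len(ncol(vals)), group,
                                FUN = seq_along)
    ExpressionMatrix(vals, group = group, replicate = replicate)
}

# Group map for the simulator's array naming
simGroupMap <- function(prefix = "REF_", nRep = 3) {
    ids <- c(paste0(prefix, "A", 1:nRep), paste0(prefix, "B", 1:nRep))
    g <- lapply(ids, function(id)
        list(group = sub(".*_([AB]).*", "\\1", id),
             replicate = as.integer(sub(".*([0-9])$", "\\1", id))))
    names(g) <- ids
    g
}

# Independent plain-R median polish (same published algorithm: alternating
# row/column sweeps with lower-middle medians), written naively as an oracle.
lowMedian <- function(x) sort(x)[(length(x) + 1) %/% 2]

oracleMedianPolish <- function(z, tol = 0.01, maxIter = 10) {
    rowEff <- rep(0, nrow(z)); colEff <- rep(0, ncol(z)); overall <- 0
    oldsum <- 0
    for (iter in seq_len(maxIter)) {
        for (i in seq_len(nrow(z))) {
            m <- lowMedian(z[i, ]); z[i, ] <- z[i, ] - m
            rowEff[i] <- rowEff[i] + m
        }
        d <- lowMedian(colEff); colEff <- colEff - d; overall <- overall + d
        for (j in seq_len(ncol(z))) {
            m <- lowMedian(z[, j]); z[, j] <- z[, j] - m
            colEff[j] <- colEff[j] + m
        }
        d <- lowMedian(rowEff); rowEff <- rowEff - d; overall <- overall + d
        newsum <- sum(abs(z))
        if (newsum == 0 || abs(newsum - oldsum) < tol * newsum) break
        oldsum <- newsum
    }
    overall + colEff
}

# ProbeMatrix with one probeset whose PM/MM encode given discrimination
# scores R = (pm - mm) / (pm + mm).
probesFromScores <- function(R) {
    pm <- matrix((1 + R) / (1 - R), ncol = 2, nrow = length(R))
    colnames(pm) <- c("A1", "A2")
    rownames(pm) <- sprintf("p%02d", seq_along(R))
    mm <- matrix(1, nrow(pm), 2, dimnames = dimnames(pm))
    ProbeMatrix(pm, probeset = rep("ps1", length(R)),
                group = c("A", "A"), replicate = 1:2, mm = mm)
}
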