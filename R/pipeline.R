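## Stage orchestration: simulate -> summarize -> degs -> pog -> report from a
## single config, with deterministic provenance headers (config hash + seed,
## no timestamps, so identical config and seed give byte-identical outputs).

#' Deterministic configuration hash
#'
#' 64-bit FNV-1a over the deparsed configuration, reported as 16 hex digits.
#' Used in output provenance headers; excludes nothing but what you pass it,
#' and never any clock state.
#'
#' @param x any R object (typically a config list).
#' @return character scalar.
#' @export
configHash <- function(x) {
    bytes <- utf8ToInt(paste(deparse(x, control = "exact"), collapse = "\n"))
    ## FNV-1a, 64-bit arithmetic emulated on two 32-bit halves
    prime_lo <- 435; prime_hi <- 256        # 0x100000001b3 = 2^40 + 2^8 + 0xb3
    lo <- 2216829733; hi <- 3421674724      # offset basis 0xcbf29ce484222325
    two32 <- 4294967296
    for (b in bytes) {
        ## xor into the low byte (values exceed .Machine$integer.max, so
        ## stay in doubles and xor only the byte that changes)
        lo <- (lo %/% 256) * 256 + bitwXor(lo %% 256, b)
        ## (hi,lo) * prime, keeping 64 bits
        new_lo <- lo * prime_lo
        new_hi <- (hi * prime_lo + lo * prime_hi +
                   floor(new_lo / two32)) %% two32
        lo <- new_lo %% two32
        hi <- new_hi
    }
    sprintf("%04x%04x%04x%04x", as.integer(hi %/% 65536),
            as.integer(hi %% 65536), as.integer(lo %/% 65536),
            as.integer(lo %% 65536))
}

.defaultRunConfig <- function() {
    list(outDir = ".", seed = 1L, pCutoff = 0.05, L = "max",
         ciLevel = 0.95, scalingTarget = 500, scalingTrim = 0.02,
         tau = 0.015, alpha1 = 0.04, alpha2 = 0.06,
         sim = list())
}

.validateRunConfig <- function(config) {
    bad <- function(msg) stop("invalid config: ", msg, call. = FALSE)
    if (!is.numeric(config$pCutoff) || config$pCutoff <= 0 ||
        config$pCutoff > 1)
        bad("pCutoff must lie in (0, 1]")
    if (!is.numeric(config$ciLevel) || config$ciLevel <= 0 ||
        config$ciLevel >= 1)
        bad("ciLevel must lie in (0, 1)")
    if (!identical(config$L, "max") &&
        (!is.numeric(config$L) || config$L < 1))
        bad("L must be 'max' or a positive integer")
    if (config$alpha1 >= config$alpha2)
        bad("alpha1 must be smaller than alpha2")
    if (config$scalingTrim <= 0 || config$scalingTrim >= 0.5)
        bad("scalingTrim must lie in (0, 0.5)")
    invisible(config)
}

#' Run the simulate / summarize / degs / pog / report pipeline
#'
#' Executes the stages in dependency order from a single configuration:
#' simulate a reference/degraded probe-level pair, RMA-summarize each
#' platform separately, compute Welch statistics and DEG lists, the POG
#' curve between the platforms, and a report of directional-agreement
#' scenarios plus per-array QC. Every output TSV carries a provenance header
#' (\code{# config_hash=..., seed=...}); outputs contain no timestamps, so a
#' rerun with the same config is byte-identical.
#'
#' @param config named list (or path to a YAML file) with any of: outDir,
#'   seed, pCutoff, L ("max" or integer), ciLevel, scalingTarget,
#'   scalingTrim, tau, alpha1, alpha2, and a \code{sim} sub-list of
#'   \code{\link{SimulationConfig}} arguments.
#' @return invisibly, a named list of written file paths.
#' @export
runPipeline <- function(config = list()) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- utils::modifyList(.defaultRunConfig(), config)
    .validateRunConfig(cfg)
    simArgs <- utils::modifyList(list(seed = cfg$seed), cfg$sim)
    simCfg <- do.call(SimulationConfig, simArgs)
    ## hash the analysis parameters, not the output location
    hash <- configHash(cfg[setdiff(names(cfg), "outDir")])
    prov <- c(sprintf("arrayConcord pipeline config_hash=%s seed=%d", hash,
                      as.integer(cfg$seed)))
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(cfg$outDir, f)
    paths <- c()

    message("stage simulate")
    sim <- simulateExperimentPair(simCfg)
    paths <- c(paths, writeSimulatedPair(sim, simCfg, cfg$outDir))

    message("stage summarize")
    results <- list()
    for (platform in c("reference", "degraded")) {
        probes <- sim[[platform]]
        expr <- rmaSummarize(probes)
        writeExpressionMatrix(expr, out(paste0(platform, "_exprs.tsv")),
                              comments = prov)
        qc <- arrayQC(probes, expr, target = cfg$scalingTarget,
                      trim = cfg$scalingTrim, tau = cfg$tau,
                      alpha1 = cfg$alpha1, alpha2 = cfg$alpha2)
        .writeTSV(qc, out(paste0(platform, "_qc.tsv")), comments = prov)
        paths <- c(paths, stats::setNames(
            c(out(paste0(platform, "_exprs.tsv")),
              out(paste0(platform, "_qc.tsv"))),
            paste0(platform, c("_exprs", "_qc"))))
        results[[platform]] <- welchTTest(expr)
    }

    message("stage degs")
    L <- if (identical(cfg$L, "max"))
        maxSharedL(results$reference, results$degraded, cfg$pCutoff)
    else as.integer(cfg$L)
    for (platform in names(results)) {
        r <- results[[platform]]
        degs <- selectDEGs(r, L = L, pCutoff = cfg$pCutoff)
        tab <- data.frame(gene_id = c(degs@up, degs@down),
                          direction = rep(c("up", "down"), each = L),
                          rank = rep(seq_len(L), 2L),
                          stringsAsFactors = FALSE)
        idx <- match(tab$gene_id, r@geneIds)
        tab$log2fc <- r@log2fc[idx]; tab$t <- r@tStat[idx]
        tab$p <- r@pValue[idx]
        .writeTSV(tab, out(paste0(platform, "_degs.tsv")), comments = prov)
        paths <- c(paths, stats::setNames(out(paste0(platform, "_degs.tsv")),
                                          paste0(platform, "_degs")))
    }

    message("stage pog")
    curve <- pogCurve(results$degraded, results$reference,
                      pCutoff = cfg$pCutoff, label = "degraded vs reference")
    .writeTSV(data.frame(two_L = curve@twoL, pog_percent = curve@pog),
              out("pog_curve.tsv"), comments = prov)
    paths <- c(paths, pog_curve = out("pog_curve.tsv"))

    message("stage report")
    rep <- do.call(rbind, lapply(c("all", "either", "both"), function(s) {
        ag <- directionalAgreement(results$degraded, results$reference,
                                   scenario = s, pCutoff = cfg$pCutoff)
        data.frame(scenario = s, n_genes = ag@nGenes,
                   n_concordant = ag@nConcordant,
                   n_discordant = ag@nDiscordant, percent = ag@percent)
    }))
    rep$compression_slope <- compressionSlope(results$degraded,
                                              results$reference)
    .writeTSV(rep, out("agreement_report.tsv"), comments = prov)
    paths <- c(paths, agreement_report = out("agreement_report.tsv"))
    invisible(paths)
}
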