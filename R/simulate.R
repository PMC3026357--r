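## Paired-platform probe-level simulator with known ground truth.
##
## The generator emulates the contrast between a healthy ("reference")
## Affymetrix-style platform and a degraded ("expired") one: fold-change
## compression, a downward shift in mean log2 intensity, a narrower
## between-gene intensity spread, and an inflated additive background that
## drives weaker detection (fewer Present calls, larger scaling factors).

#' Simulator configuration
#'
#' Defaults mirror the regime of a two-sample (A vs B) MAQC-style comparison
#' on ~8.5k common genes with 3 technical replicates per sample: baseline
#' log2 intensities around N(7.8, 2.3), a degraded platform shifted down by
#' 1.5 log2 units with its between-gene SD shrunk to 84% and fold changes
#' compressed to 80%, and a 4-fold inflated additive background.
#'
#' @param nGenes number of genes.
#' @param probesPerGene probes per probeset (11 is the Affymetrix 3' design).
#' @param nReplicates technical replicates per sample.
#' @param piDE fraction of genes differentially expressed between B and A.
#' @param effectSizeLog2 mean |true log2 fold change| of DE genes (magnitudes
#'   are exponentially distributed with this mean).
#' @param sigmaRep replicate noise SD per probe, log2 scale.
#' @param baselineMeanLog2,baselineSdLog2 between-gene distribution of
#'   sample-A log2 signal means.
#' @param compression multiplier in (0,1] applied to true log2 fold changes
#'   on the degraded platform.
#' @param intensityShiftLog2 additive shift (<= 0) of the degraded platform's
#'   mean log2 intensity.
#' @param spreadShrink multiplier in (0,1] on the degraded platform's
#'   between-gene SD.
#' @param backgroundLevel mean of the exponential additive background on the
#'   linear intensity scale (0 disables background and mismatch probes).
#' @param backgroundInflation background multiplier on the degraded platform.
#' @param seed RNG seed; the whole pair is reproducible from it.
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
SimulationConfig <- function(nGenes = 8550L, probesPerGene = 11L,
                             nReplicates = 3L, piDE = 0.7,
                             effectSizeLog2 = 1.5, sigmaRep = 0.15,
                             baselineMeanLog2 = 7.8, baselineSdLog2 = 2.3,
                             compression = 0.8, intensityShiftLog2 = -1.5,
                             spreadShrink = 0.84, backgroundLevel = 30,
                             backgroundInflation = 4, seed = 1L) {
    new("SimulationConfig", nGenes = as.integer(nGenes),
        probesPerGene = as.integer(probesPerGene),
        nReplicates = as.integer(nReplicates), piDE = piDE,
        effectSizeLog2 = effectSizeLog2, sigmaRep = sigmaRep,
        baselineMeanLog2 = baselineMeanLog2,
        baselineSdLog2 = baselineSdLog2, compression = compression,
        intensityShiftLog2 = intensityShiftLog2, spreadShrink = spreadShrink,
        backgroundLevel = backgroundLevel,
        backgroundInflation = backgroundInflation, seed = as.integer(seed))
}

.simGeneIds <- function(n) sprintf("g%05d", seq_len(n))

.simPlatform <- function(geneMeanA, fc, affinity, cfg, bgMean, arrayIds,
                         group) {
    G <- cfg@nGenes; P <- cfg@probesPerGene; nArr <- length(arrayIds)
    ## log2 signal mean per probe x array: gene mean (+ fc for B) + affinity
    geneMean <- outer(geneMeanA, rep(0, nArr), "+")
    geneMean[, group == "B"] <- geneMean[, group == "B"] + fc
    ## expand to probes (gene-major, probe-minor row order)
    probeMean <- geneMean[rep(seq_len(G), each = P), , drop = FALSE] +
        affinity
    noise <- matrix(stats::rnorm(G * P * nArr, 0, cfg@sigmaRep), G * P, nArr)
    signal <- 2 ^ (probeMean + noise)
    if (bgMean > 0) {
        pm <- signal + matrix(stats::rexp(G * P * nArr, rate = 1 / bgMean),
                              G * P, nArr)
        mm <- matrix(stats::rexp(G * P * nArr, rate = 1 / bgMean),
                     G * P, nArr)
    } else {
        pm <- signal
        mm <- NULL
    }
    ids <- .simGeneIds(G)
    probeIds <- paste0(rep(ids, each = P), "_p", sprintf("%02d", seq_len(P)))
    dimnames(pm) <- list(probeIds, arrayIds)
    if (!is.null(mm)) dimnames(mm) <- dimnames(pm)
    ProbeMatrix(pm, probeset = rep(ids, each = P), group = group,
                replicate = rep(seq_len(cfg@nReplicates), 2L), mm = mm)
}

#' Simulate a paired reference/degraded probe-level experiment
#'
#' Per gene g, the sample-A log2 signal mean is drawn from
#' N(baselineMeanLog2, baselineSdLog2); sample B adds the true log2 fold
#' change, which is 0 for non-DE genes and, for the piDE fraction of DE
#' genes, carries a fair-coin sign and an Exponential(mean = effectSizeLog2)
#' magnitude -- a heavy-tailed fold-change spectrum, so fold-change ranking
#' is informative at every list size. Probe-level PM intensity is
#' 2^(gene mean + probe affinity + N(0, sigmaRep)) plus exponential
#' background; MM probes carry background only. Probe affinities
#' (N(0, 0.5)) are drawn once and shared between the two platforms, matching
#' identically designed probes. The degraded platform uses
#' compression * true fold change, gene means shifted by intensityShiftLog2
#' with between-gene SD multiplied by spreadShrink, and background inflated
#' by backgroundInflation.
#'
#' A single seeded RNG stream is consumed in a fixed order (gene-level draws,
#' affinities, then per-platform noise and background), so the output is
#' bit-reproducible from \code{config@seed}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{reference} and \code{degraded}
#'   (\linkS4class{ProbeMatrix}) and \code{truth}
#'   (\linkS4class{GroundTruth}).
#' @export
simulateExperimentPair <- function(config) {
    validObject(config)
    set.seed(config@seed)
    G <- config@nGenes; P <- config@probesPerGene; R <- config@nReplicates
    ids <- .simGeneIds(G)

    aMean <- stats::rnorm(G, config@baselineMeanLog2, config@baselineSdLog2)
    de <- stats::runif(G) < config@piDE
    sgn <- ifelse(stats::runif(G) < 0.5, 1, -1)
    mag <- stats::rexp(G, rate = 1 / config@effectSizeLog2)
    fc <- ifelse(de, sgn * mag, 0)
    affinity <- matrix(stats::rnorm(G * P, 0, 0.5), G * P, 1L)[, 1L]

    arrayIds <- c(paste0("A", seq_len(R)), paste0("B", seq_len(R)))
    group <- rep(c("A", "B"), each = R)

    reference <- .simPlatform(aMean, fc, affinity, config,
                              config@backgroundLevel,
                              paste0("REF_", arrayIds), group)
    aMeanDeg <- config@baselineMeanLog2 + config@intensityShiftLog2 +
        config@spreadShrink * (aMean - config@baselineMeanLog2)
    degraded <- .simPlatform(aMeanDeg, config@compression * fc, affinity,
                             config,
                             config@backgroundLevel * config@backgroundInflation,
                             paste0("DEG_", arrayIds), group)

    truth <- new("GroundTruth", geneIds = ids, trueLog2fc = fc, isDE = de,
                 direction = ifelse(fc > 0, "up",
                                    ifelse(fc < 0, "down", "null")))
    list(reference = reference, degraded = degraded, truth = truth)
}

#' Analytic expectations implied by a simulator configuration
#'
#' Closed-form summaries used to test the generator: expected mean and
#' between-gene SD of log2 signal per platform (sample A), the expected
#' ratio of degraded to reference |log2 fold change| (the compression
#' multiplier itself), and the expected between-replicate Pearson correlation
#' of gene-level log2 signal when each gene is measured by a single probe,
#' \eqn{1 / (1 + (sigmaRep / baselineSdLog2)^2)}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{meanLog2}, \code{sdLog2} (each
#'   reference/degraded), \code{fcRatio} and \code{replicateCorrelation}.
#' @export
expectedDegradationReport <- function(config) {
    validObject(config)
    list(meanLog2 = c(reference = config@baselineMeanLog2,
                      degraded = config@baselineMeanLog2 +
                          config@intensityShiftLog2),
         sdLog2 = c(reference = config@baselineSdLog2,
                    degraded = config@baselineSdLog2 * config@spreadShrink),
         fcRatio = config@compression,
         replicateCorrelation =
             1 / (1 + (config@sigmaRep / config@baselineSdLog2)^2))
}

#' Write the artifacts of a simulated pair to a directory
#'
#' Writes reference and degraded probe TSVs (plus mismatch TSVs when
#' background is enabled), a ground-truth TSV (gene_id, true_log2fc, is_de)
#' and the resolved configuration as YAML.
#'
#' @param sim result of \code{\link{simulateExperimentPair}}.
#' @param config the \linkS4class{SimulationConfig} used.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
writeSimulatedPair <- function(sim, config, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    prov <- c(sprintf("arrayConcord simulate seed=%d", config@seed),
              sprintf("config_hash=%s", configHash(as.list.SimulationConfig(config))))
    paths <- c(reference_pm = file.path(dir, "reference_pm.tsv"),
               degraded_pm = file.path(dir, "degraded_pm.tsv"),
               reference_mm = file.path(dir, "reference_mm.tsv"),
               degraded_mm = file.path(dir, "degraded_mm.tsv"),
               truth = file.path(dir, "truth.tsv"),
               config = file.path(dir, "sim_config.yaml"))
    hasMM <- !is.null(mmMatrix(sim$reference))
    writeProbeMatrix(sim$reference, paths["reference_pm"],
                     mmPath = if (hasMM) paths["reference_mm"],
                     comments = prov)
    writeProbeMatrix(sim$degraded, paths["degraded_pm"],
                     mmPath = if (hasMM) paths["degraded_mm"],
                     comments = prov)
    truth <- sim$truth
    .writeTSV(data.frame(gene_id = truth@geneIds,
                         true_log2fc = truth@trueLog2fc,
                         is_de = truth@isDE, direction = truth@direction),
              paths["truth"], comments = prov)
    yaml::write_yaml(as.list.SimulationConfig(config), paths["config"])
    if (!hasMM) paths <- paths[setdiff(names(paths),
                                       c("reference_mm", "degraded_mm"))]
    invisible(paths)
}

#' @method as.list SimulationConfig
#' @export
as.list.SimulationConfig <- function(x, ...) {
    nm <- slotNames("SimulationConfig")
    stats::setNames(lapply(nm, function(s) slot(x, s)), nm)
}
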