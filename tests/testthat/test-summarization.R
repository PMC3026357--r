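test_that("background correction is positive, order-preserving and handles degenerate input", {
    set.seed(42)
    x <- rexp(500, 1 / 100) + rnorm(500, 60, 10)
    x <- pmax(x, 1)
    out <- rmaBackgroundCorrect(x)
    expect_true(all(out > 0))
    expect_identical(order(out), order(x))

    const <- rep(50, 30)
    expect_identical(rmaBackgroundCorrect(const), const)

    expect_error(rmaBackgroundCorrect(c(1, 2, 3)), "at least 10")
    expect_error(rmaBackgroundCorrect(c(-1, rep(2, 20))), "positive")
})

test_that("background correction recovers signal better than raw values", {
    # the model's own generative process: exponential signal + normal noise
    set.seed(7)
    n <- 5000
    signal <- rexp(n, rate = 1 / 150)
    observed <- signal + pmax(rnorm(n, 100, 12), 1)
    corrected <- rmaBackgroundCorrect(observed)
    rmseRaw <- sqrt(mean((observed - signal)^2))
    rmseCorrected <- sqrt(mean((corrected - signal)^2))
    expect_lt(rmseCorrected, rmseRaw)
})

test_that("quantile normalization enforces the shared reference distribution", {
    m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
    expect_equal(unname(quantileNormalize(m)),
                 cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

    same <- cbind(c(2, 9, 4), c(2, 9, 4))
    expect_equal(quantileNormalize(same), same, ignore_attr = TRUE)

    set.seed(1)
    x <- matrix(rlnorm(60, 5, 1), 15, 4)
    qn <- quantileNormalize(x)
    # identical sorted multiset in every column, ranks preserved
    sorted <- apply(qn, 2, sort)
    expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
    for (j in 1:4) expect_identical(order(qn[, j]), order(x[, j]))

    # permuted columns map onto permutations of the common reference
    perm <- cbind(x[, 1], sample(x[, 1]))
    qp <- quantileNormalize(perm)
    expect_equal(sort(qp[, 1]), sort(qp[, 2]))

    expect_warning(quantileNormalize(x[, 1, drop = FALSE]), "single-column")
})

test_that("quantile normalization matches the limma oracle", {
    skip_if_not_installed("limma")
    set.seed(23)
    x <- matrix(rlnorm(5 * 5, 6, 1.5), 5, 5)
    expect_equal(unname(quantileNormalize(x)),
                 unname(limma::normalizeQuantiles(x)), tolerance = 1e-10)
})

test_that("median polish reproduces additive structure exactly", {
    probeEff <- c(-1, 0, 2)
    arrayEff <- c(5, 7)
    lx <- outer(probeEff, arrayEff, "+")
    pm <- 2^lx
    dimnames(pm) <- list(paste0("p", 1:3), c("x1", "x2"))
    probes <- ProbeMatrix(pm, probeset = rep("ps", 3), group = c("A", "B"),
                          replicate = c(1, 1))
    e <- medianPolishSummarize(probes)
    v <- exprsMatrix(e)
    expect_equal(v[1, "x2"] - v[1, "x1"], 2)
    # constant matrix summarizes to the constant
    pmc <- matrix(2^3, 3, 2, dimnames = dimnames(pm))
    probesc <- ProbeMatrix(pmc, probeset = rep("ps", 3),
                           group = c("A", "B"), replicate = c(1, 1))
    expect_equal(unname(exprsMatrix(medianPolishSummarize(probesc))[1, ]),
                 c(3, 3))
})

test_that("median polish matches independent oracles cell for cell", {
    set.seed(5)
    lx <- matrix(rnorm(12, 8, 1), 4, 3)
    lx[2, 3] <- lx[2, 3] + 6          # one outlier cell
    pm <- 2^lx
    dimnames(pm) <- list(paste0("p", 1:4), c("x1", "x2", "x3"))
    probes <- ProbeMatrix(pm, probeset = rep("ps", 4),
                          group = c("A", "A", "B"), replicate = c(1, 2, 1))
    got <- unname(exprsMatrix(medianPolishSummarize(probes))[1, ])
    expect_equal(got, oracleMedianPolish(lx), tolerance = 1e-6)

    # odd x odd layout: lower-middle medians coincide with stats::medpolish
    lx5 <- matrix(rnorm(15, 10, 2), 5, 3)
    pm5 <- 2^lx5
    dimnames(pm5) <- list(paste0("p", 1:5), c("x1", "x2", "x3"))
    probes5 <- ProbeMatrix(pm5, probeset = rep("ps", 5),
                           group = c("A", "A", "B"), replicate = c(1, 2, 1))
    mp <- stats::medpolish(lx5, eps = 1e-9, maxiter = 10, trace.iter = FALSE)
    expect_equal(unname(exprsMatrix(medianPolishSummarize(probes5,
                                                          tol = 1e-9))[1, ]),
                 unname(mp$overall + mp$col), tolerance = 1e-6)

    # single-probe probeset passes through
    one <- ProbeMatrix(pm[1, , drop = FALSE], probeset = "solo",
                       group = c("A", "A", "B"), replicate = c(1, 2, 1))
    expect_equal(unname(exprsMatrix(medianPolishSummarize(one))[1, ]),
                 unname(log2(pm[1, ])))
})

test_that("scaling factor is target over trimmed mean and ignores trimmed outliers", {
    expect_equal(mas5ScalingFactor(rep(500, 100)), 1.0)
    expect_equal(mas5ScalingFactor(rep(250, 100)), 2.0)

    set.seed(9)
    base <- rlnorm(96, log(400), 0.3)
    outliers <- c(1e5, 2e5)
    low <- c(0.01, 0.02)
    sf1 <- mas5ScalingFactor(c(base, outliers, low))
    sf2 <- mas5ScalingFactor(c(base, outliers * 10, low / 10))
    expect_equal(sf1, sf2)

    expect_error(mas5ScalingFactor(c(-1, rep(2, 99))), "positive")
    expect_error(mas5ScalingFactor(rep(5, 10)), "trim")
})

test_that("detection calls follow the signed-rank discrimination test", {
    # PM = 10 x MM on all 11 probes: maximal discrimination -> Present
    pm <- matrix(1000, 11, 2, dimnames = list(sprintf("p%02d", 1:11),
                                              c("A1", "A2")))
    mm <- pm / 10
    probes <- ProbeMatrix(pm, probeset = rep("ps1", 11),
                          group = c("A", "A"), replicate = 1:2, mm = mm)
    dc <- detectionCalls(probes)
    expect_identical(unname(dc$calls["ps1", ]), c("P", "P"))
    expect_equal(unname(dc$percentPresent), c(100, 100))

    # PM = MM: all scores zero, below tau -> Absent
    probes0 <- ProbeMatrix(pm, probeset = rep("ps1", 11),
                           group = c("A", "A"), replicate = 1:2, mm = pm)
    dc0 <- detectionCalls(probes0)
    expect_identical(unname(dc0$calls["ps1", ]), c("A", "A"))

    expect_error(detectionCalls(ProbeMatrix(pm, probeset = rep("ps1", 11),
                                            group = c("A", "A"),
                                            replicate = 1:2)), "mismatch")
})

test_that("detection p-values match the wilcox.test oracle", {
    tau <- 0.015
    # mixed probeset with tied magnitudes (normal approximation path)
    Rmix <- c(rep(0.2, 6), rep(-0.1, 5))
    dcm <- detectionCalls(probesFromScores(Rmix))
    pOracle <- suppressWarnings(
        stats::wilcox.test(Rmix, mu = tau, alternative = "greater",
                           correct = TRUE)$p.value)
    expect_equal(unname(dcm$pValue["ps1", 1]), pOracle, tolerance = 1e-10)
    expect_identical(unname(dcm$calls["ps1", 1]),
                     if (pOracle < 0.04) "P" else if (pOracle < 0.06) "M"
                     else "A")

    # continuous scores (exact signed-rank path), several seeds
    for (seed in 1:5) {
        set.seed(seed)
        R <- round(runif(11, -0.4, 0.6), 3)
        dc <- detectionCalls(probesFromScores(R))
        pEx <- stats::wilcox.test(R, mu = tau, alternative = "greater",
                                  exact = TRUE)$p.value
        expect_equal(unname(dc$pValue["ps1", 1]), pEx, tolerance = 1e-12)
    }

    # < 3 probes: called but flagged low-confidence
    dc2 <- detectionCalls(probesFromScores(c(0.3, 0.4)))
    expect_true(dc2$lowConfidence[["ps1"]])
})

test_that("degraded platform shows the expected QC direction", {
    cfg <- SimulationConfig(nGenes = 400, seed = 17)
    sim <- simulateExperimentPair(cfg)
    qcRef <- arrayQC(sim$reference, rmaSummarize(sim$reference))
    qcDeg <- arrayQC(sim$degraded, rmaSummarize(sim$degraded))
    expect_gt(mean(qcDeg$scaling_factor), mean(qcRef$scaling_factor))
    expect_lt(mean(qcDeg$percent_present), mean(qcRef$percent_present))
    expect_lt(mean(qcDeg$mean_log2), mean(qcRef$mean_log2))
    expect_lt(mean(qcDeg$sd_log2), mean(qcRef$sd_log2))
})

test_that("noise-free pipeline keeps exact signs; quantile step compresses tails", {
    cfg <- SimulationConfig(nGenes = 1500, sigmaRep = 0, backgroundLevel = 0,
                            compression = 1, seed = 31)
    sim <- simulateExperimentPair(cfg)
    tr <- trueLog2fc(sim$truth)
    de <- isDE(sim$truth)

    # median polish alone recovers the truth exactly
    vP <- exprsMatrix(medianPolishSummarize(sim$reference))
    fcP <- rowMeans(vP[, 4:6]) - rowMeans(vP[, 1:3])
    expect_lt(max(abs(fcP - tr)), 1e-8)

    # adding quantile normalization across both samples distorts per-gene
    # fold changes wherever the two samples' intensity distributions differ:
    # the net effect is compression (slope < 1) with fold-change ranking
    # largely preserved
    vQ <- exprsMatrix(rmaSummarize(sim$reference, background = FALSE))
    fcQ <- rowMeans(vQ[, 4:6]) - rowMeans(vQ[, 1:3])
    expect_lt(sum(fcQ * tr) / sum(tr^2), 1)
    expect_gt(sum(fcQ * tr) / sum(tr^2), 0.5)
    up <- de & tr > 0
    expect_gt(stats::cor(fcQ[up], tr[up], method = "spearman"), 0.8)
})
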