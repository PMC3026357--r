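mkList <- function(up, down, L = length(up), p = 0.05) {
    new("DEGList", pCutoff = p, L = as.integer(L), up = up, down = down)
}

test_that("POG is the direction-split overlap fraction", {
    # DD=40, UU=45, L=50 -> 85
    up_a <- sprintf("u%02d", 1:50); down_a <- sprintf("d%02d", 1:50)
    up_b <- c(up_a[1:45], sprintf("x%02d", 1:5))
    down_b <- c(down_a[1:40], sprintf("y%02d", 1:10))
    a <- mkList(up_a, down_a); b <- mkList(up_b, down_b)
    expect_equal(pog(a, b), 85)
    oc <- overlapCounts(a, b)
    expect_identical(c(oc@DD, oc@UU), c(40L, 45L))

    expect_equal(pog(a, a), 100)
    disj <- mkList(sprintf("p%02d", 1:50), sprintf("q%02d", 1:50))
    expect_equal(pog(a, disj), 0)
    expect_error(pog(a, mkList("u01", "d01")), "equal L")
})

test_that("POG is symmetric and bounded on random list pairs", {
    set.seed(31)
    pool <- sprintf("g%03d", 1:200)
    for (i in 1:20) {
        g <- sample(pool)
        a <- mkList(g[1:30], g[31:60])
        h <- sample(pool)
        b <- mkList(h[1:30], h[31:60])
        pab <- pog(a, b)
        expect_identical(pab, pog(b, a))
        expect_gte(pab, 0); expect_lte(pab, 100)
    }
})

test_that("POG curves hit the forced extremes", {
    set.seed(32)
    fc <- c(seq(0.1, 5, length.out = 60), -seq(0.1, 5, length.out = 55))
    ids <- sprintf("g%03d", seq_along(fc))
    a <- makeResult(fc, ids = ids)
    cv <- pogCurve(a, a)
    expect_true(all(cv@pog == 100))
    expect_identical(cv@twoL, as.integer(2 * seq_len(55)))

    flipped <- makeResult(-fc, ids = ids)
    expect_true(all(pogCurve(a, flipped)@pog == 0))
})

test_that("noise-free compression leaves every POG at 100", {
    cfg <- SimulationConfig(nGenes = 500, sigmaRep = 0, compression = 0.7,
                            backgroundLevel = 0, probesPerGene = 3, seed = 2)
    sim <- simulateExperimentPair(cfg)
    rRef <- welchTTest(medianPolishSummarize(sim$reference))
    rDeg <- welchTTest(medianPolishSummarize(sim$degraded))
    cv <- pogCurve(rDeg, rRef)
    expect_true(all(cv@pog == 100))
})

test_that("reference band reproduces the t-interval", {
    mkCurve <- function(const, n = 30)
        new("POGCurve", twoL = as.integer(2 * seq_len(n)),
            pog = rep(const, n), label = sprintf("c%g", const))
    four <- lapply(c(70, 72, 74, 76), mkCurve)
    band <- referenceBand(four)
    m <- mean(c(70, 72, 74, 76))
    half <- stats::qt(0.975, df = 3) * stats::sd(c(70, 72, 74, 76)) / 2
    expect_true(all(abs(band@meanPog - m) < 1e-12))
    expect_true(all(abs(band@ciLower - (m - half)) < 1e-12))
    expect_true(all(abs(band@ciUpper - (m + half)) < 1e-12))

    # identical curves: zero-width band
    same <- referenceBand(lapply(c(80, 80), mkCurve))
    expect_true(all(same@ciUpper - same@ciLower == 0))
    expect_equal(referenceBand(lapply(c(60, 80), mkCurve))@meanPog[1], 70)
    expect_error(referenceBand(four[1]), "at least 2")

    # curves of different lengths are truncated to shared support
    mixed <- referenceBand(list(mkCurve(70, 10), mkCurve(80, 25)))
    expect_identical(max(mixed@twoL), 20L)
})

test_that("directional agreement counts sign matches per scenario", {
    a <- makeResult(c(1, -1, 1), p = c(0.01, 0.01, 0.2))
    b <- makeResult(c(2, -3, -1), p = c(0.01, 0.2, 0.2))
    all3 <- directionalAgreement(a, b, "all")
    expect_equal(all3@percent, 100 * 2 / 3, tolerance = 1e-12)
    expect_identical(all3@nDiscordant, 1L)

    either <- directionalAgreement(a, b, "either")
    expect_identical(either@nGenes, 2L)     # genes 1 and 2
    expect_equal(either@percent, 100)
    both <- directionalAgreement(a, b, "both")
    expect_identical(both@nGenes, 1L)
    expect_equal(both@percent, 100)

    expect_equal(directionalAgreement(a, a, "all")@percent, 100)
    expect_equal(directionalAgreement(a, a, "either")@percent, 100)

    # zero fold changes are excluded and reported
    z <- makeResult(c(1, 0, 1), p = rep(0.01, 3))
    agz <- directionalAgreement(z, b, "all")
    expect_identical(agz@nZeroExcluded, 1L)
    expect_identical(agz@nGenes, 2L)
})

test_that("scatter classification is consistent with agreement counts", {
    set.seed(33)
    n <- 300
    fa <- rnorm(n); fb <- 0.8 * fa + rnorm(n, 0, 0.5)
    a <- makeResult(fa, p = runif(n, 0, 0.2))
    b <- makeResult(fb, p = runif(n, 0, 0.2))
    for (sc in c("all", "either", "both")) {
        tab <- fcScatterTable(a, b, sc)
        ag <- directionalAgreement(a, b, sc)
        expect_identical(sum(tab$class == "discordant"), ag@nDiscordant)
        expect_identical(nrow(tab), ag@nGenes)
        expect_true(all(tab$class[tab$log2fc_a > 0 & tab$log2fc_b > 0] ==
                        "up-up"))
    }
    one <- fcScatterTable(makeResult(c(2, 0.5)), makeResult(c(1.4, -0.2)),
                          "all")
    expect_identical(one$class, c("up-up", "discordant"))
})

test_that("compression slope is the through-origin regression", {
    set.seed(34)
    fb <- rnorm(100, 0, 2)
    b <- makeResult(fb)
    expect_equal(compressionSlope(makeResult(0.7 * fb), b), 0.7)
    expect_equal(compressionSlope(b, b), 1.0)
    expect_error(compressionSlope(b, makeResult(rep(0, 100))), "zero")
})

test_that("replicate correlation summary averages pairwise correlations", {
    v <- matrix(rnorm(30, 8, 2), 10, 3)
    dup <- cbind(v[, 1], v[, 1], v[, 2], v[, 2])
    dimnames(dup) <- list(paste0("g", 1:10), c("a1", "a2", "b1", "b2"))
    e <- makeExprMatrix(dup)
    expect_equal(replicateCorrelationSummary(e, "A"), 1.0)
    expect_equal(replicateCorrelationSummary(e, "B"), 1.0)

    x <- rnorm(20)
    neg <- cbind(a1 = x, a2 = -x + 2 * mean(x), b1 = x, b2 = x)
    rownames(neg) <- paste0("g", 1:20)
    expect_equal(replicateCorrelationSummary(makeExprMatrix(neg), "A"), -1.0)

    const <- cbind(a1 = rep(1, 10), a2 = rnorm(10), b1 = rnorm(10),
                   b2 = rnorm(10))
    rownames(const) <- paste0("g", 1:10)
    expect_error(replicateCorrelationSummary(makeExprMatrix(const), "A"),
                 "constant")
})

test_that("replicate correlation follows the attenuation formula", {
    cfg <- SimulationConfig(nGenes = 8550, probesPerGene = 1, sigmaRep = 0.2,
                            backgroundLevel = 0, seed = 9)
    sim <- simulateExperimentPair(cfg)
    e <- medianPolishSummarize(sim$reference)
    expected <- 1 / (1 + (0.2 / 2.3)^2)
    expect_lt(abs(replicateCorrelationSummary(e, "A") - expected), 0.005)
    expect_lt(abs(replicateCorrelationSummary(e, "B") - expected), 0.005)
})
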