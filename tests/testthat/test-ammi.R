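test_that("double centring removes exactly the additive structure", {
    expect_equal(centerInteraction(GEMatrix(matrix(7, 4, 5))),
                 matrix(0, 4, 5), ignore_attr = TRUE)
    # a purely additive table has zero interaction
    a <- rnorm(6); b <- rnorm(4)
    ge <- GEMatrix(outer(a, b, `+`) + 50)
    expect_equal(max(abs(centerInteraction(ge))), 0, tolerance = 1e-10)
    # row and column sums of the centred matrix vanish
    Z <- centerInteraction(barleyTKW())
    expect_lt(max(abs(rowSums(Z))), 1e-9)
    expect_lt(max(abs(colSums(Z))), 1e-9)
})

test_that("decomposition recovers a planted rank-1 interaction", {
    set.seed(4)
    G <- 8; E <- 5; lam <- 6.5
    u <- rnorm(G); u <- u - mean(u); u <- u / sqrt(sum(u^2))
    v <- rnorm(E); v <- v - mean(v); v <- v / sqrt(sum(v^2))
    Y <- outer(rnorm(G), rnorm(E), `+`) + 30 + lam * outer(u, v)
    dec <- ammiDecompose(GEMatrix(Y, replicates = 2))
    expect_equal(singularValues(dec)[1], lam, tolerance = 1e-8)
    expect_lt(singularValues(dec)[2], 1e-8)
    # scores equal sqrt(lambda) * unit vectors up to a joint sign
    g1 <- genotypeScores(dec)[, 1]; e1 <- environmentScores(dec)[, 1]
    s <- sign(sum(e1 * v))
    expect_equal(unname(g1), s * sqrt(lam) * u, tolerance = 1e-8)
    expect_equal(unname(e1), s * sqrt(lam) * v, tolerance = 1e-8)
    expect_equal(axisSS(dec)[1], 2 * lam^2, tolerance = 1e-8)
})

test_that("AMMI identities hold on arbitrary balanced tables", {
    for (seed in 1:5) {
        set.seed(seed)
        G <- sample(4:12, 1); E <- sample(3:8, 1)
        ge <- GEMatrix(matrix(rnorm(G * E, 50, 8), G, E),
                       replicates = sample(1:4, 1))
        dec <- ammiDecompose(ge)
        # exact reconstruction with all axes
        expect_equal(ammiFitted(dec), geValues(ge), tolerance = 1e-8)
        # interaction SS is conserved across axes
        expect_equal(sum(axisSS(dec)), dec@interactionSS,
                     tolerance = 1e-6 * dec@interactionSS)
        # symmetric scaling: both sides' per-axis SS equal lambda
        for (n in seq_len(nAxes(dec))) {
            expect_equal(sum(genotypeScores(dec)[, n]^2),
                         singularValues(dec)[n], tolerance = 1e-8)
            expect_equal(sum(environmentScores(dec)[, n]^2),
                         singularValues(dec)[n], tolerance = 1e-8)
        }
        # score columns are mutually orthogonal
        cg <- crossprod(genotypeScores(dec))
        expect_lt(max(abs(cg - diag(diag(cg)))), 1e-8)
        # zero residual after retaining all axes
        expect_lt(max(abs(interactionResidual(dec, nAxes(dec)))), 1e-8)
    }
})

test_that("axis SS from the SVD equals brute-force successive rank-1 fits", {
    set.seed(9)
    Y <- matrix(rnorm(16, 20, 4), 4, 4)
    ge <- GEMatrix(Y, replicates = 3)
    dec <- ammiDecompose(ge)
    oracle <- successiveRank1SS(centerInteraction(ge), 3)
    expect_equal(unname(axisSS(dec)), 3 * oracle, tolerance = 1e-6)
})

test_that("Gollob df equal the free-parameter count of bilinear terms", {
    for (G in c(4, 6, 32)) for (E in c(3, 6, 9)) {
        M <- min(G - 1, E - 1)
        dfs <- G + E - 1 - 2 * seq_len(M)
        counted <- vapply(seq_len(M), function(n)
            rankParameterCount(G, E, n) - rankParameterCount(G, E, n - 1),
            numeric(1))
        expect_equal(dfs, counted)
        expect_equal(sum(dfs), (G - 1) * (E - 1) -
            (G - 1 - M) * (E - 1 - M))
    }
})

test_that("axis tests reproduce the published interaction partition", {
    dec <- ammiDecompose(barleyTKW())
    ax <- gollobAxisTests(dec, publishedAnova$errorMS,
                          publishedAnova$errorDf, nRetain = 3)
    expect_equal(ax$df, c(publishedAnova$ipcaDf, publishedAnova$residualDf))
    expect_equal(ax$ss[1:3], publishedAnova$ipcaSS, tolerance = 0.002)
    expect_equal(ax$ss[4], publishedAnova$residualSS, tolerance = 0.002)
    expect_equal(ax$f[1:3], publishedAnova$ipcaF, tolerance = 0.01)
    expect_equal(ax$pct[1:3], publishedAnova$ipcaPct, tolerance = 0.001)
    expect_true(all(ax$p[1:3] < 0.001))
    expect_error(gollobAxisTests(dec, 26.4, 372, nRetain = 9), "only 5")
    # default retention keeps the axes significant at 5%
    expect_identical(nrow(gollobAxisTests(dec, 26.4, 372)), 4L)
})

test_that("means-scale ANOVA reproduces the published strata", {
    ge <- barleyTKW()
    tab <- anovaFromMeans(ge, errorMS = 26.4, errorDf = 372)
    expect_equal(tab$ss[1], publishedAnova$ssG, tolerance = 0.002)
    expect_equal(tab$ss[2], publishedAnova$ssE, tolerance = 0.002)
    expect_equal(tab$ss[3], publishedAnova$ssGE, tolerance = 0.002)
    expect_equal(tab$df[1:3], c(31, 5, 155))
    expect_true(all(tab$p[1:3] < 0.001))
    # agreement with a naive direct-summation oracle
    bf <- bruteForceSS(geValues(ge), 3)
    expect_equal(tab$ss[1:3], unname(unlist(bf)), tolerance = 1e-10)
    # constant table: every stratum vanishes
    tab0 <- anovaFromMeans(GEMatrix(matrix(5, 4, 4)))
    expect_equal(tab0$ss, rep(0, 3), tolerance = 1e-20)
    expect_error(anovaFromMeans(ge, errorMS = 26.4), "errorDf")
})

test_that("replicate-level ANOVA is calibrated and detects huge effects", {
    # null data: genotype F centred near its theoretical mean df2/(df2-2)
    fs <- vapply(1:150, function(i) {
        rt <- simulateAMMITrial(ammiSimSpec(G = 6, E = 4, r = 3, mu = 10,
            genotypeEffects = rep(0, 6), environmentEffects = rep(0, 4),
            errorSD = 1, seed = 1000 + i))
        a <- anovaTwoWay(rt)
        a$f[a$source == "Genotypes"]
    }, numeric(1))
    expect_equal(mean(fs), 48 / 46, tolerance = 0.15)
    # huge genotype effects with vanishing noise: p collapses to zero
    rt <- simulateAMMITrial(ammiSimSpec(G = 5, E = 4, r = 2, mu = 0,
        genotypeEffects = seq(-20, 20, length.out = 5),
        environmentEffects = rep(0, 4), errorSD = 1e-6, seed = 3))
    a <- suppressWarnings(anovaTwoWay(rt))  # near-perfect fit warning
    expect_lt(a$p[a$source == "Genotypes"], 1e-12)
    # r = 1 input is directed to the means-based analysis
    rt1 <- simulateAMMITrial(ammiSimSpec(G = 4, E = 3, r = 1, seed = 2))
    expect_error(anovaTwoWay(rt1), "anovaFromMeans")
})

test_that("biplot coordinates expose means and scores as published", {
    ge <- barleyTKW()
    dec <- ammiDecompose(ge)
    b1 <- biplotCoordinates(dec, ge, "ammi1")
    expect_equal(attr(b1, "grandMean"), 44.80, tolerance = 1e-3)
    e2012 <- b1[b1$label == "2012" & b1$entity_type == "environment", ]
    expect_equal(e2012$x, 45.54, tolerance = 0.005)
    expect_equal(abs(e2012$y), 3.868, tolerance = 0.02)
    b2 <- biplotCoordinates(dec, ge, "ammi2")
    g1 <- b2[b2$label == "R63N/1", ]
    expect_equal(abs(c(g1$x, g1$y)), c(0.281, 0.328), tolerance = 0.02)
    # environment IPCA1 scores match the self-consistent printed set
    es <- environmentScores(dec)[names(publishedEnvIpca1), 1]
    expect_equal(unname(es), unname(publishedEnvIpca1), tolerance = 0.02)
    # no interaction: AMMI1 ordinates vanish
    geFlat <- GEMatrix(outer(rnorm(4), rnorm(3), `+`) + 50)
    decFlat <- suppressWarnings(ammiDecompose(geFlat))
    bFlat <- biplotCoordinates(decFlat, geFlat, "ammi1")
    expect_lt(max(abs(bFlat$y)), 1e-6)
})
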