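dhMeans <- function(ge, context = "Mean") {
    role <- genotypeRole(ge)
    y <- geValues(ge)
    m <- if (context == "Mean") rowMeans(y) else y[, context]
    m[names(role)[role == "dh_line"]]
}

test_that("quantile method isolates the published extreme lines", {
    ge <- barleyTKW()
    g08 <- extremeLines(dhMeans(ge, "2008"))
    expect_identical(minimalLines(g08), "R63N/47")   # 37.02
    expect_identical(maximalLines(g08), "R63N/18")   # 61.46
    gm <- extremeLines(dhMeans(ge))
    expect_identical(minimalLines(gm), "R63N/24")    # 34.80
    expect_identical(maximalLines(gm), "R63N/61")    # 54.59
    # extreme quantiles on a small population: singleton global extremes
    m <- setNames(c(3, 1, 4, 1.5, 9), paste0("L", 1:5))
    gl <- extremeLines(m, 0.01, 0.99)
    expect_identical(minimalLines(gl), "L2")
    expect_identical(maximalLines(gl), "L5")
    # degenerate and misconfigured inputs fail before estimation
    expect_error(extremeLines(setNames(rep(2, 5), paste0("L", 1:5))),
                 "constant")
    # interior quantiles over heavy ties make the groups collide
    expect_error(extremeLines(setNames(c(1, 2, 2, 2, 9), paste0("L", 1:5)),
                              0.4, 0.6), "overlap")
    expect_error(extremeLines(m, 0.9, 0.1), "qLow < qHigh")
    expect_error(extremeLines(m[1:2]), "at least 3")
    expect_error(extremeLines(unname(m)), "named")
})

test_that("effect estimators obey their closed forms and symmetries", {
    m <- setNames(c(10, 12, 14, 16, 18), paste0("L", 1:5))
    g <- extremeLines(m)
    expect_equal(additiveEffectDH(g, m), 4)         # (18-10)/2
    expect_equal(epistasisEffectDH(g, m), 0)        # symmetric population
    expect_equal(additiveEffectParents(54.13, 38.56), 7.785)
    expect_equal(additiveEffectParents(38.56, 54.13), 7.785)  # order-free
    expect_equal(additiveEffectParents(5, 5), 0)
    # equal extremes: zero additive effect
    m2 <- setNames(c(7, 3, 5, 7, 3), paste0("L", 1:5))
    g2 <- extremeLines(m2)
    expect_equal(additiveEffectDH(g2, m2), 2)
    # location invariance; linear scale equivariance
    for (shift in c(-5, 13)) {
        ms <- m2 + shift
        gs <- extremeLines(ms)
        expect_equal(additiveEffectDH(gs, ms), additiveEffectDH(g2, m2))
        expect_equal(epistasisEffectDH(gs, ms), epistasisEffectDH(g2, m2))
    }
    mk <- m2 * 2.5
    gk <- extremeLines(mk)
    expect_equal(additiveEffectDH(gk, mk), 2.5 * additiveEffectDH(g2, m2))
    expect_equal(epistasisEffectDH(gk, mk),
                 2.5 * epistasisEffectDH(g2, m2))
})

test_that("the full genetic-effect grid matches the published table", {
    eff <- suppressMessages(geneticEffects(barleyTKW()))
    for (key in rownames(publishedGenetics)) {
        parts <- strsplit(key, ".", fixed = TRUE)[[1]]
        sub <- eff[eff$parameter == parts[1] & eff$subset == parts[2], ]
        got <- setNames(sub$estimate, sub$context)
        expect_lt(max(abs(got[colnames(publishedGenetics)] -
                          publishedGenetics[key, ])), 0.01)
    }
    # spec invariants of the report itself
    expect_true(all(eff$estimate[eff$parameter == "a_dh"] >= 0))
    expect_true(all(eff$n_min >= 1 & eff$n_max >= 1))
})

test_that("simulated additive signal is recovered as noise vanishes", {
    spec <- dhSimSpec(nLines = 30, nLoci = 5, additive = c(2, 1, 3, 1, 1),
                      E = 1, r = 3, errorSD = 0, seed = 77)
    sim <- simulateDHPopulation(spec)
    m <- lineMeansOf(sim$table)
    g <- extremeLines(m)
    expect_equal(additiveEffectDH(g, m), sim$theoreticalAdditive)  # = 8
    # moderate noise: estimate concentrates near the planted effect
    ests <- vapply(1:60, function(i) {
        s <- dhSimSpec(nLines = 30, nLoci = 5, additive = c(2, 1, 3, 1, 1),
                       E = 1, r = 3, errorSD = 1.5, seed = 500 + i)
        sm <- simulateDHPopulation(s)
        mm <- lineMeansOf(sm$table)
        additiveEffectDH(extremeLines(mm), mm)
    }, numeric(1))
    expect_equal(mean(ests), 8, tolerance = 0.05)
})

test_that("two-locus epistasis matches exhaustive enumeration", {
    # all four homozygous classes, a = (2, 2), aa = 1 on the pair:
    # values ++ : 5, +- : -1, -+ : -1, -- : -3
    vals <- setNames(c(5, -1, -1, -3), c("pp", "pm", "mp", "mm"))
    g <- extremeLines(vals, 0.03, 0.97)
    expect_identical(minimalLines(g), "mm")
    expect_identical(maximalLines(g), "pp")
    expect_equal(additiveEffectDH(g, vals), 4)        # sum of |a|
    expect_equal(epistasisEffectDH(g, vals), 1)       # aa at the extremes
    # the simulator enumerates the same genotypic values
    spec <- dhSimSpec(nLines = 50, nLoci = 2, additive = 2,
                      epistasis = data.frame(locus1 = 1, locus2 = 2,
                                             effect = 1),
                      E = 1, r = 1, errorSD = 0, seed = 5)
    sim <- simulateDHPopulation(spec)
    expect_setequal(unique(unname(sim$values)), c(5, -1, -3))
    ext <- extremeLines(sim$values, 0.03, 0.97)
    expect_equal(additiveEffectDH(ext, sim$values), 4)
})

test_that("contrast F-tests behave analytically", {
    eff <- suppressMessages(geneticEffects(barleyTKW()))
    tst <- effectTests(eff, errorMS = 26.4, errorDf = 372)
    expect_true(all(c("ms", "f", "p", "stars") %in% colnames(tst)))
    expect_true(all(tst$f >= 0))
    # doubling the per-mean observation count doubles the contrast MS
    eff2 <- eff
    eff2$n_obs <- eff$n_obs * 2L
    tst2 <- effectTests(eff2, errorMS = 26.4, errorDf = 372)
    expect_equal(tst2$ms, 2 * tst$ms)
    # zero-noise planted signal: F explodes, p collapses
    spec <- dhSimSpec(nLines = 20, nLoci = 3, additive = 4, E = 1, r = 3,
                      errorSD = 1e-5, seed = 8)
    sim <- simulateDHPopulation(spec)
    rec <- as.data.frame(sim$table)
    withinMS <- sum(tapply(rec$value, rec$genotype, function(v)
        sum((v - mean(v))^2))) / (20 * 2)
    m <- lineMeansOf(sim$table)
    gr <- extremeLines(m)
    a <- additiveEffectDH(gr, m)
    msA <- a^2 / ((1 / 4 + 1 / 4) / 3)
    expect_gt(msA / withinMS, 1e6)
    # significance stars follow the conventional thresholds
    expect_identical(
        ammistab:::significanceStars(c(0.2, 0.04, 0.004, 1e-5, NA)),
        c("", "*", "**", "***", ""))
})

test_that("subset analyses re-identify extremes within each subset", {
    ge <- barleyTKW()
    eff <- suppressMessages(geneticEffects(ge))
    hul <- eff[eff$subset == "hulled" & eff$parameter == "a_dh" &
               eff$context == "2008", ]
    expect_identical(hul$n_lines, 15L)
    # hulled extremes for 2008: R63N/27 (41.54) and R63N/18 (61.46)
    expect_equal(hul$L_min, 41.54)
    expect_equal(hul$L_max, 61.46)
    # a genotype-role-free matrix cannot be analysed
    expect_error(suppressMessages(
        geneticEffects(GEMatrix(matrix(rnorm(12, 50), 4, 3)))), "role")
})
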