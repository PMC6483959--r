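# Reference values from the published six-year barley trial report,
# used to check end-to-end recomputation from the embedded cell means.
# Scores/ASV were printed to 3 decimals; effects to 2.

publishedStability <- data.frame(
    genotype = c("R63N/1", "R63N/3", "R63N/4", "R63N/9", "R63N/18",
                 "R63N/21", "R63N/22", "R63N/27", "R63N/28", "R63N/34",
                 "R63N/35", "R63N/61", "R63N/63", "R63N/67", "R63N/74",
                 "R63N/19", "R63N/46", "R63N/47", "R63N/14", "R63N/20",
                 "R63N/52", "R63N/65", "R63N/24", "R63N/31", "R63N/42",
                 "R63N/43", "R63N/55", "R63N/70", "R63N/71", "R63N/75",
                 "RK63/1", "1N86"),
    ipca1 = c(-0.281, 0.527, 0.274, 0.292, -0.807, 0.708, 0.062, 0.839,
              -0.720, 0.828, -0.595, -0.180, -1.032, 0.866, -2.534,
              0.171, -2.513, 2.684, 1.537, -0.754, -1.708, 2.170,
              -0.364, 0.204, 0.390, -1.134, 0.394, 0.394, -0.244,
              0.310, 0.786, -0.569),
    ipca2 = c(-0.328, 1.546, 0.830, 0.645, 1.812, 0.859, -0.142,
              -1.524, -0.091, 0.550, -1.016, -0.076, 0.391, 0.097,
              -0.178, 0.913, 1.342, -0.167, -0.347, 0.412, -2.047,
              -0.628, -1.681, -0.092, 1.140, -0.464, -0.142, 0.944,
              -0.303, -0.714, -0.505, -1.035),
    asv = c(0.712, 1.947, 1.033, 0.921, 2.563, 1.807, 0.199, 2.425,
            1.621, 1.941, 1.679, 0.412, 2.351, 1.949, 5.696, 0.990,
            5.804, 6.033, 3.471, 1.743, 4.351, 4.916, 1.870, 0.467,
            1.438, 2.591, 0.897, 1.294, 0.627, 0.997, 1.837, 1.645),
    gsi = c(8, 27, 19, 26, 30, 19, 5, 45, 35, 32, 40, 3, 34, 38, 43,
            34, 59, 61, 50, 34, 52, 44, 51, 20, 42, 46, 13, 19, 18,
            40, 28, 41),
    stringsAsFactors = FALSE)

# published ANOVA strata (replicate-total scale) and axis tests
publishedAnova <- list(
    ssG = 13210, ssE = 6920, ssGE = 10057,
    ipcaSS = c(4640, 2065, 1866), ipcaDf = c(35, 33, 31),
    ipcaF = c(5.03, 2.37, 2.28), ipcaPct = c(46.14, 20.53, 18.55),
    residualSS = 1486, residualDf = 56,
    errorMS = 26.4, errorDf = 372)

# genetic-effect grid: rows parameter x subset, columns year/mean
publishedGenetics <- local({
    g <- rbind(
        a_parents.parents   = c(1.36, 2.38, 4.09, 1.27, 5.26, 7.79, 3.69),
        a_dh.all            = c(12.22, 15.61, 10.21, 11.50, 13.92, 12.73, 9.90),
        aa_dh.all           = c(-0.47, -0.05, -0.64, -2.46, -0.90, -2.05, -0.18),
        a_dh.hulled         = c(9.96, 12.30, 6.05, 6.36, 12.17, 7.95, 7.28),
        aa_dh.hulled        = c(-1.50, 0.38, 0.10, 0.93, -1.11, -0.02, -0.24),
        a_dh.hull_less      = c(8.83, 11.33, 6.26, 10.56, 12.46, 8.95, 7.15),
        aa_dh.hull_less     = c(-0.57, -1.44, -1.17, -1.65, -0.40, -3.08, -0.25))
    colnames(g) <- c(2008:2013, "Mean")
    g
})

publishedEnvIpca1 <- c("2008" = -1.859, "2010" = -0.281, "2011" = -0.458,
                       "2012" = 3.868, "2013" = 2.513)
# (the printed 2009 IPCA1 score is internally inconsistent with the
# printed table and is not compared)
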