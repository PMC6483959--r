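# Independent oracles, deliberately avoiding the code paths they check.

# Best rank-1 approximation by alternating least squares (no svd());
# peeling terms off successively gives the per-axis interaction SS.
alsRank1 <- function(Z, iter = 500) {
    v <- Z[1, ] + colMeans(Z) + 1e-9
    for (i in seq_len(iter)) {
        u <- drop(Z %*% v) / sum(v^2)
        v <- drop(crossprod(Z, u)) / sum(u^2)
    }
    outer(u, v)
}

successiveRank1SS <- function(Z, k) {
    out <- numeric(k)
    for (i in seq_len(k)) {
        R1 <- alsRank1(Z)
        out[i] <- sum(R1^2)
        Z <- Z - R1
    }
    out
}

# free parameters of a rank-n G x E matrix with zero row/column sums
rankParameterCount <- function(G, E, n) {
    (G - 1) * (E - 1) - (G - 1 - n) * (E - 1 - n)
}

# GSI by exhaustive pairwise comparison counting (average ranks)
gsiByPairCounting <- function(means, asvs) {
    n <- length(means)
    ry <- vapply(seq_len(n), function(i)
        1 + sum(means > means[i]) + (sum(means == means[i]) - 1) / 2,
        numeric(1))
    rasv <- vapply(seq_len(n), function(i)
        1 + sum(asvs < asvs[i]) + (sum(asvs == asvs[i]) - 1) / 2,
        numeric(1))
    ry + rasv
}

# per-line means over all environments/replicates of a ReplicateTable
lineMeansOf <- function(rt) {
    rec <- as.data.frame(rt)
    tapply(rec$value, rec$genotype, mean)[unique(rec$genotype)]
}

# means-scale two-way SS by direct summation (no centring shortcut)
bruteForceSS <- function(Y, r) {
    G <- nrow(Y); E <- ncol(Y); gm <- mean(Y)
    ssG <- 0; ssE <- 0; ssGE <- 0
    for (g in seq_len(G)) for (e in seq_len(E)) {
        ssGE <- ssGE + (Y[g, e] - mean(Y[g, ]) - mean(Y[, e]) + gm)^2
    }
    for (g in seq_len(G)) ssG <- ssG + E * (mean(Y[g, ]) - gm)^2
    for (e in seq_len(E)) ssE <- ssE + G * (mean(Y[, e]) - gm)^2
    list(ssG = r * ssG, ssE = r * ssE, ssGE = r * ssGE)
}
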