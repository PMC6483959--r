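#' Doubly-centre a genotype-by-environment table
#'
#' Removes the grand mean and the genotype and environment main effects,
#' leaving the interaction matrix
#' \deqn{Z_{ge} = y_{ge} - \bar y_{g\cdot} - \bar y_{\cdot e} +
#'   \bar y_{\cdot\cdot}.}
#' Every row and column of Z sums to zero; its squared Frobenius norm
#' times r is the interaction sum of squares of the two-way ANOVA.
#'
#' @param ge a [GEMatrix-class]
#' @return the centred interaction matrix (same dimnames as the input)
#' @examples
#' Z <- centerInteraction(barleyTKW())
#' max(abs(rowSums(Z)))   # ~ 0
#' @export
centerInteraction <- function(ge) {
    y <- geValues(ge)
    sweep(sweep(y, 1L, rowMeans(y)), 2L, colMeans(y)) + mean(y)
}

#' AMMI decomposition of a genotype-by-environment table
#'
#' Fits the fixed-effects additive main effects and multiplicative
#' interaction model: genotype and environment main effects by least
#' squares, then an SVD of the doubly-centred interaction matrix. With
#' M = min(G-1, E-1) axes the model reconstructs the cell means exactly.
#'
#' Scores are symmetrically scaled (\eqn{\sqrt{\lambda_n}\gamma_{gn}},
#' \eqn{\sqrt{\lambda_n}\delta_{en}}), so for each axis the genotype and
#' environment score sums of squares both equal \eqn{\lambda_n}. Axis
#' sums of squares are \eqn{r\lambda_n^2} (replicate-total scale) and sum
#' to the interaction SS. SVD signs are arbitrary; each axis is flipped
#' so its largest-magnitude environment score is positive, a convention
#' that leaves ASV and GSI untouched. Axes are ordered by decreasing
#' singular value (the SVD order, which also breaks exact ties).
#'
#' @param ge a [GEMatrix-class]
#' @return an [AMMIDecomposition-class]
#' @examples
#' dec <- ammiDecompose(barleyTKW())
#' round(axisPct(dec)[1:3], 2)   # % of interaction SS per axis
#' @export
ammiDecompose <- function(ge) {
    y <- geValues(ge)
    G <- nrow(y); E <- ncol(y)
    r <- replicates(ge)
    Z <- centerInteraction(ge)
    M <- min(G - 1L, E - 1L)
    s <- svd(Z, nu = M, nv = M)
    lam <- s$d[seq_len(M)]
    gs <- s$u * rep(sqrt(lam), each = G)
    es <- s$v * rep(sqrt(lam), each = E)
    for (n in seq_len(M)) {       # largest-|.| environment score positive
        j <- which.max(abs(es[, n]))
        if (es[j, n] < 0) {
            es[, n] <- -es[, n]
            gs[, n] <- -gs[, n]
        }
    }
    dimnames(gs) <- list(rownames(y), paste0("IPCA", seq_len(M)))
    dimnames(es) <- list(colnames(y), paste0("IPCA", seq_len(M)))
    ssGE <- r * sum(Z^2)
    axisSS <- r * lam^2
    if (ssGE > 0) {
        pct <- 100 * axisSS / ssGE
    } else {
        warning("interaction is exactly zero; axis percentages undefined, ",
                "reported as 0")
        pct <- rep(0, M)
    }
    new("AMMIDecomposition",
        grandMean = mean(y),
        genotypeEffects = rowMeans(y) - mean(y),
        environmentEffects = colMeans(y) - mean(y),
        singularValues = lam,
        genotypeScores = gs,
        environmentScores = es,
        axisSS = axisSS,
        axisDf = G + E - 1 - 2 * seq_len(M),
        axisPct = pct,
        interaction = Z,
        interactionSS = ssGE,
        replicates = as.integer(r))
}

#' Accessors for AMMIDecomposition objects
#'
#' @param x an [AMMIDecomposition-class]
#' @return `grandMean()`: the grand mean; `genotypeEffects()` /
#'   `environmentEffects()`: named zero-sum main effects;
#'   `singularValues()`: \eqn{\lambda_n} on the cell-means scale;
#'   `genotypeScores()` / `environmentScores()`: scaled IPCA score
#'   matrices; `axisSS()`: per-axis interaction SS (replicate-total
#'   scale); `axisDf()`: Gollob df; `axisPct()`: percent of interaction
#'   SS; `nAxes()`: the number of axes M.
#' @name AMMIDecomposition-accessors
#' @aliases grandMean genotypeEffects environmentEffects singularValues
#'   genotypeScores environmentScores axisSS axisDf axisPct nAxes
NULL

#' @rdname AMMIDecomposition-accessors
#' @export
setMethod("grandMean", "AMMIDecomposition", function(x) x@grandMean)

#' @rdname AMMIDecomposition-accessors
#' @export
setMethod("genotypeEffects", "AMMIDecomposition",
    function(x) x@genotypeEffects)

#' @rdname AMMIDecomposition-accessors
#' @export
setMethod("environmentEffects", "AMMIDecomposition",
    function(x) x@environmentEffects)

#' @rdname AMMIDecomposition-accessors
#' @export
setMethod("singularValues", "AMMIDecomposition",
    function(x) x@singularValues)

#' @rdname AMMIDecomposition-accessors
#' @export
setMethod("genotypeScores", "AMMIDecomposition", function(x) x@genotypeScores)

#' @rdname AMMIDecomposition-accessors
#' @export
setMethod("environmentScores", "AMMIDecomposition",
    function(x) x@environmentScores)

#' @rdname AMMIDecomposition-accessors
#' @export
setMethod("axisSS", "AMMIDecomposition", function(x) x@axisSS)

#' @rdname AMMIDecomposition-accessors
#' @export
setMethod("axisDf", "AMMIDecomposition", function(x) x@axisDf)

#' @rdname AMMIDecomposition-accessors
#' @export
setMethod("axisPct", "AMMIDecomposition", function(x) x@axisPct)

#' @rdname AMMIDecomposition-accessors
#' @export
setMethod("nAxes", "AMMIDecomposition",
    function(x) length(x@singularValues))

setMethod("show", "AMMIDecomposition", function(object) {
    M <- nAxes(object)
    cat(sprintf(
        "AMMIDecomposition: %d genotypes x %d environments, %d axes\n",
        length(object@genotypeEffects), length(object@environmentEffects),
        M))
    cat(sprintf("  grand mean %.3f, interaction SS %.1f (r = %d)\n",
                object@grandMean, object@interactionSS, object@replicates))
    k <- min(M, 3L)
    cat(sprintf("  IPCA1..%d: %s%% of interaction SS\n", k,
                paste(sprintf("%.2f", object@axisPct[seq_len(k)]),
                      collapse = ", ")))
    invisible(NULL)
})

#' Fitted cell means and interaction residual of a truncated AMMI model
#'
#' `ammiFitted()` reconstructs \eqn{\mu + \alpha_g + \beta_e} plus the
#' first `n` multiplicative terms; with `n = nAxes(x)` the reconstruction
#' equals the observed cell means to machine precision.
#' `interactionResidual()` returns the residual term of the interaction
#' (what the retained axes leave unexplained).
#'
#' @param x an [AMMIDecomposition-class]
#' @param n number of multiplicative axes retained
#' @return a G x E matrix
#' @export
ammiFitted <- function(x, n = nAxes(x)) {
    stopifnot(is(x, "AMMIDecomposition"), n >= 0, n <= nAxes(x))
    out <- outer(x@genotypeEffects, x@environmentEffects, `+`) + x@grandMean
    if (n > 0) {
        idx <- seq_len(n)
        out <- out + x@genotypeScores[, idx, drop = FALSE] %*%
            t(x@environmentScores[, idx, drop = FALSE])
    }
    out
}

#' @rdname ammiFitted
#' @export
interactionResidual <- function(x, n) {
    stopifnot(is(x, "AMMIDecomposition"), n >= 0, n <= nAxes(x))
    out <- x@interaction
    if (n > 0) {
        idx <- seq_len(n)
        out <- out - x@genotypeScores[, idx, drop = FALSE] %*%
            t(x@environmentScores[, idx, drop = FALSE])
    }
    out
}

#' Gollob F-tests for the interaction principal component axes
#'
#' Tests each retained multiplicative axis against the trial's pooled
#' error. Axis n carries Gollob degrees of freedom
#' \eqn{G + E - 1 - 2n} (the free parameters of a rank-n bilinear term);
#' its mean square is the axis SS over that df, and
#' \eqn{F_n = MS_n / MS_{error}} is referred to
#' \eqn{F(df_n, df_{error})}. A residual row collects the interaction SS
#' and df left by the retained axes.
#'
#' @param dec an [AMMIDecomposition-class]
#' @param errorMS pooled error mean square from the replicate-level ANOVA
#' @param errorDf its degrees of freedom
#' @param nRetain number of axes to test; default: all axes with
#'   Gollob p < 0.05 (at least one)
#' @return a data.frame with rows `IPCA1..n` and `Residuals`, columns
#'   `source`, `df`, `ss`, `ms`, `f`, `p`, `pct` (percent of
#'   interaction SS)
#' @examples
#' dec <- ammiDecompose(barleyTKW())
#' gollobAxisTests(dec, errorMS = 26.4, errorDf = 372, nRetain = 3)
#' @export
gollobAxisTests <- function(dec, errorMS, errorDf, nRetain = NULL) {
    stopifnot(is(dec, "AMMIDecomposition"), errorMS > 0, errorDf > 0)
    M <- nAxes(dec)
    df <- dec@axisDf
    ms <- dec@axisSS / df
    f <- ms / errorMS
    p <- pf(f, df, errorDf, lower.tail = FALSE)
    if (is.null(nRetain))
        nRetain <- max(1L, sum(p < 0.05))
    if (nRetain > M)
        stop(sprintf("cannot retain %d axes: only %d exist", nRetain, M))
    idx <- seq_len(nRetain)
    resSS <- dec@interactionSS - sum(dec@axisSS[idx])
    G <- length(dec@genotypeEffects); E <- length(dec@environmentEffects)
    resDf <- (G - 1) * (E - 1) - sum(df[idx])
    out <- data.frame(
        source = c(paste0("IPCA", idx), "Residuals"),
        df = c(df[idx], resDf),
        ss = c(dec@axisSS[idx], resSS),
        ms = c(ms[idx], if (resDf > 0) resSS / resDf else NA_real_),
        f = c(f[idx], if (resDf > 0) (resSS / resDf) / errorMS else NA_real_),
        p = c(p[idx], if (resDf > 0)
            pf((resSS / resDf) / errorMS, resDf, errorDf,
               lower.tail = FALSE) else NA_real_),
        pct = c(dec@axisPct[idx], if (dec@interactionSS > 0)
            100 * resSS / dec@interactionSS else 0),
        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Biplot coordinates for AMMI1 and AMMI2 displays
#'
#' AMMI1 plots the entity mean (genotype row mean / environment column
#' mean) against its IPCA1 score; AMMI2 plots IPCA1 against IPCA2.
#' Coordinates are returned as a plain table for any plotting layer; the
#' grand mean (the AMMI1 reference line) is attached as
#' `attr(out, "grandMean")`.
#'
#' @param dec an [AMMIDecomposition-class]
#' @param ge the [GEMatrix-class] the decomposition was fitted to
#' @param kind `"ammi1"` or `"ammi2"`
#' @return data.frame with columns `label`, `entity_type`
#'   (`"genotype"`/`"environment"`), `x`, `y`
#' @examples
#' ge <- barleyTKW()
#' head(biplotCoordinates(ammiDecompose(ge), ge, "ammi1"))
#' @export
biplotCoordinates <- function(dec, ge, kind = c("ammi2", "ammi1")) {
    kind <- match.arg(kind)
    stopifnot(is(dec, "AMMIDecomposition"), is(ge, "GEMatrix"))
    y <- geValues(ge)
    gs <- genotypeScores(dec); es <- environmentScores(dec)
    if (kind == "ammi2" && nAxes(dec) < 2L)
        stop("ammi2 biplot needs at least 2 axes")
    if (kind == "ammi1") {
        out <- data.frame(
            label = c(rownames(y), colnames(y)),
            entity_type = rep(c("genotype", "environment"),
                              c(nrow(y), ncol(y))),
            x = c(rowMeans(y), colMeans(y)),
            y = c(gs[, 1L], es[, 1L]),
            stringsAsFactors = FALSE)
    } else {
        out <- data.frame(
            label = c(rownames(y), colnames(y)),
            entity_type = rep(c("genotype", "environment"),
                              c(nrow(y), ncol(y))),
            x = c(gs[, 1L], es[, 1L]),
            y = c(gs[, 2L], es[, 2L]),
            stringsAsFactors = FALSE)
    }
    rownames(out) <- NULL
    attr(out, "grandMean") <- grandMean(dec)
    out
}
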