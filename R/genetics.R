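#' Extreme doubled-haploid lines by the quantile method
#'
#' The minimal (maximal) group collects the DH lines whose means lie at
#' or below (at or above) the `qLow` (`qHigh`) empirical quantile of the
#' line-mean distribution — in theory the lines carrying only
#' trait-decreasing (increasing) alleles. Quantiles use linear
#' interpolation of order statistics (`type = 7`, the common default).
#' The global argmin/argmax always satisfy their own threshold, so both
#' groups are nonempty by construction; overlapping groups (tiny
#' populations with extreme quantiles, or constant means) are a
#' configuration error.
#'
#' @param lineMeans named numeric vector of DH line means (parents
#'   excluded by the caller); needs >= 3 lines
#' @param qLow,qHigh quantile probabilities, 0 < qLow < qHigh < 1;
#'   defaults 0.03 and 0.97
#' @return an [ExtremeGroups-class]
#' @examples
#' ge <- barleyTKW()
#' m <- rowMeans(geValues(ge))[genotypeRole(ge) == "dh_line"]
#' extremeLines(m)
#' @export
extremeLines <- function(lineMeans, qLow = 0.03, qHigh = 0.97) {
    if (is.null(names(lineMeans)))
        stop("lineMeans must be named by genotype id")
    if (length(lineMeans) < 3L)
        stop("need at least 3 DH lines")
    if (!(qLow > 0 && qLow < qHigh && qHigh < 1))
        stop("configuration error: need 0 < qLow < qHigh < 1")
    lo <- quantile(lineMeans, qLow, names = FALSE, type = 7)
    hi <- quantile(lineMeans, qHigh, names = FALSE, type = 7)
    minimal <- names(lineMeans)[lineMeans <= lo]
    maximal <- names(lineMeans)[lineMeans >= hi]
    if (length(intersect(minimal, maximal))) {
        if (max(lineMeans) == min(lineMeans))
            stop("configuration error: line means are constant; ",
                 "extreme groups are degenerate")
        stop("configuration error: extreme groups overlap; ",
             "use less extreme quantiles for this population size")
    }
    new("ExtremeGroups", minimal = minimal, maximal = maximal,
        qLow = qLow, qHigh = qHigh)
}

#' @rdname extremeLines
#' @param x an [ExtremeGroups-class]
#' @export
setMethod("minimalLines", "ExtremeGroups", function(x) x@minimal)

#' @rdname extremeLines
#' @export
setMethod("maximalLines", "ExtremeGroups", function(x) x@maximal)

setMethod("show", "ExtremeGroups", function(object) {
    cat(sprintf("ExtremeGroups (q = %.2f/%.2f)\n  minimal: %s\n  maximal: %s\n",
                object@qLow, object@qHigh,
                paste(object@minimal, collapse = ", "),
                paste(object@maximal, collapse = ", ")))
    invisible(NULL)
})

#' Total additive, epistatic and parental gene effects
#'
#' For a doubled-haploid population the total additive effect of all
#' genes controlling the trait and the total additive-by-additive
#' (epistasis) effect are estimated from the extreme-line group means:
#' \deqn{\hat a_{DH} = \tfrac12(\bar L_{max} - \bar L_{min}), \qquad
#'   \hat{aa}_{DH} = \tfrac12(\bar L_{max} + \bar L_{min}) - \bar L,}
#' with \eqn{\bar L} the mean over all DH lines under analysis. The
#' parental additive effect is
#' \eqn{\hat a_{Parents} = \tfrac12(P_1 - P_2)} with \eqn{P_1} the
#' better-scoring parent (so the estimate is nonnegative). Both DH
#' estimators are invariant to adding a constant to all means and scale
#' linearly with the trait.
#'
#' @param groups an [ExtremeGroups-class]
#' @param lineMeans the named DH line means the groups were derived from
#' @return the effect estimate in trait units
#' @name gene-effects
#' @examples
#' m <- setNames(c(37.02, 45, 48, 52, 61.46), paste0("L", 1:5))
#' g <- extremeLines(m)
#' additiveEffectDH(g, m)    # (61.46 - 37.02)/2
#' epistasisEffectDH(g, m)
#' additiveEffectParents(54.13, 38.56)
NULL

#' @rdname gene-effects
#' @export
additiveEffectDH <- function(groups, lineMeans) {
    stopifnot(is(groups, "ExtremeGroups"))
    (mean(lineMeans[groups@maximal]) - mean(lineMeans[groups@minimal])) / 2
}

#' @rdname gene-effects
#' @export
epistasisEffectDH <- function(groups, lineMeans) {
    stopifnot(is(groups, "ExtremeGroups"))
    (mean(lineMeans[groups@maximal]) + mean(lineMeans[groups@minimal])) / 2 -
        mean(lineMeans)
}

#' @rdname gene-effects
#' @param p1Mean,p2Mean the two parent means (order immaterial)
#' @export
additiveEffectParents <- function(p1Mean, p2Mean) {
    abs(p1Mean - p2Mean) / 2
}

#' Genetic effect estimates across environments and line subsets
#'
#' Runs the quantile extreme-line analysis per context (each environment
#' plus the cross-environment mean of line means) and per line subset
#' (all DH lines, and each seed type when `seedType()` metadata is
#' present). Extreme groups are re-identified within each subset;
#' parents never enter any DH group. Parental additive effects use the
#' per-context better- and lower-scoring parent. When an error mean
#' square is supplied, each effect is tested as a single-df linear
#' contrast of line means (see [effectTests()]).
#'
#' @param ge a [GEMatrix-class] with `role` metadata (DH lines, and two
#'   parents if parental effects are wanted)
#' @param qLow,qHigh quantile probabilities for [extremeLines()]
#' @param errorMS,errorDf optional pooled error mean square and df from
#'   the replicate-level ANOVA of the same trial
#' @return a long data.frame with one row per context x subset x
#'   parameter: columns `context`, `subset`, `parameter` (`"a_parents"`,
#'   `"a_dh"`, `"aa_dh"`), `estimate`, `n_lines`, `n_min`, `n_max`,
#'   `L_min`, `L_max`, `L_mean`, plus `ms`, `f`, `p`, `stars` when an
#'   error term is given (and the contrast bookkeeping columns
#'   `coef_ss`, `n_obs`)
#' @examples
#' eff <- geneticEffects(barleyTKW())
#' subset(eff, parameter == "a_dh" & subset == "all")[, 1:4]
#' @export
geneticEffects <- function(ge, qLow = 0.03, qHigh = 0.97,
                           errorMS = NULL, errorDf = NULL) {
    stopifnot(is(ge, "GEMatrix"))
    role <- genotypeRole(ge)
    if (is.null(role))
        stop("geneticEffects needs genotype role metadata ",
             "(parent / dh_line)")
    y <- geValues(ge)
    r <- replicates(ge)
    E <- ncol(y)
    dh <- names(role)[role == "dh_line"]
    par <- names(role)[role == "parent"]
    if (length(dh) < 3L)
        stop("need at least 3 DH lines")
    if (length(par) > 2L)
        stop("at most two genotypes may carry role = 'parent'")
    st <- seedType(ge)
    subsets <- list(all = dh)
    if (!is.null(st)) {
        for (tp in setdiff(unique(st[dh]), "unknown"))
            if (sum(st[dh] == tp) >= 3L)
                subsets[[tp]] <- dh[st[dh] == tp]
    }
    contexts <- c(colnames(y), "Mean")
    ctxMeans <- cbind(y, Mean = rowMeans(y))
    rows <- list()
    for (ctx in contexts) {
        m <- ctxMeans[, ctx]
        nObs <- if (ctx == "Mean") r * E else r
        if (length(par) == 2L) {
            est <- additiveEffectParents(m[par[1L]], m[par[2L]])
            rows[[length(rows) + 1L]] <- data.frame(
                context = ctx, subset = "parents", parameter = "a_parents",
                estimate = est, n_lines = 2L, n_min = 1L, n_max = 1L,
                L_min = min(m[par]), L_max = max(m[par]),
                L_mean = mean(m[par]),
                coef_ss = 0.5, n_obs = nObs, stringsAsFactors = FALSE)
        }
        for (sub in names(subsets)) {
            lm0 <- m[subsets[[sub]]]
            gr <- extremeLines(lm0, qLow, qHigh)
            nmin <- length(gr@minimal); nmax <- length(gr@maximal)
            n <- length(lm0)
            Lmin <- mean(lm0[gr@minimal]); Lmax <- mean(lm0[gr@maximal])
            rows[[length(rows) + 1L]] <- data.frame(
                context = ctx, subset = sub, parameter = "a_dh",
                estimate = additiveEffectDH(gr, lm0),
                n_lines = n, n_min = nmin, n_max = nmax,
                L_min = Lmin, L_max = Lmax, L_mean = mean(lm0),
                coef_ss = 1 / (4 * nmax) + 1 / (4 * nmin),
                n_obs = nObs, stringsAsFactors = FALSE)
            aaCoefSS <- nmax * (1 / (2 * nmax) - 1 / n)^2 +
                nmin * (1 / (2 * nmin) - 1 / n)^2 +
                (n - nmax - nmin) / n^2
            rows[[length(rows) + 1L]] <- data.frame(
                context = ctx, subset = sub, parameter = "aa_dh",
                estimate = epistasisEffectDH(gr, lm0),
                n_lines = n, n_min = nmin, n_max = nmax,
                L_min = Lmin, L_max = Lmax, L_mean = mean(lm0),
                coef_ss = aaCoefSS, n_obs = nObs,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    if (!is.null(errorMS)) {
        out <- effectTests(out, errorMS, errorDf)
    } else {
        message("no error mean square supplied; effect estimates ",
                "returned without significance tests")
    }
    out
}

#' F-tests for quantile-method genetic effects
#'
#' Each effect is a single-degree-of-freedom linear contrast of line
#' means. With contrast coefficients c over means of `n_obs` plots each,
#' the contrast mean square is
#' \eqn{MS = \hat\theta^2 / (\sum c_i^2 / n_{obs})} and
#' \eqn{F = MS / MS_e} is referred to \eqn{F(1, df_e)}. Significance is
#' starred at 0.05 (*), 0.01 (**) and 0.001 (***). This contrast
#' construction is this package's interpretation of the mean squares
#' \eqn{MS_a}, \eqn{MS_{aa}} entering \eqn{F_a = MS_a/MS_e} and
#' \eqn{F_{aa} = MS_{aa}/MS_e}.
#'
#' @param effects the long data.frame from [geneticEffects()] (must
#'   carry the `coef_ss` and `n_obs` bookkeeping columns)
#' @param errorMS pooled error mean square of the replicate-level trial
#' @param errorDf its degrees of freedom
#' @return `effects` augmented with columns `ms`, `f`, `p`, `stars`
#' @export
effectTests <- function(effects, errorMS, errorDf) {
    stopifnot(all(c("estimate", "coef_ss", "n_obs") %in% colnames(effects)),
              errorMS > 0, errorDf > 0)
    effects$ms <- effects$estimate^2 / (effects$coef_ss / effects$n_obs)
    effects$f <- effects$ms / errorMS
    effects$p <- pf(effects$f, 1, errorDf, lower.tail = FALSE)
    effects$stars <- significanceStars(effects$p)
    effects
}

#' @keywords internal
significanceStars <- function(p) {
    ifelse(is.na(p), "",
        ifelse(p < 0.001, "***",
        ifelse(p < 0.01, "**",
        ifelse(p < 0.05, "*", ""))))
}

#' Pivot genetic effects to the conventional wide layout
#'
#' One row per parameter x subset, one column per context (environments
#' then the cross-environment mean), mirroring how multi-year genetic
#' effect tables are usually printed. With `stars = TRUE` and test
#' columns present, estimates are formatted with significance stars.
#'
#' @param effects long data.frame from [geneticEffects()]
#' @param digits rounding for the formatted layout
#' @param stars append significance stars when available
#' @return a data.frame, first columns `parameter` and `subset`
#' @export
geneticEffectsTable <- function(effects, digits = 2, stars = TRUE) {
    key <- unique(effects[, c("parameter", "subset")])
    contexts <- unique(effects$context)
    out <- key
    for (ctx in contexts) {
        col <- vapply(seq_len(nrow(key)), function(i) {
            row <- effects[effects$context == ctx &
                           effects$parameter == key$parameter[i] &
                           effects$subset == key$subset[i], , drop = FALSE]
            if (nrow(row) == 0L) return(NA_character_)
            v <- formatC(round(row$estimate, digits), format = "f",
                         digits = digits)
            if (stars && "stars" %in% colnames(row))
                v <- paste0(v, row$stars)
            v
        }, character(1L))
        out[[ctx]] <- col
    }
    rownames(out) <- NULL
    out
}
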