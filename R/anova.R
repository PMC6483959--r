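#' Two-way fixed-effects ANOVA from replicate-level records
#'
#' Partitions the total sum of squares of a complete balanced trial into
#' genotype, environment, interaction and pooled error strata, with F
#' tests of each effect against the error mean square. Requires r >= 2
#' replicates per cell; for means-only data use [anovaFromMeans()].
#'
#' @param rt a [ReplicateTable-class]
#' @return a data.frame with columns `source`, `df`, `ss`, `ms`, `f`,
#'   `p`, `pct` (percent of the total SS of the listed rows)
#' @examples
#' spec <- ammiSimSpec(G = 6, E = 4, r = 3, mu = 50, lambdas = 4,
#'                     errorSD = 2, seed = 11)
#' anovaTwoWay(simulateAMMITrial(spec))
#' @export
anovaTwoWay <- function(rt) {
    stopifnot(is(rt, "ReplicateTable"))
    rec <- as.data.frame(rt)
    rec$genotype <- factor(rec$genotype)
    rec$environment <- factor(rec$environment)
    n <- table(rec$genotype, rec$environment)
    if (any(n == 0L) || length(unique(as.vector(n))) != 1L)
        stop("anovaTwoWay needs a complete balanced table")
    if (n[1L, 1L] < 2L)
        stop("r = 1: no within-cell error; use anovaFromMeans() and ",
             "supply an external error mean square")
    a <- anova(lm(value ~ genotype * environment, data = rec))
    ss <- a$`Sum Sq`; df <- a$Df
    out <- data.frame(
        source = c("Genotypes", "Environments", "Interactions", "Error"),
        df = df, ss = ss, ms = ss / df,
        f = c(a$`F value`[1:3], NA_real_),
        p = c(a$`Pr(>F)`[1:3], NA_real_),
        pct = 100 * ss / sum(ss),
        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Two-way ANOVA strata from a table of cell means
#'
#' Main-effect and interaction sums of squares on the replicate-total
#' scale: \eqn{SS_G = rE\sum_g(\bar y_{g\cdot}-\bar y)^2},
#' \eqn{SS_E = rG\sum_e(\bar y_{\cdot e}-\bar y)^2},
#' \eqn{SS_{GE} = r\sum Z_{ge}^2} with Z the doubly-centred interaction.
#' When an externally obtained pooled error mean square is supplied
#' (e.g. from the original replicate-level analysis), F statistics and
#' p-values are added and an Error row is appended.
#'
#' @param ge a [GEMatrix-class] (its `replicates` supplies r)
#' @param errorMS optional pooled error mean square
#' @param errorDf its degrees of freedom (required with `errorMS`)
#' @return a data.frame as in [anovaTwoWay()]
#' @examples
#' anovaFromMeans(barleyTKW(), errorMS = 26.4, errorDf = 372)
#' @export
anovaFromMeans <- function(ge, errorMS = NULL, errorDf = NULL) {
    stopifnot(is(ge, "GEMatrix"))
    if (!is.null(errorMS) && is.null(errorDf))
        stop("errorDf must accompany errorMS")
    y <- geValues(ge)
    G <- nrow(y); E <- ncol(y); r <- replicates(ge)
    Z <- centerInteraction(ge)
    ss <- c(r * E * sum((rowMeans(y) - mean(y))^2),
            r * G * sum((colMeans(y) - mean(y))^2),
            r * sum(Z^2))
    df <- c(G - 1, E - 1, (G - 1) * (E - 1))
    out <- data.frame(
        source = c("Genotypes", "Environments", "Interactions"),
        df = df, ss = ss, ms = ss / df,
        f = NA_real_, p = NA_real_, pct = NA_real_,
        stringsAsFactors = FALSE)
    if (!is.null(errorMS)) {
        out$f <- out$ms / errorMS
        out$p <- pf(out$f, out$df, errorDf, lower.tail = FALSE)
        out <- rbind(out, data.frame(
            source = "Error", df = errorDf, ss = errorMS * errorDf,
            ms = errorMS, f = NA_real_, p = NA_real_, pct = NA_real_))
    }
    out$pct <- 100 * out$ss / sum(out$ss)
    rownames(out) <- NULL
    out
}
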