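#' Configure a full analysis run
#'
#' Validates the run configuration before any computation: exactly one
#' input source (a wide CSV of cell means, a long CSV of replicate
#' records, or the embedded barley trial), sane quantiles, a writable
#' output directory.
#'
#' @param input path to a wide or long CSV (layout sniffed from the
#'   header), or NULL when `fixture = TRUE`
#' @param fixture use the embedded barley 1000-kernel weight trial
#' @param analyses subset of `c("ammi", "stability", "genetics")`
#' @param qLow,qHigh quantile probabilities for the extreme-line method
#' @param nRetain axes to retain in the ANOVA table (NULL: Gollob
#'   p < 0.05 when an error term exists, else 2)
#' @param replicates replicate count behind wide-CSV means
#' @param errorMS,errorDf optional pooled error mean square and df (for
#'   means-only input; long input derives them from the data)
#' @param outDir output directory (created if missing)
#' @param seed RNG seed recorded in the run log
#' @param verbose print progress
#' @return a validated config (list)
#' @export
runConfig <- function(input = NULL, fixture = FALSE,
                      analyses = c("ammi", "stability", "genetics"),
                      qLow = 0.03, qHigh = 0.97, nRetain = NULL,
                      replicates = 1L, errorMS = NULL, errorDf = NULL,
                      outDir = ".", seed = 1L, verbose = FALSE) {
    if (is.null(input) == !fixture)
        stop("exactly one input source: give 'input' or set fixture = TRUE")
    analyses <- match.arg(analyses,
        c("ammi", "stability", "genetics"), several.ok = TRUE)
    if (!(qLow > 0 && qLow < qHigh && qHigh < 1))
        stop("config error: need 0 < qLow < qHigh < 1")
    if (!is.null(errorMS) && is.null(errorDf))
        stop("config error: errorDf must accompany errorMS")
    structure(list(input = input, fixture = fixture, analyses = analyses,
                   qLow = qLow, qHigh = qHigh, nRetain = nRetain,
                   replicates = as.integer(replicates),
                   errorMS = errorMS, errorDf = errorDf,
                   outDir = outDir, seed = as.integer(seed),
                   verbose = isTRUE(verbose)),
              class = "ammistab_config")
}

#' Run the analyses and write a report bundle
#'
#' Executes the selected analyses and writes, under `outDir`:
#' `anova.csv` (main effects, retained interaction axes, residual,
#' error when available), `stability.csv` (per-genotype mean, IPCA1/2,
#' ASV, ranks, GSI, sorted by GSI), `genetics.csv` (additive/epistatic
#' effect grid), `biplot_ammi1.csv` / `biplot_ammi2.csv`, and `run.log`
#' (package version, seed, config). Column orders are fixed, so two runs
#' with the same config and seed produce byte-identical CSVs.
#'
#' @param config from [runConfig()]
#' @return (invisibly) a list with the computed objects and the paths
#'   written
#' @examples
#' out <- runReport(runConfig(fixture = TRUE, outDir = tempfile()))
#' head(read.csv(out$paths["stability"]), 3)
#' @export
runReport <- function(config) {
    stopifnot(inherits(config, "ammistab_config"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    say <- function(...) if (config$verbose) message(...)
    set.seed(config$seed)
    errorMS <- config$errorMS; errorDf <- config$errorDf

    if (config$fixture) {
        ge <- barleyTKW()
        say("loaded embedded barley trial: 32 genotypes x 6 years")
    } else {
        hdr <- names(read.csv(config$input, nrows = 1L,
                              check.names = FALSE))
        if (all(c("genotype", "environment", "replicate", "value")
                %in% hdr)) {
            rt <- readLongCSV(config$input)
            ge <- aggregateReplicates(rt)
            av <- anovaTwoWay(rt)
            if (is.null(errorMS)) {
                errorMS <- av$ms[av$source == "Error"]
                errorDf <- av$df[av$source == "Error"]
            }
            say("long input aggregated: r = ", replicates(ge))
        } else {
            ge <- readWideCSV(config$input, replicates = config$replicates)
        }
    }

    res <- list(ge = ge)
    paths <- c()
    num <- function(x) {
        isn <- vapply(x, is.numeric, logical(1L))
        x[isn] <- lapply(x[isn], function(v) signif(v, 10))
        x
    }
    wr <- function(obj, file) {
        p <- file.path(config$outDir, file)
        write.csv(num(obj), p, row.names = FALSE, quote = FALSE, na = "")
        p
    }

    dec <- ammiDecompose(ge)
    res$decomposition <- dec

    if ("ammi" %in% config$analyses) {
        tab <- anovaFromMeans(ge, errorMS, errorDf)
        if (!is.null(errorMS)) {
            ax <- gollobAxisTests(dec, errorMS, errorDf,
                                  nRetain = config$nRetain)
        } else {
            nr <- if (is.null(config$nRetain)) min(2L, nAxes(dec))
                  else config$nRetain
            idx <- seq_len(nr)
            resSS <- dec@interactionSS - sum(axisSS(dec)[idx])
            resDf <- (nrow(ge) - 1L) * (ncol(ge) - 1L) -
                sum(axisDf(dec)[idx])
            ax <- data.frame(
                source = c(paste0("IPCA", idx), "Residuals"),
                df = c(axisDf(dec)[idx], resDf),
                ss = c(axisSS(dec)[idx], resSS),
                ms = c(axisSS(dec)[idx] / axisDf(dec)[idx],
                       if (resDf > 0) resSS / resDf else NA_real_),
                f = NA_real_, p = NA_real_,
                pct = c(axisPct(dec)[idx],
                        100 * resSS / max(dec@interactionSS, 1e-300)))
        }
        err <- tab$source == "Error"
        full <- rbind(tab[!err, ], ax, tab[err, ])
        full$stars <- significanceStars(full$p)
        res$anova <- full
        paths["anova"] <- wr(full, "anova.csv")
        say("anova.csv written")
    }

    if ("stability" %in% config$analyses) {
        st <- stabilityReport(dec, ge)
        res$stability <- st
        paths["stability"] <- wr(as.data.frame(st), "stability.csv")
        b1 <- biplotCoordinates(dec, ge, "ammi1")
        b2 <- biplotCoordinates(dec, ge, "ammi2")
        paths["biplot_ammi1"] <- wr(b1, "biplot_ammi1.csv")
        paths["biplot_ammi2"] <- wr(b2, "biplot_ammi2.csv")
        say("stability.csv and biplot coordinate files written")
    }

    if ("genetics" %in% config$analyses &&
        !is.null(genotypeRole(ge))) {
        eff <- suppressMessages(geneticEffects(
            ge, config$qLow, config$qHigh, errorMS, errorDf))
        res$genetics <- eff
        keep <- setdiff(colnames(eff), c("coef_ss", "n_obs"))
        paths["genetics"] <- wr(eff[, keep], "genetics.csv")
        paths["genetics_wide"] <- wr(geneticEffectsTable(eff),
                                     "genetics_wide.csv")
        say("genetics.csv written")
    } else if ("genetics" %in% config$analyses) {
        say("genetics skipped: no genotype role metadata in the input")
    }

    log <- c(sprintf("ammistab %s", as.character(packageVersion("ammistab"))),
             sprintf("seed: %d", config$seed),
             sprintf("input: %s",
                     if (config$fixture) "embedded barley trial"
                     else config$input),
             sprintf("analyses: %s", paste(config$analyses, collapse = ",")),
             sprintf("quantiles: %g/%g", config$qLow, config$qHigh),
             sprintf("replicates: %d", replicates(ge)),
             sprintf("error MS: %s  df: %s",
                     ifelse(is.null(errorMS), "none", format(errorMS)),
                     ifelse(is.null(errorDf), "none", format(errorDf))))
    writeLines(log, file.path(config$outDir, "run.log"))
    paths["log"] <- file.path(config$outDir, "run.log")
    res$paths <- paths
    invisible(res)
}
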