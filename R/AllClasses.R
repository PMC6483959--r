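#' @import methods
#' @importFrom stats anova lm pf quantile rnorm sd setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

#' GEMatrix: a balanced genotype-by-environment table of cell means
#'
#' `GEMatrix` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single assay `"means"` holding phenotype cell means (rows = genotypes,
#' columns = environments). Per-genotype metadata (breeding role, seed
#' type) lives in `rowData`; the number of field replicates behind each
#' cell mean is stored in `metadata(x)$replicates`.
#'
#' The design must be balanced and complete: no missing cells, all values
#' finite, at least 3 genotypes and 3 environments (the SVD of the
#' interaction needs a non-trivial doubly-centred matrix), and unique
#' row/column labels.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment]
#' @seealso [GEMatrix()] the constructor, [geValues()], [replicates()]
#' @export
setClass("GEMatrix", contains = "SummarizedExperiment")

setValidity("GEMatrix", function(object) {
    msg <- character(0)
    if (length(SummarizedExperiment::assayNames(object)) != 1L ||
        SummarizedExperiment::assayNames(object)[1L] != "means")
        msg <- c(msg, "GEMatrix must carry exactly one assay named 'means'")
    v <- SummarizedExperiment::assay(object, withDimnames = TRUE)
    if (!is.numeric(v))
        msg <- c(msg, "assay 'means' must be numeric")
    if (nrow(v) < 3L || ncol(v) < 3L)
        msg <- c(msg, "need at least 3 genotypes and 3 environments")
    if (anyNA(v) || any(!is.finite(v))) {
        bad <- which(is.na(v) | !is.finite(v), arr.ind = TRUE)[1L, ]
        msg <- c(msg, sprintf(
            "balanced design required: cell (%s, %s) is missing or non-finite",
            rownames(v)[bad[1L]], colnames(v)[bad[2L]]))
    }
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
        msg <- c(msg, "genotype labels must be present and unique")
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
        msg <- c(msg, "environment labels must be present and unique")
    r <- S4Vectors::metadata(object)$replicates
    if (is.null(r) || length(r) != 1L || is.na(r) || r < 1 || r != round(r))
        msg <- c(msg, "metadata(x)$replicates must be a single positive integer")
    rd <- SummarizedExperiment::rowData(object)
    if ("role" %in% colnames(rd)) {
        ok <- c("parent", "dh_line")
        if (!all(rd$role %in% ok))
            msg <- c(msg, "role must be 'parent' or 'dh_line'")
    }
    if ("seed_type" %in% colnames(rd)) {
        ok <- c("hulled", "hull_less", "unknown")
        if (!all(rd$seed_type %in% ok))
            msg <- c(msg, "seed_type must be 'hulled', 'hull_less' or 'unknown'")
    }
    if (length(msg)) msg else TRUE
})

#' ReplicateTable: replicate-level records of a two-way trial
#'
#' Long-format individual-plot records `(genotype, environment, replicate,
#' value)`. Duplicate `(genotype, environment, replicate)` triples are
#' rejected; balance is only enforced when aggregating to a [GEMatrix]
#' with [aggregateReplicates()].
#'
#' @slot records a `data.frame` with columns `genotype`, `environment`,
#'   `replicate` (integer index within cell) and `value`.
#' @seealso [ReplicateTable()], [aggregateReplicates()], [readLongCSV()]
#' @export
setClass("ReplicateTable", representation(records = "data.frame"))

setValidity("ReplicateTable", function(object) {
    rec <- object@records
    need <- c("genotype", "environment", "replicate", "value")
    if (!all(need %in% colnames(rec)))
        return(paste("records must have columns:", paste(need, collapse = ", ")))
    if (nrow(rec) == 0L)
        return("empty input: no replicate records")
    if (!is.numeric(rec$value))
        return("value column must be numeric")
    key <- paste(rec$genotype, rec$environment, rec$replicate, sep = "\r")
    if (anyDuplicated(key)) {
        d <- rec[which(duplicated(key))[1L], ]
        return(sprintf("duplicate record for (%s, %s, replicate %s)",
                       d$genotype, d$environment, d$replicate))
    }
    TRUE
})

#' AMMIDecomposition: SVD decomposition of the GE interaction
#'
#' Holds the fitted additive-plus-multiplicative model
#' \deqn{y_{ge} = \mu + \alpha_g + \beta_e + \sum_{n=1}^{M}
#'   \lambda_n \gamma_{gn} \delta_{en} + Q_{ge}}
#' for a balanced genotype-by-environment table of cell means. The
#' doubly-centred interaction matrix is decomposed by SVD;
#' genotype/environment scores are symmetrically scaled by
#' \eqn{\sqrt{\lambda_n}} so that each side's per-axis sum of squares
#' equals \eqn{\lambda_n}. Axis sums of squares are on the
#' replicate-total scale, \eqn{r\lambda_n^2}.
#'
#' @slot grandMean grand mean \eqn{\mu} of the cell means
#' @slot genotypeEffects named genotype main effects \eqn{\alpha_g} (sum 0)
#' @slot environmentEffects named environment main effects \eqn{\beta_e} (sum 0)
#' @slot singularValues singular values \eqn{\lambda_n} of the centred
#'   matrix (cell-means scale), \eqn{n = 1..M}, \eqn{M = \min(G-1, E-1)}
#' @slot genotypeScores G x M matrix of scaled genotype IPCA scores
#' @slot environmentScores E x M matrix of scaled environment IPCA scores
#' @slot axisSS per-axis interaction sum of squares, \eqn{r\lambda_n^2}
#' @slot axisDf Gollob degrees of freedom per axis, \eqn{G + E - 1 - 2n}
#' @slot axisPct percent of the interaction SS captured by each axis
#' @slot interaction the doubly-centred interaction matrix
#' @slot interactionSS total interaction SS on the replicate-total scale
#' @slot replicates replicate count r behind each cell mean
#' @seealso [ammiDecompose()]
#' @export
setClass("AMMIDecomposition", representation(
    grandMean = "numeric",
    genotypeEffects = "numeric",
    environmentEffects = "numeric",
    singularValues = "numeric",
    genotypeScores = "matrix",
    environmentScores = "matrix",
    axisSS = "numeric",
    axisDf = "numeric",
    axisPct = "numeric",
    interaction = "matrix",
    interactionSS = "numeric",
    replicates = "integer"))

setValidity("AMMIDecomposition", function(object) {
    M <- length(object@singularValues)
    if (ncol(object@genotypeScores) != M || ncol(object@environmentScores) != M)
        return("score matrices must have one column per singular value")
    if (any(object@singularValues < -1e-8))
        return("singular values must be nonnegative")
    if (is.unsorted(-object@singularValues))
        return("axes must be ordered by decreasing singular value")
    if (abs(sum(object@genotypeEffects)) > 1e-6 ||
        abs(sum(object@environmentEffects)) > 1e-6)
        return("main effects must sum to zero")
    TRUE
})

#' ExtremeGroups: minimal and maximal DH lines by the quantile method
#'
#' Identifies the doubled-haploid lines whose means fall at or below the
#' `qLow` empirical quantile (minimal group: carrying, in theory, only
#' trait-decreasing alleles) and at or above the `qHigh` quantile
#' (maximal group).
#'
#' @slot minimal genotype ids of the minimal group
#' @slot maximal genotype ids of the maximal group
#' @slot qLow,qHigh the quantile probabilities used
#' @seealso [extremeLines()]
#' @export
setClass("ExtremeGroups", representation(
    minimal = "character", maximal = "character",
    qLow = "numeric", qHigh = "numeric"))

setValidity("ExtremeGroups", function(object) {
    if (length(object@minimal) == 0L || length(object@maximal) == 0L)
        return("both extreme groups must be nonempty")
    if (length(intersect(object@minimal, object@maximal)))
        return("extreme groups overlap; choose less extreme quantiles")
    TRUE
})

#' AMMISimSpec: specification of a simulated balanced AMMI trial
#'
#' @slot G,E,r design sizes: genotypes, environments, replicates per cell
#' @slot mu grand mean
#' @slot genotypeEffects,environmentEffects zero-sum main effect vectors;
#'   length 0 means "draw from N(0, sd^2) then centre"
#' @slot genotypeSD,environmentSD sd of drawn main effects
#' @slot lambdas singular values of the K planted interaction terms
#' @slot genotypeVectors,environmentVectors optional orthonormal,
#'   zero-sum score vectors (columns); random orthonormal if 0-column
#' @slot errorSD plot-level error standard deviation
#' @slot seed RNG seed; identical spec + seed gives identical output
#' @seealso [ammiSimSpec()], [simulateAMMITrial()]
#' @export
setClass("AMMISimSpec", representation(
    G = "integer", E = "integer", r = "integer",
    mu = "numeric",
    genotypeEffects = "numeric", environmentEffects = "numeric",
    genotypeSD = "numeric", environmentSD = "numeric",
    lambdas = "numeric",
    genotypeVectors = "matrix", environmentVectors = "matrix",
    errorSD = "numeric", seed = "integer"))

setValidity("AMMISimSpec", function(object) {
    K <- length(object@lambdas)
    if (K > min(object@G - 1L, object@E - 1L))
        return("number of interaction terms K must be <= min(G-1, E-1)")
    if (object@errorSD < 0) return("errorSD must be >= 0")
    if (any(object@lambdas < 0)) return("lambdas must be nonnegative")
    chk <- function(V, n, what) {
        if (ncol(V) == 0L) return(NULL)
        if (nrow(V) != n || ncol(V) != K)
            return(sprintf("%s must be %d x %d", what, n, K))
        Q <- crossprod(V)
        if (max(abs(Q - diag(ncol(V)))) > 1e-8)
            return(sprintf("%s columns must be orthonormal", what))
        if (max(abs(colSums(V))) > 1e-8)
            return(sprintf("%s columns must sum to zero", what))
        NULL
    }
    m <- c(chk(object@genotypeVectors, object@G, "genotypeVectors"),
           chk(object@environmentVectors, object@E, "environmentVectors"))
    if (length(object@genotypeEffects) &&
        abs(sum(object@genotypeEffects)) > 1e-8)
        m <- c(m, "genotypeEffects must sum to zero")
    if (length(object@environmentEffects) &&
        abs(sum(object@environmentEffects)) > 1e-8)
        m <- c(m, "environmentEffects must sum to zero")
    if (length(m)) m else TRUE
})

#' DHSimSpec: specification of a simulated doubled-haploid population
#'
#' Each line carries one of two fully homozygous allele codes (-1/+1) at
#' every locus; genotypic values are additive across loci plus optional
#' additive-by-additive (epistatic) terms for chosen locus pairs.
#'
#' @slot nLines,nLoci population and genome sizes
#' @slot additive per-locus additive effect (length nLoci)
#' @slot epistasis data.frame (locus1, locus2, effect) of interacting pairs
#' @slot base baseline genotypic value
#' @slot E,r environments and replicates for the phenotype records
#' @slot environmentSD sd of drawn (centred) environment effects
#' @slot errorSD plot-level error sd
#' @slot forceExtremes if TRUE the all-plus and all-minus lines are
#'   planted into the sample (the extreme-line estimators assume the
#'   fully decreasing/increasing allele combinations exist)
#' @slot seed RNG seed
#' @seealso [dhSimSpec()], [simulateDHPopulation()]
#' @export
setClass("DHSimSpec", representation(
    nLines = "integer", nLoci = "integer",
    additive = "numeric", epistasis = "data.frame", base = "numeric",
    E = "integer", r = "integer",
    environmentSD = "numeric", errorSD = "numeric",
    forceExtremes = "logical", seed = "integer"))

setValidity("DHSimSpec", function(object) {
    if (object@nLoci < 1L) return("nLoci must be >= 1")
    if (object@nLines < 3L) return("nLines must be >= 3")
    if (length(object@additive) != object@nLoci)
        return("additive must have one effect per locus")
    ep <- object@epistasis
    if (nrow(ep)) {
        if (!all(c("locus1", "locus2", "effect") %in% colnames(ep)))
            return("epistasis needs columns locus1, locus2, effect")
        if (any(ep$locus1 == ep$locus2) ||
            any(ep$locus1 > object@nLoci) || any(ep$locus2 > object@nLoci))
            return("epistasis pairs must index distinct existing loci")
    }
    if (object@errorSD < 0 || object@environmentSD < 0)
        return("standard deviations must be >= 0")
    TRUE
})
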