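#' Construct a GEMatrix from a matrix of cell means
#'
#' @param values numeric matrix of phenotype cell means, rows = genotypes,
#'   columns = environments; dimnames are used as labels (generated as
#'   `G1..`/`E1..` when absent).
#' @param replicates positive integer: number of field replicates behind
#'   each cell mean (1 when unknown). All ANOVA sums of squares are
#'   reported on the replicate-total scale, i.e. means-scale SS times
#'   `replicates`.
#' @param role optional character vector (length G) of genotype roles,
#'   `"parent"` or `"dh_line"`.
#' @param seedType optional character vector (length G), `"hulled"`,
#'   `"hull_less"` or `"unknown"`.
#' @return a validated [GEMatrix-class] object
#' @examples
#' ge <- GEMatrix(matrix(rnorm(12, 50), 4, 3), replicates = 3)
#' geValues(ge)
#' @export
GEMatrix <- function(values, replicates = 1L, role = NULL, seedType = NULL) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(rownames(values)))
        rownames(values) <- paste0("G", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- paste0("E", seq_len(ncol(values)))
    rd <- S4Vectors::DataFrame(row.names = rownames(values))
    if (!is.null(role)) rd$role <- as.character(role)
    if (!is.null(seedType)) rd$seed_type <- as.character(seedType)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(means = values), rowData = rd,
        metadata = list(replicates = as.integer(replicates)))
    new("GEMatrix", se)
}

#' Accessors for GEMatrix objects
#'
#' `geValues()` returns the genotype-by-environment matrix of cell means;
#' `genotypeIds()`/`environmentIds()` the ordered labels; `replicates()`
#' the replicate count r behind each mean; `genotypeRole()` and
#' `seedType()` the per-genotype metadata (or NULL when absent).
#'
#' @param x a [GEMatrix-class]
#' @return see above
#' @name GEMatrix-accessors
#' @aliases geValues genotypeIds environmentIds replicates genotypeRole
#'   seedType
#' @examples
#' ge <- barleyTKW()
#' replicates(ge)
#' table(genotypeRole(ge), seedType(ge))
NULL

#' @rdname GEMatrix-accessors
#' @export
setMethod("geValues", "GEMatrix", function(x)
    SummarizedExperiment::assay(x, "means"))

#' @rdname GEMatrix-accessors
#' @export
setMethod("genotypeIds", "GEMatrix", function(x) rownames(x))

#' @rdname GEMatrix-accessors
#' @export
setMethod("environmentIds", "GEMatrix", function(x) colnames(x))

#' @rdname GEMatrix-accessors
#' @export
setMethod("replicates", "GEMatrix", function(x)
    S4Vectors::metadata(x)$replicates)

#' @rdname GEMatrix-accessors
#' @export
setMethod("genotypeRole", "GEMatrix", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if ("role" %in% colnames(rd)) setNames(rd$role, rownames(x)) else NULL
})

#' @rdname GEMatrix-accessors
#' @export
setMethod("seedType", "GEMatrix", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if ("seed_type" %in% colnames(rd))
        setNames(rd$seed_type, rownames(x)) else NULL
})

setMethod("show", "GEMatrix", function(object) {
    v <- geValues(object)
    cat(sprintf("GEMatrix: %d genotypes x %d environments (r = %d)\n",
                nrow(v), ncol(v), replicates(object)))
    cat(sprintf("  grand mean %.3f, range [%.2f, %.2f]\n",
                mean(v), min(v), max(v)))
    role <- genotypeRole(object)
    if (!is.null(role))
        cat(sprintf("  roles: %s\n",
            paste(sprintf("%s=%d", names(table(role)), table(role)),
                  collapse = ", ")))
    invisible(NULL)
})

#' Export a GEMatrix as JSON
#'
#' Writes the cell means with explicit genotype and environment ordering,
#' the replicate count and any genotype metadata.
#'
#' @param ge a [GEMatrix-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeGEMatrixJSON <- function(ge, path) {
    v <- geValues(ge)
    obj <- list(
        genotype_ids = rownames(v),
        environment_ids = colnames(v),
        replicates = replicates(ge),
        values = unname(split(v, row(v)))[order(unique(row(v)))])
    obj$values <- lapply(seq_len(nrow(v)), function(i) unname(v[i, ]))
    role <- genotypeRole(ge)
    if (!is.null(role)) obj$role <- unname(role)
    st <- seedType(ge)
    if (!is.null(st)) obj$seed_type <- unname(st)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' The embedded spring barley 1000-kernel weight trial
#'
#' A six-year multi-environment trial of 32 spring barley genotypes (two
#' parents — breeding line 1N86 and DH line RK63/1 — and 30 doubled-haploid
#' lines derived from their F1 hybrids) grown at one South Poland location
#' in 2008-2013 in a randomized complete block design with three
#' replicates. Cells are yearly 1000-kernel weight means in grams, as
#' published (two decimals). Environments are year labels; the replicate
#' count is 3.
#'
#' @return a [GEMatrix-class] with `role` and `seed_type` genotype
#'   metadata
#' @examples
#' ge <- barleyTKW()
#' round(mean(geValues(ge)), 2)   # grand mean, g
#' @export
barleyTKW <- function() {
    path <- system.file("extdata", "barley_tkw_means.csv",
                        package = "ammistab", mustWork = TRUE)
    d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    v <- as.matrix(d[, -(1:3)])
    rownames(v) <- d$genotype
    GEMatrix(v, replicates = 3L, role = d$role, seedType = d$seed_type)
}
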