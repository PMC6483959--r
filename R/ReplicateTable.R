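#' Construct a ReplicateTable from replicate-level records
#'
#' @param records data.frame with columns `genotype`, `environment`,
#'   `replicate`, `value`
#' @return a validated [ReplicateTable-class]
#' @export
ReplicateTable <- function(records) {
    records <- as.data.frame(records)
    if (nrow(records) == 0L)
        stop("empty input: no replicate records")
    records$genotype <- as.character(records$genotype)
    records$environment <- as.character(records$environment)
    records$replicate <- as.integer(records$replicate)
    new("ReplicateTable", records = records)
}

#' @describeIn ReplicateTable the raw records
#' @param x,row.names,optional,... see [base::as.data.frame]
#' @export
setMethod("as.data.frame", "ReplicateTable",
    function(x, row.names = NULL, optional = FALSE, ...) x@records)

setMethod("show", "ReplicateTable", function(object) {
    rec <- object@records
    cat(sprintf(
        "ReplicateTable: %d records, %d genotypes x %d environments\n",
        nrow(rec), length(unique(rec$genotype)),
        length(unique(rec$environment))))
    invisible(NULL)
})

#' Aggregate replicate records to a GEMatrix of cell means
#'
#' Requires a complete balanced table: every (genotype, environment) cell
#' present with the same number r of replicates. The resulting
#' [GEMatrix-class] carries that r, so downstream ANOVA sums of squares
#' are on the replicate-total scale.
#'
#' @param x a [ReplicateTable-class]
#' @param ... unused
#' @return a [GEMatrix-class]
#' @examples
#' spec <- ammiSimSpec(G = 5, E = 4, r = 3, mu = 50, seed = 7)
#' ge <- aggregateReplicates(simulateAMMITrial(spec))
#' @rdname aggregateReplicates
#' @export
setMethod("aggregateReplicates", "ReplicateTable", function(x, ...) {
    rec <- x@records
    g <- factor(rec$genotype, levels = unique(rec$genotype))
    e <- factor(rec$environment, levels = unique(rec$environment))
    n <- table(g, e)
    if (any(n == 0L)) {
        bad <- which(n == 0L, arr.ind = TRUE)[1L, ]
        stop(sprintf(
            "balanced design required: no records for cell (%s, %s)",
            levels(g)[bad[1L]], levels(e)[bad[2L]]))
    }
    if (length(unique(as.vector(n))) != 1L)
        stop("unbalanced design: cells have unequal replicate counts (",
             paste(range(n), collapse = "-"), ")")
    m <- tapply(rec$value, list(g, e), mean)
    GEMatrix(m, replicates = as.integer(n[1L, 1L]))
})

#' Read/write genotype-by-environment data as CSV
#'
#' `readWideCSV()` reads a wide table (first column genotype labels,
#' remaining columns one per environment, cells = means) into a
#' [GEMatrix-class]. `readLongCSV()` reads replicate-level records with
#' columns `genotype`, `environment`, `replicate`, `value` into a
#' [ReplicateTable-class]. `writeWideCSV()` / `writeLongCSV()` are the
#' lossless inverses.
#'
#' @param path CSV file path (RFC-4180, UTF-8, '.' decimal separator)
#' @param replicates replicate count behind the wide-table means
#'   (1 when unknown)
#' @return a [GEMatrix-class] or [ReplicateTable-class]
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeWideCSV(barleyTKW(), f)
#' ge <- readWideCSV(f, replicates = 3)
#' @name ge-io
NULL

#' @rdname ge-io
#' @export
readWideCSV <- function(path, replicates = 1L) {
    d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(d) < 2L)
        stop("wide CSV needs a genotype column plus environment columns")
    for (j in 2:ncol(d)) {
        col <- d[[j]]
        if (is.character(col)) {
            num <- suppressWarnings(as.numeric(col))
            if (anyNA(num) && !anyNA(col)) {
                i <- which(is.na(num))[1L]
                stop(sprintf(
                    "non-numeric cell at row %d (genotype %s), column '%s'",
                    i, d[[1L]][i], colnames(d)[j]))
            }
            d[[j]] <- num
        }
    }
    v <- as.matrix(d[, -1L, drop = FALSE])
    rownames(v) <- as.character(d[[1L]])
    if (anyNA(v)) {
        bad <- which(is.na(v), arr.ind = TRUE)[1L, ]
        stop(sprintf(
            "balanced design required: cell (%s, %s) is empty",
            rownames(v)[bad[1L]], colnames(v)[bad[2L]]))
    }
    GEMatrix(v, replicates = replicates)
}

#' @rdname ge-io
#' @param ge a [GEMatrix-class] to write
#' @export
writeWideCSV <- function(ge, path) {
    v <- geValues(ge)
    d <- data.frame(genotype = rownames(v), check.names = FALSE)
    d[colnames(v)] <- as.data.frame(v, check.names = FALSE)
    write.csv(d, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname ge-io
#' @export
readLongCSV <- function(path) {
    d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(d) == 0L)
        stop("empty input: no replicate records in ", path)
    need <- c("genotype", "environment", "replicate", "value")
    if (!all(need %in% colnames(d)))
        stop("long CSV needs columns: ", paste(need, collapse = ", "))
    ReplicateTable(d[, need])
}

#' @rdname ge-io
#' @param rt a [ReplicateTable-class] to write
#' @export
writeLongCSV <- function(rt, path) {
    write.csv(as.data.frame(rt), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
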