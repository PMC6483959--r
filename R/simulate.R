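#' Specify a simulated balanced AMMI trial
#'
#' Builds a validated [AMMISimSpec-class]. Main-effect vectors may be
#' given explicitly (they are centred to sum to zero) or drawn from
#' centred normal distributions at simulation time. Interaction score
#' vectors, when not supplied, are random orthonormal vectors
#' orthogonal to the all-ones vector, so the simulated cell means
#' satisfy the double-centring identities of the AMMI model exactly.
#'
#' @param G,E,r genotypes, environments, replicates per cell
#' @param mu grand mean
#' @param genotypeEffects,environmentEffects optional main effect
#'   vectors (centred); when NULL drawn from N(0, sd^2) then centred
#' @param genotypeSD,environmentSD sd of drawn main effects
#' @param lambdas singular values of the planted interaction terms
#'   (K = length(lambdas) <= min(G-1, E-1))
#' @param genotypeVectors,environmentVectors optional G x K / E x K
#'   orthonormal zero-sum score matrices
#' @param errorSD plot-level error sd
#' @param seed RNG seed
#' @return an [AMMISimSpec-class]
#' @export
ammiSimSpec <- function(G, E, r, mu = 0,
                        genotypeEffects = NULL, environmentEffects = NULL,
                        genotypeSD = 1, environmentSD = 1,
                        lambdas = numeric(0),
                        genotypeVectors = NULL, environmentVectors = NULL,
                        errorSD = 1, seed = 1L) {
    centre <- function(v) if (is.null(v)) numeric(0) else v - mean(v)
    asmat <- function(m, n) {
        if (is.null(m)) return(matrix(numeric(0), n, 0))
        as.matrix(m)
    }
    new("AMMISimSpec",
        G = as.integer(G), E = as.integer(E), r = as.integer(r),
        mu = as.numeric(mu),
        genotypeEffects = centre(genotypeEffects),
        environmentEffects = centre(environmentEffects),
        genotypeSD = genotypeSD, environmentSD = environmentSD,
        lambdas = as.numeric(lambdas),
        genotypeVectors = asmat(genotypeVectors, G),
        environmentVectors = asmat(environmentVectors, E),
        errorSD = errorSD, seed = as.integer(seed))
}

# Gram-Schmidt: k random unit vectors orthogonal to 1 and to each other
randomCentredOrthonormal <- function(n, k) {
    if (k == 0L) return(matrix(numeric(0), n, 0))
    basis <- matrix(1 / sqrt(n), n, 1)
    out <- matrix(NA_real_, n, k)
    for (j in seq_len(k)) {
        repeat {
            v <- rnorm(n)
            v <- v - basis %*% crossprod(basis, v)
            nv <- sqrt(sum(v^2))
            if (nv > 1e-8) break
        }
        out[, j] <- v / nv
        basis <- cbind(basis, out[, j])
    }
    out
}

#' Simulate a balanced two-way trial from the AMMI model
#'
#' Generates plot values
#' \eqn{y_{ger} = \mu + \alpha_g + \beta_e +
#'   \sum_k \lambda_k \gamma_{gk} \delta_{ek} + \varepsilon_{ger}},
#' \eqn{\varepsilon \sim N(0, \sigma^2)} i.i.d. Reproducible: the same
#' spec and seed yield an identical table.
#'
#' @param spec an [AMMISimSpec-class]
#' @return a [ReplicateTable-class]; the true cell-mean matrix is
#'   attached as `attr(x, "trueMeans")` and the drawn effects as
#'   `attr(x, "truth")`
#' @examples
#' rt <- simulateAMMITrial(ammiSimSpec(G = 8, E = 5, r = 3, mu = 50,
#'                                     lambdas = c(10, 5), seed = 42))
#' aggregateReplicates(rt)
#' @export
simulateAMMITrial <- function(spec) {
    stopifnot(is(spec, "AMMISimSpec"))
    validObject(spec)
    set.seed(spec@seed)
    G <- spec@G; E <- spec@E; r <- spec@r
    K <- length(spec@lambdas)
    a <- spec@genotypeEffects
    if (!length(a)) { a <- rnorm(G, sd = spec@genotypeSD); a <- a - mean(a) }
    b <- spec@environmentEffects
    if (!length(b)) { b <- rnorm(E, sd = spec@environmentSD); b <- b - mean(b) }
    U <- spec@genotypeVectors
    if (ncol(U) == 0L && K > 0L) U <- randomCentredOrthonormal(G, K)
    V <- spec@environmentVectors
    if (ncol(V) == 0L && K > 0L) V <- randomCentredOrthonormal(E, K)
    mu <- outer(a, b, `+`) + spec@mu
    if (K > 0L)
        mu <- mu + U %*% (spec@lambdas * t(V))
    gid <- sprintf("G%02d", seq_len(G))
    eid <- sprintf("E%d", seq_len(E))
    rec <- expand.grid(replicate = seq_len(r), genotype = gid,
                       environment = eid, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
    cellMean <- mu[cbind(match(rec$genotype, gid),
                         match(rec$environment, eid))]
    rec$value <- cellMean + rnorm(nrow(rec), sd = spec@errorSD)
    out <- ReplicateTable(rec[, c("genotype", "environment",
                                  "replicate", "value")])
    dimnames(mu) <- list(gid, eid)
    attr(out, "trueMeans") <- mu
    attr(out, "truth") <- list(mu = spec@mu, genotypeEffects = a,
                               environmentEffects = b,
                               lambdas = spec@lambdas,
                               genotypeVectors = U, environmentVectors = V)
    out
}

#' Specify a simulated doubled-haploid population
#'
#' @param nLines number of DH lines
#' @param nLoci number of biallelic loci (allele codes -1/+1, fully
#'   homozygous)
#' @param additive per-locus additive effect; a scalar is recycled
#' @param epistasis optional data.frame (`locus1`, `locus2`, `effect`)
#'   of additive-by-additive interacting pairs
#' @param base baseline genotypic value
#' @param E,r environments and replicates for the phenotype records
#' @param environmentSD sd of drawn centred environment effects
#' @param errorSD plot-level error sd
#' @param forceExtremes plant the all-plus and all-minus allele lines
#'   into the sample (as lines 1 and 2); the extreme-line estimators
#'   assume such lines exist
#' @param seed RNG seed
#' @return a [DHSimSpec-class]
#' @export
dhSimSpec <- function(nLines, nLoci, additive = 1, epistasis = NULL,
                      base = 0, E = 1L, r = 1L, environmentSD = 0,
                      errorSD = 0, forceExtremes = TRUE, seed = 1L) {
    if (is.null(epistasis))
        epistasis <- data.frame(locus1 = integer(0), locus2 = integer(0),
                                effect = numeric(0))
    new("DHSimSpec",
        nLines = as.integer(nLines), nLoci = as.integer(nLoci),
        additive = rep_len(as.numeric(additive), nLoci),
        epistasis = epistasis, base = as.numeric(base),
        E = as.integer(E), r = as.integer(r),
        environmentSD = environmentSD, errorSD = errorSD,
        forceExtremes = forceExtremes, seed = as.integer(seed))
}

#' Simulate a doubled-haploid population with planted gene effects
#'
#' Draws fully homozygous allele vectors \eqn{x \in \{-1,+1\}^{nLoci}}
#' per line; the genotypic value is
#' \eqn{base + \sum_l x_l a_l + \sum_{l<m} x_l x_m\, aa_{lm}}. For the
#' all-plus versus all-minus lines (planted when `forceExtremes`), half
#' their genotypic difference equals \eqn{\sum_l |a_l|}, the theoretical
#' total additive effect the extreme-line estimator targets. Phenotype
#' records add centred environment effects and i.i.d. normal error.
#'
#' @param spec a [DHSimSpec-class]
#' @return a list: `values` (named genotypic values), `alleles`
#'   (lines x loci matrix), `table` (a [ReplicateTable-class]), and
#'   `theoreticalAdditive` (\eqn{\sum_l |a_l|})
#' @examples
#' sim <- simulateDHPopulation(dhSimSpec(nLines = 20, nLoci = 4,
#'                                       additive = 2, seed = 3))
#' sim$theoreticalAdditive
#' @export
simulateDHPopulation <- function(spec) {
    stopifnot(is(spec, "DHSimSpec"))
    validObject(spec)
    set.seed(spec@seed)
    n <- spec@nLines; L <- spec@nLoci
    X <- matrix(sample(c(-1, 1), n * L, replace = TRUE), n, L)
    if (spec@forceExtremes) {
        X[1L, ] <- sign(spec@additive)      # all trait-increasing alleles
        X[2L, ] <- -sign(spec@additive)
        X[1L, spec@additive == 0] <- 1
        X[2L, spec@additive == 0] <- -1
    }
    ids <- sprintf("DH%03d", seq_len(n))
    dimnames(X) <- list(ids, sprintf("L%d", seq_len(L)))
    g <- spec@base + drop(X %*% spec@additive)
    ep <- spec@epistasis
    for (i in seq_len(nrow(ep)))
        g <- g + X[, ep$locus1[i]] * X[, ep$locus2[i]] * ep$effect[i]
    names(g) <- ids
    b <- rnorm(spec@E, sd = spec@environmentSD)
    b <- b - mean(b)
    rec <- expand.grid(replicate = seq_len(spec@r), genotype = ids,
                       environment = sprintf("E%d", seq_len(spec@E)),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ei <- as.integer(sub("E", "", rec$environment))
    rec$value <- g[rec$genotype] + b[ei] +
        rnorm(nrow(rec), sd = spec@errorSD)
    list(values = g, alleles = X,
         table = ReplicateTable(rec[, c("genotype", "environment",
                                        "replicate", "value")]),
         theoreticalAdditive = sum(abs(spec@additive)))
}

#' Read a simulation spec from a YAML or JSON config file
#'
#' Field names match the arguments of [ammiSimSpec()] (with
#' `kind: ammi`) or [dhSimSpec()] (`kind: dh`).
#'
#' @param path a `.yaml`/`.yml` or `.json` file
#' @return an [AMMISimSpec-class] or [DHSimSpec-class]
#' @export
readSimSpec <- function(path) {
    cfg <- if (grepl("\\.ya?ml$", path)) {
        if (!requireNamespace("yaml", quietly = TRUE))
            stop("reading YAML specs needs the 'yaml' package")
        yaml::read_yaml(path)
    } else {
        jsonlite::read_json(path, simplifyVector = TRUE)
    }
    kind <- cfg$kind
    if (is.null(kind))
        stop("spec config needs a 'kind' field ('ammi' or 'dh')")
    cfg$kind <- NULL
    if (identical(kind, "ammi")) do.call(ammiSimSpec, cfg)
    else if (identical(kind, "dh")) do.call(dhSimSpec, cfg)
    else stop("unknown spec kind: ", kind)
}
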