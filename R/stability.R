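#' AMMI stability value (ASV)
#'
#' Weighted distance of a genotype from the origin of the IPCA1 x IPCA2
#' score plane,
#' \deqn{ASV = \sqrt{\left[\frac{SS_{IPCA1}}{SS_{IPCA2}}\,IPCA_1\right]^2
#'   + IPCA_2^2},}
#' where the weight compensates for the larger share of the interaction
#' sum of squares carried by the first axis. Invariant to the signs of
#' both scores; smaller values indicate more stable genotypes. Exactly
#' the first two axes enter, regardless of how many are significant.
#' The SS ratio is scale-invariant to the replicate count, so the
#' replicate-total and means-scale axis SS give the same ASV.
#'
#' @param ipca1,ipca2 genotype scores on the first two axes (vectorized)
#' @param ssIpca1,ssIpca2 interaction sums of squares of axes 1 and 2
#' @return nonnegative numeric vector
#' @examples
#' asv(-0.281, -0.328, 4640, 2065)   # 0.712
#' @export
asv <- function(ipca1, ipca2, ssIpca1, ssIpca2) {
    if (ssIpca2 <= 0 || ssIpca2 < 1e-12 * ssIpca1)
        stop("ssIpca2 is (numerically) zero: the interaction is ",
             "effectively rank-1 and the ASV weight is undefined")
    sqrt((ssIpca1 / ssIpca2 * ipca1)^2 + ipca2^2)
}

#' Per-genotype stability report: means, ASV, ranks and GSI
#'
#' Combines trait performance and stability into the genotype selection
#' index \eqn{GSI_i = RY_i + RASV_i}: the rank of the genotype mean
#' (1 = largest) plus the rank of its ASV (1 = smallest, most stable).
#' Low GSI flags genotypes that are simultaneously high-performing and
#' stable. Ties receive average ranks, so GSI may be non-integer under
#' ties.
#'
#' @param dec an [AMMIDecomposition-class] with at least 2 axes
#' @param ge the [GEMatrix-class] the decomposition was fitted to
#' @return a [S4Vectors::DataFrame] sorted by ascending `gsi`, columns
#'   `genotype`, `mean`, `ipca1`, `ipca2`, `asv`, `rank_mean`,
#'   `rank_asv`, `gsi`; the SS weight enters via
#'   `S4Vectors::metadata()$ssRatio`
#' @examples
#' ge <- barleyTKW()
#' head(stabilityReport(ammiDecompose(ge), ge), 3)
#' @export
stabilityReport <- function(dec, ge) {
    stopifnot(is(dec, "AMMIDecomposition"), is(ge, "GEMatrix"))
    if (nAxes(dec) < 2L)
        stop("stability report needs at least 2 interaction axes")
    y <- geValues(ge)
    gs <- genotypeScores(dec)
    a <- asv(gs[, 1L], gs[, 2L], axisSS(dec)[1L], axisSS(dec)[2L])
    m <- rowMeans(y)
    ry <- rank(-m, ties.method = "average")
    rasv <- rank(a, ties.method = "average")
    out <- S4Vectors::DataFrame(
        genotype = rownames(y), mean = unname(m),
        ipca1 = unname(gs[, 1L]), ipca2 = unname(gs[, 2L]),
        asv = unname(a),
        rank_mean = unname(ry), rank_asv = unname(rasv),
        gsi = unname(ry + rasv))
    out <- out[order(out$gsi, out$genotype), ]
    rownames(out) <- NULL
    S4Vectors::metadata(out) <- list(
        ssRatio = axisSS(dec)[1L] / axisSS(dec)[2L])
    out
}
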