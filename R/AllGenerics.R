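#' @rdname GEMatrix-accessors
#' @export
setGeneric("geValues", function(x) standardGeneric("geValues"))

#' @rdname GEMatrix-accessors
#' @export
setGeneric("genotypeIds", function(x) standardGeneric("genotypeIds"))

#' @rdname GEMatrix-accessors
#' @export
setGeneric("environmentIds", function(x) standardGeneric("environmentIds"))

#' @rdname GEMatrix-accessors
#' @export
setGeneric("replicates", function(x) standardGeneric("replicates"))

#' @rdname GEMatrix-accessors
#' @export
setGeneric("genotypeRole", function(x) standardGeneric("genotypeRole"))

#' @rdname GEMatrix-accessors
#' @export
setGeneric("seedType", function(x) standardGeneric("seedType"))

#' @rdname aggregateReplicates
#' @export
setGeneric("aggregateReplicates",
    function(x, ...) standardGeneric("aggregateReplicates"))

#' @rdname AMMIDecomposition-accessors
#' @export
setGeneric("grandMean", function(x) standardGeneric("grandMean"))

#' @rdname AMMIDecomposition-accessors
#' @export
setGeneric("genotypeEffects", function(x) standardGeneric("genotypeEffects"))

#' @rdname AMMIDecomposition-accessors
#' @export
setGeneric("environmentEffects",
    function(x) standardGeneric("environmentEffects"))

#' @rdname AMMIDecomposition-accessors
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))

#' @rdname AMMIDecomposition-accessors
#' @export
setGeneric("genotypeScores", function(x) standardGeneric("genotypeScores"))

#' @rdname AMMIDecomposition-accessors
#' @export
setGeneric("environmentScores",
    function(x) standardGeneric("environmentScores"))

#' @rdname AMMIDecomposition-accessors
#' @export
setGeneric("axisSS", function(x) standardGeneric("axisSS"))

#' @rdname AMMIDecomposition-accessors
#' @export
setGeneric("axisDf", function(x) standardGeneric("axisDf"))

#' @rdname AMMIDecomposition-accessors
#' @export
setGeneric("axisPct", function(x) standardGeneric("axisPct"))

#' @rdname AMMIDecomposition-accessors
#' @export
setGeneric("nAxes", function(x) standardGeneric("nAxes"))

#' @rdname extremeLines
#' @export
setGeneric("minimalLines", function(x) standardGeneric("minimalLines"))

#' @rdname extremeLines
#' @export
setGeneric("maximalLines", function(x) standardGeneric("maximalLines"))
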