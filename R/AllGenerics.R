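#' @rdname normalizeSignals
#' @export
setGeneric("normalizeSignals", function(object, ...)
    standardGeneric("normalizeSignals"))

#' @rdname differentialEffects
#' @export
setGeneric("differentialEffects", function(object, ...)
    standardGeneric("differentialEffects"))

#' @rdname computePCScores
#' @export
setGeneric("computePCScores", function(object, ...)
    standardGeneric("computePCScores"))

#' @rdname permutationNull
#' @export
setGeneric("permutationNull", function(object, ...)
    standardGeneric("permutationNull"))

#' Pathway accessor
#'
#' @param object a \linkS4class{NetworkEffects} object.
#' @return The pathway identifier.
#' @export
setGeneric("pathwayName", function(object) standardGeneric("pathwayName"))

#' Signed effect matrix accessor
#'
#' @param object a \linkS4class{NetworkEffects} object.
#' @return The miRNA x protein signed effect matrix.
#' @export
setGeneric("effectsMatrix", function(object) standardGeneric("effectsMatrix"))

#' Measured-pair accessors
#'
#' @param object a \linkS4class{NetworkEffects} object.
#' @return \code{measuredMatrix}: logical miRNA x protein matrix;
#'   \code{nMeasured}: integer vector of per-miRNA measured-protein counts.
#' @export
setGeneric("measuredMatrix", function(object) standardGeneric("measuredMatrix"))

#' @rdname measuredMatrix
#' @export
setGeneric("nMeasured", function(object) standardGeneric("nMeasured"))

#' Has a screen been normalized?
#'
#' @param object a \linkS4class{ScreenExperiment}.
#' @return Scalar logical.
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))
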