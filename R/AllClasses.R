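#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
NULL

#' ScreenExperiment: spot-level RPPA screen signals
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one reverse-phase
#' protein array screen. Rows are antibodies (one per probed protein), columns
#' are individual printed spots. Two assays are carried: \code{"signal"}
#' (raw or normalized antibody intensity) and \code{"totalProtein"} (the
#' per-spot total-protein estimate used as normalization denominator).
#'
#' Required \code{colData} columns: \code{sample_id}, \code{condition} (miRNA
#' or control identifier), \code{replicate} (biological replicate, positive
#' integer), \code{spot} (technical replicate within sample), \code{block}
#' (spotting group), \code{round} (transfection round), \code{is_control}
#' (logical) and \code{control_kind} (\code{"ctrl1"}, \code{"ctrl2"} or
#' \code{"none"}).
#'
#' @slot normalized scalar logical; \code{TRUE} after
#'   \code{\link{normalizeSignals}} has been applied.
#'
#' @seealso \code{\link{readRawSignals}}, \code{\link{normalizeSignals}},
#'   \code{\link{differentialEffects}}
#' @export
setClass("ScreenExperiment",
    contains = "SummarizedExperiment",
    slots = c(normalized = "logical"),
    prototype = prototype(normalized = FALSE)
)

.validScreenExperiment <- function(object) {
    msg <- NULL
    needed <- c("sample_id", "condition", "replicate", "spot", "block",
                "round", "is_control", "control_kind")
    missing_cols <- setdiff(needed, colnames(colData(object)))
    if (length(missing_cols))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(missing_cols, collapse = ", ")))
    if (!all(c("signal", "totalProtein") %in% assayNames(object)))
        msg <- c(msg, "assays must include 'signal' and 'totalProtein'")
    if (length(object@normalized) != 1L || is.na(object@normalized))
        msg <- c(msg, "'normalized' must be a scalar logical")
    if (is.null(msg)) {
        ck <- colData(object)$control_kind
        bad <- !ck %in% c("ctrl1", "ctrl2", "none")
        if (any(bad))
            msg <- c(msg, paste0("invalid control_kind value(s): ",
                                 paste(unique(ck[bad]), collapse = ", ")))
        if (any(colData(object)$is_control & ck == "none") ||
            any(!colData(object)$is_control & ck != "none"))
            msg <- c(msg, "control_kind must be 'none' exactly for non-control samples")
        tp <- assay(object, "totalProtein")
        sig <- assay(object, "signal")
        if (any(!is.na(sig) & !is.na(tp) & tp <= 0))
            msg <- c(msg, "totalProtein must be > 0 wherever a signal is present")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("ScreenExperiment", .validScreenExperiment)

#' EffectTable: per-(miRNA, protein) differential effects
#'
#' A \linkS4class{SummarizedExperiment} subclass produced by
#' \code{\link{differentialEffects}} (or read from disk with
#' \code{\link{readEffectTable}}). Rows are proteins, columns are miRNAs.
#' Assays: \code{log2fc}, \code{pvalue}, \code{qvalue}, \code{nobs}
#' (samples used in the contrast) and \code{missing} (logical; fewer than two
#' usable observations on either side).
#'
#' @seealso \code{\link{buildNetworkEffects}}, \code{\link{summarizeEffects}}
#' @export
setClass("EffectTable", contains = "SummarizedExperiment")

.validEffectTable <- function(object) {
    msg <- NULL
    needed <- c("log2fc", "qvalue", "nobs", "missing")
    if (!all(needed %in% assayNames(object)))
        msg <- c(msg, paste0("assays must include: ",
                             paste(needed, collapse = ", ")))
    if (is.null(msg)) {
        q <- assay(object, "qvalue")
        if (any(q < 0 | q > 1, na.rm = TRUE))
            msg <- c(msg, "qvalue must lie in [0, 1]")
        lfc <- assay(object, "log2fc")
        miss <- assay(object, "missing")
        if (any(!miss & !is.finite(lfc)))
            msg <- c(msg, "log2fc must be finite wherever not flagged missing")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("EffectTable", .validEffectTable)

#' PathwayAnnotation: signed pathway-role membership
#'
#' Curated mapping protein -> (pathway, role) with role one of
#' \code{"activator"} or \code{"repressor"}. A protein may belong to several
#' pathways with independent roles; each (protein, pathway) pair is unique.
#' Backed by a \linkS4class{DataFrame} with columns \code{protein},
#' \code{pathway}, \code{role}.
#'
#' @seealso \code{\link{readPathwayAnnotation}}, \code{\link{pathwayCensus}}
#' @export
setClass("PathwayAnnotation", contains = "DFrame")

.validPathwayAnnotation <- function(object) {
    msg <- NULL
    needed <- c("protein", "pathway", "role")
    if (!all(needed %in% colnames(object)))
        return(paste0("columns must include: ", paste(needed, collapse = ", ")))
    bad_role <- !object$role %in% c("activator", "repressor")
    if (any(bad_role))
        msg <- c(msg, paste0("invalid role in row(s) ",
                             paste(which(bad_role), collapse = ", "),
                             ": ", paste(unique(object$role[bad_role]),
                                         collapse = ", ")))
    if (any(!nzchar(object$pathway)) || anyNA(object$pathway))
        msg <- c(msg, "empty pathway identifier")
    if (any(!nzchar(object$protein)) || anyNA(object$protein))
        msg <- c(msg, "empty protein identifier")
    key <- paste(object$protein, object$pathway, sep = "\r")
    if (anyDuplicated(key))
        msg <- c(msg, paste0("duplicated (protein, pathway) pair(s): ",
                             paste(unique(key[duplicated(key)]), collapse = "; ")))
    if (is.null(msg)) TRUE else msg
}
setValidity("PathwayAnnotation", .validPathwayAnnotation)

#' NetworkEffects: signed per-pathway miRNA-network effect matrix
#'
#' The miR-N matrix for one pathway: the (miRNA x protein) matrix of signed
#' pathway effects obtained from significant protein effects and the
#' activator/repressor annotation. With the default sign weighting entries
#' are in \{-1, 0, +1\}; with magnitude weighting they carry the signed
#' |log2FC|. \code{measured} marks (miRNA, protein) pairs with a usable
#' measurement; \code{nMeasured} (its row sums) is the PC-score denominator.
#'
#' @slot pathway scalar character, pathway identifier.
#' @slot effects numeric matrix, miRNAs x proteins; 0 where non-significant
#'   or unmeasured.
#' @slot measured logical matrix, same dimensions.
#' @slot nMeasured integer vector, non-missing annotated proteins per miRNA.
#' @seealso \code{\link{buildNetworkEffects}}, \code{\link{computePCScores}},
#'   \code{\link{permutationNull}}
#' @export
setClass("NetworkEffects",
    slots = c(pathway = "character",
              effects = "matrix",
              measured = "matrix",
              nMeasured = "integer")
)

.validNetworkEffects <- function(object) {
    msg <- NULL
    if (length(object@pathway) != 1L)
        msg <- c(msg, "'pathway' must be a single identifier")
    if (!identical(dim(object@effects), dim(object@measured)))
        msg <- c(msg, "'effects' and 'measured' dimensions differ")
    if (length(object@nMeasured) != nrow(object@effects))
        msg <- c(msg, "'nMeasured' length must equal nrow(effects)")
    if (is.null(msg)) {
        if (any(object@effects[!object@measured] != 0))
            msg <- c(msg, "nonzero effect on an unmeasured (miRNA, protein) pair")
        if (any(object@nMeasured < rowSums(object@effects != 0)))
            msg <- c(msg, "nMeasured smaller than the count of nonzero effects")
        if (is.null(rownames(object@effects)) || is.null(colnames(object@effects)))
            msg <- c(msg, "effects matrix must carry miRNA/protein dimnames")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("NetworkEffects", .validNetworkEffects)

#' PredictionSet: predicted miRNA-target pairs
#'
#' One prediction dataset (e.g. TargetScan conserved) as a de-duplicated set
#' of (mirna, protein) pairs.
#'
#' @slot name scalar character, dataset label (e.g. \code{"TSC"}).
#' @slot pairs data.frame with columns \code{mirna}, \code{protein}.
#' @seealso \code{\link{bindingSiteEnrichment}}
#' @export
setClass("PredictionSet",
    slots = c(name = "character", pairs = "data.frame")
)

.validPredictionSet <- function(object) {
    msg <- NULL
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "'name' must be a non-empty scalar")
    if (!all(c("mirna", "protein") %in% colnames(object@pairs)))
        msg <- c(msg, "'pairs' needs columns mirna, protein")
    else if (anyDuplicated(paste(object@pairs$mirna, object@pairs$protein,
                                 sep = "\r")))
        msg <- c(msg, "duplicated (mirna, protein) prediction pairs")
    if (is.null(msg)) TRUE else msg
}
setValidity("PredictionSet", .validPredictionSet)
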