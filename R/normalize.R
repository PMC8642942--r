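#' Normalize RPPA signals to total protein and remove block effects
#'
#' Two steps, mirroring standard RPPA practice: (i) spot-wise division of each
#' antibody signal by the spot's total-protein estimate; (ii) per antibody,
#' an additive shift of each spotting block so that the block median equals
#' the antibody's overall median, removing block (spotting-group) effects.
#' With a single block the shift is identically zero.
#'
#' @param object a \linkS4class{ScreenExperiment} with raw signals.
#' @param ... unused.
#' @return The \linkS4class{ScreenExperiment} with the \code{signal} assay
#'   normalized, \code{totalProtein} reset to 1 (the denominator has been
#'   consumed) and \code{isNormalized(x)} set to \code{TRUE}.
#' @examples
#' sim <- simulateScreen(simConfig(nMirnas = 6, nPlantedPerPathway = 1, seed = 1))
#' norm <- normalizeSignals(sim$signals)
#' isNormalized(norm)
#' @export
setMethod("normalizeSignals", "ScreenExperiment", function(object, ...) {
    sig <- assay(object, "signal")
    tp <- assay(object, "totalProtein")
    bad <- which(!is.na(sig) & (is.na(tp) | tp <= 0), arr.ind = TRUE)
    if (nrow(bad))
        stop("non-positive total_protein at spot(s): ",
             paste(utils::head(sprintf("%s/%s", rownames(sig)[bad[, 1L]],
                                       colnames(sig)[bad[, 2L]]), 10L),
                   collapse = ", "))
    norm <- sig / tp
    block <- colData(object)$block
    med_all <- apply(norm, 1L, stats::median, na.rm = TRUE)
    for (b in unique(block)) {
        j <- which(block == b)
        med_b <- apply(norm[, j, drop = FALSE], 1L, stats::median, na.rm = TRUE)
        norm[, j] <- norm[, j, drop = FALSE] + (med_all - med_b)
    }
    assay(object, "signal") <- norm
    assay(object, "totalProtein") <- matrix(1, nrow(norm), ncol(norm),
                                            dimnames = dimnames(norm))
    object@normalized <- TRUE
    validObject(object)
    object
})
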