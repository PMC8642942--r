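#' Transform protein effects into signed per-pathway network effects
#'
#' Applies the sign rules converting a significant miRNA effect on a protein
#' into a pathway effect, given the protein's curated role: downregulating a
#' pathway activator is a negative pathway effect, downregulating a repressor
#' a positive one, and the two upregulation cases mirror these. Pairs that
#' are missing or not significant at \code{alphaQ} contribute 0; a
#' significant pair with log2FC exactly 0 is degenerate and contributes 0.
#'
#' @param effects an \linkS4class{EffectTable}.
#' @param ann a \linkS4class{PathwayAnnotation}.
#' @param alphaQ per-pair significance threshold on the q-value (default
#'   0.001).
#' @param weighting \code{"sign"} (default; effects enter as +1/-1) or
#'   \code{"magnitude"} (effects carry the signed |log2FC|).
#' @return A named list of \linkS4class{NetworkEffects}, one per pathway (in
#'   sorted pathway order; miRNAs and proteins sorted within each).
#' @examples
#' sim <- simulateScreen(simConfig(nMirnas = 10, nPlantedPerPathway = 2, seed = 1))
#' et <- differentialEffects(normalizeSignals(sim$signals))
#' nets <- buildNetworkEffects(et, sim$annotation)
#' computePCScores(nets[["WNT"]])
#' @export
buildNetworkEffects <- function(effects, ann, alphaQ = 0.001,
                                weighting = c("sign", "magnitude")) {
    stopifnot(is(effects, "EffectTable"), is(ann, "PathwayAnnotation"))
    weighting <- match.arg(weighting)
    if (!(alphaQ > 0 && alphaQ < 1)) stop("alphaQ must lie in (0, 1)")
    mirnas <- sort(colnames(effects))
    lfc <- assay(effects, "log2fc")
    qv <- assay(effects, "qvalue")
    miss <- assay(effects, "missing")
    out <- list()
    for (pw in sort(unique(ann$pathway))) {
        rows <- ann[ann$pathway == pw, ]
        prots <- sort(intersect(rows$protein, rownames(effects)))
        if (!length(prots))
            stop("no measured proteins annotated to pathway ", pw)
        role_sign <- ifelse(rows$role[match(prots, rows$protein)] ==
                                "activator", 1, -1)
        l <- t(lfc[prots, mirnas, drop = FALSE])
        q <- t(qv[prots, mirnas, drop = FALSE])
        measured <- t(!miss[prots, mirnas, drop = FALSE])
        sig <- measured & !is.na(q) & q <= alphaQ & !is.na(l) & l != 0
        eff <- matrix(0, length(mirnas), length(prots),
                      dimnames = list(mirnas, prots))
        base <- if (weighting == "sign") sign(l[sig]) else l[sig]
        eff[sig] <- base * rep(role_sign, each = nrow(eff))[sig]
        out[[pw]] <- new("NetworkEffects", pathway = pw, effects = eff,
                         measured = measured,
                         nMeasured = as.integer(rowSums(measured)))
    }
    out
}

#' @rdname pathwayName
#' @export
setMethod("pathwayName", "NetworkEffects", function(object) object@pathway)

#' @rdname effectsMatrix
#' @export
setMethod("effectsMatrix", "NetworkEffects", function(object) object@effects)

#' @rdname measuredMatrix
#' @export
setMethod("measuredMatrix", "NetworkEffects", function(object) object@measured)

#' @rdname measuredMatrix
#' @export
setMethod("nMeasured", "NetworkEffects", function(object) {
    stats::setNames(object@nMeasured, rownames(object@effects))
})

setMethod("show", "NetworkEffects", function(object) {
    cat(sprintf("NetworkEffects '%s': %d miRNAs x %d proteins, %d nonzero effects\n",
                object@pathway, nrow(object@effects), ncol(object@effects),
                sum(object@effects != 0)))
})

#' Pathway Coregulatory (PC) score
#'
#' The PC score of a miRNA on a pathway is the sum of its signed pathway
#' effects over the pathway's proteins, divided by the number of proteins
#' measured for that miRNA in the pathway. With sign weighting this is
#' (n_positive - n_negative) / n_measured and lies in [-1, +1]; negative
#' scores mark putative pathway repressors, positive scores activators.
#'
#' @param object a \linkS4class{NetworkEffects} object.
#' @param ... unused.
#' @return Named numeric vector of scores, one per miRNA. miRNAs with no
#'   measured pathway protein are excluded from scoring and get \code{NA}.
#' @export
setMethod("computePCScores", "NetworkEffects", function(object, ...) {
    num <- rowSums(object@effects)
    score <- ifelse(object@nMeasured > 0, num / object@nMeasured, NA_real_)
    names(score) <- rownames(object@effects)
    score
})
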