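#' Resampling null distribution of PC scores
#'
#' For each of \code{B} replicates and independently for each protein
#' (column), the column's nonzero significant effects are reassigned to
#' miRNAs drawn uniformly without replacement from the full miRNA list,
#' preserving the column's multiset of effect values (so per-protein counts
#' of significant up- and down-effects are exact invariants). PC scores are
#' recomputed on every permuted matrix against the observed per-miRNA
#' \code{nMeasured} denominators.
#'
#' With \code{directionPooled = TRUE} the sign split is not preserved:
#' per column, only the count of significant interactions is kept and each
#' reassigned interaction draws its sign at random from the column's
#' empirical sign frequencies.
#'
#' @param object a \linkS4class{NetworkEffects} object.
#' @param B number of resampling rounds (default 10000).
#' @param seed optional integer; when given, the RNG is seeded (and restored
#'   on exit) so results are reproducible.
#' @param directionPooled logical (default \code{FALSE}), see above.
#' @param ... unused.
#' @return A miRNA x B numeric matrix of null PC scores.
#' @examples
#' sim <- simulateScreen(simConfig(nMirnas = 10, nPlantedPerPathway = 2, seed = 1))
#' et <- differentialEffects(normalizeSignals(sim$signals))
#' net <- buildNetworkEffects(et, sim$annotation)[["WNT"]]
#' null <- permutationNull(net, B = 100, seed = 7)
#' @export
setMethod("permutationNull", "NetworkEffects", function(object, B = 10000,
        seed = NULL, directionPooled = FALSE, ...) {
    if (!(is.numeric(B) && length(B) == 1L && B >= 1)) stop("B must be >= 1")
    B <- as.integer(B)
    if (!is.null(seed)) {
        if (exists(".Random.seed", envir = globalenv())) {
            old <- get(".Random.seed", envir = globalenv())
            on.exit(assign(".Random.seed", old, envir = globalenv()))
        }
        set.seed(as.integer(seed))
    }
    eff <- object@effects
    M <- nrow(eff)
    num <- matrix(0, M, B)
    for (j in seq_len(ncol(eff))) {
        v <- eff[eff[, j] != 0, j]
        k <- length(v)
        if (k == 0L) next
        idx <- vapply(seq_len(B), function(b) sample.int(M, k), integer(k))
        vals <- if (directionPooled)
            abs(v) * sample(sign(v), k * B, replace = TRUE)
        else rep(v, times = B)
        ind <- cbind(as.vector(idx), rep(seq_len(B), each = k))
        num[ind] <- num[ind] + vals
    }
    null <- num / ifelse(object@nMeasured > 0, object@nMeasured, NA_real_)
    rownames(null) <- rownames(eff)
    null
})

#' Empirical FDR and regulator classification from a resampling null
#'
#' Each miRNA's observed PC score is tested against its own null sample with
#' the two-sided add-one empirical p-value
#' \eqn{p = (1 + \#\{b : |null_b| \ge |obs|\}) / (B + 1)}; q-values are
#' Benjamini-Hochberg across the pathway's miRNAs, and miRNAs with
#' \eqn{q \le \alpha} are classified by score sign (negative = repressor,
#' positive = activator), all others \code{"none"}.
#'
#' @param observed named numeric vector of PC scores (from
#'   \code{\link{computePCScores}}).
#' @param null miRNA x B null score matrix (from
#'   \code{\link{permutationNull}}) covering the same miRNAs.
#' @param alpha FDR level (default 0.05).
#' @param pathway optional pathway label carried into the result.
#' @param nSignificant optional named integer vector of per-miRNA nonzero
#'   pathway effects, carried into the result.
#' @return A \linkS4class{DataFrame} with columns \code{mirna},
#'   \code{pathway}, \code{score}, \code{p_emp}, \code{qvalue},
#'   \code{classification}, \code{n_measured}, \code{n_significant}.
#' @export
empiricalFdr <- function(observed, null, alpha = 0.05, pathway = NA_character_,
                         nSignificant = NULL) {
    mir <- names(observed)
    if (is.null(mir) || is.null(rownames(null)) ||
        !setequal(mir, rownames(null)))
        stop("observed scores and null samples cover different miRNA sets")
    null <- null[mir, , drop = FALSE]
    B <- ncol(null)
    keep <- !is.na(observed)
    p <- rep(NA_real_, length(observed))
    p[keep] <- (1 + rowSums(abs(null[keep, , drop = FALSE]) >=
                                abs(observed[keep]))) / (B + 1)
    q <- rep(NA_real_, length(observed))
    q[keep] <- stats::p.adjust(p[keep], method = "BH")
    cls <- rep("none", length(observed))
    cls[keep & q <= alpha & observed < 0] <- "repressor"
    cls[keep & q <= alpha & observed > 0] <- "activator"
    nm <- attr(observed, "n_measured")
    DataFrame(
        mirna = mir,
        pathway = pathway,
        score = as.numeric(observed),
        p_emp = p,
        qvalue = q,
        classification = cls,
        n_measured = if (is.null(nm)) NA_integer_ else as.integer(nm[mir]),
        n_significant = if (is.null(nSignificant)) NA_integer_
                        else as.integer(nSignificant[mir]))
}

#' End-to-end PC-score analysis across pathways
#'
#' Convenience wrapper: builds the signed network-effect matrices, computes
#' observed PC scores, draws the resampling null and classifies regulators
#' at the requested FDR, for every pathway in the annotation. One RNG stream
#' (from \code{seed}) drives all pathways, processed in sorted order.
#'
#' @param effects an \linkS4class{EffectTable}.
#' @param ann a \linkS4class{PathwayAnnotation}.
#' @param alphaQ per-interaction q-value threshold (default 0.001).
#' @param B resampling rounds (default 10000).
#' @param alphaFdr FDR level for classification (default 0.05).
#' @param seed integer seed for the resampling RNG.
#' @param weighting \code{"sign"} or \code{"magnitude"}, see
#'   \code{\link{buildNetworkEffects}}.
#' @param directionPooled see \code{\link{permutationNull}}.
#' @return A \linkS4class{DataFrame} stacking the per-pathway
#'   \code{\link{empiricalFdr}} results.
#' @examples
#' sim <- simulateScreen(simConfig(nMirnas = 20, nPlantedPerPathway = 2, seed = 1))
#' et <- differentialEffects(normalizeSignals(sim$signals))
#' res <- pcScore(et, sim$annotation, B = 200, seed = 7)
#' table(res$pathway, res$classification)
#' @export
pcScore <- function(effects, ann, alphaQ = 0.001, B = 10000, alphaFdr = 0.05,
                    seed = NULL, weighting = c("sign", "magnitude"),
                    directionPooled = FALSE) {
    nets <- buildNetworkEffects(effects, ann, alphaQ = alphaQ,
                                weighting = match.arg(weighting))
    if (!is.null(seed)) {
        if (exists(".Random.seed", envir = globalenv())) {
            old <- get(".Random.seed", envir = globalenv())
            on.exit(assign(".Random.seed", old, envir = globalenv()))
        }
        set.seed(as.integer(seed))
    }
    res <- lapply(nets, function(net) {
        obs <- computePCScores(net)
        attr(obs, "n_measured") <- nMeasured(net)
        null <- permutationNull(net, B = B, directionPooled = directionPooled)
        empiricalFdr(obs, null, alpha = alphaFdr,
                     pathway = pathwayName(net),
                     nSignificant = rowSums(effectsMatrix(net) != 0))
    })
    do.call(rbind, unname(res))
}

#' Cross-pathway overlap of classified regulators
#'
#' For each regulation direction, counts miRNAs in every Venn region of the
#' pathway significance sets (which pathways a miRNA regulates in that
#' direction), including the full intersection.
#'
#' @param results a PC-score result \linkS4class{DataFrame} (from
#'   \code{\link{pcScore}}) covering two or more pathways.
#' @return A data.frame with columns \code{direction}, \code{pathways}
#'   (\code{&}-joined sorted pathway subset), \code{count}, and a
#'   \code{members} column of comma-joined miRNA identifiers. Only non-empty
#'   exclusive regions are listed.
#' @export
overlapSummary <- function(results) {
    results <- as.data.frame(results)
    pws <- sort(unique(results$pathway))
    if (length(pws) < 2L) stop("need results for at least two pathways")
    out <- list()
    for (dir in c("repressor", "activator")) {
        hit <- results[results$classification == dir, c("mirna", "pathway")]
        membership <- vapply(split(hit$pathway, hit$mirna), function(p)
            paste(sort(unique(p)), collapse = "&"), character(1))
        tab <- table(membership)
        if (length(tab))
            out[[dir]] <- data.frame(
                direction = dir,
                pathways = names(tab),
                count = as.integer(tab),
                members = vapply(names(tab), function(r) paste(sort(
                    names(membership)[membership == r]), collapse = ","),
                    character(1)),
                row.names = NULL)
    }
    if (!length(out))
        return(data.frame(direction = character(), pathways = character(),
                          count = integer(), members = character()))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
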