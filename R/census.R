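#' Census of significant screen interactions
#'
#' Counts significant (miRNA, protein) interactions at a q-value threshold
#' and optional absolute log2FC cut-off, split by direction, together with
#' per-protein up/down regulator counts and per-direction mean significant
#' log2FCs.
#'
#' @param effects an \linkS4class{EffectTable}.
#' @param alphaQ q-value threshold (default 0.001).
#' @param fcCutoff minimum |log2FC| for a significant interaction (default 0).
#' @return A list with elements \code{n_tested}, \code{n_significant},
#'   \code{n_down}, \code{n_up}, \code{mean_down_log2fc},
#'   \code{mean_up_log2fc}, \code{n_mirnas_with_hit}, and
#'   \code{per_protein} (data.frame with per-protein down/up counts).
#' @examples
#' sim <- simulateScreen(simConfig(nMirnas = 12, nPlantedPerPathway = 2, seed = 1))
#' et <- differentialEffects(normalizeSignals(sim$signals))
#' summarizeEffects(et)$n_significant
#' @export
summarizeEffects <- function(effects, alphaQ = 0.001, fcCutoff = 0) {
    stopifnot(is(effects, "EffectTable"))
    lfc <- assay(effects, "log2fc")
    qv <- assay(effects, "qvalue")
    miss <- assay(effects, "missing")
    ok <- !miss & !is.na(qv)
    sig <- ok & qv <= alphaQ & abs(lfc) >= fcCutoff & lfc != 0
    down <- sig & lfc < 0
    up <- sig & lfc > 0
    per_protein <- data.frame(
        protein = rownames(effects),
        n_down = rowSums(down),
        n_up = rowSums(up),
        row.names = NULL)
    list(
        n_tested = sum(ok),
        n_significant = sum(sig),
        n_down = sum(down),
        n_up = sum(up),
        mean_down_log2fc = if (any(down)) mean(lfc[down]) else NA_real_,
        mean_up_log2fc = if (any(up)) mean(lfc[up]) else NA_real_,
        n_mirnas_with_hit = sum(colSums(sig) > 0),
        per_protein = per_protein)
}
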