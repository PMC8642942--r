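#' Construct / read a miRNA-target prediction set
#'
#' @param name dataset label (e.g. \code{"TSC"}, \code{"TSNC"}, \code{"mC"}).
#' @param pairs data.frame with columns \code{mirna}, \code{protein};
#'   duplicates are collapsed.
#' @return A \linkS4class{PredictionSet}.
#' @export
PredictionSet <- function(name, pairs) {
    pairs <- as.data.frame(pairs)[, c("mirna", "protein")]
    pairs$mirna <- trimws(as.character(pairs$mirna))
    pairs$protein <- trimws(as.character(pairs$protein))
    pairs <- unique(pairs)
    rownames(pairs) <- NULL
    new("PredictionSet", name = name, pairs = pairs)
}

setMethod("show", "PredictionSet", function(object) {
    cat(sprintf("PredictionSet '%s': %d predicted pairs (%d miRNAs, %d proteins)\n",
                object@name, nrow(object@pairs),
                length(unique(object@pairs$mirna)),
                length(unique(object@pairs$protein))))
})

#' @param path delimited text file with header columns \code{mirna},
#'   \code{protein}.
#' @param sep field separator (default tab).
#' @rdname PredictionSet
#' @export
readPredictionSet <- function(path, name, sep = "\t") {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                             comment.char = "", stringsAsFactors = FALSE)
    miss <- setdiff(c("mirna", "protein"), colnames(tab))
    if (length(miss))
        stop("schema error: prediction set lacks column(s): ",
             paste(miss, collapse = ", "))
    PredictionSet(name, tab)
}

#' Predicted binding-site enrichment per protein
#'
#' For each protein and each prediction dataset, tests whether the miRNAs
#' that significantly regulate the protein in the given direction are
#' enriched for predicted targeting miRNAs, with a two-sided Fisher exact
#' test on the 2x2 table \{significant in direction vs not\} x \{predicted
#' target vs not\} over the universe of all screened miRNAs (the screen
#' defines the sampling frame). Proteins absent from a prediction dataset
#' yield a valid table with an empty predicted margin (p = 1) and are
#' flagged.
#'
#' @param effects an \linkS4class{EffectTable}.
#' @param preds a \linkS4class{PredictionSet} or a list of them.
#' @param direction \code{"down"} or \code{"up"}.
#' @param alphaQ per-interaction q-value threshold (default 0.001).
#' @param fcCutoff minimum |log2FC| for a significant interaction
#'   (default 0).
#' @return A data.frame with one row per (dataset, protein): counts of the
#'   2x2 table, \code{odds_ratio} (conditional MLE), \code{pvalue},
#'   \code{significant} (p < 0.05) and \code{in_predictions}. The attribute
#'   \code{"tally"} counts proteins significant in >= 1 and >= 2 datasets.
#' @examples
#' sim <- simulateScreen(simConfig(nMirnas = 30, nPlantedPerPathway = 2, seed = 2))
#' et <- differentialEffects(normalizeSignals(sim$signals))
#' ps <- PredictionSet("toy", data.frame(
#'     mirna = colnames(et)[1:5], protein = rownames(et)[1]))
#' enr <- bindingSiteEnrichment(et, ps, direction = "down")
#' @export
bindingSiteEnrichment <- function(effects, preds, direction = c("down", "up"),
                                  alphaQ = 0.001, fcCutoff = 0) {
    stopifnot(is(effects, "EffectTable"))
    direction <- match.arg(direction)
    if (is(preds, "PredictionSet")) preds <- list(preds)
    universe <- colnames(effects)
    lfc <- assay(effects, "log2fc")
    qv <- assay(effects, "qvalue")
    miss <- assay(effects, "missing")
    sig <- !miss & !is.na(qv) & qv <= alphaQ & abs(lfc) >= fcCutoff &
        (if (direction == "down") lfc < 0 else lfc > 0)
    rows <- list()
    for (ps in preds) {
        stopifnot(is(ps, "PredictionSet"))
        for (prot in rownames(effects)) {
            predicted <- universe %in%
                ps@pairs$mirna[ps@pairs$protein == prot]
            s <- sig[prot, universe]
            a <- sum(s & predicted); b <- sum(s & !predicted)
            cc <- sum(!s & predicted); d <- sum(!s & !predicted)
            ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2L,
                                            byrow = TRUE))
            rows[[length(rows) + 1L]] <- data.frame(
                dataset = ps@name, protein = prot,
                n_sig_pred = a, n_sig_unpred = b,
                n_nonsig_pred = cc, n_nonsig_unpred = d,
                odds_ratio = unname(ft$estimate), pvalue = ft$p.value,
                significant = ft$p.value < 0.05,
                in_predictions = any(predicted))
        }
    }
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    nsig <- tapply(res$significant, res$protein, sum)
    attr(res, "tally") <- c(atLeast1 = sum(nsig >= 1),
                            atLeast2 = sum(nsig >= 2))
    res
}

#' Correlation between 3'UTR length and regulation count
#'
#' Counts, per protein, the miRNAs that significantly regulate it in the
#' given direction (q-value and |log2FC| cut-offs) and reports the Pearson
#' correlation between those counts and the proteins' 3'UTR lengths.
#'
#' @param effects an \linkS4class{EffectTable}.
#' @param utr data.frame with columns \code{protein} and \code{utr_length}
#'   (nucleotides, >= 1).
#' @param alphaQ q-value threshold (default 0.001).
#' @param fcCutoff minimum |log2FC| (default 0.5).
#' @param direction \code{"down"} or \code{"up"}.
#' @return A list with \code{r}, \code{pvalue}, \code{n} and the per-protein
#'   \code{counts} data.frame. With zero count variance \code{r} is
#'   \code{NA} with a \code{note}.
#' @export
utrRegulationCorrelation <- function(effects, utr, alphaQ = 0.001,
                                     fcCutoff = 0.5,
                                     direction = c("down", "up")) {
    stopifnot(is(effects, "EffectTable"))
    direction <- match.arg(direction)
    utr <- as.data.frame(utr)
    if (!all(c("protein", "utr_length") %in% colnames(utr)))
        stop("utr table needs columns protein, utr_length")
    if (any(utr$utr_length < 1)) stop("utr_length must be >= 1")
    lfc <- assay(effects, "log2fc")
    qv <- assay(effects, "qvalue")
    miss <- assay(effects, "missing")
    sig <- !miss & !is.na(qv) & qv <= alphaQ & abs(lfc) >= fcCutoff &
        (if (direction == "down") lfc < 0 else lfc > 0)
    counts <- data.frame(protein = rownames(effects), count = rowSums(sig))
    merged <- merge(counts, utr, by = "protein")
    if (nrow(merged) < 3L)
        stop("need >= 3 proteins with both a regulation count and a UTR length")
    if (stats::var(merged$count) == 0 || stats::var(merged$utr_length) == 0)
        return(list(r = NA_real_, pvalue = NA_real_, n = nrow(merged),
                    counts = merged, note = "zero variance; r undefined"))
    ct <- stats::cor.test(merged$count, merged$utr_length, method = "pearson")
    list(r = unname(ct$estimate), pvalue = ct$p.value, n = nrow(merged),
         counts = merged)
}
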