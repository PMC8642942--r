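#' Read / write an EffectTable as long-format delimited text
#'
#' The on-disk format is one row per (mirna, protein) with columns
#' \code{mirna}, \code{protein}, \code{log2fc}, \code{qvalue}, \code{pvalue}
#' (optional), \code{n_obs} and \code{missing}; pre-computed differential
#' tables in this shape can enter the pipeline directly.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return \code{readEffectTable}: an \linkS4class{EffectTable}.
#' @export
readEffectTable <- function(path, sep = "\t") {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                             comment.char = "", stringsAsFactors = FALSE)
    needed <- c("mirna", "protein", "log2fc", "qvalue")
    miss <- setdiff(needed, colnames(tab))
    if (length(miss))
        stop("schema error: effect table lacks column(s): ",
             paste(miss, collapse = ", "))
    if (is.null(tab$n_obs)) tab$n_obs <- NA_integer_
    if (is.null(tab$missing)) tab$missing <- is.na(tab$log2fc)
    if (is.null(tab$pvalue)) tab$pvalue <- NA_real_
    tab$mirna <- trimws(as.character(tab$mirna))
    tab$protein <- trimws(as.character(tab$protein))
    if (anyDuplicated(paste(tab$mirna, tab$protein, sep = "\r")))
        stop("duplicated (mirna, protein) row(s)")
    mirnas <- sort(unique(tab$mirna))
    proteins <- sort(unique(tab$protein))
    mk <- function(v, init) {
        m <- matrix(init, length(proteins), length(mirnas),
                    dimnames = list(proteins, mirnas))
        m[cbind(match(tab$protein, proteins), match(tab$mirna, mirnas))] <- v
        m
    }
    missing <- mk(as.logical(tab$missing), TRUE)
    lfc <- mk(tab$log2fc, NA_real_)
    missing <- missing | is.na(lfc)
    lfc[missing] <- NA_real_
    et <- new("EffectTable", SummarizedExperiment(assays = SimpleList(
        log2fc = lfc,
        pvalue = mk(tab$pvalue, NA_real_),
        qvalue = mk(tab$qvalue, NA_real_),
        nobs = mk(suppressWarnings(as.integer(tab$n_obs)), 0L),
        missing = missing)))
    validObject(et)
    et
}

#' @param x an \linkS4class{EffectTable}.
#' @rdname readEffectTable
#' @return \code{writeEffectTable}: \code{path}, invisibly.
#' @export
writeEffectTable <- function(x, path, sep = "\t") {
    stopifnot(is(x, "EffectTable"))
    long <- data.frame(
        mirna = rep(colnames(x), each = nrow(x)),
        protein = rep(rownames(x), times = ncol(x)),
        log2fc = as.vector(assay(x, "log2fc")),
        pvalue = as.vector(assay(x, "pvalue")),
        qvalue = as.vector(assay(x, "qvalue")),
        n_obs = as.vector(assay(x, "nobs")),
        missing = as.vector(assay(x, "missing")))
    utils::write.table(long, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}
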