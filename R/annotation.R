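#' Construct a pathway-role annotation
#'
#' @param protein,pathway,role character vectors of equal length (or a single
#'   data.frame given as \code{protein}); role must be \code{"activator"} or
#'   \code{"repressor"}. Identifiers are whitespace-trimmed and matched
#'   case-sensitively.
#' @param aliases optional named character vector mapping alternative protein
#'   spellings (e.g. antibody names) to the canonical identifiers; applied
#'   before validation.
#' @return A \linkS4class{PathwayAnnotation}.
#' @export
PathwayAnnotation <- function(protein, pathway = NULL, role = NULL,
                              aliases = NULL) {
    if (is.data.frame(protein) || is(protein, "DataFrame")) {
        df <- as.data.frame(protein)
        protein <- df$protein; pathway <- df$pathway; role <- df$role
    }
    protein <- trimws(as.character(protein))
    pathway <- trimws(as.character(pathway))
    role <- trimws(as.character(role))
    if (!is.null(aliases)) {
        hit <- protein %in% names(aliases)
        protein[hit] <- unname(aliases[protein[hit]])
    }
    new("PathwayAnnotation",
        DataFrame(protein = protein, pathway = pathway, role = role))
}

setMethod("show", "PathwayAnnotation", function(object) {
    tab <- table(object$pathway, object$role)
    cat(sprintf("PathwayAnnotation: %d proteins, %d pathways\n",
                length(unique(object$protein)), nrow(tab)))
    for (p in rownames(tab))
        cat(sprintf("  %s: %d activators, %d repressors\n", p,
                    if ("activator" %in% colnames(tab)) tab[p, "activator"] else 0L,
                    if ("repressor" %in% colnames(tab)) tab[p, "repressor"] else 0L))
})

#' Read a pathway-role annotation from delimited text
#'
#' Expects a header row and columns \code{protein}, \code{pathway},
#' \code{role}; roles other than activator/repressor are rejected with the
#' offending row numbers.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param aliases optional alias map, see \code{\link{PathwayAnnotation}}.
#' @return A validated \linkS4class{PathwayAnnotation}.
#' @export
readPathwayAnnotation <- function(path, sep = "\t", aliases = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                             comment.char = "", stringsAsFactors = FALSE)
    miss <- setdiff(c("protein", "pathway", "role"), colnames(tab))
    if (length(miss))
        stop("schema error: annotation lacks column(s): ",
             paste(miss, collapse = ", "))
    PathwayAnnotation(tab, aliases = aliases)
}

#' @param x a \linkS4class{PathwayAnnotation}.
#' @rdname readPathwayAnnotation
#' @return \code{writePathwayAnnotation}: \code{path}, invisibly.
#' @export
writePathwayAnnotation <- function(x, path, sep = "\t") {
    stopifnot(is(x, "PathwayAnnotation"))
    utils::write.table(as.data.frame(x), path, sep = sep, quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Per-pathway census of measured annotated proteins
#'
#' For each pathway, counts annotated proteins with at least one non-missing
#' measurement in the effect table, split by role, and lists annotated
#' proteins never measured.
#'
#' @param ann a \linkS4class{PathwayAnnotation}.
#' @param effects an \linkS4class{EffectTable} sharing the protein namespace.
#' @return A list with \code{counts} (data.frame: pathway, n_activators,
#'   n_repressors, n_measured) and \code{unmeasured} (character vector).
#' @export
pathwayCensus <- function(ann, effects) {
    stopifnot(is(ann, "PathwayAnnotation"), is(effects, "EffectTable"))
    measured_any <- rownames(effects)[rowSums(!assay(effects, "missing")) > 0]
    if (!length(intersect(unique(ann$protein), rownames(effects))))
        stop("no overlap between annotation and effect-table proteins; ",
             "check identifier conventions (see the 'aliases' argument)")
    is_meas <- ann$protein %in% measured_any
    counts <- do.call(rbind, lapply(split(seq_len(nrow(ann)), ann$pathway),
        function(i) {
            data.frame(
                pathway = ann$pathway[i[1L]],
                n_activators = sum(is_meas[i] & ann$role[i] == "activator"),
                n_repressors = sum(is_meas[i] & ann$role[i] == "repressor"),
                n_measured = sum(is_meas[i]))
        }))
    rownames(counts) <- NULL
    list(counts = counts,
         unmeasured = sort(unique(ann$protein[!is_meas])))
}
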