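#' Construct a ScreenExperiment from spot-level records
#'
#' Builds the antibody x spot matrices from a long table with one row per
#' printed spot.
#'
#' @param records data.frame with columns \code{sample_id}, \code{condition},
#'   \code{replicate}, \code{spot}, \code{block}, \code{round},
#'   \code{antibody_id}, \code{signal}, \code{total_protein},
#'   \code{is_control}, \code{control_kind}. \code{spot} and \code{round}
#'   default to 1 when absent.
#' @param normalized logical; mark the signals as already normalized.
#' @return A \linkS4class{ScreenExperiment}.
#' @export
ScreenExperiment <- function(records, normalized = FALSE) {
    records <- as.data.frame(records)
    if (is.null(records$spot)) records$spot <- 1L
    if (is.null(records$round)) records$round <- 1L
    needed <- c("sample_id", "condition", "replicate", "spot", "block",
                "round", "antibody_id", "signal", "total_protein",
                "is_control", "control_kind")
    miss <- setdiff(needed, colnames(records))
    if (length(miss))
        stop("records lack column(s): ", paste(miss, collapse = ", "))
    for (col in c("sample_id", "condition", "block", "round", "antibody_id",
                  "control_kind"))
        records[[col]] <- trimws(as.character(records[[col]]))
    col_key <- paste(records$sample_id, records$spot, sep = ".s")
    cols <- unique(col_key)
    abs <- sort(unique(records$antibody_id))
    idx <- cbind(match(records$antibody_id, abs), match(col_key, cols))
    if (anyDuplicated(idx))
        stop("duplicated (antibody, sample, spot) record(s)")
    sig <- tp <- matrix(NA_real_, length(abs), length(cols),
                        dimnames = list(abs, cols))
    sig[idx] <- records$signal
    tp[idx] <- records$total_protein
    first <- !duplicated(col_key)
    cd <- DataFrame(
        sample_id = records$sample_id[first],
        condition = records$condition[first],
        replicate = as.integer(records$replicate[first]),
        spot = as.integer(records$spot[first]),
        block = records$block[first],
        round = records$round[first],
        is_control = as.logical(records$is_control[first]),
        control_kind = records$control_kind[first],
        row.names = cols)
    new("ScreenExperiment",
        SummarizedExperiment(
            assays = SimpleList(signal = sig, totalProtein = tp),
            colData = cd),
        normalized = normalized)
}

#' @rdname isNormalized
#' @export
setMethod("isNormalized", "ScreenExperiment", function(object)
    object@normalized)

setMethod("show", "ScreenExperiment", function(object) {
    callNextMethod()
    cat("normalized:", object@normalized, "\n")
    cd <- colData(object)
    cat(sprintf("conditions: %d (%d control, %d miRNA); blocks: %d; rounds: %d\n",
        length(unique(cd$condition)),
        length(unique(cd$condition[cd$is_control])),
        length(unique(cd$condition[!cd$is_control])),
        length(unique(cd$block)), length(unique(cd$round))))
})

.default_schema <- c(
    sample_id = "sample_id", condition = "condition",
    replicate = "replicate", spot = "spot", block = "block", round = "round",
    antibody_id = "antibody_id", signal = "signal",
    total_protein = "total_protein", is_control = "is_control",
    control_kind = "control_kind")

#' Read a spot-level raw-signal table
#'
#' Reads a delimited text file (one row per printed spot), maps its columns
#' onto the canonical schema, validates every record and returns a
#' \linkS4class{ScreenExperiment}. Rows failing validation are reported with
#' their file line numbers.
#'
#' @param path path to a delimited text file with a header row.
#' @param schema named character vector mapping canonical field names
#'   (\code{sample_id}, \code{condition}, \code{replicate}, \code{spot},
#'   \code{block}, \code{round}, \code{antibody_id}, \code{signal},
#'   \code{total_protein}, \code{is_control}, \code{control_kind}) to the
#'   file's column names; only names that differ from the default need to be
#'   given. \code{spot} and \code{round} are optional file columns.
#' @param sep field separator (default tab).
#' @param normalized logical; mark signals as already normalized.
#' @return A validated \linkS4class{ScreenExperiment}.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeRawSignals(simulateScreen(simConfig(nMirnas = 4, nPlantedPerPathway = 1, seed = 1))$signals, f)
#' se <- readRawSignals(f)
#' @export
readRawSignals <- function(path, schema = character(), sep = "\t",
                           normalized = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path)
    sch <- .default_schema
    sch[names(schema)] <- schema
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             colClasses = "character", check.names = FALSE,
                             quote = "", comment.char = "")
    required <- setdiff(names(sch), c("spot", "round"))
    miss <- setdiff(sch[required], colnames(tab))
    if (length(miss))
        stop("schema error: file lacks mapped column(s): ",
             paste(miss, collapse = ", "))
    out <- data.frame(row.names = seq_len(nrow(tab)))
    for (field in names(sch)) {
        if (sch[[field]] %in% colnames(tab))
            out[[field]] <- tab[[sch[[field]]]]
        else if (field %in% c("spot", "round"))
            out[[field]] <- "1"
    }
    # line numbers: +1 for the header row
    line_no <- seq_len(nrow(out)) + 1L
    bad <- character()
    for (field in c("signal", "total_protein", "replicate", "spot")) {
        v <- suppressWarnings(as.numeric(out[[field]]))
        nonnum <- !is.na(out[[field]]) & out[[field]] != "NA" &
            nzchar(out[[field]]) & is.na(v)
        if (any(nonnum))
            bad <- c(bad, sprintf("line %d: non-numeric %s '%s'",
                                  line_no[nonnum], field,
                                  out[[field]][nonnum]))
        out[[field]] <- v
    }
    lg <- tolower(out$is_control) %in% c("true", "t", "1", "yes")
    notlg <- !tolower(out$is_control) %in%
        c("true", "t", "1", "yes", "false", "f", "0", "no")
    if (any(notlg))
        bad <- c(bad, sprintf("line %d: is_control not logical: '%s'",
                              line_no[notlg], out$is_control[notlg]))
    out$is_control <- lg
    badtp <- !is.na(out$total_protein) & out$total_protein <= 0
    if (any(badtp))
        bad <- c(bad, sprintf("line %d: total_protein must be > 0 (got %s)",
                              line_no[badtp], out$total_protein[badtp]))
    if (length(bad))
        stop("parse error in ", path, ":\n  ",
             paste(utils::head(bad, 20L), collapse = "\n  "))
    ScreenExperiment(out, normalized = normalized)
}

#' Write a ScreenExperiment as a spot-level delimited table
#'
#' Inverse of \code{\link{readRawSignals}}: one row per (antibody, spot).
#'
#' @param x a \linkS4class{ScreenExperiment}.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return \code{path}, invisibly.
#' @export
writeRawSignals <- function(x, path, sep = "\t") {
    stopifnot(is(x, "ScreenExperiment"))
    cd <- as.data.frame(colData(x))
    sig <- assay(x, "signal")
    tp <- assay(x, "totalProtein")
    long <- data.frame(
        sample_id = rep(cd$sample_id, each = nrow(x)),
        condition = rep(cd$condition, each = nrow(x)),
        replicate = rep(cd$replicate, each = nrow(x)),
        spot = rep(cd$spot, each = nrow(x)),
        block = rep(cd$block, each = nrow(x)),
        round = rep(cd$round, each = nrow(x)),
        antibody_id = rep(rownames(x), times = ncol(x)),
        signal = as.vector(sig),
        total_protein = as.vector(tp),
        is_control = rep(cd$is_control, each = nrow(x)),
        control_kind = rep(cd$control_kind, each = nrow(x)))
    long <- long[!is.na(long$signal), , drop = FALSE]
    utils::write.table(long, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
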