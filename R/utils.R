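# shared internal helpers

# percentage of num/den truncated (not rounded) to two decimals, matching
# the convention of the published census tables; 0 when den == 0
pctTrunc <- function(num, den) {
    out <- ifelse(den == 0, 0, floor(1e4 * num / den + 1e-9) / 100)
    as.numeric(out)
}

nbarcNames <- c("NB-ARC", "PF00931")

stopValidation <- function(...) {
    stop(structure(class = c("nlrValidationError", "error", "condition"),
                   list(message = paste0(...), call = sys.call(-1))))
}

#' Write a result table with a run-metadata header
#'
#' All tabular outputs carry a '#'-prefixed metadata block: package
#' version, the coordinate convention, the thresholds applied, and an md5
#' checksum for every input file the result was derived from.
#'
#' @param df data.frame-like table to write.
#' @param path output path (tab-separated, header line after metadata).
#' @param thresholds optional [NLRThresholds-class] recorded in the header.
#' @param inputs optional character vector of input file paths to checksum.
#' @param extra optional named list of further metadata fields.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(df, path, thresholds = NULL,
                             inputs = character(), extra = list()) {
    df <- as.data.frame(df)
    listish <- vapply(df, is.list, TRUE)
    df[listish] <- lapply(df[listish], function(col)
        vapply(col, function(x) paste(x, collapse = ","), ""))
    hdr <- c(sprintf("# NLRIDscan %s",
                     as.character(packageVersion("NLRIDscan"))),
             "# coordinates: 1-based, closed intervals (bp and aa)")
    if (!is.null(thresholds)) {
        v <- thresholdValues(thresholds)
        hdr <- c(hdr, sprintf("# threshold %s=%s", names(v),
                              vapply(v, format, "")))
    }
    if (length(extra))
        hdr <- c(hdr, sprintf("# %s=%s", names(extra),
                              vapply(extra, function(x)
                                  paste(format(x), collapse = ","), "")))
    for (f in inputs)
        hdr <- c(hdr, sprintf("# input %s md5=%s", basename(f),
                              unname(md5sum(f))))
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(hdr, con)
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE, col.names = TRUE))
    invisible(path)
}

#' Read a result table written by writeResultTable
#' @param path file path.
#' @return data.frame (metadata lines skipped).
#' @export
readResultTable <- function(path) {
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
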