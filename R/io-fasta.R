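#' Read a genome from a multi-record FASTA file
#'
#' Wraps \code{\link[Biostrings]{readDNAStringSet}} with strict validation:
#' sequences must consist of A, C, G, T or N (case-insensitive; normalized to
#' upper case), and malformed headers or illegal characters are reported with
#' the offending line number.  Record order is preserved and wrapped sequence
#' lines are concatenated.
#'
#' @param path path to a FASTA file.
#' @return a \link[Biostrings]{DNAStringSet}, upper-cased, named by the first
#'   whitespace-delimited token of each header.
#' @export
#' @importFrom Biostrings readDNAStringSet DNAStringSet writeXStringSet
readGenomeFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, warn = FALSE)
    inRecord <- FALSE
    for (i in seq_along(lines)) {
        ln <- lines[[i]]
        if (!nzchar(ln)) next
        if (startsWith(ln, ">")) {
            if (!nzchar(trimws(substring(ln, 2L))))
                stop(sprintf("FASTA format error at line %d: empty header", i))
            inRecord <- TRUE
        } else {
            if (!inRecord)
                stop(sprintf("FASTA format error at line %d: sequence before any header", i))
            if (grepl("[^ACGTNacgtn]", ln))
                stop(sprintf("FASTA format error at line %d: illegal character in sequence", i))
        }
    }
    if (!inRecord) stop("FASTA format error: no records in ", path)
    x <- readDNAStringSet(path)
    names(x) <- sub("\\s.*$", "", names(x))
    DNAStringSet(toupper(as.character(x)))
}

#' Write sequences to FASTA
#'
#' @param x DNAStringSet or named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return invisibly, \code{path}.
#' @export
writeGenomeFasta <- function(x, path, width = 70L) {
    if (is.character(x)) x <- DNAStringSet(toupper(x))
    writeXStringSet(x, filepath = path, width = width)
    invisible(path)
}
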