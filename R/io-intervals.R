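#' Read genome features from BED or GFF3 into a FeatureSet
#'
#' BED (0-based half-open) and GFF3 (1-based closed) are both converted at
#' this boundary into the package's internal GRanges convention by
#' \code{\link[rtracklayer]{import}}; strand "." becomes unstranded ("*").
#' Records whose coordinates are inconsistent (GFF3 end < start; BED
#' end <= start) raise a record-level error naming the line.
#'
#' @param path path to the annotation file.
#' @param format "bed" or "gff3".
#' @param name feature-set name (defaults to the file base name).
#' @param window per-side window expansion in nucleotides (default 0).
#' @return a \linkS4class{FeatureSet}.
#' @export
#' @importFrom rtracklayer import export
readFeatures <- function(path, format = c("bed", "gff3"), name = NULL,
                         window = 0L) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("no such file: ", path)
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
    lines <- readLines(path, warn = FALSE)
    for (i in seq_along(lines)) {
        ln <- lines[[i]]
        if (!nzchar(ln) || startsWith(ln, "#") || startsWith(ln, "track") ||
            startsWith(ln, "browser")) next
        f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
        if (format == "bed") {
            if (length(f) < 3L)
                stop(sprintf("BED format error at line %d: fewer than 3 columns", i))
            s <- suppressWarnings(as.integer(f[2L])); e <- suppressWarnings(as.integer(f[3L]))
            if (is.na(s) || is.na(e) || e <= s || s < 0L)
                stop(sprintf("BED record error at line %d: need 0 <= start < end", i))
        } else {
            if (length(f) < 8L)
                stop(sprintf("GFF3 format error at line %d: fewer than 8 columns", i))
            s <- suppressWarnings(as.integer(f[4L])); e <- suppressWarnings(as.integer(f[5L]))
            if (is.na(s) || is.na(e) || e < s || s < 1L)
                stop(sprintf("GFF3 record error at line %d: need 1 <= start <= end", i))
        }
    }
    gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
    gr <- granges(gr, use.mcols = TRUE)
    FeatureSet(name = name, ranges = gr, window = window)
}

#' Write a FeatureSet (or GRanges) to BED
#'
#' Output is reproducibly ordered by (chromosome, start).  The window is a
#' property of the analysis, not of the intervals, and is not applied here.
#'
#' @param x FeatureSet or GRanges.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeFeaturesBed <- function(x, path) {
    gr <- BiocGenerics::sort(.asGRanges(x), ignore.strand = TRUE)
    rtracklayer::export(gr, path, format = "bed")
    invisible(path)
}
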