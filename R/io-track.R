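#' Read a per-base conservation score track
#'
#' Accepts wiggle (fixedStep / variableStep) or bedGraph; the format is
#' sniffed from the first data line and parsed by
#' \code{\link[rtracklayer]{import}}.  Wiggle's 1-based starts and bedGraph's
#' 0-based half-open runs are converted into a per-chromosome vector of
#' per-base scores.  Positions without data carry \code{NA} (missing is not
#' zero).  Any score outside [0,1] is a format error.
#'
#' @param path path to a .wig/.bedGraph file.
#' @return a \linkS4class{ScoreTrack}.
#' @export
readScoreTrack <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, warn = FALSE)
    dataLines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                       !startsWith(lines, "track") & !startsWith(lines, "browser")]
    if (!length(dataLines)) stop("score track is empty: ", path)
    isWig <- any(startsWith(dataLines, "fixedStep") |
                 startsWith(dataLines, "variableStep"))
    gr <- rtracklayer::import(path, format = if (isWig) "wig" else "bedGraph")
    sc <- mcols(gr)$score
    if (any(sc < 0 | sc > 1))
        stop("score track format error: score outside [0,1] in ", path)
    scores <- list()
    for (chrom in unique(as.character(seqnames(gr)))) {
        g <- gr[as.character(seqnames(gr)) == chrom]
        v <- rep(NA_real_, max(end(g)))
        for (i in seq_along(g))
            v[start(g)[i]:end(g)[i]] <- mcols(g)$score[i]
        scores[[chrom]] <- v
    }
    ScoreTrack(scores)
}

#' Write a ScoreTrack as fixedStep wiggle
#'
#' Runs of consecutive scored positions are emitted as fixedStep step=1
#' stanzas; \code{NA} positions are simply not covered.
#'
#' @param x a \linkS4class{ScoreTrack}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeScoreTrack <- function(x, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (chrom in names(x@scores)) {
        v <- x@scores[[chrom]]
        r <- rle(!is.na(v))
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (j in which(r$values)) {
            writeLines(sprintf("fixedStep chrom=%s start=%d step=1", chrom,
                               starts[j]), con)
            writeLines(sprintf("%.10g", v[starts[j]:ends[j]]), con)
        }
    }
    invisible(path)
}

#' Extract per-base scores from a track
#'
#' @param x a \linkS4class{ScoreTrack}.
#' @param chrom chromosome name.
#' @param start,end 1-based closed range; clipped at position 1, and positions
#'   beyond the stored track return \code{NA}.
#' @return numeric vector of length \code{end - start + 1} (after clipping at
#'   1), with \code{NA} at uncovered positions.
#' @export
trackValues <- function(x, chrom, start, end) {
    start <- max(1L, as.integer(start)); end <- as.integer(end)
    if (end < start) return(numeric(0))
    v <- x@scores[[chrom]]
    out <- rep(NA_real_, end - start + 1L)
    if (is.null(v)) return(out)
    upto <- min(end, length(v))
    if (upto >= start) out[seq_len(upto - start + 1L)] <- v[start:upto]
    out
}
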