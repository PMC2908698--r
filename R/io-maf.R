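#' Read alignment blocks from a MAF file
#'
#' Parses "a"/"s" lines of a Multiple Alignment Format file ("i", "e", "q" and
#' comment lines are ignored).  Blocks lacking the reference species are
#' dropped (their number is recorded in the \code{"dropped"} attribute).
#' Blocks whose reference row is on the minus strand are reverse-complemented
#' to reference-forward at read time, so downstream code can assume
#' reference-forward blocks.  MAF 0-based starts are converted to the internal
#' 1-based convention.
#'
#' Species are taken as the part of the \code{src} field before the first dot
#' ("db.chrom" convention); the reference chromosome is the part after it (or
#' the whole \code{src} if it contains no dot).
#'
#' @param path path to a MAF file.
#' @param refSpecies reference species name appearing in the \code{src} field.
#' @return list of \linkS4class{AlignmentBlock}, with attribute
#'   \code{"dropped"} counting blocks excluded for lacking the reference.
#' @export
readMaf <- function(path, refSpecies) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, warn = FALSE)
    blocks <- list()
    dropped <- 0L
    cur <- NULL
    flush <- function(cur) {
        if (is.null(cur) || length(cur$species) == 0L) return(NULL)
        if (!refSpecies %in% cur$species) return(NA)  # signal drop
        if (length(unique(nchar(cur$text))) != 1L)
            stop(sprintf("MAF format error: rows of unequal column length in block starting at line %d",
                         cur$line))
        i <- match(refSpecies, cur$species)
        rows <- cur$text
        names(rows) <- cur$species
        start1 <- cur$start[i] + 1L
        if (cur$strand[i] == "-") {
            # reverse-complement all rows; re-anchor the reference start on
            # the forward strand: forwardStart0 = srcSize - (start0 + size)
            rows <- vapply(rows, function(s) .reverseComplement(s), character(1))
            start1 <- cur$srcSize[i] - (cur$start[i] + cur$size[i]) + 1L
        }
        AlignmentBlock(refSpecies = refSpecies, refChrom = cur$chrom[i],
                       refStart = start1, rows = rows)
    }
    push <- function(cur) {
        b <- flush(cur)
        if (is.null(b)) return(invisible(NULL))
        if (identical(b, NA)) dropped <<- dropped + 1L
        else blocks[[length(blocks) + 1L]] <<- b
        invisible(NULL)
    }
    for (i in seq_along(lines)) {
        ln <- trimws(lines[[i]])
        if (!nzchar(ln) || startsWith(ln, "#")) next
        if (startsWith(ln, "a")) {
            push(cur)
            cur <- list(line = i, species = character(), chrom = character(),
                        start = integer(), size = integer(),
                        strand = character(), srcSize = integer(),
                        text = character())
        } else if (startsWith(ln, "s ") || startsWith(ln, "s\t")) {
            if (is.null(cur))
                stop(sprintf("MAF format error at line %d: 's' line outside a block", i))
            f <- strsplit(ln, "[ \t]+")[[1L]]
            if (length(f) < 7L)
                stop(sprintf("MAF format error at line %d: malformed 's' line", i))
            src <- f[2L]
            sp <- sub("\\..*$", "", src)
            chrom <- if (grepl(".", src, fixed = TRUE)) sub("^[^.]*\\.", "", src) else src
            cur$species <- c(cur$species, sp)
            cur$chrom <- c(cur$chrom, chrom)
            cur$start <- c(cur$start, as.integer(f[3L]))
            cur$size <- c(cur$size, as.integer(f[4L]))
            cur$strand <- c(cur$strand, f[5L])
            cur$srcSize <- c(cur$srcSize, as.integer(f[6L]))
            cur$text <- c(cur$text, toupper(f[7L]))
        }
        # i/e/q lines ignored
    }
    push(cur)
    attr(blocks, "dropped") <- dropped
    blocks
}

#' Write alignment blocks to MAF
#'
#' Reference rows carry their genomic anchor; non-reference rows are written
#' with block-local coordinates (start 0, srcSize = ungapped length), which is
#' sufficient for the round trip of blocks produced by this package.
#'
#' @param blocks list of \linkS4class{AlignmentBlock}.
#' @param path output path.
#' @param chromLengths optional named integer vector giving reference
#'   chromosome lengths for the srcSize field.
#' @return invisibly, \code{path}.
#' @export
writeMaf <- function(blocks, path, chromLengths = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##maf version=1 scoring=none", con)
    for (b in blocks) {
        writeLines("a score=0", con)
        rows <- alignmentRows(b)
        for (sp in names(rows)) {
            gapless <- nchar(gsub("-", "", rows[[sp]], fixed = TRUE))
            if (sp == b@refSpecies) {
                srcSize <- if (!is.null(chromLengths) && b@refChrom %in% names(chromLengths))
                    chromLengths[[b@refChrom]] else b@refStart - 1L + gapless
                writeLines(sprintf("s %s.%s %d %d + %d %s", sp, b@refChrom,
                                   b@refStart - 1L, gapless, srcSize, rows[[sp]]), con)
            } else {
                writeLines(sprintf("s %s 0 %d + %d %s", sp, gapless, gapless,
                                   rows[[sp]]), con)
            }
        }
        writeLines("", con)
    }
    invisible(path)
}
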