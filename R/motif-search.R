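#' Find maximal G-tracts in a sequence
#'
#' A G-tract is a maximal run of consecutive guanines of length at least
#' \code{minTract}; runs of 7 G's are one tract, never two.  N never matches
#' and terminates any run.
#'
#' @param seq character scalar or DNAString (normalized to upper case).
#' @param minTract minimum run length (default 3).
#' @return an \link[IRanges]{IRanges} of tract positions (1-based closed),
#'   in order; empty when no run qualifies.
#' @export
findGTracts <- function(seq, minTract = 3L) {
    .findRuns(toupper(as.character(seq)), "G", minTract)
}

.findRuns <- function(seq, base, minTract) {
    m <- gregexpr(sprintf("%s{%d,}", base, minTract), seq)[[1L]]
    if (m[1L] == -1L) return(IRanges())
    IRanges(start = as.integer(m), width = attr(m, "match.length"))
}

#' Chain G-tracts into G4 motifs
#'
#' Greedy left-to-right chaining: consecutive tracts stay in one chain while
#' the gap (loop) between them is \code{<= maxLoop}; every maximal chain of
#' four or more tracts becomes exactly one motif spanning first-tract start to
#' last-tract end (a region with more than four close G-tracts is a single
#' motif, not several).  Chains of fewer than four tracts emit nothing.
#' Because maximal tracts cannot be adjacent, every loop has length >= 1.
#'
#' @param tracts IRanges of ordered maximal tracts from one sequence/strand.
#' @param maxLoop maximum loop length in nucleotides.
#' @param minTract minimum tract length (recorded, not re-checked).
#' @return list with \code{spans} (IRanges of motif extents) and \code{tracts}
#'   (IRangesList, one element per motif).
#' @export
groupTracts <- function(tracts, maxLoop = 25L, minTract = 3L) {
    if (length(tracts) == 0L)
        return(list(spans = IRanges(), tracts = IRangesList()))
    n <- length(tracts)
    gaps <- if (n > 1L) start(tracts)[-1L] - end(tracts)[-n] - 1L else integer()
    grp <- cumsum(c(1L, as.integer(gaps > maxLoop)))
    keep <- which(tabulate(grp) >= 4L)
    if (!length(keep))
        return(list(spans = IRanges(), tracts = IRangesList()))
    tl <- lapply(keep, function(g) tracts[grp == g])
    spans <- IRanges(start = vapply(tl, function(t) start(t)[1L], integer(1)),
                     end = vapply(tl, function(t) end(t)[length(t)], integer(1)))
    list(spans = spans, tracts = IRangesList(tl))
}

#' Scan a genome for G4 DNA motifs
#'
#' Finds motifs of four or more G-tracts (maximal runs of >= \code{minTract}
#' guanines) separated by loops of at most \code{maxLoop} nucleotides.
#' Forward-strand motifs come from the sequence as scanned; minus-strand
#' motifs are the G4 motifs of the reverse complement, reported on the forward
#' axis (equivalently: runs of cytosines chained by the same rule).  Output is
#' sorted by (chromosome, start, strand).
#'
#' @param genome DNAStringSet or named character vector of chromosome
#'   sequences.
#' @param minTract minimum G-tract length (default 3).
#' @param maxLoop maximum loop length (default 25; the longest loop observed
#'   in a characterized quadruplex is 22 nt).
#' @param strands "both" (default) or "forward".
#' @return a \linkS4class{G4MotifSet}.
#' @export
scanG4Motifs <- function(genome, minTract = 3L, maxLoop = 25L,
                         strands = c("both", "forward")) {
    strands <- match.arg(strands)
    stopifnot(maxLoop >= 1L, minTract >= 1L)
    seqs <- .asSeqVector(genome)
    chromv <- character(); strandv <- character()
    spans <- list(); tracts <- list()
    for (chrom in names(seqs)) {
        s <- seqs[[chrom]]
        bases <- if (strands == "both") c("+" = "G", "-" = "C") else c("+" = "G")
        for (st in names(bases)) {
            g <- groupTracts(.findRuns(s, bases[[st]], minTract),
                             maxLoop = maxLoop, minTract = minTract)
            if (length(g$spans) == 0L) next
            chromv <- c(chromv, rep(chrom, length(g$spans)))
            strandv <- c(strandv, rep(st, length(g$spans)))
            spans[[length(spans) + 1L]] <- g$spans
            tracts <- c(tracts, as.list(g$tracts))
        }
    }
    if (length(chromv)) {
        gr <- GRanges(chromv, do.call(c, spans), strand = strandv)
        mcols(gr)$tracts <- IRangesList(tracts)
        gr <- gr[order(as.character(seqnames(gr)), start(gr), as.character(strand(gr)))]
        mcols(gr)$motif_id <- sprintf("%s:%d-%d:%s", as.character(seqnames(gr)),
                                      start(gr), end(gr), as.character(strand(gr)))
        mcols(gr) <- mcols(gr)[, c("motif_id", "tracts")]
    } else {
        gr <- GRanges()
        mcols(gr)$motif_id <- character(0)
        mcols(gr)$tracts <- IRangesList()
    }
    G4MotifSet(gr, scanConfig = list(minTract = as.integer(minTract),
                                     maxLoop = as.integer(maxLoop),
                                     strands = strands))
}

#' Filter a motif set by genomic masks
#'
#' Applies the bookkeeping used before conservation analysis: motifs with
#' >= 1 bp overlap with the telomeric/subtelomeric mask are removed; motifs on
#' mitochondrial chromosomes are removed when nuclear-only analysis is
#' requested; and when the genome assembly carries multiple copies of the
#' rDNA repeat, motifs from all but one designated copy are removed so the
#' repeat is counted once.  Removal counts per reason are stored in
#' \code{metadata(motifRanges(result))$filterCounts}.
#'
#' @param x a \linkS4class{G4MotifSet}.
#' @param telomeres FeatureSet/GRanges mask of telomeric regions, or NULL.
#' @param excludeMitochondrial drop motifs on mitochondrial chromosomes?
#' @param mitochondrialChroms chromosome names treated as mitochondrial
#'   (default: auto-detected with \code{\link{isMitochondrialName}}).
#' @param rdnaRepeats GRanges with one range per rDNA repeat copy, or NULL.
#' @param rdnaKeep index (into \code{rdnaRepeats}) of the copy to keep.
#' @return the filtered \linkS4class{G4MotifSet}.
#' @export
#' @importFrom GenomicRanges seqnames
#' @importFrom IRanges overlapsAny
filterG4Motifs <- function(x, telomeres = NULL, excludeMitochondrial = FALSE,
                           mitochondrialChroms = NULL, rdnaRepeats = NULL,
                           rdnaKeep = 1L) {
    gr <- motifRanges(x)
    chroms <- unique(as.character(seqnames(gr)))
    counts <- c(telomeric = 0L, mitochondrial = 0L, rdna_duplicate = 0L)
    drop <- rep(FALSE, length(gr))
    .checkMask <- function(mask, what) {
        mn <- as.character(seqnames(mask))
        unknown <- setdiff(unique(mn), chroms)
        if (length(unknown)) {
            warning(sprintf("%s mask names unknown chromosome(s) %s; those entries ignored",
                            what, paste(unknown, collapse = ", ")))
            keep <- !mn %in% unknown
            # rebuild so stale seqlevels do not linger in overlap operations
            mask <- GRanges(mn[keep], IRanges(start(mask)[keep], end(mask)[keep]),
                            strand = strand(mask)[keep])
        }
        mask
    }
    if (!is.null(telomeres)) {
        tg <- .checkMask(.asGRanges(telomeres), "telomere")
        hit <- overlapsAny(gr, tg, ignore.strand = TRUE)
        counts["telomeric"] <- sum(hit & !drop)
        drop <- drop | hit
    }
    if (excludeMitochondrial) {
        mito <- if (is.null(mitochondrialChroms))
            chroms[isMitochondrialName(chroms)] else mitochondrialChroms
        hit <- as.character(seqnames(gr)) %in% mito
        counts["mitochondrial"] <- sum(hit & !drop)
        drop <- drop | hit
    }
    if (!is.null(rdnaRepeats) && length(rdnaRepeats) > 1L) {
        rg <- .checkMask(.asGRanges(rdnaRepeats), "rDNA")
        dup <- rg[-rdnaKeep]
        keepCopy <- rg[rdnaKeep]
        hit <- overlapsAny(gr, dup, ignore.strand = TRUE) &
               !overlapsAny(gr, keepCopy, ignore.strand = TRUE)
        counts["rdna_duplicate"] <- sum(hit & !drop)
        drop <- drop | hit
    }
    res <- gr[!drop]
    metadata(res)$filterCounts <- counts
    G4MotifSet(res, scanConfig = scanConfig(x))
}

#' @describeIn filterG4Motifs removal counts per reason, or NULL
#' @export
filterCounts <- function(x) metadata(motifRanges(x))$filterCounts

#' Physical properties of each motif
#'
#' For every motif: total length, number of G-tracts and loops, mean tract
#' and loop lengths, and the number of stacked G-quartets its most stable
#' four-tract window supports (the maximum over all windows of four
#' consecutive tracts of the minimum tract length in the window).
#'
#' @param x a \linkS4class{G4MotifSet}.
#' @return a \link[S4Vectors]{DataFrame} with one row per motif.
#' @export
motifProperties <- function(x) {
    gr <- motifRanges(x)
    tr <- motifTracts(x)
    n <- length(gr)
    nTracts <- lengths(tr)
    meanTract <- vapply(seq_len(n), function(i) mean(width(tr[[i]])), numeric(1))
    meanLoop <- vapply(seq_len(n), function(i) {
        t <- tr[[i]]
        mean(start(t)[-1L] - end(t)[-length(t)] - 1L)
    }, numeric(1))
    quartets <- vapply(seq_len(n), function(i) {
        w <- width(tr[[i]])
        max(vapply(seq_len(length(w) - 3L),
                   function(j) min(w[j:(j + 3L)]), integer(1)))
    }, integer(1))
    DataFrame(motif_id = mcols(gr)$motif_id,
              chrom = as.character(seqnames(gr)),
              start = start(gr), end = end(gr),
              strand = as.character(strand(gr)),
              length_nt = width(gr),
              n_tracts = nTracts,
              n_loops = nTracts - 1L,
              mean_tract_len = meanTract,
              mean_loop_len = meanLoop,
              stacked_quartets = quartets)
}
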