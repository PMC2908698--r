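# Independent brute-force G4 scanner used as the oracle for the regex/chain
# implementation.  Deliberately takes a different route: character-level run
# detection via rle, explicit chain loop, and minus-strand motifs obtained by
# actually reverse-complementing the string and mapping coordinates back.

oracleRevComp <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
}

# maximal runs of G of length >= minTract, as a data.frame(start, end)
oracleTracts <- function(s, minTract) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    r <- rle(chars == "G")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= minTract
    data.frame(start = starts[keep], end = ends[keep])
}

# explicit left-to-right chain loop; motifs = chains of >= 4 tracts
oracleChain <- function(tr, maxLoop) {
    if (nrow(tr) == 0L) return(data.frame(start = integer(), end = integer()))
    out <- data.frame(start = integer(), end = integer())
    chainStart <- 1L
    for (i in seq_len(nrow(tr))) {
        lastInChain <- i == nrow(tr) ||
            (tr$start[i + 1L] - tr$end[i] - 1L) > maxLoop
        if (lastInChain) {
            if (i - chainStart + 1L >= 4L)
                out <- rbind(out, data.frame(start = tr$start[chainStart],
                                             end = tr$end[i]))
            chainStart <- i + 1L
        }
    }
    out
}

# full oracle scan: data.frame(start, end, strand) sorted (start, strand)
oracleScan <- function(s, minTract = 3L, maxLoop = 25L, strands = "both") {
    fwd <- oracleChain(oracleTracts(s, minTract), maxLoop)
    fwd$strand <- rep("+", nrow(fwd))
    res <- fwd
    if (strands == "both") {
        L <- nchar(s)
        rc <- oracleChain(oracleTracts(oracleRevComp(s), minTract), maxLoop)
        if (nrow(rc)) {
            rev <- data.frame(start = L - rc$end + 1L, end = L - rc$start + 1L,
                              strand = "-")
            res <- rbind(res, rev)
        }
    }
    res[order(res$start, res$strand), , drop = FALSE]
}

# random test sequence at a given GC
randomSeq <- function(n, gc = 0.38) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

# scan result of the package as a comparable data.frame
scanAsDf <- function(set) {
    gr <- motifRanges(set)
    data.frame(start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)))
}

expect_scan_matches_oracle <- function(s, minTract = 3L, maxLoop = 25L,
                                       strands = "both") {
    got <- scanAsDf(scanG4Motifs(c(chr = s), minTract = minTract,
                                 maxLoop = maxLoop, strands = strands))
    want <- oracleScan(s, minTract, maxLoop, strands)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
}
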