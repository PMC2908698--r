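test_that("G-tracts are maximal runs of at least minTract guanines", {
    tr <- findGTracts("GGGTGGGG")
    expect_equal(IRanges::start(tr), c(1L, 5L))
    expect_equal(IRanges::end(tr), c(3L, 8L))
    expect_equal(length(findGTracts("GGTGG")), 0L)
    tr <- findGTracts("GGGGGGG")  # one run of 7, never split
    expect_equal(length(tr), 1L)
    expect_equal(IRanges::width(tr), 7L)
    # N terminates a run and never matches
    tr <- findGTracts("GGGNGGG")
    expect_equal(IRanges::start(tr), c(1L, 5L))
})

test_that("tract chaining merges close tracts into single motifs", {
    tr <- findGTracts("GGGTGGGTGGGTGGG")
    g <- groupTracts(tr, maxLoop = 25L)
    expect_equal(length(g$spans), 1L)
    expect_equal(IRanges::width(g$spans), 15L)
    expect_equal(length(g$tracts[[1]]), 4L)

    # five close tracts are ONE motif with five tracts, not several motifs
    s <- "GGGTGGGTGGGTGGGTGGG"
    g <- groupTracts(findGTracts(s), maxLoop = 25L)
    expect_equal(length(g$spans), 1L)
    expect_equal(length(g$tracts[[1]]), 5L)

    # a gap of maxLoop+1 breaks the chain: 1+3 tracts -> no motif
    s <- paste0("GGG", strrep("A", 11L), "GGGTGGGTGGG")
    g <- groupTracts(findGTracts(s), maxLoop = 10L)
    expect_equal(length(g$spans), 0L)
    # at exactly maxLoop the chain holds
    s <- paste0("GGG", strrep("A", 10L), "GGGTGGGTGGG")
    expect_equal(length(groupTracts(findGTracts(s), maxLoop = 10L)$spans), 1L)
})

test_that("minus-strand motifs are found on the reverse complement", {
    set <- scanG4Motifs(c(c1 = "CCCACCCACCCACCC"))
    gr <- motifRanges(set)
    expect_equal(length(gr), 1L)
    expect_equal(as.character(GenomicRanges::strand(gr)), "-")
    expect_equal(GenomicRanges::start(gr), 1L)
    expect_equal(GenomicRanges::end(gr), 15L)

    # a G-rich motif appears once whether or not the minus strand is scanned
    fwd <- scanG4Motifs(c(c1 = "GGGTGGGTGGGTGGG"), strands = "forward")
    both <- scanG4Motifs(c(c1 = "GGGTGGGTGGGTGGG"), strands = "both")
    expect_equal(scanAsDf(fwd), scanAsDf(both))
})

test_that("scanner agrees with the brute-force oracle on random sequences", {
    set.seed(2024)
    for (i in 1:20) {
        s <- randomSeq(2000, gc = 0.45)
        expect_scan_matches_oracle(s, maxLoop = 10L)
    }
})

test_that("strand symmetry: motifs of the reverse complement map onto minus-strand motifs", {
    set.seed(7)
    for (i in 1:10) {
        s <- randomSeq(3000, gc = 0.5)
        L <- nchar(s)
        a <- scanAsDf(scanG4Motifs(c(c = s)))
        b <- scanAsDf(scanG4Motifs(c(c = oracleRevComp(s))))
        flipped <- data.frame(start = L - b$end + 1L, end = L - b$start + 1L,
                              strand = as.character(ifelse(b$strand == "+", "-", "+")))
        flipped <- flipped[order(flipped$start, flipped$strand), ]
        rownames(a) <- rownames(flipped) <- NULL
        expect_equal(a, flipped)
    }
})

test_that("motif count is non-decreasing in the loop length threshold", {
    set.seed(99)
    for (i in 1:5) {
        s <- randomSeq(20000, gc = 0.45)
        counts <- vapply(c(5L, 10L, 15L, 20L, 25L, 30L, 40L, 50L),
                         function(ml) length(scanG4Motifs(c(c = s), maxLoop = ml)),
                         integer(1))
        expect_true(all(diff(counts) >= 0L))
    }
})

test_that("every emitted motif satisfies the type invariants", {
    set.seed(5)
    s <- randomSeq(50000, gc = 0.5)
    set <- scanG4Motifs(c(c = s), maxLoop = 12L)
    expect_true(validObject(set))  # validity enforces tract/loop invariants
    tr <- motifTracts(set)
    expect_true(all(lengths(tr) >= 4L))
    loops <- unlist(lapply(seq_along(tr), function(i) {
        st <- IRanges::start(tr[[i]]); en <- IRanges::end(tr[[i]])
        st[-1] - en[-length(en)] - 1L
    }))
    expect_true(all(loops >= 1L & loops <= 12L))
})

test_that("mask filtering removes telomeric, mitochondrial and duplicate-rDNA motifs", {
    m <- "GGGTGGGTGGGTGGG"
    pad <- strrep("A", 30)
    chr1 <- paste0(m, pad, m, pad, m, pad)         # motifs at 1, 46, 91
    chrM <- paste0(pad, m, pad)
    genome <- c(chr1 = chr1, chrM = chrM)
    set <- scanG4Motifs(genome, maxLoop = 10L)
    expect_equal(length(set), 4L)

    telo <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 15))
    rdna <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(40, 85), c(70, 115)))
    res <- filterG4Motifs(set, telomeres = telo, excludeMitochondrial = TRUE,
                          rdnaRepeats = rdna, rdnaKeep = 1L)
    expect_equal(unname(filterCounts(res)["telomeric"]), 1L)
    expect_equal(unname(filterCounts(res)["mitochondrial"]), 1L)
    expect_equal(unname(filterCounts(res)["rdna_duplicate"]), 1L)
    expect_equal(length(res), 1L)  # the motif in rDNA copy 1 survives
    expect_equal(GenomicRanges::start(motifRanges(res)), 46L)

    # overlap by a single bp is enough to remove
    telo1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(15, 15))
    res1 <- filterG4Motifs(set, telomeres = telo1)
    expect_equal(unname(filterCounts(res1)["telomeric"]), 1L)

    # a mask on an unknown chromosome warns and is ignored
    teloX <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 100))
    expect_warning(resX <- filterG4Motifs(set, telomeres = teloX), "chrX")
    expect_equal(length(resX), 4L)
})

test_that("filtering bookkeeping matches generator truth", {
    sim <- generateGenome(c(chr1 = 30000L, chrM = 10000L), gc = 0.30,
                          nMotifs = 12L, seed = 21)
    set <- scanG4Motifs(sim$genome)
    truthGr <- motifRanges(sim$truth)
    onM <- as.character(GenomicRanges::seqnames(truthGr)) == "chrM"
    res <- filterG4Motifs(set, excludeMitochondrial = TRUE)
    called <- motifRanges(res)
    # every surviving planted motif is nuclear and recovered exactly once
    ov <- GenomicRanges::countOverlaps(truthGr[!onM], called)
    expect_true(all(ov == 1L))
    expect_equal(unname(filterCounts(res)["mitochondrial"]),
                 sum(as.character(GenomicRanges::seqnames(motifRanges(set))) == "chrM"))
})

test_that("motif properties derive tract geometry and stacked quartets", {
    set <- scanG4Motifs(c(c1 = "GGGTGGGTGGGTGGG"))
    p <- as.data.frame(motifProperties(set))
    expect_equal(p$length_nt, 15L)
    expect_equal(p$n_tracts, 4L)
    expect_equal(p$n_loops, 3L)
    expect_equal(p$mean_tract_len, 3.0)
    expect_equal(p$mean_loop_len, 1.0)
    expect_equal(p$stacked_quartets, 3L)

    # tract lengths [3,3,3,3] -> 3; [5,4,3,4,5] -> windows (5,4,3,4) and
    # (4,3,4,5) both give min 3
    s <- paste0(strrep("G", 5), "T", strrep("G", 4), "T", strrep("G", 3),
                "T", strrep("G", 4), "T", strrep("G", 5))
    p2 <- as.data.frame(motifProperties(scanG4Motifs(c(c1 = s))))
    p2 <- p2[p2$strand == "+", ]
    expect_equal(p2$n_tracts, 5L)
    expect_equal(p2$stacked_quartets, 3L)
})

test_that("set comparison reports per-property stats and the multi-tract Fisher test", {
    # symmetric table has p = 1
    expect_equal(multiTractFisherTest(2, 4, 2, 4, "as_given")$p.value, 1.0)
    # identical sets: rank-sum p 1, odds ratio 1
    set <- scanG4Motifs(c(c1 = paste0("GGGTGGGTGGGTGGG", strrep("A", 30),
                                      "GGGGTGGGTGGGTGGGTGGG")))
    cmp <- compareMotifSets(set, set, fisherConstruction = "as_given")
    expect_true(all(cmp$properties$p.value == 1))
    expect_equal(cmp$fisher$estimate, 1, tolerance = 1e-6)
    # empty set: statistics undefined, not zero
    empty <- scanG4Motifs(c(c1 = "ACGTACGT"))
    cmp0 <- compareMotifSets(empty, set)
    expect_true(cmp0$undefined)
    expect_true(all(is.na(cmp0$properties$meanA)))
})

test_that("the Fisher table construction matches an exact hypergeometric oracle", {
    # P(X = a) for 2x2 tables with fixed margins, summed over tables as or
    # less probable, must equal fisher.test's two-sided p
    ft <- multiTractFisherTest(17, 34, 120, 552, "disjoint")
    a <- 17; b <- 17; c <- 103; d <- 415
    m <- a + b; n <- c + d; k <- a + c
    support <- max(0, k - n):min(m, k)
    dens <- stats::dhyper(support, m, n, k)
    pOracle <- sum(dens[dens <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
    expect_equal(ft$p.value, pOracle, tolerance = 1e-10)
})
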