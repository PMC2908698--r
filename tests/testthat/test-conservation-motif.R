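mkBlock <- function(ref, sp, refStart = 1L, chrom = "c1") {
    AlignmentBlock("ref", chrom, refStart, c(ref = ref, sp = sp))
}

test_that("motif projection maps reference positions through alignment columns", {
    # identity alignment: projection is the identity
    b <- mkBlock("GGGTGGGTGGGTGGG", "GGGTGGGTGGGTGGG")
    m <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 15))
    pr <- projectMotif(b, m, "sp")
    expect_equal(IRanges::start(pr), 1L)
    expect_equal(IRanges::end(pr), 15L)

    # gap in the reference only: species coordinates unaffected before it
    b <- mkBlock("GGG--T", "GGGAAT")
    pr <- projectMotif(b, GenomicRanges::GRanges("c1", IRanges::IRanges(1, 3)), "sp")
    expect_equal(c(IRanges::start(pr), IRanges::end(pr)), c(1L, 3L))

    # motif aligned entirely to species gaps: empty projection
    b <- mkBlock("AAGGGTT", "AA---TT")
    pr <- projectMotif(b, GenomicRanges::GRanges("c1", IRanges::IRanges(3, 5)), "sp")
    expect_equal(length(pr), 0L)

    # motif outside the block is a precondition error
    expect_error(projectMotif(b, GenomicRanges::GRanges("c1", IRanges::IRanges(50, 60)), "sp"),
                 "does not intersect")

    # anchored blocks: offsets respect refStart
    b <- mkBlock("GGGTGGGTGGGTGGG", "GGGTGGGTGGGTGGG", refStart = 101L)
    pr <- projectMotif(b, GenomicRanges::GRanges("c1", IRanges::IRanges(105, 110)), "sp")
    expect_equal(c(IRanges::start(pr), IRanges::end(pr)), c(5L, 10L))
})

test_that("conservation calls scan the degapped species row for the motif pattern", {
    motif <- scanG4Motifs(c(c1 = "GGGTGGGTGGGTGGG"))
    # identical species row: conserved
    b <- mkBlock("GGGTGGGTGGGTGGG", "GGGTGGGTGGGTGGG")
    cc <- callConservation(list(b), motif, "sp")
    expect_equal(cc$call, "conserved")

    # one disruptive G hit in a minimal 4xGGG motif: structure broken
    b <- mkBlock("GGGTGGGTGGGTGGG", "GGGTGAGTGGGTGGG")
    expect_equal(callConservation(list(b), motif, "sp")$call, "not_conserved")

    # conservation does not require identity: different loops/tract count accepted
    b <- mkBlock("GGGTGGGTGGGTGGG", "GGGAGGGTGGGAGGG")
    expect_equal(callConservation(list(b), motif, "sp")$call, "conserved")

    # no overlapping block: unalignable, never not_conserved
    far <- mkBlock("ACGTACGTAA", "ACGTACGTAA", refStart = 5000L)
    expect_equal(callConservation(list(far), motif, "sp")$call, "unalignable")

    # a quadruplex on the complementary strand still counts by default
    b <- mkBlock("GGGTGGGTGGGTGGG", "CCCACCCACCCACCC")
    expect_equal(callConservation(list(b), motif, "sp")$call, "conserved")
    expect_equal(callConservation(list(b), motif, "sp", strands = "forward")$call,
                 "not_conserved")
})

test_that("conserved fraction converges to the planted retention probability", {
    sim <- generateGenome(c(chr1 = 400000L), gc = 0.30, nMotifs = 200L, seed = 1)
    pair <- generateSpeciesPair(sim$genome, sim$truth, divergence = 0.1,
                                retention = 0.6, seed = 2)
    cc <- callConservation(pair$blocks, sim$truth, "sp")
    frac <- mean(cc$call == "conserved")
    # binomial sd ~ 0.035 at n=200; background compensation can only push up
    expect_gte(frac, 0.6 - 3 * sqrt(0.6 * 0.4 / 200))
    expect_lte(frac, 0.6 + 3 * sqrt(0.6 * 0.4 / 200) + 0.05)
    # retained motifs are always called conserved
    expect_true(all(cc$call[pair$truth$retained] == "conserved"))
})

test_that("substitution matrices are estimated from aligned pairs", {
    # a block aligned to itself is near-identity (exactly identity without
    # smoothing mass)
    s <- randomSeq(10000, gc = 0.4)
    b <- mkBlock(s, s)
    P <- probMatrix(estimateSubstitutionMatrix(b, "sp"))
    expect_true(all(diag(P) > 0.99))
    expect_true(all(abs(rowSums(P) - 1) < 1e-9))

    # hand-built block: 200 aligned G columns of which 100 are G->A
    ref <- strrep("G", 200)
    oth <- paste0(strrep("A", 100), strrep("G", 100))
    P <- probMatrix(estimateSubstitutionMatrix(mkBlock(ref, oth), "sp"))
    expect_equal(P["G", "A"], (100 + 1) / (200 + 4), tolerance = 1e-12)
    expect_equal(P["G", "A"], 0.5, tolerance = 0.02)
    # bases never observed in the reference fall back to identity rows
    expect_equal(unname(P["C", "C"]), 1)

    # an all-gap species row is unestimable
    expect_error(estimateSubstitutionMatrix(mkBlock("ACGT", "----"), "sp"),
                 "unestimable")
})

test_that("evolved rows preserve gap structure and follow the matrix", {
    ident <- SubstitutionMatrix(diag(4) |> (\(m) {
        dimnames(m) <- list(c("A","C","G","T"), c("A","C","G","T")); m })())
    b <- mkBlock("ACGTACGTAC", "ACGTACGTAC")
    set.seed(1)
    expect_equal(evolveBlock(b, ident, "sp"), "ACGTACGTAC")

    # gap columns of the real species row reappear at identical columns
    b <- mkBlock("ACGTACGTAC", "AC--ACGT-C")
    set.seed(1)
    ev <- evolveBlock(b, ident, "sp")
    expect_equal(gregexpr("-", ev)[[1]][1:3], c(3L, 4L, 9L))
    expect_equal(nchar(ev), 10L)
    # N positions are copied unchanged
    bN <- mkBlock("ANGT", "ACGT")
    expect_equal(substring(evolveBlock(bN, ident, "sp"), 2, 2), "N")

    # uniform matrix: evolved base composition is uniform regardless of input
    unif <- SubstitutionMatrix(matrix(0.25, 4, 4,
        dimnames = list(c("A","C","G","T"), c("A","C","G","T"))))
    s <- randomSeq(10000, gc = 0.8)
    set.seed(42)
    ev <- evolveBlock(mkBlock(s, s), unif, "sp")
    gfrac <- lengths(regmatches(ev, gregexpr("G", ev))) / nchar(ev)
    expect_equal(unname(gfrac), 0.25, tolerance = 0.02)
})

test_that("the evolutionary null is degenerate under the identity matrix", {
    sim <- generateGenome(c(chr1 = 20000L), gc = 0.30, nMotifs = 20L, seed = 3)
    pair <- generateSpeciesPair(sim$genome, sim$truth, divergence = 0,
                                retention = NULL, seed = 4)
    ident <- SubstitutionMatrix(diag(4) |> (\(m) {
        dimnames(m) <- list(c("A","C","G","T"), c("A","C","G","T")); m })())
    ns <- nullConservedCount(pair$blocks, sim$truth, "sp", nReps = 50L,
                             matrix = ident, seed = 9)
    expect_true(all(nullReplicates(ns) == ns@observed))
    expect_equal(empiricalP(ns), 1.0)
})

test_that("strongly retained planted motifs yield a small empirical p", {
    sim <- generateGenome(c(chr1 = 20000L), gc = 0.30, nMotifs = 40L,
                          loopLenRange = c(1L, 7L), seed = 5)
    pair <- generateSpeciesPair(sim$genome, sim$truth, divergence = 0.1,
                                retention = 0.95, seed = 6)
    ns <- nullConservedCount(pair$blocks, sim$truth, "sp", nReps = 1000L,
                             maxLoop = 10L, seed = 7)
    expect_lte(empiricalP(ns), 0.01)
})

test_that("panel conservation requires every species conserved and alignable", {
    motifs <- scanG4Motifs(c(c1 = paste0("GGGTGGGTGGGTGGG", strrep("A", 40),
                                         "GGGAGGGAGGGAGGG")))
    expect_equal(length(motifs), 2L)
    m1 <- "GGGTGGGTGGGTGGG"
    whole <- paste0(m1, strrep("A", 40), "GGGAGGGAGGGAGGG")
    # species A: both motifs aligned and conserved
    bA <- mkBlock(whole, whole)
    # species B: only the first motif aligned (block covers positions 1-20)
    seg <- substr(whole, 1, 20)
    bB <- mkBlock(seg, seg)
    callA <- callConservation(list(bA), motifs, "sp")
    callB <- callConservation(list(bB), motifs, "sp")
    pan <- panelConservation(list(A = callA, B = callB))
    expect_true(pan$conserved_in_all[1])
    expect_false(pan$alignable_in_all[2])  # excluded from the denominator
    expect_false(pan$conserved_in_all[2])
})

test_that("the null p is invariant to block processing order", {
    sim <- generateGenome(c(chrA = 8000L, chrB = 8000L), gc = 0.30,
                          nMotifs = 16L, seed = 8)
    pair <- generateSpeciesPair(sim$genome, sim$truth, divergence = 0.08,
                                retention = NULL, seed = 9)
    a <- nullConservedCount(pair$blocks, sim$truth, "sp", nReps = 40L, seed = 11)
    b <- nullConservedCount(rev(pair$blocks), sim$truth, "sp", nReps = 40L, seed = 11)
    expect_equal(empiricalP(a), empiricalP(b))
    expect_equal(sort(nullReplicates(a)), sort(nullReplicates(b)))
})
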