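gr <- function(chrom, s, e, strand = "*") {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e), strand = strand)
}

test_that("overlap counting is per query region with half-open-abutment semantics", {
    ref <- FeatureSet("f", gr("c1", c(1, 50), c(30, 80)))
    # queries inside reference intervals all count
    q <- gr("c1", c(5, 55, 70), c(10, 60, 75))
    expect_equal(countOverlappingQueries(q, ref), 3L)
    # disjoint sets count zero
    expect_equal(countOverlappingQueries(gr("c1", 100, 120), ref), 0L)
    # BED [10,20) vs [20,30): abutting, no overlap at window 0; window 1 joins
    q <- gr("c1", 11, 20)          # BED 10..20
    refB <- FeatureSet("g", gr("c1", 21, 30))   # BED 20..30
    expect_equal(countOverlappingQueries(q, refB), 0L)
    expect_equal(countOverlappingQueries(q, FeatureSet("g", gr("c1", 21, 30), 1L)), 1L)
    # multiple reference hits still count the query once
    expect_equal(countOverlappingQueries(gr("c1", 1, 100), ref), 1L)
})

test_that("observed counts are invariant to reference splitting/merging", {
    set.seed(12)
    qs <- sample(1:5000, 50)
    q <- gr("c1", qs, qs + 20)
    refA <- gr("c1", c(100, 200, 210, 1000, 1040), c(205, 300, 260, 1050, 1100))
    refB <- IRanges::reduce(refA)
    expect_equal(countOverlappingQueries(q, FeatureSet("a", refA)),
                 countOverlappingQueries(q, FeatureSet("b", refB)))
})

test_that("strand-aware counting matches same-strand features, '*' matches anything", {
    q <- gr("c1", c(10, 10), c(20, 20), strand = c("+", "-"))
    refPlus <- FeatureSet("p", gr("c1", 15, 25, "+"))
    expect_equal(countOverlappingQueries(q, refPlus, "require_same"), 1L)
    expect_equal(countOverlappingQueries(q, refPlus, "ignore"), 2L)
    refStar <- FeatureSet("s", gr("c1", 15, 25, "*"))
    expect_equal(countOverlappingQueries(q, refStar, "require_same"), 2L)
})

test_that("matched sampling preserves per-chromosome counts and length multisets", {
    set.seed(3)
    q <- gr(c("cA", "cA", "cA", "cB"), c(1, 10, 400, 7), c(5, 40, 450, 106))
    lens <- c(cA = 1000L, cB = 500L)
    for (i in 1:20) {
        r <- sampleMatchedRegions(q, lens)
        for (chrom in c("cA", "cB")) {
            qs <- q[as.character(GenomicRanges::seqnames(q)) == chrom]
            rs <- r[as.character(GenomicRanges::seqnames(r)) == chrom]
            expect_equal(length(rs), length(qs))
            expect_equal(sort(GenomicRanges::width(rs)), sort(GenomicRanges::width(qs)))
            expect_true(all(GenomicRanges::start(rs) >= 1L))
            expect_true(all(GenomicRanges::end(rs) <= lens[[chrom]]))
        }
    }
    # degenerate placement: a region as long as its chromosome is forced to 1
    r <- sampleMatchedRegions(gr("cB", 1, 500), lens)
    expect_equal(GenomicRanges::start(r), 1L)
    expect_error(sampleMatchedRegions(gr("cB", 1, 501), lens), "longer than")
})

test_that("uniform placement hits a reference at the closed-form rate", {
    set.seed(17)
    q <- gr("c1", 1, 1)          # single length-1 region
    ref <- gr("c1", 301, 400)    # 100 of 1000 positions
    lens <- c(c1 = 1000L)
    hits <- 0L
    for (i in 1:10000) {
        r <- sampleMatchedRegions(q, lens)
        hits <- hits + (countOverlappingQueries(r, FeatureSet("f", ref)) > 0L)
    }
    expect_lt(abs(hits / 10000 - 0.1), 4 * sqrt(0.1 * 0.9 / 10000))
})

test_that("association test degenerate cases behave as specified", {
    lens <- c(c1 = 1000L, c2 = 800L)
    q <- gr(c("c1", "c1", "c2"), c(10, 500, 100), c(40, 520, 130))
    # reference covering every chromosome: all counts equal |query|
    cover <- FeatureSet("all", gr(c("c1", "c2"), c(1, 1), c(1000, 800)))
    res <- associationTest(q, cover, lens, nReps = 50L, seed = 1)
    expect_equal(observedCount(res), 3L)
    expect_true(all(nullCounts(res) == 3L))
    expect_equal(pOver(res), 1.0)
    expect_equal(pUnder(res), 1.0)
    # empty reference: observed 0, both p = 1
    res <- associationTest(q, FeatureSet("none", GenomicRanges::GRanges()), lens,
                           nReps = 50L, seed = 1)
    expect_equal(observedCount(res), 0L)
    expect_equal(pOver(res), 1.0)
    # empty query errors
    expect_error(associationTest(GenomicRanges::GRanges(), cover, lens), "empty query")
})

test_that("association test is deterministic and the fast counter matches GRanges", {
    set.seed(8)
    lens <- c(c1 = 50000L, c2 = 30000L)
    qs <- c(sample(1:49000, 30), sample(1:29000, 20))
    q <- gr(rep(c("c1", "c2"), c(30, 20)), qs, qs + sample(10:60, 50, replace = TRUE))
    rs <- c(sample(1:49000, 40), sample(1:29000, 25))
    ref <- FeatureSet("f", gr(rep(c("c1", "c2"), c(40, 25)), rs,
                              rs + sample(30:200, 65, replace = TRUE)))
    a <- associationTest(q, ref, lens, nReps = 100L, seed = 5)
    b <- associationTest(q, ref, lens, nReps = 100L, seed = 5)
    expect_identical(nullCounts(a), nullCounts(b))
    # the internal fast path must equal the GenomicRanges counter
    expect_equal(observedCount(a), countOverlappingQueries(q, ref))
    # both tails count equality: p_over + p_under >= 1 + ties/R
    ties <- sum(nullCounts(a) == observedCount(a))
    expect_gte(pOver(a) + pUnder(a), 1 + ties / 100 - 1e-12)
})

test_that("planted feature enrichment is detected; extreme enrichment saturates", {
    sim <- generateGenome(c(chrA = 60000L, chrB = 60000L), gc = 0.30,
                          nMotifs = 40L, seed = 71)
    lens <- stats::setNames(Biostrings::width(sim$genome), names(sim$genome))
    fs <- generateFeatures(lens, sim$truth, nFeatures = 200L,
                           featureLenRange = c(20L, 100L), enrichment = 0.8,
                           seed = 72)
    res <- associationTest(sim$truth, fs, lens, nReps = 1000L, seed = 73)
    expect_lte(pOver(res), 0.01)
    # e = 1, window 0: every feature overlaps a motif
    fs1 <- generateFeatures(lens, sim$truth, nFeatures = 50L,
                            featureLenRange = c(20L, 100L), enrichment = 1,
                            seed = 74)
    expect_equal(countOverlappingQueries(featureRanges(fs1), sim$truth), 50L)
})

test_that("BH q-values match the step-up formula; Storey shrinks by pi0", {
    expect_equal(fdrQvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(fdrQvalues(0.2), 0.2)
    # independent step-up oracle on random p-vectors
    set.seed(41)
    for (i in 1:200) {
        p <- runif(sample(1:30, 1))
        m <- length(p)
        o <- order(p)
        qSorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
        oracle <- pmin(1, qSorted)[order(o)]
        expect_equal(fdrQvalues(p), oracle)
    }
    # q >= p under BH; monotone in sorted order
    p <- runif(50)
    q <- fdrQvalues(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    # Storey: pi0 <= 1 so q_storey <= q_BH
    qs <- fdrQvalues(p, method = "storey")
    expect_true(all(qs <= q + 1e-12))
    expect_error(fdrQvalues(c(0.5, 0)), "\\(0, 1\\]")
    expect_error(fdrQvalues(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("the multi-feature association table carries both tails and q-values", {
    sim <- generateGenome(c(chrA = 40000L, chrB = 40000L), gc = 0.30,
                          nMotifs = 25L, seed = 81)
    lens <- stats::setNames(Biostrings::width(sim$genome), names(sim$genome))
    feats <- list(
        generateFeatures(lens, sim$truth, nFeatures = 80L, enrichment = 0.9,
                         featureLenRange = c(20L, 80L), name = "enriched", seed = 82),
        generateFeatures(lens, NULL, nFeatures = 80L, enrichment = 0,
                         featureLenRange = c(20L, 80L), name = "random", seed = 83))
    tab <- associateFeatures(sim$truth, feats, lens, nReps = 200L, seed = 84)
    expect_equal(tab$feature, c("enriched", "random"))
    expect_equal(tab$n_features, c(80L, 80L))
    expect_lt(tab$q_over[1], 0.05)
    expect_gt(tab$q_over[2], 0.05)
    # rerun reproduces exactly (derived per-feature seeds)
    tab2 <- associateFeatures(sim$truth, feats, lens, nReps = 200L, seed = 84)
    expect_identical(tab, tab2)
})
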