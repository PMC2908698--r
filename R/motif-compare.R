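#' Fisher's exact test on the multi-tract fraction of two motif sets
#'
#' Compares the fraction of motifs with more than four G-tracts (sites with
#' the potential to form several distinct quadruplex topologies) between two
#' sets, e.g. conserved motifs versus all motifs.  With
#' \code{construction = "disjoint"} (the default) and set A a subset of set B,
#' the 2x2 table contrasts A against B-without-A, i.e. conserved versus
#' non-conserved motifs; this is the construction that reproduces the
#' published contrast of 17/34 conserved multi-tract motifs against 120/552
#' overall.  \code{"as_given"} uses the two sets as provided.
#'
#' @param multiA,totalA multi-tract count and total size of set A.
#' @param multiB,totalB multi-tract count and total size of set B.
#' @param construction "disjoint" (subtract A from B first) or "as_given".
#' @return list with \code{p.value}, \code{estimate} (odds ratio),
#'   \code{table} and \code{construction}.
#' @export
#' @importFrom stats fisher.test
multiTractFisherTest <- function(multiA, totalA, multiB, totalB,
                                 construction = c("disjoint", "as_given")) {
    construction <- match.arg(construction)
    if (construction == "disjoint") {
        multiB <- multiB - multiA
        totalB <- totalB - totalA
        if (multiB < 0L || totalB < multiB)
            stop("disjoint construction requires set A to be a subset of set B")
    }
    tab <- rbind(A = c(multi = multiA, not = totalA - multiA),
                 B = c(multi = multiB, not = totalB - multiB))
    ft <- fisher.test(tab, alternative = "two.sided")
    list(p.value = ft$p.value, estimate = unname(ft$estimate), table = tab,
         construction = construction)
}

#' Compare physical properties of two motif sets
#'
#' Per-property mean +/- sd for each set with a Wilcoxon rank-sum p-value for
#' the difference, plus Fisher's exact test on the fraction of multi-tract
#' motifs (> 4 G-tracts).  When \code{fisherConstruction = "disjoint"}, motifs
#' of set A are removed from set B (matched by \code{motif_id}) before the
#' table is built, so overlapping definitions like "conserved" versus "all"
#' become the disjoint conserved-versus-non-conserved contrast.
#'
#' @param setA,setB \linkS4class{G4MotifSet}s (e.g. conserved vs all).
#' @param properties property columns to compare.
#' @param fisherConstruction passed to \code{\link{multiTractFisherTest}}.
#' @return list with \code{properties} (data.frame: property, meanA, sdA,
#'   meanB, sdB, p.value), \code{fisher}, \code{nA}, \code{nB} and
#'   \code{undefined} (TRUE when a set is empty: statistics are NA, not zero).
#' @export
compareMotifSets <- function(setA, setB,
                             properties = c("length_nt", "n_tracts", "n_loops",
                                            "mean_tract_len", "mean_loop_len",
                                            "stacked_quartets"),
                             fisherConstruction = c("disjoint", "as_given")) {
    fisherConstruction <- match.arg(fisherConstruction)
    nA <- length(setA); nB <- length(setB)
    if (nA == 0L || nB == 0L) {
        tab <- data.frame(property = properties, meanA = NA_real_, sdA = NA_real_,
                          meanB = NA_real_, sdB = NA_real_, p.value = NA_real_)
        return(list(properties = tab, fisher = NULL, nA = nA, nB = nB,
                    undefined = TRUE))
    }
    pa <- as.data.frame(motifProperties(setA))
    pb <- as.data.frame(motifProperties(setB))
    rows <- lapply(properties, function(pr) {
        a <- pa[[pr]]; b <- pb[[pr]]
        p <- if (identical(sort(a), sort(b)) && length(a) == length(b))
            1.0 else rankSumTest(a, b)$p.value
        data.frame(property = pr, meanA = mean(a), sdA = stats::sd(a),
                   meanB = mean(b), sdB = stats::sd(b), p.value = p)
    })
    if (fisherConstruction == "disjoint") {
        keep <- !(pb$motif_id %in% pa$motif_id)
        fisher <- multiTractFisherTest(sum(pa$n_tracts > 4L), nA,
                                       sum(pb$n_tracts[keep] > 4L), sum(keep),
                                       construction = "as_given")
        fisher$construction <- "disjoint"
    } else {
        fisher <- multiTractFisherTest(sum(pa$n_tracts > 4L), nA,
                                       sum(pb$n_tracts > 4L), nB,
                                       construction = "as_given")
    }
    list(properties = do.call(rbind, rows), fisher = fisher, nA = nA, nB = nB,
         undefined = FALSE)
}
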