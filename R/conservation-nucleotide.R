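# Nucleotide-level conservation: classify motif positions as structure
# disruptive / non-disruptive / loop, aggregate per-base conservation scores,
# and run the binomial and rank-sum comparisons.

#' Classify the positions of one G-tract
#'
#' Within a G-tract of length \eqn{k}, a single substitution at position
#' \eqn{i} (1-based in the tract) leaves intact runs of \eqn{i-1} and
#' \eqn{k-i} guanines; the position is \emph{non-disruptive} iff one of those
#' remaining runs still reaches \code{minTract} (i.e.
#' \eqn{\max(i-1, k-i) \ge} \code{minTract}), otherwise \emph{disruptive}.
#' For a GGGG tract this gives non-disruptive ends and disruptive middles;
#' a GGG tract is all disruptive; a six-G tract is all non-disruptive.  The
#' equivalent formulation \code{"edge_beyond_core"} (a position is
#' non-disruptive iff it lies in the first \eqn{k-}\code{minTract} or last
#' \eqn{k-}\code{minTract} positions of the tract) is provided as an
#' alternative rule; the two coincide for every \eqn{k}.
#'
#' @param k tract length.
#' @param minTract minimum tract length for a viable motif (default 3).
#' @param rule "remaining_run" (default) or "edge_beyond_core".
#' @return character vector of length \code{k} over
#'   \{"disruptive", "non_disruptive"\}.
#' @export
classifyTractPositions <- function(k, minTract = 3L,
                                   rule = c("remaining_run", "edge_beyond_core")) {
    rule <- match.arg(rule)
    i <- seq_len(k)
    nd <- switch(rule,
        remaining_run = pmax(i - 1L, k - i) >= minTract,
        edge_beyond_core = (i <= k - minTract) | (i > minTract))
    ifelse(nd, "non_disruptive", "disruptive")
}

#' Classify every position of each motif
#'
#' Positions inside G-tracts are classified with
#' \code{\link{classifyTractPositions}}; all inter-tract positions are
#' \code{"loop"}.  The classification depends only on tract geometry, so it
#' is invariant under reverse complementation.
#'
#' @param x a \linkS4class{G4MotifSet}.
#' @param minTract,rule passed to \code{\link{classifyTractPositions}}.
#' @return list (one element per motif) of character vectors over the motif
#'   span in genomic order, named by genomic position.
#' @export
classifyMotifPositions <- function(x, minTract = 3L,
                                   rule = c("remaining_run", "edge_beyond_core")) {
    rule <- match.arg(rule)
    gr <- motifRanges(x)
    tr <- motifTracts(x)
    lapply(seq_along(gr), function(i) {
        cls <- rep("loop", width(gr)[i])
        off <- start(gr)[i] - 1L
        t <- tr[[i]]
        for (j in seq_along(t)) {
            pos <- (start(t)[j]:end(t)[j]) - off
            cls[pos] <- classifyTractPositions(width(t)[j], minTract, rule)
        }
        names(cls) <- seq(start(gr)[i], end(gr)[i])
        cls
    })
}

#' One-sided (or two-sided) exact binomial tail
#'
#' Exact binomial test used for the motif-versus-flank comparison:
#' \code{side = "greater"} returns \eqn{P(X \ge k)} for
#' \eqn{X \sim Bin(n, p0)}.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials.
#' @param p0 null success probability in (0,1).
#' @param side "greater", "less" or "two.sided".
#' @return the p-value.
#' @export
#' @importFrom stats pbinom binom.test
binomialTailTest <- function(k, n, p0 = 0.5,
                             side = c("greater", "less", "two.sided")) {
    side <- match.arg(side)
    if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n) ||
        k < 0 || n < 1 || k > n || k != round(k) || n != round(n))
        stop("need integers 0 <= k <= n with n >= 1")
    if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0,1)")
    switch(side,
        greater = pbinom(k - 1, n, p0, lower.tail = FALSE),
        less = pbinom(k, n, p0),
        two.sided = binom.test(k, n, p0)$p.value)
}

#' Wilcoxon/Mann-Whitney rank-sum test
#'
#' Two-sided rank-sum comparison of two score groups: exact enumeration when
#' the combined sample size is at most 20 and there are no ties, otherwise
#' the normal approximation with tie correction.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return list with \code{p.value}, \code{statistic} (Mann-Whitney U of
#'   group a) and \code{method}.
#' @export
#' @importFrom stats wilcox.test
rankSumTest <- function(a, b) {
    if (!length(a) || !length(b)) stop("both groups must be non-empty")
    exact <- (length(a) + length(b) <= 20L) && !anyDuplicated(c(a, b))
    wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                       exact = exact, correct = FALSE))
    p <- wt$p.value
    if (is.nan(p)) p <- 1  # zero-variance degenerate case (all values tied)
    list(p.value = p, statistic = unname(wt$statistic),
         method = if (exact) "exact" else "normal approximation with tie correction")
}

#' Per-motif conservation relative to flanking sequence
#'
#' For each motif, compares the mean defined conservation score over the
#' motif with the mean over the 100 nucleotides (by default) on either side
#' (truncated at chromosome ends).  Missing scores (unaligned bases) are
#' excluded from the means, never imputed as zero.  The per-motif indicator
#' is TRUE only when the motif mean is \emph{strictly} greater (ties count as
#' not-more-conserved, the conservative choice).  Motifs with no defined
#' score in the motif or in the flanks are excluded and counted.  The number
#' of indicators among included motifs is tested against Binomial(n, 1/2)
#' with an upper-tail exact binomial test.
#'
#' @param motifs a \linkS4class{G4MotifSet}.
#' @param track a \linkS4class{ScoreTrack}.
#' @param flank flank width per side (default 100).
#' @return list with \code{perMotif} (data.frame motif_id, motifMean,
#'   flankMean, indicator), \code{nExcluded}, \code{k}, \code{n} and
#'   \code{p.value}.
#' @export
motifVsFlank <- function(motifs, track, flank = 100L) {
    gr <- motifRanges(motifs)
    ids <- mcols(gr)$motif_id
    mm <- fm <- rep(NA_real_, length(gr))
    for (i in seq_along(gr)) {
        chrom <- as.character(seqnames(gr))[i]
        s <- start(gr)[i]; e <- end(gr)[i]
        inside <- trackValues(track, chrom, s, e)
        flanks <- c(trackValues(track, chrom, s - flank, s - 1L),
                    trackValues(track, chrom, e + 1L, e + flank))
        if (any(!is.na(inside))) mm[i] <- mean(inside, na.rm = TRUE)
        if (any(!is.na(flanks))) fm[i] <- mean(flanks, na.rm = TRUE)
    }
    ok <- !is.na(mm) & !is.na(fm)
    ind <- mm > fm
    k <- sum(ind[ok]); n <- sum(ok)
    list(perMotif = data.frame(motif_id = ids, motifMean = mm, flankMean = fm,
                               indicator = ind, stringsAsFactors = FALSE),
         nExcluded = sum(!ok), k = k, n = n,
         p.value = if (n > 0L) binomialTailTest(k, n, 0.5, "greater") else NA_real_)
}

#' Conservation of disruptive versus non-disruptive G-tract positions
#'
#' Pools conservation scores by position class across all motifs (G-tract
#' positions only; loops are ignored), reports the class means and a
#' two-sided rank-sum p-value for the difference.  If a class is empty (for
#' example when every tract has exactly \code{minTract} guanines, so no
#' position is non-disruptive) the means are still reported and the p-value
#' is flagged undefined.
#'
#' @param motifs a \linkS4class{G4MotifSet}.
#' @param track a \linkS4class{ScoreTrack}.
#' @param minTract,rule classification parameters.
#' @return list with \code{meanDisruptive}, \code{meanNonDisruptive},
#'   \code{nDisruptive}, \code{nNonDisruptive}, \code{p.value},
#'   \code{undefined}.
#' @export
disruptiveVsNondisruptive <- function(motifs, track, minTract = 3L,
                                      rule = c("remaining_run", "edge_beyond_core")) {
    rule <- match.arg(rule)
    gr <- motifRanges(motifs)
    cls <- classifyMotifPositions(motifs, minTract, rule)
    dis <- numeric(0); nond <- numeric(0)
    for (i in seq_along(gr)) {
        v <- trackValues(track, as.character(seqnames(gr))[i],
                         start(gr)[i], end(gr)[i])
        c_i <- cls[[i]]
        dis <- c(dis, v[c_i == "disruptive" & !is.na(v)])
        nond <- c(nond, v[c_i == "non_disruptive" & !is.na(v)])
    }
    undefined <- !length(dis) || !length(nond)
    list(meanDisruptive = if (length(dis)) mean(dis) else NA_real_,
         meanNonDisruptive = if (length(nond)) mean(nond) else NA_real_,
         nDisruptive = length(dis), nNonDisruptive = length(nond),
         p.value = if (undefined) NA_real_ else rankSumTest(dis, nond)$p.value,
         undefined = undefined)
}
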