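# Association of motif sets with genome features via chromosome- and
# length-matched random placement, with FDR control over many feature tests.

#' Window-expanded feature ranges
#'
#' Expands each interval of a FeatureSet by its window on both sides and
#' clips to [1, chromosome length] where lengths are known.
#'
#' @param x a \linkS4class{FeatureSet} (or GRanges, returned expanded by
#'   \code{window}).
#' @param chromLengths named integer vector of chromosome lengths (optional).
#' @param window used when \code{x} is a plain GRanges.
#' @return GRanges.
#' @export
windowedRanges <- function(x, chromLengths = NULL, window = 0L) {
    if (methods::is(x, "FeatureSet")) {
        window <- featureWindow(x)
        x <- featureRanges(x)
    }
    s <- pmax(1L, start(x) - window)
    e <- end(x) + window
    if (!is.null(chromLengths)) {
        chn <- as.character(seqnames(x))
        known <- chn %in% names(chromLengths)
        e[known] <- pmin(e[known], unname(chromLengths[chn[known]]))
    }
    GRanges(seqnames(x), IRanges(s, e), strand = strand(x))
}

#' Count query regions overlapping a reference feature set
#'
#' The unit of counting is the query region (e.g. a motif): the result is the
#' number of query regions with at least 1 bp of overlap with at least one
#' (window-expanded) reference interval.  With
#' \code{strandMode = "require_same"} a stranded query only matches reference
#' features on its own strand; unstranded records (strand "*") on either side
#' match any strand.  The count is invariant to splitting or merging of
#' overlapping reference intervals.
#'
#' @param query G4MotifSet, FeatureSet or GRanges.
#' @param reference FeatureSet (its window is applied) or GRanges.
#' @param strandMode "ignore" (default) or "require_same".
#' @param chromLengths named lengths used to clip window expansion.
#' @return integer count.
#' @export
countOverlappingQueries <- function(query, reference,
                                    strandMode = c("ignore", "require_same"),
                                    chromLengths = NULL) {
    strandMode <- match.arg(strandMode)
    q <- .asGRanges(query)
    r <- windowedRanges(if (methods::is(reference, "FeatureSet")) reference
                        else .asGRanges(reference),
                        chromLengths = chromLengths)
    if (!length(r)) return(0L)
    sum(overlapsAny(q, r, ignore.strand = (strandMode == "ignore")))
}

#' Sample a chromosome- and length-matched random region set
#'
#' For each chromosome, places the same number of regions with the same
#' multiset of lengths as the query, each start drawn uniformly from the
#' placements that fit the chromosome.  Random regions may overlap one
#' another and any genomic feature (plain uniform placement).  When the query
#' carries strand annotations, strands are assigned uniformly.  Uses R's
#' global RNG.
#'
#' @param query GRanges (or G4MotifSet/FeatureSet) to match.
#' @param chromLengths named integer vector; every query chromosome must be
#'   present and every region must fit its chromosome.
#' @return GRanges of random regions.
#' @export
sampleMatchedRegions <- function(query, chromLengths) {
    q <- .asGRanges(query)
    chn <- as.character(seqnames(q))
    if (!all(chn %in% names(chromLengths)))
        stop("chromLengths missing: ",
             paste(setdiff(unique(chn), names(chromLengths)), collapse = ", "))
    L <- unname(chromLengths[chn])
    w <- width(q)
    if (any(w > L)) stop("query region longer than its chromosome")
    starts <- 1L + as.integer(floor(stats::runif(length(q)) * (L - w + 1)))
    st <- as.character(strand(q))
    newStrand <- ifelse(st == "*", "*",
                        c("+", "-")[1L + (stats::runif(length(q)) < 0.5)])
    GRanges(chn, IRanges(starts, width = w), strand = newStrand)
}

# --- fast internal null machinery -----------------------------------------
# Reference intervals are reduced per chromosome (and per strand when strand
# aware) to sorted disjoint [s,e]; a query [qs,qe] then overlaps some
# reference iff j = findInterval(qe, s) >= 1 and e[j] >= qs.

.refIndex <- function(refGr) {
    red <- IRanges::reduce(refGr, ignore.strand = TRUE)
    idx <- list()
    for (chrom in unique(as.character(seqnames(red)))) {
        g <- red[as.character(seqnames(red)) == chrom]
        o <- order(start(g))
        idx[[chrom]] <- list(s = start(g)[o], e = end(g)[o])
    }
    idx
}

.fastCount <- function(chn, qs, qe, idx) {
    n <- 0L
    for (chrom in unique(chn)) {
        r <- idx[[chrom]]
        sel <- chn == chrom
        if (is.null(r)) next
        j <- findInterval(qe[sel], r$s)
        n <- n + sum(j >= 1L & r$e[pmax(j, 1L)] >= qs[sel])
    }
    n
}

#' Permutation test for motif/feature association
#'
#' Compares the observed number of query regions overlapping the (window
#' expanded) reference features with the distribution of that count over
#' \code{nReps} chromosome- and length-matched random placements of the
#' query (\code{\link{sampleMatchedRegions}}).  Both tails are computed:
#' \code{p_over} = fraction of replicates with a count >= observed,
#' \code{p_under} = fraction with a count <= observed (equality counts toward
#' both tails).  A tail with zero as-extreme replicates is floored at 1/R and
#' labelled "< 1/R".  Deterministic given the master seed.
#'
#' @param query G4MotifSet/FeatureSet/GRanges (non-empty).
#' @param reference FeatureSet or GRanges; an empty reference yields an
#'   observed count of 0 with both p-values 1.
#' @param chromLengths named chromosome lengths (placement domain).
#' @param nReps number of random region sets (default 1000).
#' @param strandMode "ignore" (default) or "require_same".
#' @param seed master seed (default 1).
#' @return an \linkS4class{AssociationResult}.
#' @export
associationTest <- function(query, reference, chromLengths, nReps = 1000L,
                            strandMode = c("ignore", "require_same"),
                            seed = 1L) {
    strandMode <- match.arg(strandMode)
    stopifnot(nReps >= 1L)
    q <- .asGRanges(query)
    if (!length(q)) stop("empty query set")
    featName <- if (methods::is(reference, "FeatureSet")) featureName(reference)
                else "reference"
    r <- windowedRanges(if (methods::is(reference, "FeatureSet")) reference
                        else .asGRanges(reference), chromLengths = chromLengths)
    if (!length(r)) {
        return(new("AssociationResult", feature = featName, observed = 0L,
                   nullCounts = rep(0L, nReps), pOver = 1, pUnder = 1,
                   pOverLabel = "1", pUnderLabel = "1",
                   seed = as.integer(seed)))
    }
    chn <- as.character(seqnames(q))
    if (!all(chn %in% names(chromLengths)))
        stop("chromLengths missing: ",
             paste(setdiff(unique(chn), names(chromLengths)), collapse = ", "))
    L <- unname(chromLengths[chn])
    w <- width(q)
    if (any(w > L)) stop("query region longer than its chromosome")
    strandAware <- strandMode == "require_same"
    qStrand <- as.character(strand(q))
    if (strandAware) {
        idxPlus <- .refIndex(r[as.character(strand(r)) %in% c("+", "*")])
        idxMinus <- .refIndex(r[as.character(strand(r)) %in% c("-", "*")])
        idxAny <- .refIndex(r)
        countFun <- function(chn, qs, qe, st) {
            sum3 <- 0L
            for (grp in list(list("+", idxPlus), list("-", idxMinus),
                             list("*", idxAny))) {
                sel <- st == grp[[1L]]
                if (any(sel))
                    sum3 <- sum3 + .fastCount(chn[sel], qs[sel], qe[sel], grp[[2L]])
            }
            sum3
        }
    } else {
        idxAny <- .refIndex(r)
        countFun <- function(chn, qs, qe, st) .fastCount(chn, qs, qe, idxAny)
    }
    observed <- countFun(chn, start(q), end(q), qStrand)
    anyStranded <- any(qStrand != "*")
    nullCounts <- integer(nReps)
    set.seed(as.integer(seed))
    for (rep_ in seq_len(nReps)) {
        ns <- 1L + as.integer(floor(stats::runif(length(q)) * (L - w + 1)))
        st <- if (strandAware && anyStranded)
            ifelse(qStrand == "*", "*",
                   c("+", "-")[1L + (stats::runif(length(q)) < 0.5)])
        else qStrand
        nullCounts[rep_] <- countFun(chn, ns, ns + w - 1L, st)
    }
    .tail <- function(count) {
        if (count == 0L) list(p = 1 / nReps, label = sprintf("< 1/%d", nReps))
        else list(p = count / nReps, label = format(count / nReps))
    }
    over <- .tail(sum(nullCounts >= observed))
    under <- .tail(sum(nullCounts <= observed))
    new("AssociationResult", feature = featName, observed = as.integer(observed),
        nullCounts = nullCounts, pOver = over$p, pUnder = under$p,
        pOverLabel = over$label, pUnderLabel = under$label,
        seed = as.integer(seed))
}

#' FDR q-values for a vector of p-values
#'
#' \code{"BH"} is the Benjamini-Hochberg step-up
#' (\eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1), the
#' deterministic default.  \code{"storey"} multiplies the same step-up by
#' Storey's plug-in null proportion estimate
#' \eqn{\hat\pi_0 = \#\{p > \lambda\} / ((1-\lambda) m)} at
#' \eqn{\lambda = 0.5} (floored at \eqn{1/m} so q-values stay positive).
#'
#' @param p p-values in (0, 1].
#' @param method "BH" or "storey".
#' @param lambda Storey tuning parameter.
#' @return q-values in input order.
#' @export
#' @importFrom stats p.adjust
fdrQvalues <- function(p, method = c("BH", "storey"), lambda = 0.5) {
    method <- match.arg(method)
    if (any(is.na(p)) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    q <- p.adjust(p, method = "BH")
    if (method == "storey") {
        pi0 <- min(1, max(mean(p > lambda) / (1 - lambda), 1 / length(p)))
        q <- pmin(1, pi0 * q)
    }
    q
}

#' Association table over many feature sets
#'
#' Runs \code{\link{associationTest}} for each feature set against the same
#' query, with per-feature seeds derived from the master seed, and reports a
#' table shaped like a feature-association summary: feature name, number of
#' features, number of overlapping query regions, both empirical p-values and
#' their q-values (FDR over each tail's p-vector).
#'
#' @param query G4MotifSet/GRanges.
#' @param features list of \linkS4class{FeatureSet}.
#' @param chromLengths named chromosome lengths.
#' @param nReps replicates per test.
#' @param strandModes named character vector (per feature) or single mode.
#' @param seed master seed.
#' @param fdrMethod "BH" or "storey".
#' @return data.frame with one row per feature.
#' @export
associateFeatures <- function(query, features, chromLengths, nReps = 1000L,
                              strandModes = "ignore", seed = 1L,
                              fdrMethod = c("BH", "storey")) {
    fdrMethod <- match.arg(fdrMethod)
    if (length(strandModes) == 1L)
        strandModes <- stats::setNames(rep(strandModes, length(features)),
                                       vapply(features, featureName, character(1)))
    rows <- lapply(features, function(fs) {
        res <- associationTest(query, fs, chromLengths, nReps = nReps,
                               strandMode = strandModes[[featureName(fs)]],
                               seed = deriveStageSeed(seed, featureName(fs)))
        data.frame(feature = featureName(fs), n_features = length(fs),
                   window = featureWindow(fs), n_query_overlapping = observedCount(res),
                   p_over = pOver(res), p_under = pUnder(res),
                   stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$q_over <- fdrQvalues(tab$p_over, method = fdrMethod)
    tab$q_under <- fdrQvalues(tab$p_under, method = fdrMethod)
    tab
}
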