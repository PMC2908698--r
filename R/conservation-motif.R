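# Motif-level conservation: project reference motifs through alignment
# blocks, re-scan the aligned species sequence for the G4 pattern, and assess
# the conserved count against an evolutionary null that "evolves" each block
# under a substitution matrix estimated from the aligned pair.

# Column bookkeeping for one block/species pair.  All downstream calls (real
# and evolved) reuse this: the evolved rows preserve the real species row's
# gap columns, so the maps never change within a null run.
.blockIndex <- function(block, species) {
    rows <- alignmentRows(block)
    if (!species %in% names(rows))
        return(NULL)
    refc <- strsplit(rows[[block@refSpecies]], "", fixed = TRUE)[[1L]]
    spc <- strsplit(rows[[species]], "", fixed = TRUE)[[1L]]
    refNonGap <- refc != "-"
    spNonGap <- spc != "-"
    refAtSpCols <- refc[spNonGap]
    list(refStart = block@refStart,
         refWidth = sum(refNonGap),
         colOfRefPos = which(refNonGap),        # ref ungapped pos -> column
         spPosOfCol = cumsum(spNonGap),          # column -> species ungapped pos
         spNonGap = spNonGap,
         spChars = spc[spNonGap],                # degapped species sequence
         refAtSpCols = refAtSpCols,              # ref char over each species base
         idxByBase = lapply(stats::setNames(.BASES, .BASES),
                            function(b) which(refAtSpCols == b)),
         idxN = which(refAtSpCols == "N"),
         refChars = refc, spCharsGapped = spc)
}

#' Project a reference motif into a species row of an alignment block
#'
#' Maps the motif's reference positions through the alignment columns
#' (skipping reference gaps) to the ungapped coordinate range they occupy in
#' the species row.  Positions aligned to species gaps contribute no
#' coordinates; if the whole motif aligns to gaps the projection is empty.
#'
#' @param block an \linkS4class{AlignmentBlock}.
#' @param motif GRanges of length 1 (or anything with one range) giving the
#'   motif's reference interval; must intersect the block's reference
#'   interval.
#' @param species species row to project into.
#' @return IRanges of length 1 in block-local ungapped species coordinates,
#'   or an empty IRanges.
#' @export
projectMotif <- function(block, motif, species) {
    gr <- .asGRanges(motif)
    stopifnot(length(gr) == 1L)
    idx <- .blockIndex(block, species)
    if (is.null(idx)) stop("species '", species, "' not in block")
    refEnd <- idx$refStart + idx$refWidth - 1L
    ls <- max(start(gr), idx$refStart) - idx$refStart + 1L
    le <- min(end(gr), refEnd) - idx$refStart + 1L
    if (ls > le)
        stop("motif does not intersect the block's reference interval")
    cols <- idx$colOfRefPos[ls:le]
    cols <- cols[idx$spNonGap[cols]]
    if (!length(cols)) return(IRanges())
    sp <- idx$spPosOfCol[cols]
    IRanges(min(sp), max(sp))
}

# Motif spans of one strand of a degapped string, as plain start/end vectors
# (no S4 in the replicate-loop hot path).
.chainSpans <- function(s, base, minTract, maxLoop) {
    m <- gregexpr(sprintf("%s{%d,}", base, minTract), s)[[1L]]
    if (m[1L] == -1L) return(NULL)
    st <- as.integer(m)
    en <- st + attr(m, "match.length") - 1L
    n <- length(st)
    gaps <- if (n > 1L) st[-1L] - en[-n] - 1L else integer()
    grp <- cumsum(c(1L, as.integer(gaps > maxLoop)))
    cnt <- tabulate(grp)
    first <- which(!duplicated(grp))
    last <- cumsum(cnt)
    keep <- cnt >= 4L
    if (!any(keep)) return(NULL)
    list(s = st[first][keep], e = en[last][keep])
}

# Both-strand motif spans of a degapped species string, merged to disjoint
# sorted intervals (start/end vectors).
.speciesMotifSpans <- function(s, minTract, maxLoop, strands) {
    g <- .chainSpans(s, "G", minTract, maxLoop)
    c_ <- if (strands == "both") .chainSpans(s, "C", minTract, maxLoop) else NULL
    if (is.null(g) && is.null(c_)) return(NULL)
    st <- c(g$s, c_$s); en <- c(g$e, c_$e)
    o <- order(st)
    st <- st[o]; en <- en[o]
    if (length(st) > 1L) {
        ms <- st[1L]; me <- en[1L]; outS <- integer(); outE <- integer()
        for (i in 2L:length(st)) {
            if (st[i] <= me + 1L) me <- max(me, en[i])
            else { outS <- c(outS, ms); outE <- c(outE, me); ms <- st[i]; me <- en[i] }
        }
        st <- c(outS, ms); en <- c(outE, me)
    }
    list(s = st, e = en)
}

# TRUE/FALSE per projected interval: does any species motif span overlap it
# by >= 1 column?  proj given as parallel start/end vectors (NA = empty);
# spans as disjoint sorted start/end vectors (or NULL).
.projConserved <- function(projStart, projEnd, spans) {
    out <- rep(FALSE, length(projStart))
    if (is.null(spans)) return(out)
    ok <- !is.na(projStart)
    j <- findInterval(projEnd[ok], spans$s)
    out[ok] <- j >= 1L & spans$e[pmax(j, 1L)] >= projStart[ok]
    out
}

# Precompute, for a set of blocks and motifs, everything the conservation
# call needs except the (possibly evolved) species sequence.
.conservationSetup <- function(blocks, motifs, species) {
    gr <- .asGRanges(motifs)
    setup <- list()
    for (bi in seq_along(blocks)) {
        b <- blocks[[bi]]
        idx <- .blockIndex(b, species)
        if (is.null(idx)) next
        refEnd <- idx$refStart + idx$refWidth - 1L
        hit <- which(as.character(seqnames(gr)) == b@refChrom &
                     start(gr) <= refEnd & end(gr) >= idx$refStart)
        if (!length(hit)) next
        ps <- pe <- rep(NA_integer_, length(hit))
        for (k in seq_along(hit)) {
            pr <- projectMotif(b, gr[hit[k]], species)
            if (length(pr)) { ps[k] <- start(pr); pe[k] <- end(pr) }
        }
        setup[[length(setup) + 1L]] <- list(block = b, idx = idx,
                                            motifIdx = hit,
                                            projStart = ps, projEnd = pe)
    }
    setup
}

# Conserved-per-motif logical given per-block degapped species strings.
.conservedFromStrings <- function(setup, nMotifs, strings, minTract, maxLoop,
                                  strands) {
    conserved <- rep(FALSE, nMotifs)
    for (i in seq_along(setup)) {
        st <- setup[[i]]
        spans <- .speciesMotifSpans(strings[[i]], minTract, maxLoop, strands)
        hit <- .projConserved(st$projStart, st$projEnd, spans)
        conserved[st$motifIdx] <- conserved[st$motifIdx] | hit
    }
    conserved
}

#' Call motif-level conservation for one species
#'
#' For each reference motif, every overlapping alignment block is examined:
#' the species row is degapped and re-scanned for the G4 pattern (on both
#' strands by default, since a quadruplex on the complementary strand still
#' forms a structure), and the motif is conserved if some species motif
#' overlaps the projected reference-motif interval by at least one position.
#' The conserved motif is not required to be identical: differing loop sizes,
#' tract counts and sequences are accepted.  Motifs spanning several blocks
#' are conserved if any block yields a conserved call (block boundaries are
#' aligner artifacts).  A motif with no aligned block in the species is
#' \code{"unalignable"}, never \code{"not_conserved"}.
#'
#' @param blocks list of \linkS4class{AlignmentBlock}.
#' @param motifs \linkS4class{G4MotifSet} or GRanges of reference motifs.
#' @param species species row to assess.
#' @param minTract,maxLoop scan parameters used on the species sequence.
#' @param strands "both" (default) or "forward".
#' @return data.frame with columns motif_id, species, call (conserved /
#'   not_conserved / unalignable).
#' @export
callConservation <- function(blocks, motifs, species, minTract = 3L,
                             maxLoop = 25L, strands = c("both", "forward")) {
    strands <- match.arg(strands)
    gr <- .asGRanges(motifs)
    ids <- mcols(gr)$motif_id
    if (is.null(ids)) ids <- sprintf("motif%d", seq_along(gr))
    setup <- .conservationSetup(blocks, gr, species)
    alignable <- rep(FALSE, length(gr))
    for (st in setup) alignable[st$motifIdx] <- TRUE
    strings <- lapply(setup, function(st) paste(st$idx$spChars, collapse = ""))
    conserved <- .conservedFromStrings(setup, length(gr), strings, minTract,
                                       maxLoop, strands)
    call <- ifelse(!alignable, "unalignable",
                   ifelse(conserved, "conserved", "not_conserved"))
    data.frame(motif_id = ids, species = species, call = call,
               stringsAsFactors = FALSE)
}

#' Aggregate conservation calls across a species panel
#'
#' A motif is "conserved across the panel" (e.g. across the sensu stricto
#' species) if it is called conserved in every species, each species being
#' alignable for it; motifs unalignable in any panel species are excluded
#' from the denominator rather than counted as not conserved.
#'
#' @param calls list of per-species data.frames from
#'   \code{\link{callConservation}} (same motifs in each).
#' @return data.frame with motif_id, alignable_in_all, conserved_in_all.
#' @export
panelConservation <- function(calls) {
    stopifnot(length(calls) >= 1L)
    ids <- calls[[1L]]$motif_id
    mat <- vapply(calls, function(df) {
        stopifnot(identical(df$motif_id, ids))
        df$call
    }, character(length(ids)))
    mat <- matrix(mat, nrow = length(ids))
    data.frame(motif_id = ids,
               alignable_in_all = apply(mat != "unalignable", 1L, all),
               conserved_in_all = apply(mat == "conserved", 1L, all),
               stringsAsFactors = FALSE)
}

#' Estimate a nucleotide substitution matrix from aligned pairs
#'
#' Counts aligned non-gap (reference, other) nucleotide pairs over the
#' block(s) and row-normalizes with add-one smoothing, yielding the observed
#' conditional probabilities of nucleotide change between the aligned
#' sequences.  A reference base never observed falls back to an identity row.
#'
#' @param blocks an \linkS4class{AlignmentBlock} or a list of them (a list
#'   pools counts, giving the "global" matrix for a species pair).
#' @param species the non-reference species row.
#' @param pseudocount add-one smoothing constant (default 1).
#' @return a \linkS4class{SubstitutionMatrix}.
#' @export
estimateSubstitutionMatrix <- function(blocks, species, pseudocount = 1) {
    if (methods::is(blocks, "AlignmentBlock")) blocks <- list(blocks)
    counts <- matrix(0, 4, 4, dimnames = list(.BASES, .BASES))
    any_cols <- FALSE
    for (b in blocks) {
        idx <- .blockIndex(b, species)
        if (is.null(idx)) next
        ok <- idx$refAtSpCols %in% .BASES & idx$spChars %in% .BASES
        if (!any(ok)) next
        any_cols <- TRUE
        tt <- table(factor(idx$refAtSpCols[ok], levels = .BASES),
                    factor(idx$spChars[ok], levels = .BASES))
        counts <- counts + unclass(tt)
    }
    if (!any_cols)
        stop("unestimable: no aligned non-gap columns for species '", species, "'")
    probs <- counts + pseudocount
    zero <- rowSums(counts) == 0
    probs <- probs / rowSums(probs)
    for (b in .BASES[zero]) {
        probs[b, ] <- 0; probs[b, b] <- 1
    }
    SubstitutionMatrix(probs)
}

#' Evolve a block's species row under a substitution matrix
#'
#' Generates one null ("evolved") species row: every non-gap reference
#' nucleotide \eqn{a} is replaced by an independent draw from \eqn{P(\cdot|a)}.
#' The real species row's gap columns are reproduced at the same columns, so
#' the alignability geometry is held fixed and only substitutions drive the
#' null.  Reference N positions are copied unchanged, and columns where the
#' reference is gapped keep the real species base.  Uses R's global RNG
#' (seed with \code{set.seed} for reproducibility).
#'
#' @param block an \linkS4class{AlignmentBlock}.
#' @param matrix a \linkS4class{SubstitutionMatrix}.
#' @param species species row to replace.
#' @return the evolved gapped row (character scalar, same column count).
#' @export
evolveBlock <- function(block, matrix, species) {
    idx <- .blockIndex(block, species)
    if (is.null(idx)) stop("species '", species, "' not in block")
    ev <- .evolveChars(idx, probMatrix(matrix))
    out <- idx$spCharsGapped
    out[idx$spNonGap] <- ev
    paste(out, collapse = "")
}

# Evolve the degapped species char vector of a block index.
.evolveChars <- function(idx, P) {
    ev <- idx$spChars
    for (b in .BASES) {
        pos <- idx$idxByBase[[b]]
        if (length(pos))
            ev[pos] <- sample(.BASES, length(pos), replace = TRUE, prob = P[b, ])
    }
    # ref N -> copy N; ref gap -> keep real species base (already in ev)
    if (length(idx$idxN)) ev[idx$idxN] <- "N"
    ev
}

#' Empirical significance of the conserved-motif count
#'
#' Builds the evolutionary null for motif-level conservation: per replicate,
#' every block's species row is replaced by a row evolved under the
#' substitution matrix (estimated per block by default, or once globally from
#' all blocks), conservation is re-called for every motif, and the conserved
#' count recorded.  The empirical p-value is the fraction of replicates whose
#' count is at least the observed count, reported as "< 1/N" when no
#' replicate reaches it (the numeric p is then floored at 1/N so it stays in
#' (0,1]).  With \code{pEstimator = "add_one"} the (r+1)/(N+1) estimator is
#' used instead.  Per-replicate, per-block seeds are derived from the master
#' seed by stable hashing, so the result is invariant to block processing
#' order.
#'
#' @param blocks list of \linkS4class{AlignmentBlock}.
#' @param motifs \linkS4class{G4MotifSet} or GRanges.
#' @param species species to test.
#' @param nReps number of evolved replicates (>= 1).
#' @param minTract,maxLoop,strands scan parameters (as
#'   \code{\link{callConservation}}).
#' @param matrixScope "block" (one matrix per alignment block; default) or
#'   "global" (one matrix pooled over all blocks).
#' @param matrix optional \linkS4class{SubstitutionMatrix} used for every
#'   block instead of estimating from the data (e.g. the identity matrix as a
#'   degenerate control, or a known generating matrix in simulations).
#' @param seed master seed.
#' @param pseudocount smoothing for matrix estimation.
#' @param pEstimator "empirical" (r/N with a 1/N floor) or "add_one"
#'   ((r+1)/(N+1)).
#' @return a \linkS4class{NullSummary}.
#' @export
nullConservedCount <- function(blocks, motifs, species, nReps = 1000L,
                               minTract = 3L, maxLoop = 25L,
                               strands = c("both", "forward"),
                               matrixScope = c("block", "global"),
                               matrix = NULL, seed = 1L, pseudocount = 1,
                               pEstimator = c("empirical", "add_one")) {
    strands <- match.arg(strands)
    matrixScope <- match.arg(matrixScope)
    pEstimator <- match.arg(pEstimator)
    stopifnot(nReps >= 1L)
    gr <- .asGRanges(motifs)
    setup <- .conservationSetup(blocks, gr, species)
    strings <- lapply(setup, function(st) paste(st$idx$spChars, collapse = ""))
    observed <- sum(.conservedFromStrings(setup, length(gr), strings,
                                          minTract, maxLoop, strands))
    if (!is.null(matrix)) {
        mats <- rep(list(probMatrix(matrix)), length(setup))
    } else if (matrixScope == "global") {
        glob <- probMatrix(estimateSubstitutionMatrix(
            lapply(setup, `[[`, "block"), species, pseudocount))
        mats <- rep(list(glob), length(setup))
    } else {
        mats <- lapply(setup, function(st)
            probMatrix(estimateSubstitutionMatrix(st$block, species, pseudocount)))
    }
    blockIds <- vapply(setup, function(st)
        sprintf("%s:%d", st$block@refChrom, st$block@refStart), character(1))
    reps <- integer(nReps)
    for (r in seq_len(nReps)) {
        evStrings <- vector("list", length(setup))
        for (i in seq_along(setup)) {
            set.seed(deriveStageSeed(seed, sprintf("evolve/%d/%s", r, blockIds[i])))
            evStrings[[i]] <- paste(.evolveChars(setup[[i]]$idx, mats[[i]]),
                                    collapse = "")
        }
        reps[r] <- sum(.conservedFromStrings(setup, length(gr), evStrings,
                                             minTract, maxLoop, strands))
    }
    rGe <- sum(reps >= observed)
    if (pEstimator == "add_one") {
        p <- (rGe + 1) / (nReps + 1)
        pLabel <- format(p)
    } else if (rGe == 0L) {
        p <- 1 / nReps
        pLabel <- sprintf("< 1/%d", nReps)
    } else {
        p <- rGe / nReps
        pLabel <- format(p)
    }
    new("NullSummary", species = species, observed = as.integer(observed),
        replicates = reps, p = p, pLabel = pLabel, seed = as.integer(seed))
}
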