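# Synthetic genomes, alignments, tracks and feature sets with known ground
# truth, so every pipeline stage is testable without external downloads.
# Every generator is a pure function of its arguments and seed.

#' Jukes-Cantor style divergence matrix
#'
#' Row-stochastic substitution matrix with identity weight \code{1 - d} and
#' the remaining mass spread evenly over the three other bases.
#'
#' @param d per-site divergence in [0, 1).
#' @return a \linkS4class{SubstitutionMatrix}.
#' @export
divergenceMatrix <- function(d) {
    stopifnot(d >= 0, d < 1)
    p <- matrix(d / 3, 4, 4, dimnames = list(.BASES, .BASES))
    diag(p) <- 1 - d
    SubstitutionMatrix(p)
}

# Build one planted motif sequence from the tract/loop distributions.
# Loops never contain G (nor C), so a planted instance cannot spawn extra
# tracts on either strand within itself.
.plantMotifSeq <- function(nTracts, tractLens, loopLens) {
    loops <- lapply(loopLens, function(l)
        paste(sample(c("A", "T"), l, replace = TRUE), collapse = ""))
    parts <- character(2L * nTracts - 1L)
    parts[seq(1L, by = 2L, length.out = nTracts)] <-
        vapply(tractLens, function(k) strrep("G", k), character(1))
    parts[seq(2L, by = 2L, length.out = nTracts - 1L)] <- unlist(loops)
    paste(parts, collapse = "")
}

#' Generate a random genome with planted G4 motifs
#'
#' Background bases are drawn i.i.d. at the configured GC content (defaults
#' emulate the yeast nuclear genome, GC 0.38).  Planted motifs are built from
#' the tract-count / tract-length / loop-length distributions (defaults give
#' mostly minimal four-tract motifs with short loops, matching the observed
#' predominance of three stacked quartets) and written over the background at
#' uniformly chosen sites separated by more than \code{maxLoop} nucleotides,
#' so no two planted motifs can merge into one call.  Motifs are planted on
#' either strand.  Background-arising motifs are permitted; the truth object
#' records the exact planted intervals, strands and tract geometry.
#'
#' @param chromLengths named integer vector of chromosome lengths.
#' @param gc GC fraction in (0,1).
#' @param nMotifs number of motifs to plant.
#' @param nTractProbs named probabilities for the number of tracts (names are
#'   tract counts).
#' @param tractLenProbs named probabilities for individual tract lengths.
#' @param loopLenRange inclusive range loop lengths are drawn from.
#' @param strandProb probability a planted motif is on the plus strand.
#' @param maxLoop scan loop threshold the plant spacing must respect.
#' @param seed integer seed.
#' @return list with \code{genome} (DNAStringSet) and \code{truth}
#'   (\linkS4class{G4MotifSet} of planted motifs).
#' @export
generateGenome <- function(chromLengths = c(chr1 = 100000L), gc = 0.38,
                           nMotifs = 50L,
                           nTractProbs = c("4" = 0.78, "5" = 0.15, "6" = 0.07),
                           tractLenProbs = c("3" = 0.75, "4" = 0.17,
                                             "5" = 0.06, "6" = 0.02),
                           loopLenRange = c(1L, 10L), strandProb = 0.5,
                           maxLoop = 25L, seed = 1L) {
    stopifnot(gc > 0, gc < 1)
    set.seed(as.integer(seed))
    baseProbs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    chroms <- lapply(chromLengths, function(L)
        sample(.BASES, L, replace = TRUE, prob = baseProbs))
    placed <- lapply(chromLengths, function(L) integer(0))  # occupied w/ buffer
    truthRows <- list()
    attempts <- 0L
    chromPick <- names(chromLengths)
    chromW <- chromLengths / sum(chromLengths)
    for (m in seq_len(nMotifs)) {
        nt <- as.integer(sample(names(nTractProbs), 1L, prob = nTractProbs))
        tl <- as.integer(sample(names(tractLenProbs), nt, replace = TRUE,
                                prob = tractLenProbs))
        ll <- sample(loopLenRange[1L]:loopLenRange[2L], nt - 1L, replace = TRUE)
        seqStr <- .plantMotifSeq(nt, tl, ll)
        wlen <- nchar(seqStr)
        minus <- stats::runif(1) >= strandProb
        repeat {
            attempts <- attempts + 1L
            if (attempts > 10000L)
                stop("could not place ", nMotifs,
                     " motifs in 10000 attempts; lower the motif density")
            chrom <- sample(chromPick, 1L, prob = chromW)
            L <- chromLengths[[chrom]]
            if (L < wlen + 2L) next
            s <- sample.int(L - wlen + 1L, 1L)
            e <- s + wlen - 1L
            # keep planted motifs separated by more than maxLoop so calls
            # cannot chain across plants
            busy <- placed[[chrom]]
            if (length(busy) &&
                any(pmax(s - maxLoop - 1L, 1L) <= busy &
                    busy <= pmin(e + maxLoop + 1L, L))) next
            break
        }
        inst <- if (minus) .reverseComplement(seqStr) else seqStr
        chroms[[chrom]][s:e] <- strsplit(inst, "", fixed = TRUE)[[1L]]
        placed[[chrom]] <- c(placed[[chrom]], s:e)
        # tract coordinates on the forward axis (ascending)
        offs <- cumsum(c(0L, utils::head(tl, -1L) + ll))
        tstart <- s + offs
        if (minus) tstart <- e - (offs + tl) + 1L
        tr <- IRanges(start = sort(tstart), width = tl[order(tstart)])
        truthRows[[m]] <- list(chrom = chrom, start = s, end = e,
                               strand = if (minus) "-" else "+", tracts = tr)
    }
    gr <- GRanges(vapply(truthRows, `[[`, character(1), "chrom"),
                  IRanges(vapply(truthRows, `[[`, integer(1), "start"),
                          vapply(truthRows, `[[`, integer(1), "end")),
                  strand = vapply(truthRows, `[[`, character(1), "strand"))
    mcols(gr)$tracts <- IRangesList(lapply(truthRows, `[[`, "tracts"))
    o <- order(as.character(seqnames(gr)), start(gr))
    gr <- gr[o]
    mcols(gr)$motif_id <- sprintf("%s:%d-%d:%s", as.character(seqnames(gr)),
                                  start(gr), end(gr), as.character(strand(gr)))
    mcols(gr) <- mcols(gr)[, c("motif_id", "tracts")]
    genome <- Biostrings::DNAStringSet(vapply(chroms, paste, character(1),
                                              collapse = ""))
    names(genome) <- names(chromLengths)
    truth <- G4MotifSet(gr, scanConfig = list(
        minTract = min(as.integer(names(tractLenProbs))),
        maxLoop = as.integer(maxLoop), strands = "both"))
    list(genome = genome, truth = truth)
}

#' Generate an aligned "species" pair with controlled motif retention
#'
#' Emits gapless pairwise alignment blocks (one per chromosome) in which
#' non-motif positions of the reference are substituted according to the
#' divergence matrix.  When \code{retention} is a probability, each planted
#' motif is either retained intact (copied unchanged, probability
#' \code{retention}) or actively broken: one disruptive tract position
#' (by the remaining-run rule) is mutated to a non-tract base.  With
#' \code{retention = NULL} motif positions evolve neutrally like everything
#' else (no planted conservation signal - the calibration regime).
#'
#' @param genome DNAStringSet (the reference).
#' @param truth planted-motif \linkS4class{G4MotifSet} from
#'   \code{\link{generateGenome}} (may be empty).
#' @param matrix a \linkS4class{SubstitutionMatrix}; default
#'   \code{divergenceMatrix(divergence)}.
#' @param divergence scalar divergence used when \code{matrix} is NULL.
#' @param retention per-motif retention probability, or NULL for neutral
#'   evolution of motif positions.
#' @param refSpecies,speciesName row names for the emitted blocks.
#' @param seed integer seed.
#' @return list with \code{blocks} (list of \linkS4class{AlignmentBlock}) and
#'   \code{truth} (data.frame motif_id, retained; all NA when neutral).
#' @export
generateSpeciesPair <- function(genome, truth = NULL, matrix = NULL,
                                divergence = 0.1, retention = NULL,
                                refSpecies = "ref", speciesName = "sp",
                                seed = 1L) {
    if (is.null(matrix)) matrix <- divergenceMatrix(divergence)
    P <- probMatrix(matrix)
    set.seed(as.integer(seed))
    seqs <- .asSeqVector(genome)
    species <- lapply(seqs, function(s) {
        chars <- strsplit(s, "", fixed = TRUE)[[1L]]
        out <- chars
        for (b in .BASES) {
            pos <- which(chars == b)
            if (length(pos))
                out[pos] <- sample(.BASES, length(pos), replace = TRUE,
                                   prob = P[b, ])
        }
        out
    })
    truthGr <- if (is.null(truth)) GRanges() else motifRanges(truth)
    retained <- rep(NA, length(truthGr))
    if (!is.null(retention) && length(truthGr)) {
        cls <- classifyMotifPositions(truth)
        refCharsAll <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
        for (i in seq_along(truthGr)) {
            chrom <- as.character(seqnames(truthGr))[i]
            s <- start(truthGr)[i]; e <- end(truthGr)[i]
            refChars <- refCharsAll[[chrom]][s:e]
            keep <- stats::runif(1) < retention
            mot <- refChars
            if (!keep) {
                # break the motif pattern outright: leave only three intact
                # tracts, and within each disrupted tract substitute every
                # minTract-th base so no run of minTract tract bases remains
                tr <- motifTracts(truth)[[i]]
                minTract <- scanConfig(truth)$minTract
                nBreak <- length(tr) - 3L
                brk <- sample(seq_along(tr), nBreak)
                for (j in brk) {
                    local <- (start(tr)[j]:end(tr)[j]) - s + 1L
                    hitLocal <- local[seq_along(local) %% minTract == 0L]
                    tractBase <- mot[hitLocal[1L]]  # G (plus) or C (minus)
                    mot[hitLocal] <- sample(setdiff(.BASES, tractBase),
                                            length(hitLocal), replace = TRUE)
                }
            }
            species[[chrom]][s:e] <- mot
            retained[i] <- keep
        }
    }
    blocks <- lapply(names(seqs), function(chrom) {
        rows <- c(seqs[[chrom]], paste(species[[chrom]], collapse = ""))
        names(rows) <- c(refSpecies, speciesName)
        AlignmentBlock(refSpecies = refSpecies, refChrom = chrom,
                       refStart = 1L, rows = rows)
    })
    list(blocks = blocks,
         truth = data.frame(motif_id = if (length(truthGr))
                                mcols(truthGr)$motif_id else character(0),
                            retained = retained, stringsAsFactors = FALSE))
}

#' Generate a feature set with controlled enrichment near planted motifs
#'
#' Each feature is placed, with probability \code{enrichment}, so that it
#' overlaps the \code{window}-expanded interval of a randomly chosen planted
#' motif; otherwise uniformly at random (chromosomes weighted by length).
#'
#' @param chromLengths named chromosome lengths.
#' @param truth planted-motif \linkS4class{G4MotifSet} (required when
#'   \code{enrichment > 0}).
#' @param nFeatures number of features.
#' @param featureLenRange inclusive range feature lengths are drawn from.
#' @param enrichment probability of motif-proximal placement, in [0,1].
#' @param window proximity window in nucleotides.
#' @param name feature-set name.
#' @param seed integer seed.
#' @return a \linkS4class{FeatureSet} (window 0; the enrichment window only
#'   shapes placement).
#' @export
generateFeatures <- function(chromLengths, truth = NULL, nFeatures = 200L,
                             featureLenRange = c(100L, 500L), enrichment = 0,
                             window = 0L, name = "synthetic_feature",
                             seed = 1L) {
    stopifnot(enrichment >= 0, enrichment <= 1)
    set.seed(as.integer(seed))
    truthGr <- if (is.null(truth)) GRanges() else .asGRanges(truth)
    if (enrichment > 0 && !length(truthGr))
        stop("enriched placement needs planted-motif truth")
    chromW <- chromLengths / sum(chromLengths)
    lens <- sample(featureLenRange[1L]:featureLenRange[2L], nFeatures,
                   replace = TRUE)
    chn <- character(nFeatures); st <- integer(nFeatures)
    for (i in seq_len(nFeatures)) {
        if (stats::runif(1) < enrichment) {
            j <- sample.int(length(truthGr), 1L)
            chrom <- as.character(seqnames(truthGr))[j]
            L <- chromLengths[[chrom]]
            lo <- max(1L, start(truthGr)[j] - window - lens[i] + 1L)
            hi <- min(L - lens[i] + 1L, end(truthGr)[j] + window)
            st[i] <- if (hi <= lo) lo else sample(lo:hi, 1L)
            chn[i] <- chrom
        } else {
            chrom <- sample(names(chromLengths), 1L, prob = chromW)
            L <- chromLengths[[chrom]]
            st[i] <- sample.int(L - lens[i] + 1L, 1L)
            chn[i] <- chrom
        }
    }
    FeatureSet(name, GRanges(chn, IRanges(st, width = lens)), window = 0L)
}

#' Generate a conservation score track with boosts at planted motifs
#'
#' Background scores are Normal(\code{bgMean}, \code{bgSd}); positions inside
#' planted motifs receive \code{motifBoost}, disruptive tract positions an
#' additional \code{disruptiveBoost}; clamping to [0,1] is applied last.
#' Defaults emulate the magnitudes seen in phastCons tracks around yeast G4
#' motifs (background near 0.65, motif boost of a few hundredths).  A random
#' fraction of positions can be marked missing (unaligned).
#'
#' @param genome DNAStringSet (defines chromosome names/lengths).
#' @param truth planted-motif \linkS4class{G4MotifSet}.
#' @param bgMean,bgSd background score distribution before clamping.
#' @param motifBoost added inside planted motifs.
#' @param disruptiveBoost added at disruptive positions (on top of
#'   \code{motifBoost}).
#' @param naFraction fraction of positions set missing.
#' @param minTract classification parameter for disruptive positions.
#' @param seed integer seed.
#' @return a \linkS4class{ScoreTrack}.
#' @export
generateScoreTrack <- function(genome, truth = NULL, bgMean = 0.64,
                               bgSd = 0.2, motifBoost = 0.02,
                               disruptiveBoost = 0.04, naFraction = 0,
                               minTract = 3L, seed = 1L) {
    set.seed(as.integer(seed))
    lens <- if (methods::is(genome, "XStringSet")) {
        stats::setNames(Biostrings::width(genome), names(genome))
    } else stats::setNames(nchar(genome), names(genome))
    scores <- lapply(lens, function(L) stats::rnorm(L, bgMean, bgSd))
    if (!is.null(truth) && length(truth)) {
        gr <- motifRanges(truth)
        cls <- classifyMotifPositions(truth, minTract)
        for (i in seq_along(gr)) {
            chrom <- as.character(seqnames(gr))[i]
            span <- start(gr)[i]:end(gr)[i]
            scores[[chrom]][span] <- scores[[chrom]][span] + motifBoost
            dis <- span[cls[[i]] == "disruptive"]
            scores[[chrom]][dis] <- scores[[chrom]][dis] + disruptiveBoost
        }
    }
    scores <- lapply(scores, function(v) {
        v <- pmin(1, pmax(0, v))
        if (naFraction > 0)
            v[stats::runif(length(v)) < naFraction] <- NA_real_
        v
    })
    ScoreTrack(scores)
}
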