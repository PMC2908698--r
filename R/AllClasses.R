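#' @import methods
#' @importFrom S4Vectors metadata metadata<- mcols mcols<- DataFrame Rle
#' @importFrom IRanges IRanges IRangesList start end width
#' @importFrom GenomicRanges GRanges granges seqnames strand
#' @importFrom BiocGenerics sort
NULL

.BASES <- c("A", "C", "G", "T")

#' G4MotifSet: a located set of G-quadruplex DNA motifs
#'
#' Container for G4 DNA motif calls on a genome.  Each motif is a run of four
#' or more G-tracts (maximal runs of >= \code{minTract} guanines on the motif
#' strand) separated by loops of at most \code{maxLoop} nucleotides.  The
#' ranges are standard 1-based closed \link[GenomicRanges]{GRanges}; the
#' per-motif G-tract coordinates (forward genomic axis, ascending) are kept as
#' an \link[IRanges]{IRangesList} column so that loop geometry, disruptive
#' positions and stacked-quartet counts can be derived without re-scanning.
#'
#' @slot motifs GRanges with metadata columns \code{motif_id} (character) and
#'   \code{tracts} (IRangesList of per-motif G-tract ranges).
#' @slot scanConfig list with elements \code{minTract}, \code{maxLoop},
#'   \code{strands} recording the scan that produced the set.
#'
#' @export
setClass("G4MotifSet",
    representation(motifs = "GRanges", scanConfig = "list"))

.validG4MotifSet <- function(object) {
    gr <- object@motifs
    cfg <- object@scanConfig
    msg <- character()
    need <- c("minTract", "maxLoop", "strands")
    if (!all(need %in% names(cfg)))
        return(sprintf("scanConfig must contain %s", paste(need, collapse = ", ")))
    if (!all(c("motif_id", "tracts") %in% colnames(mcols(gr))))
        return("motifs must carry 'motif_id' and 'tracts' metadata columns")
    if (length(gr) == 0L) return(TRUE)
    tr <- mcols(gr)$tracts
    nt <- lengths(tr)
    if (any(nt < 4L))
        msg <- c(msg, "every motif needs >= 4 G-tracts")
    ts <- start(tr); te <- end(tr)
    first <- vapply(ts, `[`, integer(1), 1L)
    last <- vapply(te, function(x) x[length(x)], integer(1))
    if (any(first != start(gr)) || any(last != end(gr)))
        msg <- c(msg, "motif span must run from first tract start to last tract end")
    if (any(unlist(width(tr), use.names = FALSE) < cfg$minTract))
        msg <- c(msg, sprintf("all tract widths must be >= minTract (%d)", cfg$minTract))
    loopw <- unlist(lapply(seq_along(tr), function(i) {
        s <- ts[[i]]; e <- te[[i]]
        if (length(s) < 2L) return(integer())
        s[-1L] - e[-length(e)] - 1L
    }), use.names = FALSE)
    if (length(loopw) && (any(loopw < 1L) || any(loopw > cfg$maxLoop)))
        msg <- c(msg, sprintf("every loop length must lie in [1, %d]", cfg$maxLoop))
    if (length(msg)) msg else TRUE
}
setValidity("G4MotifSet", .validG4MotifSet)

#' Construct a G4MotifSet
#'
#' @param motifs GRanges with \code{motif_id} and \code{tracts} metadata.
#' @param scanConfig list(minTract, maxLoop, strands).
#' @return A \linkS4class{G4MotifSet}.
#' @export
G4MotifSet <- function(motifs = GRanges(),
                       scanConfig = list(minTract = 3L, maxLoop = 25L,
                                         strands = "both")) {
    if (is.null(mcols(motifs)$motif_id)) mcols(motifs)$motif_id <- character(0)
    if (is.null(mcols(motifs)$tracts)) mcols(motifs)$tracts <- IRangesList()
    new("G4MotifSet", motifs = motifs, scanConfig = scanConfig)
}

#' @describeIn G4MotifSet the motif GRanges (coordinates, strand, ids, tracts)
#' @param x a G4MotifSet
#' @export
motifRanges <- function(x) x@motifs

#' @describeIn G4MotifSet per-motif G-tract ranges (forward genomic axis)
#' @export
motifTracts <- function(x) mcols(x@motifs)$tracts

#' @describeIn G4MotifSet the scan configuration used to build the set
#' @export
scanConfig <- function(x) x@scanConfig

setMethod("length", "G4MotifSet", function(x) length(x@motifs))

setMethod("[", "G4MotifSet", function(x, i, j, ..., drop = TRUE) {
    initialize(x, motifs = x@motifs[i], scanConfig = x@scanConfig)
})

setMethod("show", "G4MotifSet", function(object) {
    cfg <- object@scanConfig
    cat(sprintf("G4MotifSet with %d motifs (minTract=%d, maxLoop=%d, strands=%s)\n",
                length(object), cfg$minTract, cfg$maxLoop, cfg$strands))
    if (length(object)) {
        nt <- lengths(motifTracts(object))
        cat(sprintf("  chromosomes: %s\n",
            paste(unique(as.character(seqnames(object@motifs))), collapse = ", ")))
        cat(sprintf("  G-tracts per motif: %d-%d (mean %.2f)\n",
            min(nt), max(nt), mean(nt)))
    }
    fc <- metadata(object@motifs)$filterCounts
    if (!is.null(fc))
        cat("  filtered:", paste(sprintf("%s=%d", names(fc), fc), collapse = " "), "\n")
    invisible(NULL)
})

#' AlignmentBlock: one reference-anchored pairwise/multiple alignment block
#'
#' Rows are gapped sequences over \{A,C,G,T,N,-\}, all of equal column count,
#' keyed by species name.  The reference row is anchored to a genomic interval
#' (1-based closed, forward strand; minus-strand MAF blocks are
#' reverse-complemented at read time).
#'
#' @slot refSpecies name of the reference species (must be a row).
#' @slot refChrom reference chromosome name.
#' @slot refStart 1-based start of the reference segment.
#' @slot rows named character vector of gapped rows.
#' @export
setClass("AlignmentBlock",
    representation(refSpecies = "character", refChrom = "character",
                   refStart = "integer", rows = "character"))

.validAlignmentBlock <- function(object) {
    r <- object@rows
    if (is.null(names(r)) || !object@refSpecies %in% names(r))
        return("reference species must be one of the row names")
    nc <- unique(nchar(r))
    if (length(nc) != 1L)
        return("all rows must have the same column count")
    if (nc == 0L) return("empty block")
    refrow <- r[[object@refSpecies]]
    if (nchar(gsub("-", "", refrow, fixed = TRUE)) == 0L)
        return("reference row is all gaps")
    if (object@refStart < 1L) return("refStart must be >= 1")
    TRUE
}
setValidity("AlignmentBlock", .validAlignmentBlock)

#' @describeIn AlignmentBlock constructor
#' @param refSpecies,refChrom,refStart,rows see slots
#' @export
AlignmentBlock <- function(refSpecies, refChrom, refStart, rows) {
    new("AlignmentBlock", refSpecies = refSpecies, refChrom = refChrom,
        refStart = as.integer(refStart), rows = toupper(rows))
}

#' @describeIn AlignmentBlock the gapped rows, named by species
#' @param x an AlignmentBlock
#' @export
alignmentRows <- function(x) x@rows

#' @describeIn AlignmentBlock ungapped reference width
#' @export
refWidth <- function(x)
    nchar(gsub("-", "", x@rows[[x@refSpecies]], fixed = TRUE))

#' @describeIn AlignmentBlock the reference interval as a GRanges
#' @export
refInterval <- function(x)
    GRanges(x@refChrom, IRanges(x@refStart, x@refStart + refWidth(x) - 1L))

setMethod("show", "AlignmentBlock", function(object) {
    cat(sprintf("AlignmentBlock %s:%d-%d (ref %s), %d rows x %d columns\n",
        object@refChrom, object@refStart, object@refStart + refWidth(object) - 1L,
        object@refSpecies, length(object@rows), nchar(object@rows[[1L]])))
    invisible(NULL)
})

#' SubstitutionMatrix: conditional nucleotide change probabilities
#'
#' A 4x4 row-stochastic matrix \eqn{P(b \mid a)} over A,C,G,T: row \eqn{a} is
#' the distribution of the aligned partner base given reference base \eqn{a}.
#'
#' @slot probs numeric 4x4 matrix, rows summing to 1 within 1e-9.
#' @export
setClass("SubstitutionMatrix", representation(probs = "matrix"))

.validSubMat <- function(object) {
    p <- object@probs
    if (!identical(dim(p), c(4L, 4L)) ||
        !identical(rownames(p), .BASES) || !identical(colnames(p), .BASES))
        return("probs must be 4x4 with A,C,G,T dimnames")
    if (any(p < 0)) return("all entries must be >= 0")
    if (any(abs(rowSums(p) - 1) > 1e-9)) return("rows must sum to 1 within 1e-9")
    TRUE
}
setValidity("SubstitutionMatrix", .validSubMat)

#' @describeIn SubstitutionMatrix constructor from a matrix
#' @param probs 4x4 row-stochastic matrix with A,C,G,T dimnames
#' @export
SubstitutionMatrix <- function(probs) {
    storage.mode(probs) <- "double"
    new("SubstitutionMatrix", probs = probs)
}

#' @describeIn SubstitutionMatrix extract the probability matrix
#' @param x a SubstitutionMatrix
#' @export
probMatrix <- function(x) x@probs

setMethod("show", "SubstitutionMatrix", function(object) {
    cat("SubstitutionMatrix P(column | row):\n")
    print(round(object@probs, 4))
    invisible(NULL)
})

#' ScoreTrack: per-base conservation scores in [0,1]
#'
#' One numeric vector per chromosome; positions without data (unaligned bases)
#' carry \code{NA}, which is distinct from a score of 0.
#'
#' @slot scores named list of numeric vectors, values in [0,1] or NA.
#' @export
setClass("ScoreTrack", representation(scores = "list"))

.validScoreTrack <- function(object) {
    s <- object@scores
    if (length(s) && is.null(names(s))) return("scores must be a named list")
    for (v in s) {
        if (!is.numeric(v)) return("scores must be numeric vectors")
        d <- v[!is.na(v)]
        if (length(d) && (min(d) < 0 || max(d) > 1))
            return("every defined score must lie in [0,1]")
    }
    TRUE
}
setValidity("ScoreTrack", .validScoreTrack)

#' @describeIn ScoreTrack constructor
#' @param scores named list of per-chromosome numeric vectors
#' @export
ScoreTrack <- function(scores = list()) new("ScoreTrack", scores = scores)

setMethod("show", "ScoreTrack", function(object) {
    cat(sprintf("ScoreTrack over %d chromosome(s)\n", length(object@scores)))
    for (nm in names(object@scores)) {
        v <- object@scores[[nm]]
        cat(sprintf("  %s: %d positions, %d scored\n", nm, length(v), sum(!is.na(v))))
    }
    invisible(NULL)
})

#' FeatureSet: a named collection of genome feature intervals
#'
#' Wraps a GRanges and a window half-width: when overlaps are counted the
#' intervals are expanded by \code{window} nucleotides on each side (and
#' clipped to the chromosome), matching windowed feature definitions such as
#' "within 500 nt of an ARS".
#'
#' @slot name feature-set name.
#' @slot ranges GRanges (strand "*" means unstranded).
#' @slot window non-negative integer expansion per side.
#' @export
setClass("FeatureSet",
    representation(name = "character", ranges = "GRanges", window = "integer"))

setValidity("FeatureSet", function(object) {
    if (object@window < 0L) return("window must be >= 0")
    if (length(object@name) != 1L) return("name must be a single string")
    TRUE
})

#' @describeIn FeatureSet constructor
#' @param name,ranges,window see slots
#' @export
FeatureSet <- function(name, ranges, window = 0L) {
    new("FeatureSet", name = name, ranges = ranges, window = as.integer(window))
}

#' @describeIn FeatureSet the underlying (unexpanded) GRanges
#' @param x a FeatureSet
#' @export
featureRanges <- function(x) x@ranges

#' @describeIn FeatureSet the feature-set name
#' @export
featureName <- function(x) x@name

#' @describeIn FeatureSet the per-side window expansion in nucleotides
#' @export
featureWindow <- function(x) x@window

setMethod("length", "FeatureSet", function(x) length(x@ranges))

setMethod("show", "FeatureSet", function(object) {
    cat(sprintf("FeatureSet '%s': %d intervals, window %d nt\n",
                object@name, length(object@ranges), object@window))
    invisible(NULL)
})

#' AssociationResult: a motif/feature association test
#'
#' Holds the observed number of query regions overlapping the (window
#' expanded) reference features, the null distribution of that count over
#' chromosome- and length-matched random query placements, and two-tailed
#' empirical p-values.  Equality with the observed count contributes to both
#' tails.  A tail with zero as-extreme replicates is floored at 1/R and
#' labelled "< 1/R".
#'
#' @slot feature reference feature-set name.
#' @slot observed observed overlap count (query regions).
#' @slot nullCounts integer vector of replicate counts.
#' @slot pOver,pUnder empirical p-values in (0,1].
#' @slot pOverLabel,pUnderLabel printable forms (used when floored).
#' @slot seed master seed used for the random placements.
#' @export
setClass("AssociationResult",
    representation(feature = "character", observed = "integer",
                   nullCounts = "integer", pOver = "numeric",
                   pUnder = "numeric", pOverLabel = "character",
                   pUnderLabel = "character", seed = "integer"))

setValidity("AssociationResult", function(object) {
    if (object@pOver <= 0 || object@pOver > 1 ||
        object@pUnder <= 0 || object@pUnder > 1)
        return("empirical p-values must lie in (0,1]")
    TRUE
})

#' @describeIn AssociationResult observed overlap count
#' @param x an AssociationResult
#' @export
observedCount <- function(x) x@observed

#' @describeIn AssociationResult replicate null counts
#' @export
nullCounts <- function(x) x@nullCounts

#' @describeIn AssociationResult upper-tail empirical p (over-association)
#' @export
pOver <- function(x) x@pOver

#' @describeIn AssociationResult lower-tail empirical p (under-association)
#' @export
pUnder <- function(x) x@pUnder

setMethod("show", "AssociationResult", function(object) {
    cat(sprintf("AssociationResult '%s': observed %d, R=%d, p_over %s, p_under %s\n",
        object@feature, object@observed, length(object@nullCounts),
        object@pOverLabel, object@pUnderLabel))
    invisible(NULL)
})

#' NullSummary: empirical significance of a conserved-motif count
#'
#' Result of the evolutionary null for motif-level conservation: the observed
#' number of conserved motifs for a species, the replicate conserved counts
#' obtained by re-scanning sequence evolved under the estimated substitution
#' matrix, and the empirical p-value (fraction of replicates with a count at
#' least as large as observed; floored at 1/N, labelled "< 1/N").
#'
#' @slot species species compared against the reference.
#' @slot observed observed conserved count.
#' @slot replicates integer vector of replicate conserved counts.
#' @slot p empirical p-value in (0,1].
#' @slot pLabel printable p (used when floored).
#' @slot seed master seed.
#' @export
setClass("NullSummary",
    representation(species = "character", observed = "integer",
                   replicates = "integer", p = "numeric", pLabel = "character",
                   seed = "integer"))

setValidity("NullSummary", function(object) {
    if (object@p <= 0 || object@p > 1) return("p must lie in (0,1]")
    TRUE
})

#' @describeIn NullSummary replicate conserved counts
#' @param x a NullSummary
#' @export
nullReplicates <- function(x) x@replicates

#' @describeIn NullSummary the empirical p-value
#' @export
empiricalP <- function(x) x@p

setMethod("show", "NullSummary", function(object) {
    cat(sprintf("NullSummary [%s]: observed %d conserved, N=%d replicates, p %s (seed %d)\n",
        object@species, object@observed, length(object@replicates),
        object@pLabel, object@seed))
    invisible(NULL)
})
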