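# Internal helpers shared across modules.

# Stable 31-bit string hash (polynomial, mod 2^31-1).  Used to derive
# per-stage and per-replicate seeds from a master seed so that results are
# independent of processing order and stages can be rerun in isolation.
.stableHash <- function(x) {
    h <- 0
    for (cp in utf8ToInt(x)) h <- (h * 131 + cp) %% 2147483647
    as.integer(h)
}

#' Derive a reproducible per-stage seed from a master seed
#'
#' Seeds for independent pipeline stages (or null-model replicates) are
#' derived by stable hashing of the master seed together with a stage label,
#' so each stage is reproducible on its own and insensitive to the order in
#' which other stages run.
#'
#' @param master integer master seed.
#' @param stage character label (e.g. "scan", "conserve/rep17").
#' @return an integer seed in [0, 2^31-2].
#' @export
deriveStageSeed <- function(master, stage) {
    .stableHash(paste(as.integer(master), stage, sep = "\r"))
}

.reverseComplement <- function(x) {
    vapply(x, function(s) {
        paste(rev(strsplit(chartr("ACGTN-", "TGCAN-", s), "", fixed = TRUE)[[1L]]),
              collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

# Coerce DNAStringSet / named character to a named uppercase character vector.
.asSeqVector <- function(genome) {
    if (methods::is(genome, "DNAStringSet") || methods::is(genome, "XStringSet"))
        genome <- as.character(genome)
    if (!is.character(genome) || is.null(names(genome)))
        stop("genome must be a named character vector or DNAStringSet")
    toupper(genome)
}

#' Is a chromosome name mitochondrial?
#'
#' Heuristic on common naming conventions (chrM, chrMT, chrMito, Mito, MT...).
#'
#' @param x character vector of chromosome names.
#' @return logical vector.
#' @export
isMitochondrialName <- function(x) {
    grepl("^(chr)?(m|mt|mito(chondri(on|al?))?)$", x, ignore.case = TRUE)
}

# Coerce G4MotifSet / FeatureSet / GRanges to GRanges.
.asGRanges <- function(x) {
    if (methods::is(x, "G4MotifSet")) return(motifRanges(x))
    if (methods::is(x, "FeatureSet")) return(featureRanges(x))
    if (methods::is(x, "GRanges")) return(x)
    stop("cannot coerce object of class ", class(x)[1L], " to GRanges")
}
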