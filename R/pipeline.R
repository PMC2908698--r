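# Pipeline driver and report tables.  The package's command surface is its
# exported functions; this file provides the end-to-end scan driver with a
# run manifest, and the summary tables (per-species counts/densities, motif
# property comparisons, feature associations).

#' Motif density per kilobase
#'
#' @param nMotifs motif count (may be a vector).
#' @param kb kilobases of sequence considered.
#' @return motifs per kb (0 when \code{nMotifs} is 0, even if \code{kb} is 0).
#' @export
motifDensity <- function(nMotifs, kb) {
    ifelse(nMotifs == 0, 0, nMotifs / kb)
}

#' Per-species motif count and density table
#'
#' @param counts named integer vector of motif counts per species/genome.
#' @param kb named numeric vector of kilobases considered (same names).
#' @return data.frame with species, n_motifs, kb_considered, density_per_kb.
#' @export
densityReport <- function(counts, kb) {
    stopifnot(identical(names(counts), names(kb)))
    data.frame(species = names(counts), n_motifs = as.integer(counts),
               kb_considered = as.numeric(kb),
               density_per_kb = motifDensity(as.integer(counts), as.numeric(kb)),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a run manifest
#'
#' Records the subcommand, the fully resolved configuration, the master seed,
#' md5 digests of the input files and the package version, as JSON.  Reruns
#' with an identical manifest produce byte-identical outputs, so no
#' timestamp is included.
#'
#' @param outDir output directory (created if needed).
#' @param subcommand stage name (e.g. "scan").
#' @param config named list of resolved parameters.
#' @param seed master seed.
#' @param inputs character vector of input file paths (digested).
#' @return invisibly, the manifest path.
#' @export
writeRunManifest <- function(outDir, subcommand, config, seed, inputs = character()) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
    manifest <- list(subcommand = subcommand,
                     tool = "g4scope",
                     version = as.character(utils::packageVersion("g4scope")),
                     seed = as.integer(seed),
                     config = config,
                     inputs = digests)
    path <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(path)
}

#' Scan a FASTA genome and write motif calls
#'
#' End-to-end scan stage: reads the genome, scans for G4 motifs, applies the
#' telomere/mitochondrial/rDNA filters, and writes \code{motifs.bed} (BED6,
#' name = motif id, score = number of G-tracts), \code{motifs.tsv} (one row
#' per motif with its physical properties) and \code{manifest.json} to
#' \code{outDir}.  Per-filter removal counts are kept in the returned set's
#' metadata and echoed into the manifest, making count bookkeeping across
#' filtering steps auditable.
#'
#' @param fasta path to the genome FASTA.
#' @param outDir output directory.
#' @param minTract,maxLoop,strands scan parameters.
#' @param telomeres optional BED path or FeatureSet/GRanges telomere mask.
#' @param excludeMitochondrial drop mitochondrial motifs?
#' @param rdnaRepeats optional GRanges of rDNA repeat copies.
#' @param seed master seed recorded in the manifest (the scan itself is
#'   deterministic).
#' @return the filtered \linkS4class{G4MotifSet}, invisibly.
#' @export
runScanPipeline <- function(fasta, outDir, minTract = 3L, maxLoop = 25L,
                            strands = "both", telomeres = NULL,
                            excludeMitochondrial = FALSE, rdnaRepeats = NULL,
                            seed = 0L) {
    genome <- readGenomeFasta(fasta)
    motifs <- scanG4Motifs(genome, minTract = minTract, maxLoop = maxLoop,
                           strands = strands)
    teloMask <- if (is.character(telomeres)) {
        featureRanges(readFeatures(telomeres, "bed", name = "telomeres"))
    } else telomeres
    motifs <- filterG4Motifs(motifs, telomeres = teloMask,
                             excludeMitochondrial = excludeMitochondrial,
                             rdnaRepeats = rdnaRepeats)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    gr <- motifRanges(motifs)
    bed <- gr
    mcols(bed) <- NULL
    mcols(bed)$name <- mcols(gr)$motif_id
    mcols(bed)$score <- lengths(motifTracts(motifs))
    rtracklayer::export(bed, file.path(outDir, "motifs.bed"), format = "bed")
    props <- as.data.frame(motifProperties(motifs))
    utils::write.table(props, file.path(outDir, "motifs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    inputs <- c(fasta, if (is.character(telomeres)) telomeres)
    writeRunManifest(outDir, "scan",
                     config = list(minTract = minTract, maxLoop = maxLoop,
                                   strands = strands,
                                   excludeMitochondrial = excludeMitochondrial,
                                   filterCounts = as.list(filterCounts(motifs))),
                     seed = seed, inputs = inputs)
    invisible(motifs)
}
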