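## Central S4 containers. Validity checks are kept cheap (length/shape
## consistency); deep semantic checks (canonical form of every kmer, etc.)
## live in the functions that build the objects.

#' ReadSet: a set of sequencing reads
#'
#' Parallel character vectors of identifiers, uppercase nucleotide sequences
#' over \{A,C,G,T,N\} and phred+33 quality strings. The quality string of
#' every read has the same length as its sequence.
#'
#' @slot id character, read identifiers.
#' @slot sequence character, nucleotide sequences.
#' @slot quality character, phred+33 quality strings.
#' @exportClass ReadSet
setClass("ReadSet",
    representation(id = "character", sequence = "character",
                   quality = "character"))

setValidity("ReadSet", function(object) {
    n <- length(object@id)
    if (length(object@sequence) != n || length(object@quality) != n)
        return("id, sequence and quality must have equal length")
    bad <- which(nchar(object@quality) != nchar(object@sequence))
    if (length(bad))
        return(sprintf("quality length != sequence length at read %d", bad[1]))
    TRUE
})

#' Construct a ReadSet
#'
#' @param id,sequence,quality parallel character vectors; sequences are
#'   uppercased on construction. If `quality` is missing, constant Q40
#'   ("I") strings are filled in.
#' @return A [ReadSet-class] object.
#' @examples
#' rs <- ReadSet("r1", "ACGT", "IIII")
#' sequences(rs)
#' @export
ReadSet <- function(id = character(), sequence = character(), quality = NULL) {
    sequence <- toupper(as.character(sequence))
    if (is.null(quality))
        quality <- vapply(nchar(sequence),
                          function(n) strrep("I", n), character(1))
    new("ReadSet", id = as.character(id), sequence = sequence,
        quality = as.character(quality))
}

#' KmerTable: canonical k-mer counts at fixed k
#'
#' Maps each canonical k-mer (the lexicographically smaller of a k-mer and
#' its reverse complement, A<C<G<T) to a positive occurrence count. K-mers
#' are stored sorted lexicographically. Also serves as a presence set for
#' reference genomes in contamination screening.
#'
#' @slot k integer k-mer length (1--32).
#' @slot kmer character, canonical k-mers, sorted.
#' @slot count numeric, occurrence counts (>= 1).
#' @exportClass KmerTable
setClass("KmerTable",
    representation(k = "integer", kmer = "character", count = "numeric"))

setValidity("KmerTable", function(object) {
    if (length(object@k) != 1L || is.na(object@k) || object@k < 1L ||
        object@k > 32L)
        return("k must be a single integer in [1, 32]")
    if (length(object@kmer) != length(object@count))
        return("kmer and count must have equal length")
    if (length(object@count) && any(object@count < 1))
        return("all counts must be >= 1")
    if (length(object@kmer) && any(nchar(object@kmer) != object@k))
        return("all kmers must have length k")
    TRUE
})

#' SpectrumHistogram: k-mer multiplicity spectrum
#'
#' For each multiplicity m >= 1, the number of distinct canonical k-mers
#' observed exactly m times ("coverage against count of kmers with a given
#' coverage"). Only non-empty bins are stored; [spectrumBins()] densifies.
#'
#' @slot multiplicity integer, sorted ascending, >= 1.
#' @slot count numeric, number of distinct k-mers per multiplicity.
#' @exportClass SpectrumHistogram
setClass("SpectrumHistogram",
    representation(multiplicity = "integer", count = "numeric"))

setValidity("SpectrumHistogram", function(object) {
    if (length(object@multiplicity) != length(object@count))
        return("multiplicity and count must have equal length")
    if (length(object@multiplicity)) {
        if (any(object@multiplicity < 1L))
            return("multiplicities must be >= 1")
        if (is.unsorted(object@multiplicity, strictly = TRUE))
            return("multiplicities must be strictly increasing")
        if (any(object@count < 0))
            return("bin counts must be >= 0")
    }
    TRUE
})

#' SubsampleSpec: how to subsample a read stream
#'
#' Screening subsamples reads for speed (default fraction 0.10). Systematic
#' mode takes every round(1/fraction)-th read starting from the first;
#' random mode draws a seeded Bernoulli sample.
#'
#' @slot fraction numeric in (0, 1].
#' @slot mode "systematic" or "random".
#' @slot seed integer seed for random mode.
#' @exportClass SubsampleSpec
setClass("SubsampleSpec",
    representation(fraction = "numeric", mode = "character", seed = "integer"))

setValidity("SubsampleSpec", function(object) {
    if (length(object@fraction) != 1L || is.na(object@fraction) ||
        object@fraction <= 0 || object@fraction > 1)
        return("fraction must be a single value in (0, 1]")
    if (!object@mode %in% c("systematic", "random"))
        return("mode must be 'systematic' or 'random'")
    TRUE
})

#' @rdname SubsampleSpec-class
#' @param fraction fraction of reads to keep, in (0, 1].
#' @param mode "systematic" (deterministic, default) or "random" (seeded).
#' @param seed integer seed used by random mode.
#' @return A [SubsampleSpec-class] object.
#' @export
subsampleSpec <- function(fraction = 0.10, mode = c("systematic", "random"),
                          seed = 1L) {
    new("SubsampleSpec", fraction = as.numeric(fraction),
        mode = match.arg(mode), seed = as.integer(seed))
}

#' ScreenReport: result of a contamination screen
#'
#' Carries the two headline metrics of a k-mer contamination screen: the
#' percentage of (sub)sampled reads containing one or more reference k-mers,
#' and the percentage of the reference's distinct k-mers observed anywhere
#' in the sampled reads.
#'
#' @slot reference_name character.
#' @slot k integer k-mer size used.
#' @slot reads_screened,reads_with_hit numeric counts.
#' @slot reads_with_hit_pct numeric percentage.
#' @slot ref_kmers_total,ref_kmers_observed numeric counts.
#' @slot ref_covered_pct numeric percentage.
#' @slot subsample_fraction numeric fraction screened.
#' @exportClass ScreenReport
setClass("ScreenReport",
    representation(reference_name = "character", k = "integer",
                   reads_screened = "numeric", reads_with_hit = "numeric",
                   reads_with_hit_pct = "numeric",
                   ref_kmers_total = "numeric",
                   ref_kmers_observed = "numeric",
                   ref_covered_pct = "numeric",
                   subsample_fraction = "numeric"))

setValidity("ScreenReport", function(object) {
    if (object@reads_with_hit < 0 || object@reads_with_hit > object@reads_screened)
        return("reads_with_hit must lie in [0, reads_screened]")
    if (object@ref_kmers_observed < 0 ||
        object@ref_kmers_observed > object@ref_kmers_total)
        return("ref_kmers_observed must lie in [0, ref_kmers_total]")
    TRUE
})

#' SpectraSet: spectra for R1, R2 and their pooled counts
#'
#' @slot r1,r2,combined [SpectrumHistogram-class] objects. `combined` is the
#'   spectrum of the pooled k-mer counts of both files, not the sum of the
#'   two histograms.
#' @slot k integer k-mer size.
#' @exportClass SpectraSet
setClass("SpectraSet",
    representation(r1 = "SpectrumHistogram", r2 = "SpectrumHistogram",
                   combined = "SpectrumHistogram", k = "integer"))

#' SpectraAnalysis: interpretation of a k-mer spectrum
#'
#' @slot error_threshold integer multiplicity separating the low-coverage
#'   error peak from genomic content.
#' @slot peaks data.frame with columns `multiplicity`, `height` (smoothed),
#'   sorted by multiplicity.
#' @slot main_peak integer multiplicity of the main genomic peak.
#' @slot zygosity "homozygous", "heterozygous" or "undetermined".
#' @slot genome_size_estimate numeric, in distinct-k-mer units (a proxy for
#'   bases).
#' @exportClass SpectraAnalysis
setClass("SpectraAnalysis",
    representation(error_threshold = "integer", peaks = "data.frame",
                   main_peak = "integer", zygosity = "character",
                   genome_size_estimate = "numeric"))

#' AdaptorSpec: junction-adaptor matching parameters
#'
#' Defaults describe the 38-base Nextera junction adaptor (the 19-base
#' transposon end sequence concatenated with its reverse complement).
#'
#' @slot junction character junction sequence.
#' @slot min_overlap integer minimum end-overlap (bases) for partial matches.
#' @slot max_mismatch_rate numeric mismatch tolerance per overlap base
#'   (0.11 allows 4 mismatches over the full 38-base window).
#' @exportClass AdaptorSpec
setClass("AdaptorSpec",
    representation(junction = "character", min_overlap = "integer",
                   max_mismatch_rate = "numeric"))

setValidity("AdaptorSpec", function(object) {
    if (object@min_overlap > nchar(object@junction))
        return("min_overlap must not exceed the junction length")
    TRUE
})

#' @rdname AdaptorSpec-class
#' @param junction junction-adaptor sequence.
#' @param min_overlap minimum bases of end overlap for a partial match.
#' @param max_mismatch_rate allowed mismatches per base of overlap.
#' @return An [AdaptorSpec-class] object.
#' @export
adaptorSpec <- function(junction = nexteraJunction(), min_overlap = 18L,
                        max_mismatch_rate = 0.11) {
    new("AdaptorSpec", junction = toupper(junction),
        min_overlap = as.integer(min_overlap),
        max_mismatch_rate = as.numeric(max_mismatch_rate))
}

#' The 38-base Nextera junction adaptor
#'
#' The 19-base Nextera transposon end sequence concatenated with its own
#' reverse complement; this sequence marks the circularization junction
#' inside a long-mate-pair read.
#' @return A character string of length 38.
#' @export
nexteraJunction <- function() {
    paste0("CTGTCTCTTATACACATCT", "AGATGTGTATAAGAGACAG")
}

#' MatePairReport: junction analysis of an LMP library
#'
#' @slot category_counts named numeric, pairs per category (A: adaptor in
#'   both reads, B: read 2 only, C: read 1 only, D: neither).
#' @slot excluded_too_short named numeric, per-category pairs excluded
#'   because a clipped mate fell below the minimum length.
#' @slot duplication_rate numeric percent.
#' @slot gc_histogram data.frame (`gc_bin`, `reads`): per-read mean GC%
#'   binned.
#' @slot clipped_paths named character, per-category output FASTQ paths
#'   (empty when no files were written).
#' @exportClass MatePairReport
setClass("MatePairReport",
    representation(category_counts = "numeric",
                   excluded_too_short = "numeric",
                   duplication_rate = "numeric",
                   gc_histogram = "data.frame",
                   clipped_paths = "character"))

#' OrientationReport: alignment-based pair orientation profile
#'
#' @slot pairs data.frame with one row per concordant pair: `category`
#'   (may be NA when no category labels were supplied), `orientation`
#'   ("mate_pair", "paired_end" or "tandem") and `insert` (outer span,
#'   bases).
#' @slot discordant numeric, pairs on different references.
#' @slot unmapped numeric, pairs with an unmapped mate.
#' @exportClass OrientationReport
setClass("OrientationReport",
    representation(pairs = "data.frame", discordant = "numeric",
                   unmapped = "numeric"))

#' DemuxReport: demultiplexing result
#'
#' @slot assigned named numeric, reads (or pairs) per sample.
#' @slot undetermined,ambiguous numeric counts.
#' @slot paths named character, per-sample output paths.
#' @exportClass DemuxReport
setClass("DemuxReport",
    representation(assigned = "numeric", undetermined = "numeric",
                   ambiguous = "numeric", paths = "character"))

#' PerBaseQuality: per-cycle quality statistics
#'
#' @slot stats data.frame with columns `cycle`, `mean`, `median`, `q25`,
#'   `q75`, `n`; statistics at each cycle are computed only over reads
#'   reaching that cycle.
#' @slot read_lengths table of read lengths.
#' @exportClass PerBaseQuality
setClass("PerBaseQuality",
    representation(stats = "data.frame", read_lengths = "table"))

#' RunSummary: headline run metrics and red flags
#'
#' @slot read_count numeric.
#' @slot mean_q30_bases_per_read numeric, mean number of bases at Q>=30 per
#'   read.
#' @slot q30_read_pct numeric, percent of reads whose mean quality is >=30.
#' @slot gc_histogram data.frame (`gc_bin`, `reads`).
#' @slot flags data.frame (`metric`, `value`, `threshold`) of breached
#'   minima.
#' @exportClass RunSummary
setClass("RunSummary",
    representation(read_count = "numeric",
                   mean_q30_bases_per_read = "numeric",
                   q30_read_pct = "numeric",
                   gc_histogram = "data.frame",
                   flags = "data.frame"))

#' MetricStore: per-run/per-base/per-range QC metric warehouse
#'
#' A single-file store of named QC values scoped to a whole run, a single
#' base position, or an inclusive base range, keyed by run metadata
#' (run alias, instrument, chemistry and software versions, lane, sample,
#' barcode). Backed by an environment so that [putMetrics()] mutates in
#' place; [saveStore()] persists to a TSV file.
#'
#' @slot env environment holding the `records` data.frame.
#' @slot path character, file backing the store ("" for in-memory).
#' @exportClass MetricStore
setClass("MetricStore",
    representation(env = "environment", path = "character"))

#' SimConfig: simulator configuration
#'
#' @slot seed integer.
#' @slot genome_size numeric, bases.
#' @slot gc_fraction numeric in (0, 1).
#' @slot ploidy integer, 1 or 2.
#' @slot het_snp_rate numeric heterozygous SNP rate (diploid only).
#' @slot read_length integer bases.
#' @slot depth numeric fold-coverage.
#' @slot substitution_error_rate numeric per-base substitution rate.
#' @slot quality_profile integer, constant phred score or one per cycle.
#' @exportClass SimConfig
setClass("SimConfig",
    representation(seed = "integer", genome_size = "numeric",
                   gc_fraction = "numeric", ploidy = "integer",
                   het_snp_rate = "numeric", read_length = "integer",
                   depth = "numeric", substitution_error_rate = "numeric",
                   quality_profile = "integer"))

setValidity("SimConfig", function(object) {
    rates <- c(object@gc_fraction, object@het_snp_rate,
               object@substitution_error_rate)
    if (any(rates < 0 | rates > 1))
        return("all rates must lie in [0, 1]")
    if (object@depth <= 0) return("depth must be > 0")
    if (!object@ploidy %in% c(1L, 2L)) return("ploidy must be 1 or 2")
    TRUE
})

#' @rdname SimConfig-class
#' @param seed integer seed driving every random choice.
#' @param genome_size genome length in bases.
#' @param gc_fraction target GC fraction.
#' @param ploidy 1 (haploid) or 2 (diploid).
#' @param het_snp_rate per-base heterozygous SNP rate between haplotypes.
#' @param read_length read length in bases.
#' @param depth fold-coverage of the genome.
#' @param substitution_error_rate per-base sequencing substitution rate.
#' @param quality_profile constant phred score, or a vector of one score per
#'   cycle.
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(seed = 1L, genome_size = 1e5, gc_fraction = 0.5,
                      ploidy = 1L, het_snp_rate = 0, read_length = 100L,
                      depth = 10, substitution_error_rate = 0,
                      quality_profile = 40L) {
    new("SimConfig", seed = as.integer(seed),
        genome_size = as.numeric(genome_size),
        gc_fraction = as.numeric(gc_fraction), ploidy = as.integer(ploidy),
        het_snp_rate = as.numeric(het_snp_rate),
        read_length = as.integer(read_length), depth = as.numeric(depth),
        substitution_error_rate = as.numeric(substitution_error_rate),
        quality_profile = as.integer(quality_profile))
}
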