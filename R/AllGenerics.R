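#' @name accessors
#' @title Accessors for knowyourdata containers
#' @description Small accessor generics: slot access is never part of the
#'   supported interface.
#' @param x an object.
#' @param ... unused.
NULL

#' @rdname accessors
#' @export
setGeneric("readIds", function(x, ...) standardGeneric("readIds"))
#' @rdname accessors
#' @export
setGeneric("sequences", function(x, ...) standardGeneric("sequences"))
#' @rdname accessors
#' @export
setGeneric("qualities", function(x, ...) standardGeneric("qualities"))
#' @rdname accessors
#' @export
setGeneric("kmerLength", function(x, ...) standardGeneric("kmerLength"))
#' @rdname accessors
#' @export
setGeneric("kmerCounts", function(x, ...) standardGeneric("kmerCounts"))
#' @rdname accessors
#' @export
setGeneric("spectrumBins", function(x, ...) standardGeneric("spectrumBins"))

#' @describeIn accessors read identifiers.
setMethod("readIds", "ReadSet", function(x, ...) x@id)
#' @describeIn accessors nucleotide sequences.
setMethod("sequences", "ReadSet", function(x, ...) x@sequence)
#' @describeIn accessors phred+33 quality strings.
setMethod("qualities", "ReadSet", function(x, ...) x@quality)

#' @describeIn accessors number of reads.
#' @export
setMethod("length", "ReadSet", function(x) length(x@id))

#' @describeIn accessors subset a ReadSet.
#' @param i index vector.
#' @param j,drop ignored.
#' @export
setMethod("[", "ReadSet", function(x, i, j, ..., drop = TRUE) {
    new("ReadSet", id = x@id[i], sequence = x@sequence[i],
        quality = x@quality[i])
})

#' @describeIn accessors k-mer length of a table.
setMethod("kmerLength", "KmerTable", function(x, ...) x@k)
#' @describeIn accessors named numeric vector of canonical k-mer counts.
setMethod("kmerCounts", "KmerTable", function(x, ...)
    setNames(x@count, x@kmer))
#' @describeIn accessors number of distinct canonical k-mers.
#' @export
setMethod("length", "KmerTable", function(x) length(x@kmer))

#' @describeIn accessors k-mer length of a spectra set.
setMethod("kmerLength", "SpectraSet", function(x, ...) x@k)

#' @describeIn accessors dense named bins of a spectrum; `upto` pads with
#'   explicit zero bins through multiplicity `upto`.
#' @param upto pad dense bins up to this multiplicity (default: maximum
#'   observed).
setMethod("spectrumBins", "SpectrumHistogram", function(x, upto = NULL, ...) {
    m <- if (is.null(upto)) {
        if (length(x@multiplicity)) max(x@multiplicity) else 0L
    } else as.integer(upto)
    bins <- numeric(m)
    keep <- x@multiplicity <= m
    bins[x@multiplicity[keep]] <- x@count[keep]
    names(bins) <- seq_len(m)
    bins
})

setMethod("show", "ReadSet", function(object) {
    cat(sprintf("ReadSet with %d read(s)\n", length(object)))
    if (length(object)) {
        n <- min(3L, length(object))
        for (i in seq_len(n))
            cat(sprintf("  %s  %s\n", object@id[i],
                        substr(object@sequence[i], 1L, 40L)))
        if (length(object) > n) cat("  ...\n")
    }
})

setMethod("show", "KmerTable", function(object) {
    cat(sprintf("KmerTable: k=%d, %d distinct canonical kmer(s), total count %g\n",
                object@k, length(object@kmer), sum(object@count)))
})

setMethod("show", "SpectrumHistogram", function(object) {
    cat(sprintf("SpectrumHistogram: %d bin(s), %g distinct kmer(s)\n",
                length(object@multiplicity), sum(object@count)))
})

setMethod("show", "ScreenReport", function(object) {
    cat(sprintf(paste0(
        "ScreenReport vs '%s' (k=%d, subsample %.2f)\n",
        "  reads with >=1 reference kmer: %g / %g (%.4f%%)\n",
        "  reference kmers observed:      %g / %g (%.4f%%)\n"),
        object@reference_name, object@k, object@subsample_fraction,
        object@reads_with_hit, object@reads_screened,
        object@reads_with_hit_pct, object@ref_kmers_observed,
        object@ref_kmers_total, object@ref_covered_pct))
})

setMethod("show", "SpectraAnalysis", function(object) {
    cat(sprintf(paste0(
        "SpectraAnalysis: error threshold %d, %d peak(s), main peak at %s\n",
        "  zygosity: %s; genome size estimate: %.0f distinct kmers\n"),
        object@error_threshold, nrow(object@peaks),
        ifelse(is.na(object@main_peak), "NA", object@main_peak),
        object@zygosity, object@genome_size_estimate))
})

setMethod("show", "MatePairReport", function(object) {
    cat("MatePairReport\n  category counts:",
        paste(sprintf("%s=%g", names(object@category_counts),
                      object@category_counts), collapse = " "),
        sprintf("\n  excluded (too short after clip): %g\n",
                sum(object@excluded_too_short)),
        sprintf(" duplication rate: %.2f%%\n", object@duplication_rate))
})

setMethod("show", "DemuxReport", function(object) {
    cat(sprintf(
        "DemuxReport: %d sample(s), %g assigned, %g undetermined, %g ambiguous\n",
        length(object@assigned), sum(object@assigned), object@undetermined,
        object@ambiguous))
})

setMethod("show", "MetricStore", function(object) {
    cat(sprintf("MetricStore: %d record(s)%s\n", nrow(storeRecords(object)),
                if (nzchar(object@path))
                    sprintf(" backed by '%s'", object@path) else ""))
})
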