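## phred+33 decoding of one quality string
.phred <- function(qual) utf8ToInt(qual) - 33L

#' Per-cycle base quality statistics
#'
#' Mean, median and quartiles of phred scores at every cycle (1-based read
#' position), computed only over the reads that reach that cycle, plus the
#' read-length distribution. Quartiles use linear interpolation on the
#' sorted per-cycle scores.
#'
#' @param reads a [ReadSet-class].
#' @return A [PerBaseQuality-class].
#' @export
perBaseQuality <- function(reads) {
    stopifnot(is(reads, "ReadSet"))
    if (!length(reads)) stop("empty input")
    lens <- nchar(reads@quality)
    maxlen <- max(lens)
    mat <- matrix(NA_integer_, nrow = length(reads), ncol = maxlen)
    for (i in seq_along(reads@quality))
        mat[i, seq_len(lens[i])] <- .phred(reads@quality[i])
    stats <- data.frame(
        cycle = seq_len(maxlen),
        mean = apply(mat, 2, mean, na.rm = TRUE),
        median = apply(mat, 2, median, na.rm = TRUE),
        q25 = apply(mat, 2, quantile, probs = 0.25, na.rm = TRUE,
                    names = FALSE),
        q75 = apply(mat, 2, quantile, probs = 0.75, na.rm = TRUE,
                    names = FALSE),
        n = colSums(!is.na(mat)))
    new("PerBaseQuality", stats = stats, read_lengths = table(lens))
}

#' Q30 yield summary
#'
#' The headline per-run quality figures: the number of reads, the mean
#' number of bases per read at or above the quality threshold, and the
#' percent of reads whose mean quality reaches the threshold. The common
#' phrasing "average length of read with quality score at 30 or above" is
#' ambiguous, so both readings are computed and labelled.
#'
#' @param reads a [ReadSet-class].
#' @param q_threshold phred threshold (default 30).
#' @return list with `read_count`, `mean_q30_bases_per_read`,
#'   `q30_read_pct`.
#' @export
q30Summary <- function(reads, q_threshold = 30L) {
    stopifnot(is(reads, "ReadSet"))
    if (!length(reads)) stop("empty input")
    per_read <- lapply(reads@quality, .phred)
    n_hi <- vapply(per_read, function(q) sum(q >= q_threshold), numeric(1))
    mean_q <- vapply(per_read, mean, numeric(1))
    list(read_count = length(reads),
         mean_q30_bases_per_read = mean(n_hi),
         q30_read_pct = 100 * mean(mean_q >= q_threshold))
}

#' Summarize a run with red-flag thresholds
#'
#' Combines the Q30 summary and the GC histogram, and flags every
#' configured metric whose value falls below its expected minimum. No
#' thresholds are enabled by default.
#'
#' @param reads a [ReadSet-class].
#' @param thresholds named list of minima over the scalar metrics
#'   (`read_count`, `mean_q30_bases_per_read`, `q30_read_pct`).
#' @param q_threshold phred threshold for the Q30 metrics.
#' @param gc_bin_width GC histogram bin width (percentage points).
#' @return A [RunSummary-class].
#' @export
summarizeRun <- function(reads, thresholds = list(), q_threshold = 30L,
                         gc_bin_width = 1) {
    q <- q30Summary(reads, q_threshold)
    gc <- gcReadHistogram(reads, gc_bin_width)
    flags <- data.frame(metric = character(), value = numeric(),
                        threshold = numeric(), stringsAsFactors = FALSE)
    for (metric in names(thresholds)) {
        if (!metric %in% names(q))
            stop("unknown metric in thresholds: ", metric)
        value <- q[[metric]]
        if (value < thresholds[[metric]])
            flags <- rbind(flags, data.frame(
                metric = metric, value = value,
                threshold = as.numeric(thresholds[[metric]]),
                stringsAsFactors = FALSE))
    }
    new("RunSummary", read_count = q$read_count,
        mean_q30_bases_per_read = q$mean_q30_bases_per_read,
        q30_read_pct = q$q30_read_pct, gc_histogram = gc, flags = flags)
}

#' Serialize a report object
#'
#' Writes any toolkit report (screen, run summary, mate-pair, demux,
#' spectra analysis) as JSON; the same representation feeds
#' [parseToolkitReport()]. The JSON is deterministic: no timestamps or
#' environment details.
#'
#' @param object a report object.
#' @param path output path (JSON).
#' @param ... unused.
#' @return `path`, invisibly.
#' @export
setGeneric("writeReport", function(object, path, ...)
    standardGeneric("writeReport"))

## plain-list views of the report classes (shared by JSON export and the
## metric store)
.report_list <- function(object) {
    if (is(object, "ScreenReport")) list(
        type = "screen", reference_name = object@reference_name,
        k = object@k, reads_screened = object@reads_screened,
        reads_with_hit = object@reads_with_hit,
        reads_with_hit_pct = object@reads_with_hit_pct,
        ref_kmers_total = object@ref_kmers_total,
        ref_kmers_observed = object@ref_kmers_observed,
        ref_covered_pct = object@ref_covered_pct,
        subsample_fraction = object@subsample_fraction)
    else if (is(object, "RunSummary")) list(
        type = "run_summary", read_count = object@read_count,
        mean_q30_bases_per_read = object@mean_q30_bases_per_read,
        q30_read_pct = object@q30_read_pct,
        gc_histogram = object@gc_histogram, flags = object@flags)
    else if (is(object, "MatePairReport")) list(
        type = "matepair", category_counts = as.list(object@category_counts),
        excluded_too_short = as.list(object@excluded_too_short),
        duplication_rate = object@duplication_rate,
        gc_histogram = object@gc_histogram)
    else if (is(object, "DemuxReport")) list(
        type = "demux", assigned = as.list(object@assigned),
        undetermined = object@undetermined, ambiguous = object@ambiguous)
    else if (is(object, "SpectraAnalysis")) list(
        type = "spectra", error_threshold = object@error_threshold,
        main_peak = object@main_peak, zygosity = object@zygosity,
        genome_size_estimate = object@genome_size_estimate,
        peaks = object@peaks)
    else stop("unknown report type: ", class(object)[1])
}

#' @rdname writeReport
#' @export
setMethod("writeReport", "ANY", function(object, path, ...) {
    jsonlite::write_json(.report_list(object), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
})
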