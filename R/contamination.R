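#' Build a reference k-mer table from a FASTA file
#'
#' Collects every distinct canonical k-mer of every sequence in the
#' reference. Counts are occurrence counts, but screening uses the table as
#' a presence set.
#'
#' @param fasta path to a FASTA file, or a (named) character vector of
#'   sequences.
#' @param k k-mer length (default 21, the screening default).
#' @return A [KmerTable-class].
#' @export
buildReferenceTable <- function(fasta, k = 21L) {
    seqs <- if (is.character(fasta) && length(fasta) == 1L &&
                file.exists(fasta)) readFasta(fasta) else fasta
    if (!length(seqs) || !any(nzchar(seqs)))
        stop("reference contains no sequence")
    countKmers(unname(seqs), k)
}

#' Screen reads against a reference k-mer table
#'
#' The k-mer contamination screen reports two headline figures: the
#' percentage of reads containing one or more reference (contaminant)
#' k-mers, and the percentage of the reference's distinct k-mers that are
#' observed anywhere in the screened reads ("percentage of the contaminant
#' genome covered", measured k-mer-natively). Screening subsamples the read
#' stream (default: systematic 10%); use `subsample = NULL` to screen every
#' read.
#'
#' @param reads a [ReadSet-class] or character vector of sequences.
#' @param ref_table reference [KmerTable-class] (see
#'   [buildReferenceTable()]).
#' @param subsample a [subsampleSpec()] or `NULL` for no subsampling.
#' @param reference_name label carried into the report.
#' @return A [ScreenReport-class].
#' @export
screenReads <- function(reads, ref_table, subsample = subsampleSpec(),
                        reference_name = "reference") {
    stopifnot(is(ref_table, "KmerTable"))
    seqs <- .as_sequences(reads)
    fraction <- if (is.null(subsample)) 1 else subsample@fraction
    if (!is.null(subsample))
        seqs <- seqs[.subsample_indices(length(seqs), subsample)]
    if (!length(seqs))
        stop("no reads left after subsampling; cannot form a percentage")
    res <- .cpp_screen_reads(seqs, ref_table@k, ref_table@kmer)
    hit <- sum(res$hits > 0L)
    obs <- sum(res$observed)
    total <- length(ref_table@kmer)
    new("ScreenReport", reference_name = reference_name, k = ref_table@k,
        reads_screened = length(seqs), reads_with_hit = hit,
        reads_with_hit_pct = 100 * hit / length(seqs),
        ref_kmers_total = total, ref_kmers_observed = obs,
        ref_covered_pct = if (total) 100 * obs / total else 0,
        subsample_fraction = fraction)
}

#' Interpret a contamination screen
#'
#' A high read-hit percentage alone does not establish contamination: for
#' related organisms it frequently reflects k-mers shared between species.
#' True contamination shows both a high read-hit percentage and substantial
#' coverage of the contaminant reference.
#'
#' @param report a [ScreenReport-class].
#' @param read_hit_threshold_pct minimum reads-with-hit percentage (default
#'   5).
#' @param coverage_threshold_pct minimum reference-covered percentage
#'   (default 20).
#' @return One of `"true_contamination"` (both thresholds met),
#'   `"shared_kmers_only"` (read threshold met, coverage not), `"clean"`.
#' @export
interpretScreen <- function(report, read_hit_threshold_pct = 5,
                            coverage_threshold_pct = 20) {
    stopifnot(is(report, "ScreenReport"),
              read_hit_threshold_pct >= 0, read_hit_threshold_pct <= 100,
              coverage_threshold_pct >= 0, coverage_threshold_pct <= 100)
    if (report@reads_with_hit_pct >= read_hit_threshold_pct) {
        if (report@ref_covered_pct >= coverage_threshold_pct)
            "true_contamination" else "shared_kmers_only"
    } else "clean"
}

#' Filter reads by reference k-mer content
#'
#' Partitions a read stream (or paired streams) by reference k-mer content.
#' Unlike screening, filtering never subsamples: it must be total to be
#' useful. In paired mode the whole pair moves together: a pair counts as a
#' hit when either mate has at least `min_hit_kmers` reference k-mer
#' windows.
#'
#' @param reads a [ReadSet-class] (read 1 in paired mode).
#' @param ref_table reference [KmerTable-class].
#' @param mode `"discard_hits"` sends hits to `removed`; `"keep_hits"`
#'   sends them to `kept`. The two modes partition identically with labels
#'   swapped.
#' @param min_hit_kmers minimum matching k-mer windows for a read to count
#'   as a hit (default 1).
#' @param r2 optional mate [ReadSet-class] for paired filtering.
#' @return A list with `kept`, `removed` (ReadSets, or lists of `r1`/`r2`
#'   ReadSets in paired mode) and a `summary` data.frame.
#' @export
filterReads <- function(reads, ref_table,
                        mode = c("discard_hits", "keep_hits"),
                        min_hit_kmers = 1L, r2 = NULL) {
    mode <- match.arg(mode)
    stopifnot(is(ref_table, "KmerTable"), min_hit_kmers >= 1L,
              is(reads, "ReadSet"))
    hits <- .cpp_screen_reads(reads@sequence, ref_table@k, ref_table@kmer)$hits
    is_hit <- hits >= min_hit_kmers
    if (!is.null(r2)) {
        stopifnot(is(r2, "ReadSet"), length(r2) == length(reads))
        hits2 <- .cpp_screen_reads(r2@sequence, ref_table@k,
                                   ref_table@kmer)$hits
        is_hit <- is_hit | hits2 >= min_hit_kmers
    }
    grab <- if (mode == "discard_hits") !is_hit else is_hit
    pick <- function(rs, sel) rs[which(sel)]
    kept <- if (is.null(r2)) pick(reads, grab)
            else list(r1 = pick(reads, grab), r2 = pick(r2, grab))
    removed <- if (is.null(r2)) pick(reads, !grab)
               else list(r1 = pick(reads, !grab), r2 = pick(r2, !grab))
    list(kept = kept, removed = removed,
         summary = data.frame(input = length(reads), kept = sum(grab),
                              removed = sum(!grab), mode = mode,
                              min_hit_kmers = as.integer(min_hit_kmers),
                              stringsAsFactors = FALSE))
}
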