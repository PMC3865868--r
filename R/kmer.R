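#' Canonical form of a k-mer
#'
#' The canonical form is the lexicographically smaller (A < C < G < T, byte
#' order) of a k-mer and its reverse complement; counting on canonical
#' k-mers makes every downstream analysis strand-neutral. Idempotent.
#'
#' @param kmer character vector of k-mers over \{A,C,G,T\}.
#' @return Character vector of canonical k-mers.
#' @examples
#' canonicalKmer(c("TTT", "ACGT", "CGT"))  # "AAA" "ACGT" "ACG"
#' @export
canonicalKmer <- function(kmer) {
    kmer <- toupper(kmer)
    if (any(grepl("[^ACGT]", kmer)))
        stop("k-mers must contain only A, C, G, T")
    rc <- .revcomp(kmer)
    vapply(seq_along(kmer), function(i)
        sort(c(kmer[i], rc[i]), method = "radix")[1], character(1))
}

## reverse complement of plain character sequences (IUPAC N kept as N)
.revcomp <- function(x) {
    comp <- chartr("ACGTN", "TGCAN", x)
    vapply(comp, function(s)
        intToUtf8(rev(utf8ToInt(s))), character(1), USE.NAMES = FALSE)
}

.as_sequences <- function(reads) {
    if (is(reads, "ReadSet")) reads@sequence
    else if (is.character(reads)) toupper(reads)
    else stop("reads must be a ReadSet or a character vector")
}

## Which stream indices does a subsample spec select?
## Systematic mode keeps 0-based indices divisible by round(1/fraction);
## random mode draws a seeded Bernoulli sample without disturbing the
## caller's RNG state.
.subsample_indices <- function(n, spec) {
    if (is.null(spec) || spec@fraction == 1) return(seq_len(n))
    if (spec@mode == "systematic") {
        step <- max(1L, as.integer(round(1 / spec@fraction)))
        which((seq_len(n) - 1L) %% step == 0L)
    } else {
        old <- if (exists(".Random.seed", .GlobalEnv))
            get(".Random.seed", .GlobalEnv) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
        set.seed(spec@seed)
        which(runif(n) < spec@fraction)
    }
}

#' Count canonical k-mers in a read stream
#'
#' Slides a window of k bases base-by-base over every (sub)sampled read; a
#' read of length L contributes max(0, L - k + 1) windows, minus any window
#' containing a non-ACGT character (those are skipped entirely). Counts
#' accumulate on canonical k-mers.
#'
#' @param reads a [ReadSet-class] or character vector of sequences.
#' @param k k-mer length, 1--32 (21 is the screening default, 31 the
#'   spectrum default).
#' @param subsample optional [subsampleSpec()]; `NULL` uses every read.
#' @return A [KmerTable-class] with k-mers sorted lexicographically.
#' @examples
#' kmerCounts(countKmers("ACGTACGT", 3))  # ACG: 4, GTA: 2
#' @export
countKmers <- function(reads, k, subsample = NULL) {
    k <- as.integer(k)
    if (is.na(k) || k < 1L) stop("k must be >= 1")
    if (k > 32L) stop("k must be <= 32")
    seqs <- .as_sequences(reads)
    if (!is.null(subsample)) {
        stopifnot(is(subsample, "SubsampleSpec"))
        seqs <- seqs[.subsample_indices(length(seqs), subsample)]
    }
    res <- .cpp_count_kmers(seqs, k)
    new("KmerTable", k = k, kmer = res$kmer, count = res$count)
}

#' K-mer multiplicity spectrum of a table
#'
#' Bins the distinct k-mers of a [KmerTable-class] by their multiplicity:
#' bin m holds the number of distinct canonical k-mers seen exactly m
#' times. The bin counts always sum to the number of distinct k-mers in the
#' table. An empty table yields an empty histogram.
#'
#' @param table a [KmerTable-class].
#' @return A [SpectrumHistogram-class].
#' @export
kmerSpectrum <- function(table) {
    stopifnot(is(table, "KmerTable"))
    if (!length(table@count))
        return(new("SpectrumHistogram", multiplicity = integer(),
                   count = numeric()))
    tab <- tabulate(as.integer(table@count))
    m <- which(tab > 0L)
    new("SpectrumHistogram", multiplicity = m, count = as.numeric(tab[m]))
}

#' Save / load a k-mer table
#'
#' Tables serialize to a diffable, language-neutral text format: a one-line
#' header `#knowyourdata kmer-table v1 k=<k>` followed by TAB-separated
#' `kmer<TAB>count` rows sorted lexicographically. `load(save(T))`
#' reproduces `T` exactly.
#'
#' @param table a [KmerTable-class].
#' @param path file path (gzip written when the path ends in `.gz`).
#' @return `saveKmerTable`: `path`, invisibly. `loadKmerTable`: a
#'   [KmerTable-class].
#' @export
saveKmerTable <- function(table, path) {
    stopifnot(is(table, "KmerTable"))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    writeLines(sprintf("#knowyourdata kmer-table v1 k=%d", table@k), con)
    if (length(table@kmer))
        writeLines(sprintf("%s\t%d", table@kmer, as.integer(table@count)),
                   con)
    invisible(path)
}

#' @rdname saveKmerTable
#' @param k if given, the k the caller expects; a mismatch with the file
#'   header is an error.
#' @export
loadKmerTable <- function(path, k = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    if (!length(lines) ||
        !grepl("^#knowyourdata kmer-table v1 k=\\d+$", lines[1]))
        stop("not a knowyourdata kmer-table v1 file: ", path)
    file_k <- as.integer(sub("^.*k=", "", lines[1]))
    if (!is.null(k) && as.integer(k) != file_k)
        stop("kmer table '", path, "' has k=", file_k,
             " but k=", k, " was requested")
    body <- lines[-1]
    body <- body[nzchar(body)]
    if (!length(body))
        return(new("KmerTable", k = file_k, kmer = character(),
                   count = numeric()))
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L))
        stop("malformed kmer-table row in ", path)
    kmer <- vapply(parts, `[[`, "", 1L)
    if (any(nchar(kmer) != file_k))
        stop("kmer table '", path, "' contains rows whose kmer length ",
             "disagrees with the header k=", file_k)
    new("KmerTable", k = file_k, kmer = kmer,
        count = as.numeric(vapply(parts, `[[`, "", 2L)))
}
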