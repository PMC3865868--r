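#' Read a FASTQ file
#'
#' Parses a 4-line-per-record FASTQ file (plain or gzip-compressed) with
#' phred+33 qualities into a [ReadSet-class]. Malformed records (missing
#' '@' or '+' marker, sequence/quality length mismatch) raise an error
#' naming the 1-based record index. N bases are preserved verbatim.
#'
#' @param path file path; gzip detected transparently.
#' @param encoding quality encoding; only "phred33" is supported -
#'   "phred64" is rejected with an error.
#' @return A [ReadSet-class].
#' @examples
#' f <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), f)
#' readFastq(f)
#' @export
readFastq <- function(path, encoding = "phred33") {
    if (!identical(encoding, "phred33"))
        stop("only phred+33 (Sanger) qualities are supported, not '",
             encoding, "'")
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)  # gzfile handled by readLines via file magic
    if (length(lines) %% 4L != 0L)
        stop("FASTQ file '", path, "' has ", length(lines),
             " lines, not a multiple of 4")
    n <- length(lines) %/% 4L
    if (n == 0L) return(ReadSet())
    hdr <- lines[seq(1L, by = 4L, length.out = n)]
    seq <- lines[seq(2L, by = 4L, length.out = n)]
    plus <- lines[seq(3L, by = 4L, length.out = n)]
    qual <- lines[seq(4L, by = 4L, length.out = n)]
    bad <- which(substr(hdr, 1L, 1L) != "@")
    if (length(bad))
        stop("FASTQ record ", bad[1], ": header does not start with '@'")
    bad <- which(substr(plus, 1L, 1L) != "+")
    if (length(bad))
        stop("FASTQ record ", bad[1], ": separator line does not start with '+'")
    bad <- which(nchar(qual) != nchar(seq))
    if (length(bad))
        stop("FASTQ record ", bad[1], ": quality length ", nchar(qual[bad[1]]),
             " != sequence length ", nchar(seq[bad[1]]))
    new("ReadSet", id = substring(hdr, 2L), sequence = seq, quality = qual)
}

#' Write a FASTQ file
#'
#' Round-trips with [readFastq()] byte-for-byte in ids, sequences and
#' qualities.
#'
#' @param reads a [ReadSet-class].
#' @param path output path.
#' @param gzip write gzip-compressed output.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path, gzip = FALSE) {
    stopifnot(is(reads, "ReadSet"))
    con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    n <- length(reads)
    if (n) {
        out <- character(4L * n)
        idx <- 4L * (seq_len(n) - 1L)
        out[idx + 1L] <- paste0("@", reads@id)
        out[idx + 2L] <- reads@sequence
        out[idx + 3L] <- "+"
        out[idx + 4L] <- reads@quality
        writeLines(out, con)
    }
    invisible(path)
}

#' Read a FASTA file
#'
#' Wrapped sequence lines are concatenated; the id is the header up to the
#' first whitespace.
#'
#' @param path FASTA file, plain or gzipped.
#' @return Named character vector of uppercase sequences.
#' @export
readFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    set <- Biostrings::readDNAStringSet(path)
    seqs <- toupper(as.character(set))
    names(seqs) <- sub("\\s.*$", "", names(set))
    seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 70L) {
    set <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(set, path, width = width)
    invisible(path)
}

cigar_reference_span <- function(cigar) {
    ## reference-consuming operations: M, D, N, =, X
    vapply(cigar, function(cg) {
        if (is.na(cg) || cg == "*") return(0L)
        ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
        if (!length(ops) || sum(nchar(ops)) != nchar(cg))
            stop("malformed CIGAR string: ", cg)
        len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
        op <- substr(ops, nchar(ops), nchar(ops))
        sum(len[op %in% c("M", "D", "N", "=", "X")])
    }, integer(1), USE.NAMES = FALSE)
}

#' Parse read pairs from a SAM file
#'
#' Consumes primary alignments only (secondary 0x100 and supplementary
#' 0x800 records are skipped) and assembles one pair per read name, using
#' the first/second-mate flags. The aligned length is the reference span of
#' the CIGAR string (M/D/N/=/X operations). Unmapped mates (flag 0x4) are
#' flagged `mapped = FALSE` and their positions ignored.
#'
#' @param path SAM text file (tab-separated, 11 mandatory columns).
#' @return A data.frame with one row per read name having both primary
#'   mates: `qname`, and per mate `ref`, `pos`, `strand`, `alen`, `mapped`.
#' @export
parseSamPairs <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@")]
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(data.frame(qname = character(), ref1 = character(),
                          pos1 = integer(), strand1 = character(),
                          alen1 = integer(), mapped1 = logical(),
                          ref2 = character(), pos2 = integer(),
                          strand2 = character(), alen2 = integer(),
                          mapped2 = logical(), stringsAsFactors = FALSE))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 11L)
    if (length(short))
        stop("SAM line ", short[1], " has fewer than 11 mandatory columns")
    qname <- vapply(fields, `[[`, "", 1L)
    flag <- as.integer(vapply(fields, `[[`, "", 2L))
    rname <- vapply(fields, `[[`, "", 3L)
    pos <- as.integer(vapply(fields, `[[`, "", 4L))
    cigar <- vapply(fields, `[[`, "", 6L)
    primary <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
    qname <- qname[primary]; flag <- flag[primary]; rname <- rname[primary]
    pos <- pos[primary]; cigar <- cigar[primary]
    mapped <- bitwAnd(flag, 0x4L) == 0L
    strand <- ifelse(bitwAnd(flag, 0x10L) != 0L, "-", "+")
    alen <- cigar_reference_span(cigar)
    first <- bitwAnd(flag, 0x40L) != 0L
    second <- bitwAnd(flag, 0x80L) != 0L
    ## reads without mate flags cannot be paired; drop with the unpaired
    m1 <- which(first)
    m2 <- which(second)
    common <- intersect(qname[m1], qname[m2])
    i1 <- m1[match(common, qname[m1])]
    i2 <- m2[match(common, qname[m2])]
    data.frame(qname = common,
               ref1 = rname[i1], pos1 = pos[i1], strand1 = strand[i1],
               alen1 = alen[i1], mapped1 = mapped[i1],
               ref2 = rname[i2], pos2 = pos[i2], strand2 = strand[i2],
               alen2 = alen[i2], mapped2 = mapped[i2],
               stringsAsFactors = FALSE)
}

#' MD5 checksum manifest
#'
#' Computes the standard MD5 digest of each file and optionally writes an
#' `md5sum`-compatible manifest ("<md5><two spaces><path>" per line).
#'
#' @param paths files to checksum.
#' @param out optional manifest output path.
#' @param labels path strings written to the manifest (defaults to `paths`;
#'   pass basenames for location-independent manifests).
#' @return data.frame with columns `path` and `md5`.
#' @export
md5Manifest <- function(paths, out = NULL, labels = paths) {
    missing <- paths[!file.exists(paths)]
    if (length(missing)) stop("no such file: ", missing[1])
    md5 <- unname(tools::md5sum(paths))
    manifest <- data.frame(path = labels, md5 = md5, stringsAsFactors = FALSE)
    if (!is.null(out))
        writeLines(sprintf("%s  %s", manifest$md5, manifest$path), out)
    manifest
}
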