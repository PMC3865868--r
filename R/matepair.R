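#' Find the junction adaptor in reads
#'
#' Scans each read for the leftmost window matching the junction adaptor.
#' Interior windows must match the full junction; at the read ends a
#' partial overlap of at least `min_overlap` bases (a junction prefix at
#' the 3' end, a junction suffix at the 5' start) also qualifies. A window
#' qualifies when its mismatches do not exceed
#' `floor(max_mismatch_rate * overlap_length)` - with the defaults, 4
#' mismatches over the full 38-base window, scaled down for partial
#' overlaps.
#'
#' @param reads a [ReadSet-class] or character vector.
#' @param adaptor an [adaptorSpec()].
#' @return Integer vector of 0-based junction start positions, `NA` where
#'   no window qualifies.
#' @export
findJunction <- function(reads, adaptor = adaptorSpec()) {
    stopifnot(is(adaptor, "AdaptorSpec"))
    .cpp_find_junction(.as_sequences(reads), adaptor@junction,
                       adaptor@min_overlap, adaptor@max_mismatch_rate)
}

#' Classify pairs by junction presence and clip at the junction
#'
#' Pairs are classified by per-mate junction detection: category A has the
#' adaptor in both reads, B in read 2 only, C in read 1 only, D in neither.
#' Each mate with a detected junction is truncated at the junction start
#' (the genomic sequence beyond it belongs to the distal fragment end).
#' Pairs in which any clipped mate falls below `min_length` are excluded
#' from the clipped output but still counted in their category.
#'
#' @param r1,r2 [ReadSet-class] mates, equal length.
#' @param adaptor an [adaptorSpec()].
#' @param min_length minimum clipped mate length (default 25).
#' @return A list: `category` (character per pair), `junction1`,
#'   `junction2` (0-based positions or NA), `kept` (logical per pair),
#'   `r1_clipped`, `r2_clipped` (ReadSets over all pairs, clipped where a
#'   junction was found).
#' @export
classifyAndClip <- function(r1, r2, adaptor = adaptorSpec(),
                            min_length = 25L) {
    stopifnot(is(r1, "ReadSet"), is(r2, "ReadSet"),
              length(r1) == length(r2))
    j1 <- findJunction(r1, adaptor)
    j2 <- findJunction(r2, adaptor)
    category <- ifelse(!is.na(j1) & !is.na(j2), "A",
                ifelse(is.na(j1) & !is.na(j2), "B",
                ifelse(!is.na(j1) & is.na(j2), "C", "D")))
    clip <- function(rs, j) {
        keep_len <- ifelse(is.na(j), nchar(rs@sequence), j)
        new("ReadSet", id = rs@id,
            sequence = substr(rs@sequence, 1L, keep_len),
            quality = substr(rs@quality, 1L, keep_len))
    }
    r1c <- clip(r1, j1)
    r2c <- clip(r2, j2)
    kept <- nchar(r1c@sequence) >= min_length &
            nchar(r2c@sequence) >= min_length
    list(category = category, junction1 = j1, junction2 = j2, kept = kept,
         r1_clipped = r1c, r2_clipped = r2c)
}

#' PCR duplicate rate from read-prefix signatures
#'
#' Each pair's signature is the first `signature_bases` bases of the raw
#' (unclipped) read 1 concatenated with the first `signature_bases` bases
#' of read 2; the duplication rate is
#' `100 * (1 - distinct_signatures / pairs_considered)`. Pairs with either
#' mate shorter than `signature_bases` are skipped (their number is
#' attached as attribute `skipped`).
#'
#' @param r1,r2 [ReadSet-class] mates.
#' @param signature_bases prefix length per mate (default 16).
#' @return Numeric percent, with attributes `considered` and `skipped`.
#' @export
duplicateRate <- function(r1, r2, signature_bases = 16L) {
    stopifnot(is(r1, "ReadSet"), is(r2, "ReadSet"),
              length(r1) == length(r2))
    ok <- nchar(r1@sequence) >= signature_bases &
          nchar(r2@sequence) >= signature_bases
    if (!any(ok)) stop("no pair is long enough to form a signature")
    sig <- paste0(substr(r1@sequence[ok], 1L, signature_bases),
                  substr(r2@sequence[ok], 1L, signature_bases))
    rate <- 100 * (1 - length(unique(sig)) / length(sig))
    structure(rate, considered = sum(ok), skipped = sum(!ok))
}

#' Per-read GC percent
#'
#' `100 * (G + C) / (A + C + G + T)` per read; N bases are excluded from
#' the denominator. Reads with no called base yield `NA`.
#'
#' @param reads a [ReadSet-class] or character vector.
#' @return Numeric vector of GC percentages.
#' @examples
#' gcPercent(c("GGCC", "ACGT", "ANGT"))  # 100, 50, 33.33
#' @export
gcPercent <- function(reads) {
    seqs <- .as_sequences(reads)
    counts <- function(ch) nchar(seqs) - nchar(gsub(ch, "", seqs))
    gc <- counts("[GC]")
    called <- counts("[ACGT]")
    ifelse(called > 0L, 100 * gc / called, NA_real_)
}

#' GC content histogram over reads
#'
#' Per-read GC percent is `100 * (G + C) / (A + C + G + T)`; N bases are
#' excluded from the denominator. Reads consisting entirely of N are
#' skipped (count attached as attribute `skipped`). A second mode in this
#' histogram is a classic contamination signature.
#'
#' @param reads a [ReadSet-class] or character vector.
#' @param bin_width bin width in GC percentage points (default 1).
#' @return data.frame (`gc_bin` = left bin edge, `reads`), with attribute
#'   `skipped`.
#' @export
gcReadHistogram <- function(reads, bin_width = 1) {
    pct <- gcPercent(reads)
    ok <- !is.na(pct)
    bin <- floor(pct[ok] / bin_width) * bin_width
    tab <- table(bin)
    structure(data.frame(gc_bin = as.numeric(names(tab)),
                         reads = as.numeric(tab)),
              skipped = sum(!ok))
}

#' Orientation and insert-size analysis of aligned pairs
#'
#' For each pair with both mates mapped to the same reference, the mate
#' with the smaller leftmost position is "left". Orientation is
#' `paired_end` when left is on + and right on - (inward-facing),
#' `mate_pair` when left is on - and right on + (outward-facing), and
#' `tandem` when both mates share a strand. Insert size is the 1-based
#' inclusive outer span: rightmost aligned end minus leftmost start plus
#' one. Pairs with an unmapped mate, or mates on different references,
#' go to the `unmapped` / `discordant` buckets.
#'
#' @param aligned_pairs data.frame as returned by [parseSamPairs()].
#' @param categories optional character vector of pair categories (e.g.
#'   from [classifyAndClip()]) aligned with the rows of `aligned_pairs`.
#' @return An [OrientationReport-class].
#' @export
orientationAnalysis <- function(aligned_pairs, categories = NULL) {
    ap <- aligned_pairs
    if (!is.null(categories))
        stopifnot(length(categories) == nrow(ap))
    unmapped <- !ap$mapped1 | !ap$mapped2
    discordant <- !unmapped & ap$ref1 != ap$ref2
    conc <- !unmapped & !discordant
    idx <- which(conc)
    left_is_1 <- ap$pos1[idx] <= ap$pos2[idx]
    left_strand <- ifelse(left_is_1, ap$strand1[idx], ap$strand2[idx])
    right_strand <- ifelse(left_is_1, ap$strand2[idx], ap$strand1[idx])
    orientation <- ifelse(left_strand == right_strand, "tandem",
                   ifelse(left_strand == "+", "paired_end", "mate_pair"))
    end1 <- ap$pos1[idx] + ap$alen1[idx] - 1L
    end2 <- ap$pos2[idx] + ap$alen2[idx] - 1L
    insert <- pmax(end1, end2) - pmin(ap$pos1[idx], ap$pos2[idx]) + 1L
    new("OrientationReport",
        pairs = data.frame(
            qname = ap$qname[idx],
            category = if (is.null(categories)) NA_character_
                       else categories[idx],
            orientation = orientation, insert = as.integer(insert),
            stringsAsFactors = FALSE),
        discordant = sum(discordant), unmapped = sum(unmapped))
}

#' Full long-mate-pair library analysis
#'
#' Runs junction classification and clipping over a library, computes the
#' duplicate rate and per-read GC histogram on the raw reads, and (when
#' `output_dir` is given) writes per-category clipped FASTQ files.
#'
#' @param r1,r2 [ReadSet-class] mates.
#' @param adaptor an [adaptorSpec()].
#' @param min_length minimum clipped mate length (default 25).
#' @param output_dir optional directory for per-category clipped FASTQ
#'   files (`<prefix>_<cat>_R1.fastq` etc.).
#' @param prefix file-name prefix for outputs.
#' @param write_d also write category-D (no junction) pairs.
#' @return A [MatePairReport-class]; the classification vectors are
#'   attached as attribute `detail`.
#' @export
analyzeMatePairs <- function(r1, r2, adaptor = adaptorSpec(),
                             min_length = 25L, output_dir = NULL,
                             prefix = "lmp", write_d = FALSE) {
    cc <- classifyAndClip(r1, r2, adaptor, min_length)
    cats <- c("A", "B", "C", "D")
    counts <- vapply(cats, function(ct) sum(cc$category == ct), numeric(1))
    excl <- vapply(cats, function(ct)
        sum(cc$category == ct & !cc$kept), numeric(1))
    dup <- duplicateRate(r1, r2)
    gc <- gcReadHistogram(c(r1@sequence, r2@sequence))
    paths <- character(0)
    if (!is.null(output_dir)) {
        dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
        out_cats <- if (write_d) cats else c("A", "B", "C")
        for (ct in out_cats) {
            sel <- which(cc$category == ct & cc$kept)
            p1 <- file.path(output_dir, sprintf("%s_%s_R1.fastq", prefix, ct))
            p2 <- file.path(output_dir, sprintf("%s_%s_R2.fastq", prefix, ct))
            writeFastq(cc$r1_clipped[sel], p1)
            writeFastq(cc$r2_clipped[sel], p2)
            paths[paste0(ct, "_R1")] <- p1
            paths[paste0(ct, "_R2")] <- p2
        }
    }
    structure(new("MatePairReport", category_counts = counts,
                  excluded_too_short = excl,
                  duplication_rate = as.numeric(dup),
                  gc_histogram = gc, clipped_paths = paths),
              detail = cc)
}
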