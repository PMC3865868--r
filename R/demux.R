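#' Read a demultiplexing sample sheet
#'
#' TSV with columns `sample`, `barcode`, `offsets` (comma-separated
#' non-negative integers) and `overhang` (the restriction-site remnant
#' immediately following the barcode; identical across all rows of one
#' run). Barcode offsets shift the barcode by 0-n filler bases so the
#' overhang does not occupy the same cycles in every read.
#'
#' @param path TSV path.
#' @return A sample-sheet data.frame; `offsets` is a list column of
#'   integer vectors.
#' @export
readSampleSheet <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = "character")
    need <- c("sample", "barcode", "offsets", "overhang")
    if (!all(need %in% names(df)))
        stop("sample sheet must have columns: ", paste(need, collapse = ", "))
    barcodeSpecs(df$sample, df$barcode,
                 lapply(strsplit(df$offsets, ","), as.integer),
                 df$overhang)
}

#' Construct barcode specs
#'
#' @param sample sample names (unique).
#' @param barcode barcode sequences (4-10 bases).
#' @param offsets list of integer vectors of allowed offsets (recycled).
#' @param overhang overhang sequence, identical for all samples.
#' @return Sample-sheet data.frame as used by [matchBarcode()] and
#'   [demultiplex()].
#' @export
barcodeSpecs <- function(sample, barcode, offsets = list(0L),
                         overhang = "") {
    barcode <- toupper(barcode)
    overhang <- toupper(overhang)
    if (anyDuplicated(sample)) stop("sample names must be unique")
    if (length(unique(overhang)) > 1L)
        stop("the overhang must be identical across all specs in one run")
    if (any(nchar(barcode) < 4L | nchar(barcode) > 10L))
        stop("barcodes must be 4-10 bases long")
    if (!is.list(offsets)) offsets <- list(as.integer(offsets))
    structure(data.frame(sample = sample, barcode = barcode,
                         overhang = overhang[1], stringsAsFactors = FALSE),
              offsets = rep(offsets, length.out = length(sample)))
}

#' Match offset inline barcodes in reads
#'
#' Every (sample, offset) candidate is scored jointly (no first-match
#' shortcut): the barcode is tested at `[offset, offset + length)` and the
#' overhang immediately after it. A candidate is valid when its barcode
#' mismatches are at most `max_barcode_mismatch` and its overhang
#' mismatches at most `max_overhang_mismatch` (exact by default - the
#' overhang is what disambiguates the offset). The candidate score is the
#' barcode mismatch count; the unique minimum-score valid candidate wins.
#' A tie at the minimum is `ambiguous`; no valid candidate (including reads
#' too short for every candidate) is `undetermined`.
#'
#' @param reads a [ReadSet-class] or character vector.
#' @param specs sample sheet from [barcodeSpecs()] / [readSampleSheet()].
#' @param max_barcode_mismatch default 1.
#' @param max_overhang_mismatch default 0.
#' @return data.frame per read: `status` ("assigned", "undetermined",
#'   "ambiguous"), `sample` (NA unless assigned), `offset` (NA unless
#'   assigned).
#' @export
matchBarcode <- function(reads, specs, max_barcode_mismatch = 1L,
                         max_overhang_mismatch = 0L) {
    seqs <- .as_sequences(reads)
    n <- length(seqs)
    offsets <- attr(specs, "offsets")
    best_score <- rep(Inf, n)
    best_sample <- rep(NA_character_, n)
    best_offset <- rep(NA_integer_, n)
    tied <- rep(FALSE, n)
    oh <- specs$overhang[1]
    ohl <- nchar(oh)
    for (s in seq_len(nrow(specs))) {
        bc <- specs$barcode[s]
        bl <- nchar(bc)
        for (off in offsets[[s]]) {
            long_enough <- nchar(seqs) >= off + bl + ohl
            bc_mm <- .cpp_hamming(substr(seqs, off + 1L, off + bl), bc)
            score <- ifelse(long_enough, bc_mm, NA_integer_)
            valid <- !is.na(score) & score <= max_barcode_mismatch
            if (ohl > 0L && any(valid)) {
                oh_mm <- .cpp_hamming(
                    substr(seqs, off + bl + 1L, off + bl + ohl), oh)
                valid <- valid & !is.na(oh_mm) &
                         oh_mm <= max_overhang_mismatch
            }
            improve <- valid & score < best_score
            tie <- valid & score == best_score &
                   (specs$sample[s] != best_sample | off != best_offset)
            tie[is.na(tie)] <- FALSE
            tied[tie] <- TRUE
            tied[improve] <- FALSE
            best_score[improve] <- score[improve]
            best_sample[improve] <- specs$sample[s]
            best_offset[improve] <- off
        }
    }
    status <- ifelse(is.infinite(best_score), "undetermined",
              ifelse(tied, "ambiguous", "assigned"))
    data.frame(status = status,
               sample = ifelse(status == "assigned", best_sample,
                               NA_character_),
               offset = ifelse(status == "assigned", best_offset,
                               NA_integer_),
               stringsAsFactors = FALSE)
}

#' Demultiplex reads by offset inline barcodes
#'
#' Routes each read (or pair) according to [matchBarcode()]. With
#' `trim = TRUE` the offset filler bases and the barcode are removed from
#' read 1; the overhang is retained because it connects directly to
#' genomic sequence. Read 2 is never modified. Undetermined and ambiguous
#' reads are written to an `Undetermined` file. The counts always satisfy
#' `assigned + undetermined + ambiguous == input`.
#'
#' @param r1 a [ReadSet-class] (read 1).
#' @param specs sample sheet from [barcodeSpecs()] / [readSampleSheet()].
#' @param r2 optional mate [ReadSet-class]; routed with its read 1.
#' @param trim remove offset + barcode from read 1 (default TRUE).
#' @param output_dir optional directory for per-sample FASTQ files
#'   (`<sample>_R1.fastq`, `<sample>_R2.fastq`, `Undetermined_R1.fastq`).
#' @param max_barcode_mismatch,max_overhang_mismatch see [matchBarcode()].
#' @param gzip write gzipped FASTQ.
#' @return A [DemuxReport-class]; per-read assignments are attached as
#'   attribute `assignments`.
#' @export
demultiplex <- function(r1, specs, r2 = NULL, trim = TRUE,
                        output_dir = NULL, max_barcode_mismatch = 1L,
                        max_overhang_mismatch = 0L, gzip = FALSE) {
    stopifnot(is(r1, "ReadSet"))
    if (!is.null(r2)) stopifnot(is(r2, "ReadSet"), length(r2) == length(r1))
    m <- matchBarcode(r1, specs, max_barcode_mismatch,
                      max_overhang_mismatch)
    if (trim && length(r1)) {
        bl <- nchar(specs$barcode)[match(m$sample, specs$sample)]
        start <- ifelse(m$status == "assigned", m$offset + bl + 1L, 1L)
        r1 <- new("ReadSet", id = r1@id,
                  sequence = substring(r1@sequence, start),
                  quality = substring(r1@quality, start))
    }
    assigned <- vapply(specs$sample, function(s)
        sum(m$status == "assigned" & m$sample == s, na.rm = TRUE),
        numeric(1))
    paths <- character(0)
    if (!is.null(output_dir)) {
        dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
        ext <- if (gzip) ".fastq.gz" else ".fastq"
        groups <- c(setNames(as.list(specs$sample), specs$sample),
                    list(Undetermined = NA))
        for (g in names(groups)) {
            sel <- if (g == "Undetermined") which(m$status != "assigned")
                   else which(m$status == "assigned" & m$sample == g)
            p1 <- file.path(output_dir, paste0(g, "_R1", ext))
            writeFastq(r1[sel], p1, gzip = gzip)
            paths[paste0(g, "_R1")] <- p1
            if (!is.null(r2)) {
                p2 <- file.path(output_dir, paste0(g, "_R2", ext))
                writeFastq(r2[sel], p2, gzip = gzip)
                paths[paste0(g, "_R2")] <- p2
            }
        }
    }
    structure(new("DemuxReport", assigned = assigned,
                  undetermined = sum(m$status == "undetermined"),
                  ambiguous = sum(m$status == "ambiguous"),
                  paths = paths),
              assignments = m)
}
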