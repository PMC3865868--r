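## Independent oracles and small fixture builders shared across test files.
## The oracles deliberately avoid the package's own k-mer machinery.

oracle_revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## naive window enumeration + dictionary counting on canonical kmers
oracle_count_kmers <- function(seqs, k) {
    all_kmers <- unlist(lapply(seqs, function(s) {
        L <- nchar(s)
        if (L < k) return(character())
        substring(s, 1:(L - k + 1), k:L)
    }))
    all_kmers <- all_kmers[!grepl("[^ACGT]", all_kmers)]
    if (!length(all_kmers)) return(numeric())
    rc <- oracle_revcomp(all_kmers)
    canon <- ifelse(all_kmers <= rc, all_kmers, rc)
    tab <- table(canon)
    out <- as.numeric(tab)
    names(out) <- names(tab)
    out[order(names(out), method = "radix")]
}

random_dna <- function(n, seed) {
    set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## minimal SAM text around a list of alignment rows
sam_text <- function(rows, ref = "chr1", ref_len = 100000) {
    c(sprintf("@SQ\tSN:%s\tLN:%d", ref, ref_len),
      vapply(rows, function(r)
          paste(r$qname, r$flag, r$rname %||% ref, r$pos, 60L,
                r$cigar, "*", 0L, 0L, "*", "*", sep = "\t"),
          character(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## FastQC-dialect report fragment used by the metric-store tests
fastqc_fixture <- function() {
    c("##FastQC\t0.11.9",
      ">>Basic Statistics\tpass",
      "#Measure\tValue",
      "Filename\trun1.fastq",
      "Total Sequences\t20000",
      "Sequence length\t100",
      ">>END_MODULE",
      ">>Per base sequence quality\tpass",
      "#Base\tMean\tMedian",
      "1\t32.1\t33.0",
      "2\t31.8\t32.0",
      "10-14\t30.0\t31.0",
      "15-19\t29.5\t30.0",
      ">>END_MODULE",
      ">>Per sequence GC content\twarn",
      "#GC Content\tCount",
      "40\t120",
      "41\t230",
      "42\t180",
      ">>END_MODULE")
}
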