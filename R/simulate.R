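## Run expr under a fixed seed without disturbing the caller's RNG state.
.with_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
            else if (exists(".Random.seed", .GlobalEnv))
                rm(".Random.seed", envir = .GlobalEnv))
    set.seed(seed)
    expr
}

.BASES <- c("A", "C", "G", "T")

## Substitute bases at the given rate; each error picks uniformly among the
## three other bases. Returns the mutated sequences and per-read error counts.
.add_errors <- function(seqs, rate) {
    n_err <- integer(length(seqs))
    if (rate <= 0 || !length(seqs))
        return(list(seqs = seqs, n_errors = n_err))
    lens <- nchar(seqs)
    bounds <- cumsum(lens)
    hit <- which(runif(sum(lens)) < rate)
    if (!length(hit)) return(list(seqs = seqs, n_errors = n_err))
    read <- findInterval(hit - 1L, bounds) + 1L
    pos <- hit - c(0L, bounds)[read]
    shift <- sample(3L, length(hit), replace = TRUE)
    by_read <- split(seq_along(hit), read)
    for (r in names(by_read)) {
        i <- as.integer(r)
        chars <- utf8ToInt(seqs[i])
        for (j in by_read[[r]]) {
            code <- match(intToUtf8(chars[pos[j]]), .BASES)
            if (is.na(code)) next  # leave N untouched
            chars[pos[j]] <- utf8ToInt(.BASES[(code - 1L + shift[j]) %% 4L + 1L])
            n_err[i] <- n_err[i] + 1L
        }
        seqs[i] <- intToUtf8(chars)
    }
    list(seqs = seqs, n_errors = n_err)
}

.quality_string <- function(profile, len) {
    intToUtf8(33L + rep_len(profile, len))
}

#' Simulate a genome
#'
#' Draws an i.i.d. nucleotide sequence at the configured GC fraction.
#' For `ploidy = 2` a second haplotype is emitted, differing from the first
#' by Bernoulli(`het_snp_rate`) substitutions. Byte-identical output under
#' a fixed seed.
#'
#' @param config a [simConfig()].
#' @return Character vector of one (haploid) or two (diploid) sequences,
#'   named `hap1` (and `hap2`).
#' @export
simGenome <- function(config) {
    stopifnot(is(config, "SimConfig"))
    .with_seed(config@seed, {
        g <- config@gc_fraction
        prob <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
        hap1 <- paste(sample(.BASES, config@genome_size, replace = TRUE,
                             prob = prob), collapse = "")
        if (config@ploidy == 1L) return(c(hap1 = hap1))
        snp <- which(runif(config@genome_size) < config@het_snp_rate)
        chars <- utf8ToInt(hap1)
        if (length(snp)) {
            old <- match(strsplit(intToUtf8(chars[snp]), "")[[1]], .BASES)
            new <- (old - 1L + sample(3L, length(snp), replace = TRUE)) %% 4L + 1L
            chars[snp] <- utf8ToInt(paste(.BASES[new], collapse = ""))
        }
        c(hap1 = hap1, hap2 = intToUtf8(chars))
    })
}

#' Simulate sequencing reads
#'
#' Uniform start positions over the genome (haplotypes drawn uniformly for
#' diploid input), uniform strands, per-base substitution errors at the
#' configured rate, and constant or per-cycle qualities. The read count is
#' `round(depth * genome_size / read_length / (2 if paired))` (pairs count
#' two reads). Truth records origin coordinates per read or pair.
#'
#' @param genome character vector of haplotype sequences (from
#'   [simGenome()]).
#' @param config a [simConfig()].
#' @param paired simulate read pairs with a normal insert size.
#' @param insert_mean,insert_sd insert-size distribution (paired mode).
#' @param id_prefix prefix for read identifiers.
#' @return Unpaired: list(`reads` = [ReadSet-class], `truth`). Paired:
#'   list(`r1`, `r2`, `truth`).
#' @export
simReads <- function(genome, config, paired = FALSE, insert_mean = 300,
                     insert_sd = 30, id_prefix = "read") {
    stopifnot(is(config, "SimConfig"))
    genome <- unname(genome)
    G <- nchar(genome[1])
    L <- config@read_length
    if (L > G) stop("read_length exceeds the genome size")
    n <- round(config@depth * G / L / (if (paired) 2 else 1))
    .with_seed(config@seed + 1L, {
        hap <- sample(length(genome), n, replace = TRUE)
        if (!paired) {
            start <- sample.int(G - L + 1L, n, replace = TRUE)
            strand <- sample(c("+", "-"), n, replace = TRUE)
            seqs <- substr(genome[hap], start, start + L - 1L)
            seqs[strand == "-"] <- .revcomp(seqs[strand == "-"])
            err <- .add_errors(seqs, config@substitution_error_rate)
            qual <- .quality_string(config@quality_profile, L)
            reads <- new("ReadSet",
                         id = sprintf("%s_%d", id_prefix, seq_len(n)),
                         sequence = err$seqs,
                         quality = rep(qual, n))
            truth <- data.frame(read_id = reads@id,
                                haplotype = hap, start = start,
                                strand = strand, errors = err$n_errors,
                                stringsAsFactors = FALSE)
            return(list(reads = reads, truth = truth))
        }
        ins <- pmin(pmax(round(rnorm(n, insert_mean, insert_sd)), L), G)
        start <- vapply(ins, function(i)
            sample.int(G - i + 1L, 1L), integer(1))
        s1 <- substr(genome[hap], start, start + L - 1L)
        s2 <- .revcomp(substr(genome[hap], start + ins - L, start + ins - 1L))
        e1 <- .add_errors(s1, config@substitution_error_rate)
        e2 <- .add_errors(s2, config@substitution_error_rate)
        qual <- .quality_string(config@quality_profile, L)
        stem <- sprintf("%s_%d", id_prefix, seq_len(n))
        r1 <- new("ReadSet", id = paste0(stem, "/1"), sequence = e1$seqs,
                  quality = rep(qual, n))
        r2 <- new("ReadSet", id = paste0(stem, "/2"), sequence = e2$seqs,
                  quality = rep(qual, n))
        truth <- data.frame(pair_id = stem, haplotype = hap, start = start,
                            insert = ins, errors1 = e1$n_errors,
                            errors2 = e2$n_errors, stringsAsFactors = FALSE)
        list(r1 = r1, r2 = r2, truth = truth)
    })
}

#' Spike contaminant reads into a host read set
#'
#' Adds `round(fraction * n_host / (1 - fraction))` contaminant reads so
#' that the contaminant makes up `fraction` of the output, interleaved by a
#' seeded shuffle (deterministic); with `fraction = 0` the host set is
#' returned unchanged. Truth labels every read by origin.
#'
#' @param host_reads,contaminant_reads [ReadSet-class] objects.
#' @param fraction contaminant fraction of the output, in `[0, 1)`.
#' @param seed shuffle seed.
#' @return list(`reads`, `truth` with `read_id` and `origin`).
#' @export
spikeContaminant <- function(host_reads, contaminant_reads, fraction,
                             seed = 1L) {
    stopifnot(is(host_reads, "ReadSet"), is(contaminant_reads, "ReadSet"),
              fraction >= 0, fraction < 1)
    n_host <- length(host_reads)
    n_c <- round(fraction * n_host / (1 - fraction))
    if (n_c > length(contaminant_reads))
        stop("need ", n_c, " contaminant reads but only ",
             length(contaminant_reads), " are available")
    if (n_c == 0L)
        return(list(reads = host_reads,
                    truth = data.frame(read_id = host_reads@id,
                                       origin = rep("host", n_host),
                                       stringsAsFactors = FALSE)))
    spike <- contaminant_reads[seq_len(n_c)]
    ids <- c(host_reads@id, spike@id)
    seqs <- c(host_reads@sequence, spike@sequence)
    quals <- c(host_reads@quality, spike@quality)
    origin <- c(rep("host", n_host), rep("contaminant", n_c))
    ord <- .with_seed(seed, sample(n_host + n_c))
    list(reads = new("ReadSet", id = ids[ord], sequence = seqs[ord],
                     quality = quals[ord]),
         truth = data.frame(read_id = ids[ord], origin = origin[ord],
                            stringsAsFactors = FALSE))
}

#' Simulate a Nextera-style long-mate-pair library
#'
#' True mate pairs come from a normally distributed fragment (truncated
#' below at twice the read length) that is circularized; the junction
#' point splits the sequenced segment into two arms, and each mate reads
#' its arm into the junction adaptor. A mate whose arm is shorter than the
#' read length contains the adaptor starting exactly at the arm length;
#' a longer arm leaves no adaptor in the read. Arm lengths are drawn so
#' that an in-read junction always shows at least the detector's minimum
#' overlap (`arm <= read_length - min_overlap`): junctions are either
#' absent or detectably present. Artefact pairs (fraction
#' `1 - true_mp_fraction`) are ordinary short-insert paired-end pairs
#' without a junction.
#'
#' @param genome a single genome sequence (character).
#' @param n_pairs number of pairs.
#' @param config a [simConfig()] (read length, seed, error rate,
#'   qualities).
#' @param fragment_mean,fragment_sd circularized-fragment size
#'   distribution.
#' @param true_mp_fraction fraction of genuine mate pairs.
#' @param artefact_insert_mean,artefact_insert_sd artefact (paired-end)
#'   insert distribution.
#' @param adaptor an [adaptorSpec()].
#' @param arm_min,arm_max arm-length range (bases).
#' @return list(`r1`, `r2` ReadSets, `truth` with per-pair category,
#'   junction positions, arm lengths and fragment size).
#' @export
simLmpLibrary <- function(genome, n_pairs, config, fragment_mean = 3000,
                          fragment_sd = 300, true_mp_fraction = 0.8,
                          artefact_insert_mean = 300,
                          artefact_insert_sd = 30,
                          adaptor = adaptorSpec(), arm_min = 25L,
                          arm_max = 180L) {
    stopifnot(is(config, "SimConfig"), length(genome) == 1L)
    genome <- unname(genome)
    G <- nchar(genome)
    RL <- config@read_length
    J <- adaptor@junction
    jl <- nchar(J)
    allowed_arms <- c(seq(arm_min, RL - adaptor@min_overlap),
                      seq(RL, arm_max))
    .with_seed(config@seed + 2L, {
        n_mp <- round(true_mp_fraction * n_pairs)
        is_mp <- sample(c(rep(TRUE, n_mp), rep(FALSE, n_pairs - n_mp)))
        a1 <- ifelse(is_mp, sample(allowed_arms, n_pairs, replace = TRUE),
                     NA_integer_)
        a2 <- ifelse(is_mp, sample(allowed_arms, n_pairs, replace = TRUE),
                     NA_integer_)
        frag <- ifelse(is_mp,
                       pmax(round(rnorm(n_pairs, fragment_mean,
                                        fragment_sd)),
                            2L * RL, a1 + a2),
                       NA_integer_)
        ins <- ifelse(is_mp, NA_integer_,
                      pmin(pmax(round(rnorm(n_pairs, artefact_insert_mean,
                                            artefact_insert_sd)),
                                RL + 10L), G))
        span <- ifelse(is_mp, frag, ins)
        start <- vapply(span, function(w)
            sample.int(G - w + 1L, 1L), integer(1))
        s1 <- character(n_pairs)
        s2 <- character(n_pairs)
        for (i in seq_len(n_pairs)) {
            if (is_mp[i]) {
                Fs <- substr(genome, start[i], start[i] + frag[i] - 1L)
                Fl <- frag[i]
                if (a1[i] < RL) {
                    distal <- max(0L, RL - a1[i] - jl)
                    s1[i] <- substr(paste0(
                        substr(Fs, Fl - a1[i] + 1L, Fl), J,
                        substr(Fs, 1L, distal)), 1L, RL)
                } else {
                    s1[i] <- substr(Fs, Fl - a1[i] + 1L, Fl - a1[i] + RL)
                }
                if (a2[i] < RL) {
                    distal <- max(0L, RL - a2[i] - jl)
                    s2[i] <- substr(paste0(
                        .revcomp(substr(Fs, 1L, a2[i])), J,
                        if (distal > 0L)
                            .revcomp(substr(Fs, Fl - distal + 1L, Fl))
                        else ""), 1L, RL)
                } else {
                    s2[i] <- .revcomp(substr(Fs, a2[i] - RL + 1L, a2[i]))
                }
            } else {
                s1[i] <- substr(genome, start[i], start[i] + RL - 1L)
                s2[i] <- .revcomp(substr(genome, start[i] + ins[i] - RL,
                                         start[i] + ins[i] - 1L))
            }
        }
        e1 <- .add_errors(s1, config@substitution_error_rate)
        e2 <- .add_errors(s2, config@substitution_error_rate)
        qual <- .quality_string(config@quality_profile, RL)
        stem <- sprintf("lmp_%d", seq_len(n_pairs))
        j1 <- ifelse(is_mp & a1 < RL, a1, NA_integer_)
        j2 <- ifelse(is_mp & a2 < RL, a2, NA_integer_)
        category <- ifelse(!is.na(j1) & !is.na(j2), "A",
                    ifelse(is.na(j1) & !is.na(j2), "B",
                    ifelse(!is.na(j1) & is.na(j2), "C", "D")))
        truth <- data.frame(pair_id = stem, is_true_mp = is_mp,
                            category = category, junction1 = j1,
                            junction2 = j2, arm1 = a1, arm2 = a2,
                            fragment_size = frag, artefact_insert = ins,
                            start = start, stringsAsFactors = FALSE)
        list(r1 = new("ReadSet", id = paste0(stem, "/1"),
                      sequence = e1$seqs, quality = rep(qual, n_pairs)),
             r2 = new("ReadSet", id = paste0(stem, "/2"),
                      sequence = e2$seqs, quality = rep(qual, n_pairs)),
             truth = truth)
    })
}

#' Spike PCR duplicates into a paired library
#'
#' Appends `round(fraction * n)` copies of pairs drawn (with replacement)
#' from the library. On a library whose pair signatures are all distinct,
#' [duplicateRate()] then returns exactly
#' `100 * fraction / (1 + fraction)`.
#'
#' @param r1,r2 [ReadSet-class] mates.
#' @param fraction duplicate fraction to add, relative to the library size.
#' @param seed sampling seed.
#' @return list(`r1`, `r2`, `duplicated_from` = source indices).
#' @export
spikeDuplicates <- function(r1, r2, fraction, seed = 1L) {
    stopifnot(is(r1, "ReadSet"), is(r2, "ReadSet"),
              length(r1) == length(r2), fraction >= 0)
    n <- length(r1)
    n_dup <- round(fraction * n)
    if (n_dup == 0L) return(list(r1 = r1, r2 = r2,
                                 duplicated_from = integer()))
    idx <- .with_seed(seed, sample.int(n, n_dup, replace = TRUE))
    dup_ids <- sprintf("%s_dup%d", sub("/[12]$", "", r1@id[idx]),
                       seq_len(n_dup))
    grow <- function(rs, suffix) new("ReadSet",
        id = c(rs@id, paste0(dup_ids, suffix)),
        sequence = c(rs@sequence, rs@sequence[idx]),
        quality = c(rs@quality, rs@quality[idx]))
    list(r1 = grow(r1, "/1"), r2 = grow(r2, "/2"), duplicated_from = idx)
}

#' Simulate offset inline-barcoded (RAD-style) reads
#'
#' Each read is `offset filler bases + barcode + overhang + genomic
#' sequence` drawn from one of `locus_count` fixed restriction loci, with
#' the offset drawn uniformly from the sample's allowed set and samples
#' drawn uniformly. Optional per-read barcode errors mutate bases inside
#' the barcode only; the configured substitution rate applies to the
#' genomic portion.
#'
#' @param genome a single genome sequence.
#' @param specs sample sheet from [barcodeSpecs()].
#' @param locus_count number of restriction loci.
#' @param n_reads reads to emit.
#' @param config a [simConfig()].
#' @param barcode_errors substitutions to place inside each read's barcode
#'   (default 0).
#' @return list(`reads`, `truth` with `read_id`, `sample`, `offset`,
#'   `locus`).
#' @export
simRadReads <- function(genome, specs, locus_count, n_reads, config,
                        barcode_errors = 0L) {
    stopifnot(is(config, "SimConfig"), length(genome) == 1L)
    genome <- unname(genome)
    G <- nchar(genome)
    RL <- config@read_length
    offsets <- attr(specs, "offsets")
    oh <- specs$overhang[1]
    .with_seed(config@seed + 3L, {
        glen_max <- RL - min(unlist(offsets)) - min(nchar(specs$barcode)) -
            nchar(oh)
        loci <- sample.int(G - glen_max + 1L, locus_count)
        srow <- sample.int(nrow(specs), n_reads, replace = TRUE)
        offset <- vapply(srow, function(s) {
            o <- offsets[[s]]
            o[sample.int(length(o), 1L)]
        }, integer(1))
        locus <- sample.int(locus_count, n_reads, replace = TRUE)
        bc <- specs$barcode[srow]
        glen <- RL - offset - nchar(bc) - nchar(oh)
        genomic <- substr(genome, loci[locus], loci[locus] + glen - 1L)
        genomic <- .add_errors(genomic, config@substitution_error_rate)$seqs
        if (barcode_errors > 0L) {
            for (i in seq_len(n_reads)) {
                chars <- utf8ToInt(bc[i])
                pos <- sample.int(length(chars), barcode_errors)
                old <- match(strsplit(intToUtf8(chars[pos]), "")[[1]],
                             .BASES)
                new <- (old - 1L +
                        sample(3L, length(pos), replace = TRUE)) %% 4L + 1L
                chars[pos] <- utf8ToInt(paste(.BASES[new], collapse = ""))
                bc[i] <- intToUtf8(chars)
            }
        }
        filler <- vapply(offset, function(o)
            paste(sample(.BASES, o, replace = TRUE), collapse = ""),
            character(1))
        seqs <- paste0(filler, bc, oh, genomic)
        qual <- vapply(nchar(seqs), function(L)
            .quality_string(config@quality_profile, L), character(1))
        ids <- sprintf("rad_%d", seq_len(n_reads))
        list(reads = new("ReadSet", id = ids, sequence = seqs,
                         quality = qual),
             truth = data.frame(read_id = ids,
                                sample = specs$sample[srow],
                                offset = offset, locus = locus,
                                stringsAsFactors = FALSE))
    })
}
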