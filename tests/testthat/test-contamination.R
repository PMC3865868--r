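ref_seq <- random_dna(2000, 501)
ref_tab <- buildReferenceTable(c(ref = ref_seq), k = 21)

test_that("reference tables cover the expected distinct kmers", {
    one <- buildReferenceTable(c(x = random_dna(100, 77)), k = 21)
    expect_equal(length(one), 80L)  # L - k + 1 for a repeat-free sequence
    homo <- buildReferenceTable(c(x = strrep("A", 100)), k = 21)
    expect_equal(length(homo), 1L)
    both <- buildReferenceTable(
        c(x = ref_seq, y = oracle_revcomp(ref_seq)), k = 21)
    expect_identical(both@kmer, ref_tab@kmer)
    expect_error(buildReferenceTable(c(x = ""), 21), "no sequence")
})

test_that("reads drawn from the reference all hit; tiling covers it fully", {
    starts <- seq(1, 2000 - 100 + 1, by = 20)
    reads <- substring(ref_seq, starts, starts + 99)
    rep <- screenReads(reads, ref_tab, subsample = NULL)
    expect_equal(rep@reads_with_hit_pct, 100)
    expect_equal(rep@ref_covered_pct, 100)
    expect_equal(rep@reads_with_hit, rep@reads_screened)
})

test_that("unrelated random sequences barely collide at k=21", {
    other <- vapply(1:200, function(i) random_dna(100, 9000 + i), "")
    rep <- screenReads(other, ref_tab, subsample = NULL)
    expect_lt(rep@reads_with_hit_pct, 1)
    expect_lt(rep@ref_covered_pct, 1)
})

test_that("screen interpretation follows the two-threshold rule", {
    mk <- function(hit, cov) new("ScreenReport", reference_name = "r",
        k = 21L, reads_screened = 1000, reads_with_hit = 10 * hit,
        reads_with_hit_pct = hit, ref_kmers_total = 10000,
        ref_kmers_observed = 100 * cov, ref_covered_pct = cov,
        subsample_fraction = 1)
    expect_equal(interpretScreen(mk(40, 85)), "true_contamination")
    ## the shared-kmers signature: many reads hit, little of the genome seen
    expect_equal(interpretScreen(mk(12, 0.8)), "shared_kmers_only")
    expect_equal(interpretScreen(mk(0.1, 0.05)), "clean")
})

test_that("filtering partitions totally and modes are symmetric", {
    clean <- ReadSet(sprintf("c%d", 1:50),
                     vapply(1:50, function(i) random_dna(100, 600 + i), ""))
    fr <- filterReads(clean, ref_tab, mode = "discard_hits")
    expect_equal(length(fr$removed), 0L)
    expect_equal(length(fr$kept), 50L)

    hits <- ReadSet(sprintf("h%d", 1:20),
                    substring(ref_seq, seq(1, 951, by = 50),
                              seq(100, 1050, by = 50)))
    all_reads <- ReadSet(c(readIds(clean), readIds(hits)),
                         c(sequences(clean), sequences(hits)))
    fd <- filterReads(all_reads, ref_tab, mode = "discard_hits")
    fk <- filterReads(all_reads, ref_tab, mode = "keep_hits")
    expect_setequal(readIds(fd$removed), readIds(hits))
    expect_identical(readIds(fk$kept), readIds(fd$removed))
    expect_identical(readIds(fk$removed), readIds(fd$kept))
    expect_equal(fd$summary$kept + fd$summary$removed, length(all_reads))
})

test_that("paired filtering removes the whole pair when either mate hits", {
    r1 <- ReadSet(c("p1/1", "p2/1"),
                  c(substr(ref_seq, 1, 100), random_dna(100, 700)))
    r2 <- ReadSet(c("p1/2", "p2/2"),
                  c(random_dna(100, 701), random_dna(100, 702)))
    fr <- filterReads(r1, ref_tab, mode = "discard_hits", r2 = r2)
    expect_equal(readIds(fr$removed$r1), "p1/1")
    expect_equal(readIds(fr$removed$r2), "p1/2")
    expect_equal(readIds(fr$kept$r1), "p2/1")
})

test_that("reference coverage is monotone in depth on nested read sets", {
    cfg <- simConfig(seed = 77, genome_size = 20000, depth = 6,
                     read_length = 100)
    g <- simGenome(cfg)
    tab <- buildReferenceTable(c(g = g[1]), 21)
    reads <- simReads(g, cfg)$reads
    cov <- vapply(c(200, 600, 1200), function(n)
        screenReads(reads[seq_len(n)], tab, subsample = NULL)@ref_covered_pct,
        numeric(1))
    expect_true(all(diff(cov) >= 0))
})

test_that("screening errors on an empty sample", {
    expect_error(screenReads(character(), ref_tab, subsample = NULL),
                 "no reads")
})
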